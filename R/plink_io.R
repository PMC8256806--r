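# PLINK 1 binary trio (.bed/.bim/.fam) reader/writer.
#
# .bed layout: 3 header bytes (0x6c, 0x1b, 0x01 = SNP-major), then for each
# SNP ceil(n_samples/4) bytes; each byte packs 4 genotypes, first sample in
# the two LOWEST-order bits. 2-bit codes: 00 = hom allele1 (dosage 0),
# 01 = missing, 10 = het (dosage 1), 11 = hom allele2 (dosage 2).

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b))
PLINK_SNP_MAJOR <- as.raw(0x01)

# 256 x 4 lookup: dosage of sample k (k = 1..4) for each byte value
.plink_decode_lut <- local({
  code2dos <- c(0L, NA_integer_, 1L, 2L)  # codes 0b00,0b01,0b10,0b11
  lut <- matrix(NA_integer_, nrow = 256L, ncol = 4L)
  for (b in 0:255) {
    lut[b + 1L, ] <- code2dos[bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L) + 1L]
  }
  lut
})

#' Read a PLINK 1 binary genotype set
#'
#' Parses the `.bed`/`.bim`/`.fam` trio at `prefix` into a
#' [genotype_dataset()]. Dosages count copies of allele2 (the .bim A2 /
#' second allele column here is `allele2`). The population label of each
#' sample is taken from the .fam family-ID column unless a
#' `sample_id -> population` mapping is supplied.
#'
#' Only autosomal biallelic SNPs are retained: SNPs on non-numeric
#' chromosomes are dropped with a message. SNPs are sorted by
#' (chrom, pos_bp) after loading.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @param pop_map optional data.frame (sample_id, population) or path to a
#'   two-column TSV overriding the .fam family-ID labels.
#' @return a `genotype_dataset`
#' @export
read_plink <- function(prefix, pop_map = NULL) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("missing file: ", p)

  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 2L) stop(".fam must have >= 2 columns")
  samples <- data.frame(sample_id = fam[[2L]], population = fam[[1L]],
                        stringsAsFactors = FALSE)

  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer",
                                          "character", "character"))
  snps <- data.frame(snp_id = bim[[2L]], chrom = bim[[1L]],
                     pos_bp = bim[[4L]], allele1 = bim[[5L]],
                     allele2 = bim[[6L]], stringsAsFactors = FALSE)

  n_samples <- nrow(samples)
  n_snps <- nrow(snps)
  bpsnp <- ceiling(n_samples / 4)
  expected <- 3 + bpsnp * n_snps

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:2], PLINK_MAGIC))
    stop(".bed format error: bad magic bytes at offset 0-1 (expected 6c 1b, ",
         "got ", paste(format(raw[seq_len(min(2, length(raw)))]),
                       collapse = " "), ")")
  if (raw[3L] != PLINK_SNP_MAJOR)
    stop(".bed format error: mode byte at offset 2 is ", format(raw[3L]),
         ", expected 01 (SNP-major)")
  if (length(raw) != expected)
    stop(".bed size mismatch: got ", length(raw), " bytes, expected ",
         expected, " = 3 + ceil(", n_samples, "/4) x ", n_snps)

  body <- as.integer(raw[-(1:3)])
  # decode all bytes at once, then trim each SNP's padding samples
  dec <- .plink_decode_lut[body + 1L, , drop = FALSE]  # (bpsnp*n_snps) x 4
  # row-block j holds SNP j; within a block, bytes x 4 sample slots
  dos <- matrix(NA_integer_, nrow = n_samples, ncol = n_snps)
  slot <- matrix(t(dec), nrow = 4L * bpsnp)  # (4*bpsnp) x n_snps
  dos[] <- slot[seq_len(n_samples), , drop = FALSE]

  ds <- genotype_dataset(dos, snps, samples)
  ds <- apply_pop_map(ds, pop_map)
  ds <- drop_nonautosomal(ds)
  sort_dataset(ds)
}

apply_pop_map <- function(dataset, pop_map) {
  if (is.null(pop_map)) return(dataset)
  if (is.character(pop_map) && length(pop_map) == 1L) {
    pop_map <- utils::read.table(pop_map, header = FALSE, sep = "\t",
                                 colClasses = "character")
  }
  pop_map <- as.data.frame(pop_map, stringsAsFactors = FALSE)
  names(pop_map)[1:2] <- c("sample_id", "population")
  idx <- match(dataset$samples$sample_id, pop_map$sample_id)
  hit <- !is.na(idx)
  dataset$samples$population[hit] <- pop_map$population[idx[hit]]
  dataset
}

drop_nonautosomal <- function(dataset) {
  num <- suppressWarnings(as.numeric(dataset$snps$chrom))
  keep <- !is.na(num) & num >= 1
  if (!all(keep)) {
    message("dropping ", sum(!keep), " SNP(s) on non-autosomal chromosomes")
    dataset <- subset_dataset(dataset, snps = which(keep))
  }
  dataset
}

sort_dataset <- function(dataset) {
  num <- suppressWarnings(as.numeric(dataset$snps$chrom))
  ord <- order(num, dataset$snps$chrom, dataset$snps$pos_bp)
  if (is.unsorted(ord)) dataset <- subset_dataset(dataset, snps = ord)
  dataset
}

#' Write a genotype dataset as a PLINK 1 binary trio
#'
#' Emits SNP-major `.bed` (pad bits zero), six-column `.bim`
#' (chrom, id, 0 cM, pos, allele1, allele2) and `.fam` with the population
#' label in the family-ID column, so that `read_plink(prefix)` returns the
#' input dataset.
#'
#' @param dataset a `genotype_dataset`
#' @param prefix output path prefix
#' @return `prefix`, invisibly
#' @export
write_plink <- function(dataset, prefix) {
  validate_genotype_dataset(dataset)
  d <- dataset$dosages
  n_samples <- nrow(d)
  n_snps <- ncol(d)
  bpsnp <- ceiling(n_samples / 4)

  # dosage -> 2-bit code; NA -> 01
  dos2code <- function(x) {
    code <- integer(length(x))
    code[is.na(x)] <- 1L
    code[!is.na(x) & x == 1L] <- 2L
    code[!is.na(x) & x == 2L] <- 3L
    code
  }
  codes <- matrix(0L, nrow = 4L * bpsnp, ncol = n_snps)  # pad slots code 00
  codes[seq_len(n_samples), ] <- dos2code(d)
  k <- matrix(codes, nrow = 4L)  # 4 x (bpsnp * n_snps), column = one byte
  bytes <- k[1L, ] + bitwShiftL(k[2L, ], 2L) + bitwShiftL(k[3L, ], 4L) +
    bitwShiftL(k[4L, ], 6L)

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(c(PLINK_MAGIC, PLINK_SNP_MAJOR), con)
  writeBin(as.raw(bytes), con)

  bim <- data.frame(dataset$snps$chrom, dataset$snps$snp_id, 0L,
                    dataset$snps$pos_bp, dataset$snps$allele1,
                    dataset$snps$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(dataset$samples$population, dataset$samples$sample_id,
                    0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
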