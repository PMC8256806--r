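#' Construct a genotype dataset
#'
#' The central container of the package: a samples x SNPs matrix of diploid
#' allele2 dosages (0, 1, 2 or `NA` for missing) together with a SNP map and
#' per-sample population labels. All downstream statistics (allele
#' frequencies, GRM, f-statistics, FST/FLK scans) consume this object.
#'
#' @param dosages integer matrix, samples x SNPs, values in \{0, 1, 2, NA\};
#'   `NA` is the missing-genotype sentinel (never 0, which is a legal
#'   homozygote).
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos_bp` (1-based,
#'   as in a PLINK .bim), `allele1`, `allele2`; one row per column of
#'   `dosages`, sorted by (chrom, pos_bp).
#' @param samples data.frame with columns `sample_id` and `population`
#'   (non-empty labels); one row per row of `dosages`.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, snps, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  obj <- structure(
    list(dosages = dosages, snps = snps, samples = samples),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(obj)
  obj
}

validate_genotype_dataset <- function(x) {
  stopifnot(inherits(x, "genotype_dataset"))
  d <- x$dosages
  if (nrow(d) != nrow(x$samples))
    stop("dosage rows (", nrow(d), ") != number of samples (",
         nrow(x$samples), ")")
  if (ncol(d) != nrow(x$snps))
    stop("dosage columns (", ncol(d), ") != number of SNPs (",
         nrow(x$snps), ")")
  need_snp <- c("snp_id", "chrom", "pos_bp", "allele1", "allele2")
  if (!all(need_snp %in% names(x$snps)))
    stop("snps table must have columns: ", paste(need_snp, collapse = ", "))
  if (!all(c("sample_id", "population") %in% names(x$samples)))
    stop("samples table must have columns sample_id, population")
  bad <- d[!is.na(d)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(x$snps$snp_id))
    stop("snp_ids must be unique")
  if (any(!nzchar(x$samples$population)) || anyNA(x$samples$population))
    stop("population labels must be non-empty")
  if (any(x$snps$pos_bp < 1L))
    stop("pos_bp must be >= 1")
  if (any(x$snps$allele1 == x$snps$allele2))
    stop("allele1 must differ from allele2")
  invisible(x)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "samples x", nrow(x$snps),
      "SNPs\n")
  tab <- table(x$samples$population)
  cat("populations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  nm <- sum(is.na(x$dosages))
  cat(sprintf("missing genotypes: %d (%.4f%%)\n", nm,
              100 * nm / length(x$dosages)))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

#' Subset a genotype dataset by sample and/or SNP index
#'
#' @param dataset a `genotype_dataset`
#' @param samples integer or logical index over samples (rows)
#' @param snps integer or logical index over SNPs (columns)
#' @return the subset `genotype_dataset`
#' @export
subset_dataset <- function(dataset, samples = NULL, snps = NULL) {
  d <- dataset$dosages
  si <- if (is.null(samples)) seq_len(nrow(d)) else samples
  vi <- if (is.null(snps)) seq_len(ncol(d)) else snps
  genotype_dataset(
    d[si, vi, drop = FALSE],
    dataset$snps[vi, , drop = FALSE],
    dataset$samples[si, , drop = FALSE]
  )
}

#' Relabel populations (e.g. to merge farms into contrast groups)
#'
#' @param dataset a `genotype_dataset`
#' @param mapping named character vector: old label -> new label. Labels not
#'   in `mapping` are kept unchanged.
#' @return a `genotype_dataset` with rewritten population labels
#' @export
relabel_populations <- function(dataset, mapping) {
  pop <- dataset$samples$population
  hit <- pop %in% names(mapping)
  pop[hit] <- unname(mapping[pop[hit]])
  out <- dataset
  out$samples$population <- pop
  out
}
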