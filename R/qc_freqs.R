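#' Quality-control filtering of a genotype dataset
#'
#' Filters are applied in a fixed order: (1) SNPs with call rate below
#' `min_snp_call_rate` are removed; (2) samples with call rate below
#' `min_sample_call_rate` on the surviving SNPs are removed; (3) SNPs with
#' minor allele frequency below `min_maf` on the surviving samples are
#' removed. The report counts removals per step and the overall genotyping
#' rate (non-missing cells / total cells) of the final set.
#'
#' @param dataset a `genotype_dataset`
#' @param min_snp_call_rate,min_sample_call_rate,min_maf thresholds in [0,1].
#'   Defaults follow conventional SNP-array practice (0.90 / 0.90 / 0.01).
#' @return list with elements `dataset` (filtered `genotype_dataset`) and
#'   `report` (class `qc_report`).
#' @export
qc_filter <- function(dataset, min_snp_call_rate = 0.90,
                      min_sample_call_rate = 0.90, min_maf = 0.01) {
  stopifnot(min_snp_call_rate >= 0, min_snp_call_rate <= 1,
            min_sample_call_rate >= 0, min_sample_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  d <- dataset$dosages
  n_snps_in <- ncol(d)
  n_samples_in <- nrow(d)

  snp_cr <- colMeans(!is.na(d))
  keep_snp <- snp_cr >= min_snp_call_rate
  n_snp_callrate_removed <- sum(!keep_snp)
  d2 <- d[, keep_snp, drop = FALSE]

  sample_cr <- rowMeans(!is.na(d2))
  keep_sample <- sample_cr >= min_sample_call_rate
  n_sample_callrate_removed <- sum(!keep_sample)
  d3 <- d2[keep_sample, , drop = FALSE]

  maf <- function(m) {
    p <- colMeans(m, na.rm = TRUE) / 2
    pmin(p, 1 - p)
  }
  mafs <- maf(d3)
  keep_maf <- !is.na(mafs) & mafs >= min_maf
  n_maf_removed <- sum(!keep_maf)

  out <- subset_dataset(dataset,
                        samples = which(keep_sample),
                        snps = which(keep_snp)[keep_maf])
  if (ncol(out$dosages) == 0L)
    stop("QC removed all SNPs: nothing left to analyze")

  report <- structure(list(
    n_snps_in = n_snps_in, n_snps_out = ncol(out$dosages),
    n_samples_in = n_samples_in, n_samples_out = nrow(out$dosages),
    n_snp_callrate_removed = n_snp_callrate_removed,
    n_sample_callrate_removed = n_sample_callrate_removed,
    n_maf_removed = n_maf_removed,
    genotyping_rate = mean(!is.na(out$dosages)),
    thresholds = c(min_snp_call_rate = min_snp_call_rate,
                   min_sample_call_rate = min_sample_call_rate,
                   min_maf = min_maf)
  ), class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  SNPs:    %d in -> %d out (%d call-rate, %d MAF)\n",
              x$n_snps_in, x$n_snps_out, x$n_snp_callrate_removed,
              x$n_maf_removed))
  cat(sprintf("  samples: %d in -> %d out (%d call-rate)\n",
              x$n_samples_in, x$n_samples_out, x$n_sample_callrate_removed))
  cat(sprintf("  total genotyping rate: %.6f\n", x$genotyping_rate))
  invisible(x)
}

#' Per-population allele frequencies
#'
#' Computes, for every population label and SNP, the allele2 frequency among
#' non-missing genotypes and the haploid sample size (2 x genotyped
#' diploids). Frequencies where a population has zero non-missing calls are
#' `NA` (undefined), never 0.
#'
#' @param dataset a `genotype_dataset`
#' @return object of class `pop_freqs`: list with `populations` (labels),
#'   `freqs` (populations x SNPs matrix in [0,1] or NA), `n_hap`
#'   (populations x SNPs matrix of haploid counts), and `snps` (the SNP map).
#' @export
allele_frequencies <- function(dataset) {
  validate_genotype_dataset(dataset)
  pops <- unique(dataset$samples$population)
  d <- dataset$dosages
  nf <- length(pops)
  freqs <- matrix(NA_real_, nrow = nf, ncol = ncol(d),
                  dimnames = list(pops, dataset$snps$snp_id))
  n_hap <- matrix(0L, nrow = nf, ncol = ncol(d),
                  dimnames = dimnames(freqs))
  for (i in seq_along(pops)) {
    rows <- dataset$samples$population == pops[i]
    sub <- d[rows, , drop = FALSE]
    n_called <- colSums(!is.na(sub))
    s <- colSums(sub, na.rm = TRUE)
    n_hap[i, ] <- 2L * n_called
    ok <- n_called > 0L
    freqs[i, ok] <- s[ok] / (2 * n_called[ok])
  }
  structure(list(populations = pops, freqs = freqs, n_hap = n_hap,
                 snps = dataset$snps),
            class = "pop_freqs")
}

#' Build a `pop_freqs` object directly from frequency matrices
#'
#' Mainly for working with simulator ground truth (realized leaf
#' frequencies) or externally computed frequency tables.
#'
#' @param freqs populations x SNPs matrix of allele2 frequencies
#' @param n_hap matching matrix of haploid counts (scalar recycled)
#' @param snps optional SNP map data.frame (snp_id, chrom, pos_bp)
#' @return a `pop_freqs` object
#' @export
pop_freqs <- function(freqs, n_hap, snps = NULL) {
  freqs <- as.matrix(freqs)
  if (length(n_hap) == 1L)
    n_hap <- matrix(as.integer(n_hap), nrow(freqs), ncol(freqs),
                    dimnames = dimnames(freqs))
  if (is.null(rownames(freqs)))
    rownames(freqs) <- paste0("pop", seq_len(nrow(freqs)))
  if (is.null(snps))
    snps <- data.frame(snp_id = paste0("snp", seq_len(ncol(freqs))),
                       chrom = "1", pos_bp = seq_len(ncol(freqs)),
                       stringsAsFactors = FALSE)
  structure(list(populations = rownames(freqs), freqs = freqs,
                 n_hap = as.matrix(n_hap), snps = snps),
            class = "pop_freqs")
}

#' @export
print.pop_freqs <- function(x, ...) {
  cat("pop_freqs:", length(x$populations), "populations x",
      ncol(x$freqs), "SNPs\n")
  cat("populations:", paste(x$populations, collapse = ", "), "\n")
  invisible(x)
}
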