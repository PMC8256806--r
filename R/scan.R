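# End-to-end selection scan: FST contrast between two groups of
# populations, plus the multi-population FLK test with q-value FDR, and
# the intersection of SNPs flagged by both methods.

#' Default scan configuration
#'
#' @param window_snps smoothing window (odd number of SNPs)
#' @param quantile smoothed-FST flagging quantile
#' @param max_gap_snps gap tolerance when merging flagged SNPs into regions
#' @param fdr FLK q-value significance cut-off
#' @param estimator FST estimator, "wc" or "plain"
#' @param block_size_snps jackknife block size (f-statistics)
#' @return named list of options
#' @export
scan_config <- function(window_snps = 9, quantile = 0.95, max_gap_snps = 2,
                        fdr = 0.15, estimator = "wc",
                        block_size_snps = 500) {
  list(window_snps = window_snps, quantile = quantile,
       max_gap_snps = max_gap_snps, fdr = fdr, estimator = estimator,
       block_size_snps = block_size_snps)
}

#' Run a selection scan
#'
#' Two detection routes are combined:
#' \itemize{
#'   \item FST route: the populations in `focal` are pooled into one group
#'     and those in `rest` into another; per-SNP Weir-Cockerham FST between
#'     the two groups is smoothed over a sliding window and regions above
#'     the `quantile` threshold are called.
#'   \item FLK route: per-population frequencies (all populations except
#'     the outgroup) are tested for excess differentiation against the
#'     kinship matrix estimated with `build_kinship()` (outgroup used for
#'     rooting only); p-values are converted to Storey q-values and SNPs at
#'     q <= `fdr` are flagged.
#' }
#' The returned `both_snps` is the intersection of SNPs inside called FST
#' regions with FLK-significant SNPs.
#'
#' @param dataset a `genotype_dataset`
#' @param focal character vector of focal population labels (FST group A)
#' @param rest character vector of comparison populations (FST group B);
#'   default: all non-focal, non-outgroup populations
#' @param outgroup outgroup label for kinship rooting, or `NULL` to skip
#'   the FLK route
#' @param config a [scan_config()] list
#' @param kinship optional precomputed `kinship_f` (or true F matrix),
#'   bypassing estimation
#' @return object of class `scan_result`: list with `scan` (per-SNP table:
#'   snp_id, chrom, pos_bp, fst, smoothed_fst, flk, flk_p, flk_q),
#'   `fst_regions`, `fst_threshold`, `flk_snps`, `both_snps`, `config`
#' @export
run_scan <- function(dataset, focal, rest = NULL, outgroup = NULL,
                     config = scan_config(), kinship = NULL) {
  pops <- unique(dataset$samples$population)
  if (!all(focal %in% pops))
    stop("[fst] focal populations not in dataset: ",
         paste(setdiff(focal, pops), collapse = ", "))
  if (is.null(rest)) rest <- setdiff(pops, c(focal, outgroup))
  if (!length(rest)) stop("[fst] no comparison populations left")

  # FST route: two pooled groups
  mapping <- c(stats::setNames(rep("groupA", length(focal)), focal),
               stats::setNames(rep("groupB", length(rest)), rest))
  two <- relabel_populations(
    subset_dataset(dataset,
                   samples = which(dataset$samples$population %in%
                                     c(focal, rest))),
    mapping)
  freqs2 <- allele_frequencies(two)
  fst <- per_snp_fst(freqs2, estimator = config$estimator)
  snps <- dataset$snps
  sm <- smooth_fst(fst, snps$chrom, snps$pos_bp, config$window_snps)
  regions <- call_fst_regions(sm, snps$chrom, snps$pos_bp,
                              quantile = config$quantile,
                              max_gap_snps = config$max_gap_snps)
  fst_flagged <- attr(regions, "flagged")
  in_region <- snps_in_regions(snps, regions)

  # FLK route
  flk_stat <- rep(NA_real_, nrow(snps))
  flk_p <- rep(NA_real_, nrow(snps))
  flk_q <- rep(NA_real_, nrow(snps))
  flk_snps <- character(0)
  if (!is.null(outgroup) || !is.null(kinship)) {
    freqs_all <- allele_frequencies(dataset)
    if (is.null(kinship))
      kinship <- build_kinship(freqs_all, outgroup)
    ft <- flk(freqs_all, kinship)
    flk_stat <- ft$flk
    flk_p <- ft$p_value
    ok <- !is.na(flk_p)
    if (any(ok)) flk_q[ok] <- qvalues(flk_p[ok])
    flk_sig <- !is.na(flk_q) & flk_q <= config$fdr
    flk_snps <- snps$snp_id[flk_sig]
  }

  scan <- data.frame(snp_id = snps$snp_id, chrom = snps$chrom,
                     pos_bp = snps$pos_bp,
                     fst = pmax(fst, 0),  # display clamp; raw kept below
                     fst_raw = fst, smoothed_fst = sm,
                     flk = flk_stat, flk_p = flk_p, flk_q = flk_q,
                     stringsAsFactors = FALSE)
  both <- intersect(snps$snp_id[in_region], flk_snps)
  structure(list(scan = scan, fst_regions = regions,
                 fst_threshold = attr(regions, "threshold"),
                 fst_flagged_snps = snps$snp_id[fst_flagged],
                 fst_region_snps = snps$snp_id[in_region],
                 flk_snps = flk_snps, both_snps = both,
                 focal = focal, rest = rest, outgroup = outgroup,
                 kinship = kinship, config = config),
            class = "scan_result")
}

snps_in_regions <- function(snps, regions) {
  hit <- rep(FALSE, nrow(snps))
  for (k in seq_len(nrow(regions))) {
    hit <- hit | (snps$chrom == regions$chrom[k] &
                    snps$pos_bp >= regions$start_bp[k] &
                    snps$pos_bp <= regions$end_bp[k])
  }
  hit
}

#' @export
print.scan_result <- function(x, ...) {
  cat("selection scan:", paste(x$focal, collapse = "+"), "vs",
      paste(x$rest, collapse = "+"), "\n")
  cat(sprintf("  FST: %d region(s) above the %.0fth quantile (threshold %.4g)\n",
              nrow(x$fst_regions), 100 * x$config$quantile,
              x$fst_threshold))
  if (length(x$flk_snps) || any(!is.na(x$scan$flk)))
    cat(sprintf("  FLK: %d SNP(s) at q <= %.2f; %d flagged by both methods\n",
                length(x$flk_snps), x$config$fdr, length(x$both_snps)))
  invisible(x)
}

#' One-vs-rest scans for every focal population
#'
#' Mirrors the per-farm design: each population in `populations` is
#' contrasted with the remaining ones pooled.
#'
#' @param dataset a `genotype_dataset`
#' @param populations populations to scan (default: all except `outgroup`)
#' @param outgroup optional outgroup (excluded from contrasts; enables FLK)
#' @param config a [scan_config()]
#' @return named list of `scan_result`, one per focal population
#' @export
run_scan_one_vs_rest <- function(dataset, populations = NULL,
                                 outgroup = NULL, config = scan_config()) {
  pops <- unique(dataset$samples$population)
  if (is.null(populations)) populations <- setdiff(pops, outgroup)
  out <- lapply(populations, function(p)
    run_scan(dataset, focal = p, rest = setdiff(populations, p),
             outgroup = outgroup, config = config))
  names(out) <- populations
  out
}
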