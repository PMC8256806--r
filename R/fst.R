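# Per-SNP FST, sliding-window smoothing, and 95th-quantile region calling.

#' Per-SNP FST across populations
#'
#' Default estimator is the Weir-Cockerham ANOVA theta on allele counts
#' (sample-size corrected, valid for any number of populations with unequal
#' sizes). With haploid counts n_i and allele2 frequencies p_i over r
#' populations:
#'   MSP = sum n_i (p_i - pbar)^2 / (r - 1)    (between populations)
#'   MSG = sum n_i p_i (1 - p_i) / (n - r)     (within populations)
#'   nc  = (n - sum n_i^2 / n) / (r - 1)
#'   theta = (MSP - MSG) / (MSP + (nc - 1) MSG)
#' The "plain" estimator is the uncorrected variance ratio
#' var(p_i) / (pbar (1 - pbar)) with unweighted mean and population
#' variance (divides by r), which equals 1 for a fixed difference.
#'
#' Raw values are returned unclamped (Weir-Cockerham theta can be slightly
#' negative); SNPs monomorphic in the pooled sample or with fewer than two
#' informative populations are `NA` and excluded downstream.
#'
#' @param freqs a `pop_freqs` with >= 2 populations
#' @param estimator "wc" (default) or "plain"
#' @return numeric vector, one value per SNP
#' @export
per_snp_fst <- function(freqs, estimator = c("wc", "plain")) {
  estimator <- match.arg(estimator)
  P <- freqs$freqs
  N <- freqs$n_hap
  if (nrow(P) < 2L)
    stop("FST needs >= 2 populations")
  ok <- !is.na(P) & N > 0
  r <- colSums(ok)
  P0 <- ifelse(ok, P, 0)
  N0 <- ifelse(ok, N, 0)
  n_tot <- colSums(N0)
  pbar_w <- colSums(N0 * P0) / n_tot

  if (estimator == "plain") {
    pbar <- colSums(P0) / r
    v <- colSums(ok * (P0 - rep(pbar, each = nrow(P0)))^2) / r
    den <- pbar * (1 - pbar)
    fst <- ifelse(den > 0, v / den, NA_real_)
  } else {
    msp <- colSums(N0 * (P0 - rep(pbar_w, each = nrow(P0)))^2) / (r - 1)
    msg_num <- colSums(N0 * P0 * (1 - P0))
    msg <- msg_num / (n_tot - r)
    nc <- (n_tot - colSums(N0^2) / n_tot) / (r - 1)
    den <- msp + (nc - 1) * msg
    fst <- ifelse(den > 0, (msp - msg) / den, NA_real_)
    # pooled-monomorphic SNPs carry no differentiation information
    fst[pbar_w <= 0 | pbar_w >= 1] <- NA_real_
  }
  fst[r < 2] <- NA_real_
  unname(fst)
}

#' Weir-Cockerham variance components for one SNP (exposed for checking)
#'
#' @param p vector of allele2 frequencies per population
#' @param n vector of haploid counts per population
#' @return list(msp, msg, nc, theta)
#' @export
wc_components <- function(p, n) {
  r <- length(p)
  stopifnot(r >= 2L, length(n) == r)
  n_tot <- sum(n)
  pbar <- sum(n * p) / n_tot
  msp <- sum(n * (p - pbar)^2) / (r - 1)
  msg <- sum(n * p * (1 - p)) / (n_tot - r)
  nc <- (n_tot - sum(n^2) / n_tot) / (r - 1)
  den <- msp + (nc - 1) * msg
  list(msp = msp, msg = msg, nc = nc,
       theta = if (den > 0) (msp - msg) / den else NA_real_)
}

#' Genome-wide multi-locus Weir-Cockerham FST
#'
#' The standard multi-locus estimator: variance components are summed over
#' SNPs before taking the ratio,
#' sum_l (MSP_l - MSG_l) / sum_l (MSP_l + (nc_l - 1) MSG_l), which is far
#' less biased than averaging per-SNP ratios.
#'
#' @param freqs a `pop_freqs`
#' @return scalar FST estimate
#' @export
mean_fst <- function(freqs) {
  P <- freqs$freqs
  N <- freqs$n_hap
  if (nrow(P) < 2L) stop("FST needs >= 2 populations")
  ok <- !is.na(P) & N > 0
  r <- colSums(ok)
  P0 <- ifelse(ok, P, 0)
  N0 <- ifelse(ok, N, 0)
  n_tot <- colSums(N0)
  pbar <- colSums(N0 * P0) / n_tot
  msp <- colSums(N0 * (P0 - rep(pbar, each = nrow(P0)))^2) / (r - 1)
  msg <- colSums(N0 * P0 * (1 - P0)) / (n_tot - r)
  nc <- (n_tot - colSums(N0^2) / n_tot) / (r - 1)
  use <- r >= 2 & pbar > 0 & pbar < 1
  sum(msp[use] - msg[use]) /
    sum(msp[use] + (nc[use] - 1) * msg[use])
}

#' Sliding-window smoothing of a per-SNP statistic
#'
#' Centered mean over `window_snps` consecutive SNPs within each
#' chromosome, truncated at chromosome edges, step 1 SNP so every SNP
#' carries a smoothed value. `NA` input values are excluded from window
#' means. Input must already be sorted by (chrom, pos); unsorted input is
#' an error, never silently re-sorted.
#'
#' @param values per-SNP statistic (e.g. FST)
#' @param chrom chromosome per SNP
#' @param pos position per SNP (bp)
#' @param window_snps odd window width >= 1
#' @return smoothed numeric vector, same length
#' @export
smooth_fst <- function(values, chrom, pos, window_snps = 9) {
  stopifnot(length(values) == length(chrom), length(chrom) == length(pos))
  if (window_snps < 1 || window_snps %% 2 == 0)
    stop("window_snps must be odd and >= 1")
  num <- suppressWarnings(as.numeric(chrom))
  o <- order(num, chrom, pos)
  if (any(o != seq_along(o)))
    stop("SNPs must be sorted by (chrom, pos) before smoothing")
  half <- (window_snps - 1L) %/% 2L
  out <- rep(NA_real_, length(values))
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    v <- values[ix]
    m <- length(v)
    vz <- ifelse(is.na(v), 0, v)
    cnt <- as.numeric(!is.na(v))
    cs <- cumsum(c(0, vz))
    cc <- cumsum(c(0, cnt))
    lo <- pmax(seq_len(m) - half, 1L)
    hi <- pmin(seq_len(m) + half, m)
    s <- cs[hi + 1L] - cs[lo]
    k <- cc[hi + 1L] - cc[lo]
    out[ix] <- ifelse(k > 0, s / k, NA_real_)
  }
  out
}

#' Call candidate selection regions from smoothed FST
#'
#' Flags SNPs whose smoothed FST lies strictly above the empirical
#' `quantile` (type-7 interpolation) of all smoothed values genome-wide and
#' merges flagged SNPs into regions, tolerating up to `max_gap_snps`
#' consecutive below-threshold SNPs inside a region. Region coordinates are
#' 1-based inclusive and span the first to last member SNP.
#'
#' @param smoothed smoothed per-SNP values
#' @param chrom,pos SNP coordinates (sorted)
#' @param quantile flagging quantile (default 0.95)
#' @param max_gap_snps below-threshold SNPs tolerated inside a region
#' @param method_tag label stored in the output (default "FST")
#' @return data.frame chrom, start_bp, end_bp, n_snps (above-threshold
#'   members), peak (max smoothed value), method; attribute `threshold`
#'   stores the cutoff, `flagged` the logical flag vector.
#' @export
call_fst_regions <- function(smoothed, chrom, pos, quantile = 0.95,
                             max_gap_snps = 2, method_tag = "FST") {
  usable <- !is.na(smoothed)
  if (sum(usable) < 20L)
    warning("fewer than 20 SNPs: empirical quantile threshold is unstable")
  thr <- stats::quantile(smoothed[usable], probs = quantile, type = 7,
                         names = FALSE)
  flagged <- !is.na(smoothed) & smoothed > thr
  regions <- merge_flagged(flagged, chrom, pos, smoothed, max_gap_snps,
                           method_tag)
  attr(regions, "threshold") <- thr
  attr(regions, "flagged") <- flagged
  regions
}

merge_flagged <- function(flagged, chrom, pos, stat, max_gap_snps,
                          method_tag) {
  rows <- list()
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    f <- flagged[ix]
    hits <- which(f)
    if (!length(hits)) next
    start <- hits[1L]
    last <- hits[1L]
    flush <- function(start, last) {
      members <- intersect(start:last, hits)
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = ch, start_bp = pos[ix[start]], end_bp = pos[ix[last]],
        n_snps = length(members),
        peak = max(stat[ix[members]], na.rm = TRUE),
        method = method_tag, stringsAsFactors = FALSE)
    }
    for (h in hits[-1L]) {
      if (h - last - 1L <= max_gap_snps) {
        last <- h
      } else {
        flush(start, last)
        start <- h
        last <- h
      }
    }
    flush(start, last)
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), n_snps = integer(0),
                      peak = numeric(0), method = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
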