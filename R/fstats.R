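# f2 and outgroup-f3 drift statistics with block-jackknife errors.
#
# Per-SNP contributions use Patterson-style finite-sample bias corrections
# with haploid counts:
#   f2(A,B):    (pA - pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)
#   f3(O;A,B):  (pO - pA)(pO - pB) - pO(1-pO)/(nO-1)
# The estimate is the mean over usable SNPs; standard errors come from the
# weighted delete-one-block jackknife over contiguous SNP blocks.

freq_row <- function(freqs, pop) {
  i <- match(pop, freqs$populations)
  if (is.na(i)) stop("population not found: ", pop)
  i
}

#' Per-SNP f2 contributions for a population pair
#'
#' @param freqs a `pop_freqs`
#' @param pop_a,pop_b population labels
#' @return numeric vector of per-SNP contributions (`NA` where a frequency
#'   is undefined or a haploid count is < 2; such SNPs are skipped by the
#'   aggregators)
#' @export
f2 <- function(freqs, pop_a, pop_b) {
  ia <- freq_row(freqs, pop_a); ib <- freq_row(freqs, pop_b)
  pa <- freqs$freqs[ia, ]; pb <- freqs$freqs[ib, ]
  na <- freqs$n_hap[ia, ]; nb <- freqs$n_hap[ib, ]
  out <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  out[is.na(pa) | is.na(pb) | na < 2 | nb < 2] <- NA_real_
  unname(out)
}

#' Per-SNP outgroup-f3 contributions
#'
#' f3(O; A, B) measures the shared drift between the outgroup's root and
#' the A-B divergence point; larger values indicate more closely related
#' pairs.
#'
#' @param freqs a `pop_freqs`
#' @param outgroup,pop_a,pop_b distinct population labels
#' @return numeric vector of per-SNP contributions (NA = skipped)
#' @export
f3_outgroup <- function(freqs, outgroup, pop_a, pop_b) {
  io <- freq_row(freqs, outgroup)
  ia <- freq_row(freqs, pop_a); ib <- freq_row(freqs, pop_b)
  po <- freqs$freqs[io, ]; pa <- freqs$freqs[ia, ]; pb <- freqs$freqs[ib, ]
  no <- freqs$n_hap[io, ]
  out <- (po - pa) * (po - pb) - po * (1 - po) / (no - 1)
  out[is.na(po) | is.na(pa) | is.na(pb) | no < 2 |
        freqs$n_hap[ia, ] < 2 | freqs$n_hap[ib, ] < 2] <- NA_real_
  unname(out)
}

make_blocks <- function(chrom, block_size_snps) {
  # contiguous blocks of block_size_snps SNPs, never spanning chromosomes
  ids <- integer(length(chrom))
  offset <- 0L
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    ids[ix] <- offset + ((seq_along(ix) - 1L) %/% block_size_snps) + 1L
    offset <- max(ids[ix])
  }
  ids
}

#' Weighted delete-one-block jackknife over SNP blocks
#'
#' Splits SNPs into contiguous blocks (within chromosomes), forms
#' delete-one-block means and combines them with the weighted jackknife
#' (unequal block sizes supported) into a standard error, z-score and
#' two-sided normal p-value for the mean contribution.
#'
#' @param contributions per-SNP numeric contributions (NA skipped)
#' @param chrom chromosome label per SNP (same length); `NULL` = one
#'   chromosome
#' @param block_size_snps SNPs per block (default 500, roughly 12.5 Mb at
#'   25 kb spacing — comfortably beyond livestock LD range)
#' @return list(estimate, std_error, z_score, p_value, n_blocks, n_snps).
#'   Zero-variance input reports `std_error = 0` and `NA` z/p rather than
#'   infinities.
#' @export
block_jackknife <- function(contributions, chrom = NULL,
                            block_size_snps = 500) {
  keep <- !is.na(contributions)
  x <- contributions[keep]
  n <- length(x)
  if (n < 2L) stop("need >= 2 usable contributions")
  chrom <- if (is.null(chrom)) rep("1", n) else chrom[keep]
  blocks <- make_blocks(chrom, block_size_snps)
  g <- length(unique(blocks))
  if (g < 2L)
    stop("only one jackknife block: need more SNPs or a smaller block size")

  total <- sum(x)
  theta <- total / n
  m_j <- as.numeric(tapply(x, blocks, length))
  s_j <- as.numeric(tapply(x, blocks, sum))
  theta_minus <- (total - s_j) / (n - m_j)
  h_j <- n / m_j
  theta_J <- g * theta - sum((1 - m_j / n) * theta_minus)
  tau <- h_j * theta - (h_j - 1) * theta_minus
  var_J <- mean((tau - theta_J)^2 / (h_j - 1))
  se <- sqrt(max(var_J, 0))
  if (se <= 1e-12 * max(1, abs(theta))) se <- 0  # numerically constant

  if (se == 0) {
    z <- NA_real_; p <- NA_real_
  } else {
    z <- theta / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(estimate = theta, std_error = se, z_score = z, p_value = p,
       n_blocks = g, n_snps = n)
}

#' Outgroup-f3 table for all focal population pairs
#'
#' Computes f3(outgroup; A, B) with block-jackknife errors for every
#' unordered pair of non-outgroup populations, sorted by estimate
#' descending (most closely related pairs first).
#'
#' @param freqs a `pop_freqs`
#' @param outgroup the outgroup population label
#' @param block_size_snps jackknife block size
#' @return data.frame with columns A, B, estimate, std_error, z_score,
#'   p_value, n_blocks, n_snps
#' @export
f3_table <- function(freqs, outgroup, block_size_snps = 500) {
  pops <- setdiff(freqs$populations, outgroup)
  if (length(pops) < 2L) stop("need >= 2 focal populations")
  pairs <- utils::combn(pops, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    contrib <- f3_outgroup(freqs, outgroup, a, b)
    jk <- block_jackknife(contrib, freqs$snps$chrom, block_size_snps)
    data.frame(A = a, B = b, estimate = jk$estimate,
               std_error = jk$std_error, z_score = jk$z_score,
               p_value = jk$p_value, n_blocks = jk$n_blocks,
               n_snps = jk$n_snps, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$estimate), , drop = FALSE]
}

#' f2 table for all population pairs
#'
#' @param freqs a `pop_freqs`
#' @param block_size_snps jackknife block size
#' @return data.frame A, B, estimate, std_error, z_score, p_value
#' @export
f2_table <- function(freqs, block_size_snps = 500) {
  pops <- freqs$populations
  if (length(pops) < 2L) stop("need >= 2 populations")
  pairs <- utils::combn(pops, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    jk <- block_jackknife(f2(freqs, a, b), freqs$snps$chrom,
                          block_size_snps)
    data.frame(A = a, B = b, estimate = jk$estimate,
               std_error = jk$std_error, z_score = jk$z_score,
               p_value = jk$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
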