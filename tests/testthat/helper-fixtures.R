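# Small in-code fixtures shared across test files.

# deterministic toy dataset: 4 samples (2 pops) x 3 SNPs, one missing call
toy_dataset <- function() {
  dos <- rbind(
    c(0L, 1L, 2L),
    c(1L, NA, 2L),
    c(2L, 0L, 1L),
    c(2L, 1L, 0L)
  )
  genotype_dataset(
    dos,
    data.frame(snp_id = c("s1", "s2", "s3"), chrom = c("1", "1", "2"),
               pos_bp = c(100L, 200L, 50L), allele1 = "A", allele2 = "B",
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0("ind", 1:4),
               population = c("P1", "P1", "P2", "P2"),
               stringsAsFactors = FALSE)
  )
}

random_dataset <- function(n_samples = 12, n_snps = 40, n_pops = 2,
                           miss_rate = 0.05, seed = 101) {
  set.seed(seed)
  dos <- matrix(rbinom(n_samples * n_snps, 2, 0.4), n_samples)
  dos[runif(length(dos)) < miss_rate] <- NA
  genotype_dataset(
    dos,
    data.frame(snp_id = sprintf("r%03d", seq_len(n_snps)),
               chrom = as.character(rep(1:2, each = ceiling(n_snps / 2),
                                        length.out = n_snps)),
               pos_bp = rep(seq_len(ceiling(n_snps / 2)) * 1000L,
                            2)[seq_len(n_snps)],
               allele1 = "A", allele2 = "C", stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("i%02d", seq_len(n_samples)),
               population = rep(paste0("pop", seq_len(n_pops)),
                                length.out = n_samples),
               stringsAsFactors = FALSE)
  )
}

# brute-force GRM oracle: explicit loops, no linear algebra shortcuts
grm_oracle <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  Z <- dosages[, poly, drop = FALSE]
  p <- p[poly]
  for (j in seq_len(ncol(Z))) {
    Z[, j] <- ifelse(is.na(Z[, j]), 0, Z[, j] - 2 * p[j])
  }
  k <- 2 * sum(p * (1 - p))
  n <- nrow(Z)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    G[i, j] <- sum(Z[i, ] * Z[j, ]) / k
  G
}

# Weir-Cockerham theta oracle for one SNP, transcribed term by term
wc_oracle <- function(p, n) {
  r <- length(p)
  n_tot <- sum(n)
  pbar <- sum(n * p) / n_tot
  msp <- sum(n * (p - pbar)^2) / (r - 1)
  msg <- sum(n * p * (1 - p)) / (n_tot - r)
  nc <- (n_tot - sum(n^2) / n_tot) / (r - 1)
  (msp - msg) / (msp + (nc - 1) * msg)
}

# FLK oracle: explicit GLS solve per SNP
flk_oracle <- function(p, F) {
  one <- rep(1, length(p))
  Fi <- solve(F)
  p0 <- sum(Fi %*% p) / sum(Fi %*% one)
  d <- p - p0 * one
  as.numeric(t(d) %*% solve(p0 * (1 - p0) * F) %*% d)
}

# equal-block delete-one jackknife oracle
jackknife_oracle <- function(x, block_ids) {
  theta <- mean(x)
  loo <- sapply(unique(block_ids), function(b) mean(x[block_ids != b]))
  g <- length(loo)
  se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  list(estimate = theta, se = se)
}

# hypergeometric tail by enumeration of more-extreme tables
fisher_oracle <- function(obs, K, N, n) {
  ks <- obs:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
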