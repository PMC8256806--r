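# FST estimators, smoothing, region calling, kinship, FLK, q-values,
# and the scan orchestrator.

test_that("per-SNP FST: fixed difference and null frequencies", {
  fr <- pop_freqs(rbind(A = c(1, 0.3), B = c(0, 0.3)), n_hap = 100000)
  plain <- per_snp_fst(fr, estimator = "plain")
  expect_equal(plain[1], 1)
  expect_equal(plain[2], 0)
  wc <- per_snp_fst(fr, estimator = "wc")
  expect_equal(wc[1], 1, tolerance = 1e-4)
  expect_lt(abs(wc[2]), 1e-4)
  expect_error(per_snp_fst(pop_freqs(rbind(A = 0.5), n_hap = 10)),
               ">= 2 populations")
})

test_that("WC theta matches the component-formula oracle", {
  # counts (allele2/haploids): 30/100 and 70/100
  fr <- pop_freqs(rbind(A = 0.30, B = 0.70), n_hap = 100)
  expect_equal(per_snp_fst(fr), wc_oracle(c(0.3, 0.7), c(100, 100)),
               tolerance = 1e-12)
  # unequal sizes, 3 populations
  p <- c(0.1, 0.45, 0.8); n <- c(40, 130, 64)
  fr3 <- pop_freqs(rbind(A = p[1], B = p[2], C = p[3]),
                   n_hap = matrix(n, 3, 1))
  expect_equal(per_snp_fst(fr3), wc_oracle(p, n), tolerance = 1e-12)
  wcc <- wc_components(p, n)
  expect_equal(wcc$theta, wc_oracle(p, n), tolerance = 1e-14)
})

test_that("monomorphic SNPs are excluded, not zero", {
  fr <- pop_freqs(rbind(A = c(0, 0.5), B = c(0, 0.5)), n_hap = 50)
  expect_true(is.na(per_snp_fst(fr)[1]))
})

test_that("smoothing truncates at edges and is linear", {
  chrom <- rep("1", 5); pos <- 1:5
  expect_equal(smooth_fst(c(0, 1, 0, 1, 0), chrom, pos, 3),
               c(0.5, 1 / 3, 2 / 3, 1 / 3, 0.5))
  expect_equal(smooth_fst(rep(0.2, 5), chrom, pos, 3), rep(0.2, 5))
  x <- runif(5); y <- runif(5)
  expect_equal(smooth_fst(2 * x + 3 * y, chrom, pos, 3),
               2 * smooth_fst(x, chrom, pos, 3) +
                 3 * smooth_fst(y, chrom, pos, 3))
  expect_equal(smooth_fst(x, chrom, pos, 1), x)  # window 1 = identity
  expect_error(smooth_fst(x, chrom, pos, 4), "odd")
  expect_error(smooth_fst(x, chrom, rev(pos), 3), "sorted")
  # windows never cross the chromosome boundary
  ch2 <- c("1", "1", "2", "2")
  sm <- smooth_fst(c(1, 1, 0, 0), ch2, c(1, 2, 1, 2), 3)
  expect_equal(sm, c(1, 1, 0, 0))
})

test_that("region calling flags ~5% of iid values and merges runs", {
  set.seed(70)
  n <- 10000
  sm <- runif(n)
  regions <- call_fst_regions(sm, rep("1", n), seq_len(n) * 100,
                              quantile = 0.95, max_gap_snps = 0)
  frac <- sum(regions$n_snps) / n
  expect_gt(frac, 0.043)
  expect_lt(frac, 0.057)

  # constant input: nothing strictly above the quantile
  expect_equal(nrow(call_fst_regions(rep(1, 100), rep("1", 100), 1:100)), 0)

  # a clustered peak becomes one region spanning its members
  vals <- c(rep(0, 50), rep(5, 10), rep(0, 40))
  r <- call_fst_regions(vals, rep("1", 100), seq_len(100) * 10,
                        quantile = 0.80, max_gap_snps = 2)
  expect_equal(nrow(r), 1)
  expect_equal(r$start_bp, 510)
  expect_equal(r$end_bp, 600)
  expect_equal(r$n_snps, 10)
  expect_warning(call_fst_regions(runif(10), rep("1", 10), 1:10),
                 "unstable")
})

test_that("kinship: two populations plus outgroup give a diagonal F", {
  sim <- simulate_dataset("((A:0.1,B:0.1):0.05,O:0.25);", n_snps = 5000,
                          samples_per_pop = 50, seed = 71)
  fr <- allele_frequencies(sim$dataset)
  kf <- build_kinship(fr, "O")
  expect_setequal(kf$populations, c("A", "B"))
  expect_lt(abs(kf$F["A", "B"]), 0.02)  # no shared post-root branch
  expect_gt(kf$F["A", "A"], 0.05)
})

test_that("estimated kinship recovers true shared drift within 20%", {
  tree <- "(((A:0.08,B:0.08):0.06,(C:0.08,D:0.08):0.06):0.04,O:0.3);"
  sim <- simulate_dataset(tree, n_snps = 20000, samples_per_pop = 100,
                          seed = 72)
  fr <- allele_frequencies(sim$dataset)
  kf <- build_kinship(fr, "O")
  # true shared drift of the sibling pair (A,B) relative to ingroup MRCA
  true_shared <- 1 - (1 - 0.06)
  expect_lt(abs(kf$F["A", "B"] - true_shared) / true_shared, 0.2)
  expect_lt(abs(kf$F["A", "A"] - (1 - 0.92 * 0.94)) / (1 - 0.92 * 0.94),
            0.2)
})

test_that("NJ reconstructs a 4-leaf additive topology", {
  # additive distances from the tree ((A,B),(C,D)) with internal edge
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.2
  for (i in c("A", "B")) for (j in c("C", "D"))
    d[i, j] <- d[j, i] <- 0.4
  tr <- ape::nj(as.dist(d))
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[rownames(d), colnames(d)], d, tolerance = 1e-10)
})

test_that("FLK matches the brute-force GLS oracle and the LK reduction", {
  F <- matrix(c(.1, .05, 0, .05, .1, 0, 0, 0, .2), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p <- c(0.5, 0.6, 0.9)
  fr <- pop_freqs(rbind(A = p[1], B = p[2], C = p[3]), n_hap = 1000)
  got <- flk(fr, F)
  expect_equal(got$flk, flk_oracle(p, F), tolerance = 1e-10)
  expect_equal(attr(got, "df"), 2L)

  # star tree F = f I reduces to the Lewontin-Krakauer form
  f <- 0.07
  Fs <- diag(f, 4); dimnames(Fs) <- list(paste0("P", 1:4), paste0("P", 1:4))
  ps <- c(0.3, 0.35, 0.4, 0.55)
  frs <- pop_freqs(matrix(ps, 4, 1,
                          dimnames = list(paste0("P", 1:4), NULL)),
                   n_hap = 1000)
  got2 <- flk(frs, Fs)
  p0 <- mean(ps)
  lk <- sum((ps - p0)^2) / (f * p0 * (1 - p0))
  expect_equal(got2$flk, lk, tolerance = 1e-12)

  # equal frequencies: zero quadratic form, p-value 1
  fre <- pop_freqs(matrix(0.4, 4, 1,
                          dimnames = list(paste0("P", 1:4), NULL)),
                   n_hap = 1000)
  gote <- flk(fre, Fs)
  expect_equal(gote$flk, 0, tolerance = 1e-12)
  expect_equal(gote$p_value, 1)
})

test_that("FLK is invariant to allele relabeling (p -> 1-p)", {
  sim <- simulate_dataset("((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);",
                          n_snps = 300, samples_per_pop = 30, seed = 73)
  fr <- allele_frequencies(sim$dataset)
  F <- kinship_from_tree(sim$truth$tree)
  a <- flk(fr, F)
  fr2 <- fr
  fr2$freqs <- 1 - fr$freqs
  b <- flk(fr2, F)
  expect_equal(a$flk, b$flk, tolerance = 1e-10)
})

test_that("SNPs with boundary ancestral estimates are excluded", {
  F <- diag(0.1, 2); dimnames(F) <- list(c("A", "B"), c("A", "B"))
  fr <- pop_freqs(rbind(A = c(0, 0.5), B = c(0, 0.6)), n_hap = 100)
  got <- flk(fr, F)
  expect_true(is.na(got$flk[1]))
  expect_equal(attr(got, "n_excluded"), 1L)
})

test_that("q-values follow the step-up minima with forced pi0", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.9)
  q <- qvalues(p, pi0 = 1)
  # enumerating pi0 * m * t / rank(t) over t >= p_(i):
  # raw = (.05, .05, .05, .05, .9); running minima from the top
  expect_equal(as.vector(q), c(0.05, 0.05, 0.05, 0.05, 0.9),
               tolerance = 1e-12)
  expect_equal(as.vector(qvalues(0.03, pi0 = 1)), 0.03)
  # monotone in p
  set.seed(74)
  ps <- runif(500)
  qs <- qvalues(ps)
  expect_true(all(diff(qs[order(ps)]) >= -1e-12))
  expect_error(qvalues(numeric(0)), "no p-values")
})

test_that("pi0 estimate is consistent on uniform p-values", {
  set.seed(75)
  q <- qvalues(runif(10000))
  expect_gt(attr(q, "pi0"), 0.9)
  expect_lte(attr(q, "pi0"), 1.1)
})

test_that("run_scan combines FST regions and FLK hits", {
  sel <- selection_spec("A", n_loci = 40, c_sel = 0.5, cluster_size = 10)
  sim <- simulate_dataset("((A:0.02,B:0.02):0.02,O:0.2);", n_snps = 6000,
                          samples_per_pop = 50, selected = sel, seed = 76)
  res <- run_scan(sim$dataset, focal = "A", rest = "B", outgroup = "O")
  expect_s3_class(res, "scan_result")
  expect_equal(nrow(res$scan), 6000)
  truth_ids <- sim$dataset$snps$snp_id[sim$truth$selected$snp_index]
  detected <- truth_ids %in% union(res$fst_flagged_snps, res$flk_snps)
  expect_gte(mean(detected), 0.8)
  # q-values monotone in p
  ok <- !is.na(res$scan$flk_q)
  o <- order(res$scan$flk_p[ok])
  expect_true(all(diff(res$scan$flk_q[ok][o]) >= -1e-12))
  # display clamp never negative, raw preserved
  expect_true(all(res$scan$fst >= 0, na.rm = TRUE))
  expect_true(any(res$scan$fst_raw < 0, na.rm = TRUE))
})

test_that("null scan yields (almost) no FLK discoveries at q <= 0.15", {
  sim <- simulate_dataset("((A:0.05,B:0.05):0.05,O:0.25);", n_snps = 5000,
                          samples_per_pop = 40, seed = 79)
  res <- run_scan(sim$dataset, focal = "A", rest = "B", outgroup = "O")
  expect_lte(length(res$flk_snps) / 5000, 0.01)
})

test_that("one-vs-rest produces a scan per focal population", {
  sim <- simulate_dataset("(((A:0.05,B:0.05):0.03,(C:0.05,D:0.05):0.03):0.03,O:0.2);",
                          n_snps = 800, samples_per_pop = 15, seed = 77)
  scans <- run_scan_one_vs_rest(sim$dataset, outgroup = "O")
  expect_named(scans, c("A", "B", "C", "D"))
  expect_true(all(vapply(scans, inherits, logical(1), "scan_result")))
})

test_that("unknown focal populations abort with the stage name", {
  sim <- simulate_dataset("(A:0.1,B:0.1);", n_snps = 50,
                          samples_per_pop = 5, seed = 78)
  expect_error(run_scan(sim$dataset, focal = "Z"), "\\[fst\\]")
})
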