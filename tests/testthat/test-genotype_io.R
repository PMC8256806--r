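# PLINK binary IO, QC filtering, allele frequencies.

test_that("bed decoding matches hand-decoded 2-bit codes", {
  # single genotype byte 0b11_10_01_00: sample 1 in the low bits
  # 00 -> dosage 0, 01 -> missing, 10 -> het, 11 -> dosage 2
  prefix <- file.path(tempdir(), "onebyte")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xE4)), paste0(prefix, ".bed"))
  writeLines("1\tsnpA\t0\t500\tA\tG", paste0(prefix, ".bim"))
  writeLines(sprintf("pop%d ind%d 0 0 0 -9", c(1, 1, 2, 2), 1:4),
             paste0(prefix, ".fam"))
  ds <- read_plink(prefix)
  expect_equal(as.vector(ds$dosages), c(0L, NA, 1L, 2L))
  expect_equal(ds$samples$population, c("pop1", "pop1", "pop2", "pop2"))
  expect_equal(ds$snps$pos_bp, 500L)
})

test_that("read/write round trip is the identity, including missing", {
  for (ds in list(toy_dataset(), random_dataset(n_samples = 5),
                  random_dataset(n_samples = 8, n_snps = 17,
                                 seed = 7))) {
    prefix <- file.path(tempdir(), "rt")
    write_plink(ds, prefix)
    back <- read_plink(prefix)
    expect_identical(back$dosages, ds$dosages)
    expect_equal(back$snps$snp_id, ds$snps$snp_id)
    expect_equal(back$snps$pos_bp, ds$snps$pos_bp)
    expect_equal(back$samples$population, ds$samples$population)
  }
})

test_that("bed size follows ceil(n/4) 2-bit packing", {
  ds <- random_dataset(n_samples = 5, n_snps = 3)
  prefix <- file.path(tempdir(), "packed5")
  write_plink(ds, prefix)
  expect_equal(file.size(paste0(prefix, ".bed")), 3 + 3 * 2)
  ds4 <- random_dataset(n_samples = 4, n_snps = 3)
  write_plink(ds4, file.path(tempdir(), "packed4"))
  expect_equal(file.size(file.path(tempdir(), "packed4.bed")), 3 + 3 * 1)
})

test_that("bad magic, bad mode and truncation are reported", {
  prefix <- file.path(tempdir(), "bad")
  ds <- toy_dataset()
  write_plink(ds, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 100)
  writeBin(c(as.raw(0), raw[-1]), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")
  writeBin(c(raw[1:2], as.raw(0), raw[-(1:3)]), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "mode byte")
  writeBin(raw[-length(raw)], paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "size mismatch")
})

test_that("non-autosomal SNPs are dropped and SNPs are sorted on load", {
  ds <- toy_dataset()
  ds$snps$chrom <- c("2", "X", "1")  # s2 non-autosomal; order scrambled
  prefix <- file.path(tempdir(), "sortme")
  write_plink(ds, prefix)
  expect_message(back <- read_plink(prefix), "non-autosomal")
  expect_equal(back$snps$snp_id, c("s3", "s1"))  # chr1 before chr2
  expect_equal(back$dosages[, 1], ds$dosages[, 3])
})

test_that("qc_filter applies SNP, sample, MAF steps in order", {
  ds <- toy_dataset()
  res <- qc_filter(ds, 0, 0, 0)
  expect_identical(res$dataset$dosages, ds$dosages)  # identity thresholds
  expect_equal(res$report$genotyping_rate, 11 / 12)

  # monomorphic SNP removed by MAF filter
  dos <- cbind(ds$dosages, mono = c(2L, 2L, 2L, 2L))
  snps <- rbind(ds$snps, data.frame(snp_id = "s4", chrom = "2",
                                    pos_bp = 99L, allele1 = "A",
                                    allele2 = "B"))
  ds5 <- genotype_dataset(dos, snps, ds$samples)
  res <- qc_filter(ds5, 0, 0, min_maf = 0.01)
  expect_equal(res$dataset$snps$snp_id, c("s1", "s2", "s3"))
  expect_equal(res$report$n_maf_removed, 1)

  # SNP call-rate filter fires before sample filter
  dos2 <- ds$dosages
  dos2[1:3, 2] <- NA
  ds6 <- genotype_dataset(dos2, ds$snps, ds$samples)
  res <- qc_filter(ds6, min_snp_call_rate = 0.5,
                   min_sample_call_rate = 0.5, min_maf = 0)
  expect_equal(res$report$n_snp_callrate_removed, 1)
  expect_equal(res$report$n_samples_out, 4)
  expect_error(qc_filter(ds, min_snp_call_rate = 1.01), "min_snp_call_rate")
})

test_that("qc_filter is idempotent", {
  ds <- random_dataset(miss_rate = 0.2, seed = 5)
  r1 <- qc_filter(ds, 0.8, 0.8, 0.05)
  r2 <- qc_filter(r1$dataset, 0.8, 0.8, 0.05)
  expect_identical(r2$dataset$dosages, r1$dataset$dosages)
  expect_equal(r2$report$n_snp_callrate_removed, 0)
  expect_equal(r2$report$n_maf_removed, 0)
})

test_that("allele_frequencies counts dosages per population", {
  ds <- toy_dataset()
  fr <- allele_frequencies(ds)
  # P1 at s1: genotypes 0,1 -> 1/4; P1 at s2: 1,NA -> 1/2 with n_hap 2
  expect_equal(fr$freqs["P1", "s1"], 0.25)
  expect_equal(fr$freqs["P1", "s2"], 0.5)
  expect_equal(fr$n_hap["P1", "s2"], 2L)
  # P2 at s3: genotypes 1,0 -> 0.25, n_hap 4
  expect_equal(fr$freqs["P2", "s3"], 0.25)
  expect_equal(fr$n_hap["P2", "s3"], 4L)

  one <- genotype_dataset(matrix(c(0L, 1L, 2L), 3),
                          ds$snps[1, ],
                          data.frame(sample_id = c("a", "b", "c"),
                                     population = "P"))
  fr1 <- allele_frequencies(one)
  expect_equal(as.vector(fr1$freqs), 0.5)
  expect_equal(as.vector(fr1$n_hap), 6L)

  two <- genotype_dataset(matrix(c(2L, 2L, NA), 3), ds$snps[1, ],
                          data.frame(sample_id = c("a", "b", "c"),
                                     population = "P"))
  fr2 <- allele_frequencies(two)
  expect_equal(as.vector(fr2$freqs), 1.0)
  expect_equal(as.vector(fr2$n_hap), 4L)
})

test_that("population with zero calls at a SNP yields NA freq, not 0", {
  ds <- toy_dataset()
  ds$dosages[1:2, 3] <- NA  # P1 uncalled at s3
  fr <- allele_frequencies(ds)
  expect_true(is.na(fr$freqs["P1", "s3"]))
  expect_equal(fr$n_hap["P1", "s3"], 0L)
})

test_that("self-concatenation doubles n_hap and preserves freqs", {
  ds <- random_dataset(seed = 42)
  dbl <- genotype_dataset(rbind(ds$dosages, ds$dosages), ds$snps,
                          rbind(ds$samples,
                                transform(ds$samples,
                                          sample_id = paste0(sample_id,
                                                             "b"))))
  f1 <- allele_frequencies(ds)
  f2_ <- allele_frequencies(dbl)
  expect_equal(f2_$freqs, f1$freqs)
  expect_equal(f2_$n_hap, 2L * f1$n_hap)
})
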