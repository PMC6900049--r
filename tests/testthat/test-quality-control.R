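test_that("allele frequencies follow the allele-count definition", {
  g <- genotype_matrix(cbind(a = c(0, 1, 2, 2, 1), b = c(0, 0, 0, 0, 0),
                             c = c(2, 2, NA, NA, NA)))
  p <- allele_frequencies(g)
  expect_equal(unname(p), c(6 / 10, 0, 1))
  maf <- minor_allele_frequencies(g)
  expect_equal(unname(maf), c(0.4, 0, 0))  # monomorphic either way -> 0
  g2 <- genotype_matrix(matrix(NA_real_, 2, 1, dimnames = list(NULL, "bad")))
  expect_error(allele_frequencies(g2), "bad")
})

test_that("HWE chi-square test matches hand computation and conventions", {
  expect_equal(hwe_pvalue(25, 50, 25), 1)            # exact HWE proportions
  # (50, 0, 50): expected (25, 50, 25), chi2 = 25 + 50 + 25 = 100
  expect_lt(hwe_pvalue(50, 0, 50), 1e-6)
  expect_equal(hwe_pvalue(50, 0, 50), pchisq(100, 1, lower.tail = FALSE))
  expect_equal(hwe_pvalue(100, 0, 0), 1)             # monomorphic -> 1
  expect_error(hwe_pvalue(-1, 2, 3), "nonnegative")
  expect_error(hwe_pvalue(0, 0, 0), "positive")
})

test_that("ld_r2 is a squared correlation, sign- and label-invariant", {
  x <- c(0, 1, 2, 1, 0, 2, 2, 0)
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, 2 - x), 1)
  expect_equal(ld_r2(x, rep(1, 8)), 0)     # constant -> defined as 0
  expect_error(ld_r2(c(1, NA), c(NA, 1)), "fewer than 2")
  set.seed(1)
  a <- rbinom(10000, 2, 0.3); b <- rbinom(10000, 2, 0.4)
  expect_lt(ld_r2(a, b), 0.01)
})

test_that("variant filters drop the expected markers on the committed fixture", {
  raw <- system.file("extdata", "qc_fixture.raw", package = "cattleGP")
  g <- read_genotypes(raw, "plink_raw")
  out <- apply_variant_filters(g)
  expect_setequal(out$geno$marker_ids, c("snpA", "snpE", "snpF"))
  rep <- out$report
  expect_identical(rep$stage, c("missingness", "maf", "hwe"))
  expect_identical(rep$n_in, c(6L, 5L, 4L))
  expect_identical(rep$n_out, c(5L, 4L, 3L))
  # stage counts telescope
  expect_identical(rep$n_in[-1], rep$n_out[-nrow(rep)])
})

test_that("filter inequalities are strict and vacuous thresholds keep all", {
  # marker with MAF exactly 0.05: 2 alt alleles in 20 -> p = 0.05
  d <- cbind(edge = c(1, 1, rep(0, 18)), keep = rep(c(0, 1, 2, 1), 5))
  g <- genotype_matrix(d)
  out <- apply_variant_filters(g, maf_min = 0.05)
  expect_false("edge" %in% out$geno$marker_ids)
  out2 <- apply_variant_filters(g, maf_min = 0, miss_max = 1, hwe_min = 0)
  expect_identical(ncol(out2$geno$dosages), 2L)
  expect_error(apply_variant_filters(g, maf_min = -0.1), "thresholds")
})

test_that("loosening thresholds never removes a previous survivor", {
  sim <- quick_dataset(n = 120, m = 150, seed = 9, missing_rate = 0.03,
                       maf_range = c(0.01, 0.5))
  strict <- apply_variant_filters(sim$geno, 0.10, 0.03, 1e-3)
  loose <- apply_variant_filters(sim$geno, 0.05, 0.05, 1e-6)
  expect_true(all(strict$geno$marker_ids %in% loose$geno$marker_ids))
})

test_that("ld_prune keeps the left marker, satisfies its postcondition, and is idempotent", {
  x <- c(0, 1, 2, 1, 0, 2, 1, 0, 2, 1)
  g <- genotype_matrix(cbind(m1 = x, m2 = x, m3 = rev(x)),
                       position = c(10, 20, 30))
  pr <- ld_prune(g, window = 3, r2_max = 0.995)
  expect_identical(pr$kept[1], "m1")
  expect_false("m2" %in% pr$kept)

  sim <- quick_dataset(n = 150, m = 200, seed = 10, ld = 0.9)
  pr1 <- ld_prune(sim$geno, window = 20, r2_max = 0.2)
  expect_lt(ncol(pr1$geno$dosages), 200L)
  # postcondition: no kept pair within the window exceeds the threshold
  d <- pr1$geno$dosages
  mkept <- ncol(d)
  for (j in seq_len(mkept)) {
    for (k in seq_len(mkept)) {
      if (k > j && k - j <= 19) {
        expect_lte(ld_r2(d[, j], d[, k]), 0.2)
      }
    }
  }
  pr2 <- ld_prune(pr1$geno, window = 20, r2_max = 0.2)
  expect_identical(pr2$kept, pr1$kept)
  expect_error(ld_prune(sim$geno, window = 1), "window")
})

test_that("ld_prune with no correlated pairs keeps everything", {
  sim <- quick_dataset(n = 100, m = 30, seed = 11, ld = 0)
  pr <- ld_prune(sim$geno, window = 10, r2_max = 0.995)
  expect_identical(pr$kept, sim$geno$marker_ids)
})

test_that("mean imputation fills with the marker mean and is identity on complete data", {
  g <- genotype_matrix(cbind(a = c(0, 2, NA), b = c(1, NA, NA), c = c(0, 1, 2)))
  out <- mean_impute(g)
  expect_equal(unname(out$dosages[, "a"]), c(0, 2, 1))
  expect_equal(unname(out$dosages[, "b"]), c(1, 1, 1))
  expect_identical(out$dosages[, "c"], g$dosages[, "c"])
  g2 <- genotype_matrix(cbind(c(0, 1, 2)))
  expect_identical(mean_impute(g2)$dosages, g2$dosages)
})
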