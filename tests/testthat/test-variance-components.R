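test_that("fixed-effect design coding follows the factor/covariate rules", {
  df <- data.frame(sample_id = sprintf("s%d", 1:8),
                   gender = rep(c("M", "F"), 4), farm = "f1", year = 2010,
                   slaughter_age = NA_real_,
                   CW = rnorm(8), ADG = rnorm(8))
  p <- phenotype_table(df)
  des <- build_fixed_design(p, "CW", use_age = FALSE)
  expect_identical(ncol(des$X), 2L)  # intercept + gender contrast
  expect_identical(colnames(des$X)[1], "(Intercept)")

  # ADG omits the age covariate by default
  df$slaughter_age <- runif(8, 540, 730)
  p2 <- phenotype_table(df)
  expect_false("slaughter_age" %in% colnames(build_fixed_design(p2, "ADG")$X))
  expect_true("slaughter_age" %in% colnames(build_fixed_design(p2, "CW")$X))

  # rows with missing trait are dropped; constant factors add no columns
  df$CW[3] <- NA
  p3 <- phenotype_table(df)
  des3 <- build_fixed_design(p3, "CW")
  expect_identical(length(des3$y), 7L)
  expect_false(any(grepl("farm|year", colnames(des3$X))))
})

test_that("aliased design columns are dropped with a warning", {
  df <- data.frame(sample_id = sprintf("s%d", 1:10),
                   gender = rep(c("M", "F"), 5),
                   farm = rep(c("f1", "f2"), 5),  # aliased with gender
                   year = 2010, slaughter_age = 600, CW = rnorm(10))
  p <- phenotype_table(df)
  expect_warning(des <- build_fixed_design(p, "CW", use_age = FALSE),
                 "aliased")
  expect_identical(qr(des$X)$rank, ncol(des$X))
})

test_that("profile REML agrees with a direct restricted-likelihood grid oracle", {
  set.seed(31)
  sim <- quick_dataset(n = 120, m = 300, h2 = 0.5, seed = 13)
  geno <- mean_impute(sim$geno)
  des <- build_fixed_design(sim$pheno, "trait")
  grm <- vanraden_grm(geno)
  fit <- fit_reml(des$y, des$X, grm)
  expect_true(fit$converged)

  # oracle: direct (solve/determinant) restricted likelihood with sigma_e2
  # profiled in closed form -- no eigendecomposition anywhere
  direct_profile <- function(lam) {
    n <- length(des$y); p <- ncol(des$X)
    V1 <- lam * grm$values + diag(n)
    Vi <- solve(V1)
    XtViX <- crossprod(des$X, Vi %*% des$X)
    b <- solve(XtViX, crossprod(des$X, Vi %*% des$y))
    r <- des$y - des$X %*% b
    se2 <- drop(crossprod(r, Vi %*% r)) / (n - p)
    direct_restricted_ll(des$y, des$X, grm$values, lam * se2, se2)
  }
  lams <- 10^seq(-2, 2, length.out = 41)
  ll <- vapply(lams, direct_profile, 0)
  i <- which.max(ll)
  opt <- optimize(function(l) -direct_profile(exp(l)),
                  log(c(lams[max(1, i - 1)], lams[min(41, i + 1)])),
                  tol = 1e-10)
  lam_star <- exp(opt$minimum)
  h2_oracle <- lam_star / (1 + lam_star)
  expect_lt(abs(fit$h2 - h2_oracle), 1e-4)

  # reported optimum beats every point of a wide lambda grid
  ll_wide <- vapply(10^seq(-3, 3, length.out = 21), direct_profile, 0)
  expect_gte(fit$loglik + 1e-6, max(ll_wide))
})

test_that("heritability is invariant to rescaling the phenotype", {
  sim <- quick_dataset(n = 150, m = 300, h2 = 0.4, seed = 14)
  geno <- mean_impute(sim$geno)
  des <- build_fixed_design(sim$pheno, "trait")
  grm <- grm_eigen(vanraden_grm(geno))
  f1 <- fit_reml(des$y, des$X, grm)
  f2 <- fit_reml(100 * des$y, des$X, grm)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-6)
  expect_equal(f2$sigma_a2, 1e4 * f1$sigma_a2, tolerance = 1e-4)
})

test_that("an identity GRM is flagged non-identifiable", {
  n <- 50
  grm <- structure(list(values = diag(n), sample_ids = as.character(1:n),
                        denominator = 1, ridge = 0), class = "grm")
  expect_warning(fit <- fit_reml(rnorm(n), matrix(1, n, 1), grm),
                 "identifiable")
  expect_false(fit$converged)
  expect_true(is.na(fit$h2))
})

test_that("pure-noise phenotypes drive h2 to the lower boundary, flagged", {
  sim <- quick_dataset(n = 150, m = 300, seed = 15)
  geno <- mean_impute(sim$geno)
  grm <- vanraden_grm(geno)
  set.seed(1)
  y <- rnorm(150)  # no genetic signal at all
  fit <- fit_reml(y, matrix(1, 150, 1), grm)
  expect_lt(fit$h2, 0.05)
  # SE is NA only if the optimum hit the search edge
  if (!fit$boundary) expect_true(is.finite(fit$se_h2))
})

test_that("GLS fixed effects: noiseless recovery and permutation equivariance", {
  sim <- quick_dataset(n = 80, m = 100, seed = 16)
  geno <- mean_impute(sim$geno)
  grm <- vanraden_grm(geno)
  X <- cbind(1, rnorm(80), runif(80))
  b_true <- c(10, 2, -1)
  y <- drop(X %*% b_true)
  vc <- vc_known(1e-8, 1)
  b_hat <- estimate_fixed_effects(y, X, grm, vc)
  expect_equal(unname(b_hat), b_true, tolerance = 1e-6)

  perm <- sample(80)
  grm_p <- grm_submatrix(grm, grm$sample_ids[perm])
  b_perm <- estimate_fixed_effects(y[perm], X[perm, ], grm_p, vc)
  expect_equal(unname(b_perm), unname(b_hat), tolerance = 1e-8)
})

test_that("REML recovers simulated fixed effects within 3 SE over replicates", {
  sim <- quick_dataset(n = 200, m = 400, h2 = 0.5, seed = 17)
  geno <- mean_impute(sim$geno)
  grm <- grm_eigen(vanraden_grm(geno))
  Z <- geno$dosages
  b_true <- c(10, 2, -1)
  X <- cbind(1, rnorm(200), runif(200))
  reps <- 30
  est <- matrix(0, reps, 3)
  set.seed(18)
  for (r in seq_len(reps)) {
    alpha <- rnorm(400); g <- drop(Z %*% alpha); g <- g / sd(g)
    y <- drop(X %*% b_true) + g + rnorm(200)
    vc <- fit_reml(y, X, grm)
    est[r, ] <- estimate_fixed_effects(y, X, grm, vc)
  }
  se <- apply(est, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(est) - b_true) < 3 * se + 1e-8))
})
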