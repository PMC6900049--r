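test_that("prior scale formula and its preconditions", {
  expect_equal(derive_scale(4.2, 1), 2.2 / 4.2)
  expect_equal(derive_scale(4.2, 0.1), 0.22 / 4.2)
  expect_equal(derive_scale(4.2, 0.1), 10 * derive_scale(4.2, 0.01))
  expect_error(derive_scale(4.2, 0), "expected_marker_variance")
  expect_error(derive_scale(2, 1), "v_df")
  expect_error(mcmc_config(v_df = 1.5), "v_df")
  expect_error(mcmc_config(n_iter = 100, burn_in = 100), "burn_in")
})

test_that("GEBVs are the exact dosage-effect product", {
  Z <- rbind(c(0, 2), c(1, 1))
  out <- gebv_from_effects(Z, c(0.5, -0.25), sample_ids = c("a", "b"))
  expect_equal(out$gebv, c(-0.5, 0.25))
  expect_equal(gebv_from_effects(Z, c(0, 0))$gebv, c(0, 0))
  # duplicating a marker and halving its effect leaves GEBV unchanged
  Z2 <- cbind(Z, Z[, 2])
  expect_equal(gebv_from_effects(Z2, c(0.5, -0.125, -0.125))$gebv,
               out$gebv)
  expect_error(gebv_from_effects(Z, c(1, 2, 3)), "ncol")
})

test_that("samplers are bit-reproducible from the chain seed", {
  sim <- quick_dataset(n = 60, m = 40, seed = 31)
  Z <- mean_impute(sim$geno)$dosages
  y <- sim$pheno$trait
  X <- matrix(1, 60, 1)
  for (model in c("bayesA", "bayesB", "bayesCpi", "bayesR")) {
    cfg <- mcmc_config(n_iter = 300, burn_in = 50, seed = 42)
    a <- run_sampler(model, y, X, Z, cfg)
    b <- run_sampler(model, y, X, Z, cfg)
    expect_identical(a$alpha_mean, b$alpha_mean)
    expect_identical(a$traces, b$traces)
    expect_equal(sum(a$mix_props), 1, tolerance = 1e-12)
    expect_true(all(a$traces[, "sigma_e2"] > 0))
    expect_true(a$pi_mean >= 0 && a$pi_mean <= 1)
  }
})

test_that("conjugate single-marker posterior matches the closed form", {
  set.seed(7)
  n <- 150
  z <- rbinom(n, 2, 0.4)
  zc <- z - mean(z)
  alpha_true <- 0.6
  y <- alpha_true * zc + rnorm(n)
  s2_marker <- 0.5; s2_e <- 1
  cfg <- mcmc_config(n_iter = 20000, burn_in = 2000, seed = 9,
                     Sa2 = s2_marker, sigma_e2_init = s2_e,
                     fix_se2 = TRUE, fix_marker_var = TRUE)
  ps <- run_sampler("bayesA", y, NULL, matrix(z, ncol = 1), cfg)
  C <- sum(zc^2) + s2_e / s2_marker
  post_mean <- sum(zc * y) / C
  post_sd <- sqrt(s2_e / C)
  mc_se <- post_sd / sqrt(ps$n_kept)  # draws are iid in this conjugate case
  expect_lt(abs(ps$alpha_mean - post_mean), 3 * mc_se)
})

test_that("BayesCpi with pi forced to 0 converges to SNP-BLUP", {
  sim <- quick_dataset(n = 50, m = 200, h2 = 0.5, seed = 32)
  geno <- mean_impute(sim$geno)
  Z <- geno$dosages
  y <- sim$pheno$trait
  s2a <- 0.002; s2e <- 1
  cfg <- mcmc_config(n_iter = 8000, burn_in = 1000, seed = 3, Sa2 = s2a,
                     sigma_e2_init = s2e, fix_se2 = TRUE,
                     fix_marker_var = TRUE, pi_init = 0)
  cfg$pi_update <- FALSE
  ps <- run_sampler("bayesCpi", y, matrix(1, 50, 1), Z, cfg)
  W <- sweep(Z, 2, colMeans(Z))
  sb <- snp_blup(y, matrix(1, 50, 1), W, s2e / s2a, 1)
  gebv_bayes <- drop(W %*% ps$alpha_mean)
  expect_gt(cor(gebv_bayes, sb$gebv), 0.995)
  expect_lt(max(abs(gebv_bayes - sb$gebv)), 0.1 * sd(sb$gebv))
})

test_that("BayesB honours its fixed pi and ranks causal markers higher", {
  cfg <- sim_config(n_individuals = 400, n_markers = 300,
                    architecture = "point_normal", pi_true = 0.95,
                    heritability_true = 0.6, ld_decay = 0, seed = 33)
  sim <- simulate_dataset(cfg)
  Z <- mean_impute(sim$geno)$dosages
  mc <- mcmc_config(n_iter = 2000, burn_in = 400, seed = 2, pi_fixed = 0.95,
                    vc_prior = 1)
  ps <- run_sampler("bayesB", sim$pheno$trait, matrix(1, 400, 1), Z, mc)
  expect_identical(ps$pi_mean, 0.95)
  causal <- sim$truth$marker_effects != 0
  expect_gt(mean(ps$incl_prob[causal]), 2 * mean(ps$incl_prob[!causal]))
})

test_that("BayesR on pure-noise data loads the zero component above its prior", {
  sim <- quick_dataset(n = 300, m = 400, seed = 34)
  Z <- mean_impute(sim$geno)$dosages
  set.seed(35)
  y <- rnorm(300)  # no genetic signal
  mc <- mcmc_config(n_iter = 3000, burn_in = 600, seed = 4, vc_prior = var(y) / 2)
  ps <- run_sampler("bayesR", y, matrix(1, 300, 1), Z, mc)
  expect_gt(ps$mix_props[1], 0.25)
  expect_lt(ps$genetic_variance_mean, 0.15 * var(y))
})

test_that("BayesR recovers the identifiable part of a four-component architecture", {
  # the two large-variance components carry essentially all the signal;
  # their combined mass and the genetic variance are the recoverable targets
  props <- c(0.90, 0.05, 0.03, 0.02)
  cfg <- sim_config(n_individuals = 600, n_markers = 2000,
                    architecture = "four_component", component_props = props,
                    heritability_true = 0.5, ld_decay = 0, seed = 1)
  sim <- simulate_dataset(cfg)
  Z <- mean_impute(sim$geno)$dosages
  mc <- mcmc_config(n_iter = 3000, burn_in = 600, seed = 1, vc_prior = 1)
  ps <- run_sampler("bayesR", sim$pheno$trait, matrix(1, 600, 1), Z, mc)
  expect_lt(abs(sum(ps$mix_props[3:4]) - sum(props[3:4])), 0.4)
  expect_lt(abs(ps$genetic_variance_mean - 1), 0.5)
  # markers the sampler is confident about are overwhelmingly true signals
  confident <- ps$comp_prob[, 4] > 0.5
  if (any(confident)) {
    expect_gt(mean(sim$truth$marker_effects[confident]^2),
              mean(sim$truth$marker_effects^2))
  }
})

test_that("sampler rejects invalid inputs", {
  sim <- quick_dataset(n = 20, m = 10, seed = 36)
  Z <- mean_impute(sim$geno)$dosages
  y <- sim$pheno$trait
  expect_error(run_sampler("bayesA", c(y[-1], NA), NULL, Z, mcmc_config(100, 10)),
               "complete")
  Zm <- Z; Zm[1, 1] <- NA
  expect_error(run_sampler("bayesA", y, NULL, Zm, mcmc_config(100, 10)),
               "missing")
})
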