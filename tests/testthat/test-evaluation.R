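test_that("fold plans are balanced, exhaustive and reproducible", {
  plan <- make_fold_plan(1217, k = 5, repeats = 10, seed = 1)
  sizes <- table(plan$assignments[, 1])
  expect_setequal(as.integer(sizes), c(244L, 244L, 243L, 243L, 243L))
  # every sample in exactly one fold per repeat; reference sets ~974
  for (r in 1:10) {
    expect_identical(length(plan$assignments[, r]), 1217L)
    expect_true(all(plan$assignments[, r] %in% 1:5))
  }
  expect_setequal(1217L - as.integer(sizes), c(973L, 973L, 974L, 974L, 974L))

  plan10 <- make_fold_plan(10, k = 5, repeats = 2, seed = 2)
  expect_true(all(table(plan10$assignments[, 1]) == 2))
  expect_identical(make_fold_plan(100, seed = 3)$assignments,
                   make_fold_plan(100, seed = 3)$assignments)
  expect_error(make_fold_plan(10, k = 1), "k")
  expect_error(make_fold_plan(3, k = 5), "n")
})

test_that("phenotype correction subtracts the fixed-effect fit", {
  expect_equal(correct_phenotypes(c(1, 2), matrix(1, 2, 1), 0), c(1, 2))
  expect_equal(correct_phenotypes(c(11, 12), matrix(1, 2, 1), 10), c(1, 2))
  X <- cbind(1, c(0, 1))
  b <- c(3, 2)
  y <- drop(X %*% b)
  expect_equal(correct_phenotypes(y, X, b), c(0, 0))
  expect_error(correct_phenotypes(1:3, matrix(1, 2, 1), 0), "dimensions")
})

test_that("predictive ability is the Pearson correlation with guards", {
  y <- c(1, 2, 4)
  expect_equal(predictive_ability(y, y), 1)
  expect_equal(predictive_ability(-y, y), -1)
  expect_equal(predictive_ability(c(1, 2, 3), c(1, 2, 4)), 0.98198,
               tolerance = 1e-5)
  expect_warning(r <- predictive_ability(c(1, 1, 1), y), "undefined")
  expect_true(is.na(r))
  expect_error(predictive_ability(c(1, 2), c(1, 2)), "3 validation")
})

test_that("accuracy rescales ability by the square root of heritability", {
  expect_equal(round(predictive_accuracy(0.254, 0.24), 3), 0.518)
  expect_equal(round(predictive_accuracy(0.242, 0.37), 3), 0.398)
  expect_equal(predictive_accuracy(0.3, 1), 0.3)
  expect_error(predictive_accuracy(0.3, 0), "h2")
  expect_error(predictive_accuracy(0.3, -1), "h2")
})

test_that("inflation slope is the OLS slope of yhat on GEBV", {
  g <- c(0, 1, 2)
  expect_equal(inflation_slope(g, g), 1)
  expect_equal(inflation_slope(2 * g, g), 2)
  expect_equal(inflation_slope(c(1, 2, 2), c(0, 1, 2)), 0.5)
  expect_warning(b <- inflation_slope(g, c(1, 1, 1)), "undefined")
  expect_true(is.na(b))
})

test_that("MSE is the mean squared difference, translation invariant", {
  expect_equal(mean_squared_error(c(1, 2), c(1, 2)), 0)
  expect_equal(mean_squared_error(c(1, 2), c(0, 0)), 2.5)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(mean_squared_error(a + 5, b + 5), mean_squared_error(a, b))
  expect_error(mean_squared_error(numeric(0), numeric(0)), "empty")
})

test_that("cross-validation produces a complete, internally consistent table", {
  sim <- quick_dataset(n = 250, m = 400, h2 = 0.5, seed = 41)
  geno <- mean_impute(sim$geno)
  mc <- mcmc_config(n_iter = 150, burn_in = 30, seed = 1)
  cv <- run_cross_validation(geno, sim$pheno, "trait",
                             methods = c("gblup", "bayesA"),
                             k = 5, repeats = 2, seed = 5, mcmc = mc)
  expect_identical(nrow(cv), 2L * 5L * 2L)
  h2 <- attr(cv, "vc")$h2
  # accuracy/ability = 1/sqrt(h2) exactly, row by row
  expect_equal(cv$accuracy, cv$ability / sqrt(h2), tolerance = 1e-12)
  expect_true(all(is.finite(cv$mse)))
  expect_true(all(cv$n_val %in% c(50L)))
  summ <- attr(cv, "summary")
  expect_identical(nrow(summ), 2L)

  # deterministic: rerun gives the identical table
  cv2 <- run_cross_validation(geno, sim$pheno, "trait",
                              methods = c("gblup", "bayesA"),
                              k = 5, repeats = 2, seed = 5, mcmc = mc)
  expect_identical(as.data.frame(cv), as.data.frame(cv2))
})

test_that("trait-averaged aggregation is the unweighted mean of trait means", {
  tab <- data.frame(trait = rep(c("A", "B"), each = 4),
                    method = "gblup",
                    ability = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.5, 0.5, 0.5))
  agg <- aggregate_metrics(tab)
  expect_equal(agg$ability, mean(c(0.25, 0.5)))
  expect_identical(agg$n_traits, 2L)
  one <- aggregate_metrics(tab[tab$trait == "A", ])
  expect_equal(one$ability, 0.25)
  expect_error(aggregate_metrics(tab[0, ]), "empty")
})
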