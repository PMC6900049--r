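# shared test helpers: small simulated datasets and LD summaries

quick_dataset <- function(n = 100, m = 200, h2 = 0.4, seed = 1,
                          architecture = "normal", ld = 0.3, ...) {
  cfg <- sim_config(n_individuals = n, n_markers = m,
                    heritability_true = h2, ld_decay = ld,
                    architecture = architecture, seed = seed, ...)
  simulate_dataset(cfg)
}

# mean squared correlation between adjacent marker columns, vectorized
mean_adjacent_r2 <- function(dosages) {
  m <- ncol(dosages)
  x <- scale(dosages)
  r <- colSums(x[, -m, drop = FALSE] * x[, -1, drop = FALSE]) / (nrow(x) - 1)
  mean(r^2, na.rm = TRUE)
}

# hand-built variance components for prediction tests with known truth
vc_known <- function(sigma_a2, sigma_e2) {
  structure(list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
                 h2 = sigma_a2 / (sigma_a2 + sigma_e2), se_h2 = NA_real_,
                 loglik = NA_real_, n_iter = 0L, converged = TRUE,
                 boundary = FALSE),
            class = "variance_components")
}

# restricted log-likelihood computed directly from unrotated matrices;
# an independent oracle for the eigen-profile REML implementation
direct_restricted_ll <- function(y, X, G, sigma_a2, sigma_e2) {
  n <- length(y); p <- ncol(X)
  V <- sigma_a2 * G + diag(sigma_e2, n)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  b <- solve(XtViX, crossprod(X, Vi %*% y))
  r <- y - X %*% b
  -0.5 * ((n - p) * log(2 * pi) + determinant(V)$modulus +
            determinant(XtViX)$modulus + drop(crossprod(r, Vi %*% r)))
}
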