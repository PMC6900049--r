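#' MCMC configuration for the Bayesian alphabet samplers
#'
#' Defaults follow standard practice for these models: 50,000 Gibbs cycles
#' with the first 10,000 discarded as burn-in, scalar traces thinned to
#' every 10th cycle, and prior degrees of freedom v = 4.2 for the scaled
#' inverse-chi-square marker-variance priors. Posterior means of marker
#' effects use every post-burn-in cycle; thinning applies to stored scalar
#' traces only.
#'
#' @param n_iter total Gibbs cycles (default 50000).
#' @param burn_in cycles discarded (default 10000); must be < n_iter.
#' @param thin keep-every for scalar traces (default 10).
#' @param seed integer seed for the chain.
#' @param pi_fixed BayesB's fixed prior proportion of zero-effect markers
#'   (default 0.95; the value is a modelling assumption, not an estimate).
#' @param pi_init starting value of pi for BayesCpi (updated under its
#'   uniform prior) and the value used in deriving the prior scale.
#' @param v_df prior degrees of freedom (> 2; default 4.2).
#' @param vc_prior expected genetic variance used to derive the prior scale
#'   Sa2 and the BayesR component variances; defaults to half the
#'   phenotypic variance of the training records when NULL. Use the REML
#'   additive variance when available.
#' @param Sa2 optional explicit prior scale overriding the derivation.
#' @param update_vg BayesR: refresh the component variances each cycle from
#'   the realized genetic variance instead of keeping them fixed at
#'   \code{vc_prior} (default FALSE).
#' @param center center marker columns before sampling (default TRUE; the
#'   intercept absorbs the shift and marker effects are unchanged).
#' @param fix_se2,fix_marker_var hold the residual / marker variances at
#'   their initial values (used by conjugate-case validation).
#' @param sigma_e2_init starting residual variance; defaults to half the
#'   phenotypic variance when NULL.
#' @return an object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_iter = 50000L, burn_in = 10000L, thin = 10L,
                        seed = 1L, pi_fixed = 0.95, pi_init = 0.5,
                        v_df = 4.2, vc_prior = NULL, Sa2 = NULL,
                        update_vg = FALSE, center = TRUE,
                        fix_se2 = FALSE, fix_marker_var = FALSE,
                        sigma_e2_init = NULL) {
  if (burn_in >= n_iter) stop("burn_in must be < n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  if (v_df <= 2) stop("v_df must be > 2 (prior scale formula requires it)")
  if (pi_fixed < 0 || pi_fixed >= 1) stop("pi_fixed must be in [0, 1)")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 pi_fixed = pi_fixed, pi_init = pi_init, v_df = v_df,
                 vc_prior = vc_prior, Sa2 = Sa2, update_vg = update_vg,
                 center = center, fix_se2 = fix_se2,
                 fix_marker_var = fix_marker_var,
                 sigma_e2_init = sigma_e2_init),
            class = "mcmc_config")
}

#' Prior scale of the marker-variance distribution
#'
#' Sa2 = (v - 2) * E(sigma_j2) / v, the scale of the scaled
#' inverse-chi-square prior whose mean equals the expected per-marker
#' variance E(sigma_j2). The expectation is usually derived from a genetic
#' variance as sigma_a2 / ((1 - pi) * sum 2 p (1 - p)).
#'
#' @param v_df prior degrees of freedom (> 2).
#' @param expected_marker_variance E(sigma_j2) (> 0).
#' @return the scale Sa2.
#' @export
derive_scale <- function(v_df, expected_marker_variance) {
  if (!is.finite(v_df) || v_df <= 2) stop("'v_df' must be > 2")
  if (!is.finite(expected_marker_variance) || expected_marker_variance <= 0)
    stop("'expected_marker_variance' must be > 0")
  (v_df - 2) * expected_marker_variance / v_df
}

#' Run a Bayesian-alphabet Gibbs sampler
#'
#' Single-site Gibbs over fixed effects (flat prior), marker effects, their
#' variances, inclusion indicators / mixture labels, and the residual
#' variance, for one of:
#' \describe{
#'   \item{bayesA}{every marker has an effect; per-marker variances from
#'     scaled-inv-chi-square(v, Sa2).}
#'   \item{bayesB}{point-normal mixture with fixed prior zero-proportion
#'     \code{pi_fixed}; indicators sampled with the effect integrated out.}
#'   \item{bayesCpi}{point-normal with one common effect variance and pi
#'     updated from Beta(M - m1 + 1, m1 + 1) under its uniform prior.}
#'   \item{bayesR}{four-component normal mixture with variances 0, 0.01\%,
#'     0.1\% and 1\% of the genetic variance and mixture proportions from
#'     Dirichlet(counts + 1).}
#' }
#'
#' @param model one of "bayesA", "bayesB", "bayesCpi", "bayesR".
#' @param y numeric vector of training phenotypes (complete).
#' @param X fixed-effect design matrix (may have zero columns).
#' @param Z N x M dosage matrix on the 0/1/2 coding, mean-imputed (no
#'   missing values); centered internally when \code{cfg$center}.
#' @param cfg an \code{\link{mcmc_config}}.
#' @return object of class \code{posterior_summary}: alpha_mean, b_mean,
#'   pi_mean, incl_prob, comp_prob, mix_props, sigma_e2_mean,
#'   genetic_variance_mean, traces (thinned scalar draws), model, Sa2.
#' @export
run_sampler <- function(model = c("bayesA", "bayesB", "bayesCpi", "bayesR"),
                        y, X, Z, cfg = mcmc_config()) {
  model <- match.arg(model)
  stopifnot(inherits(cfg, "mcmc_config"))
  Z <- as.matrix(Z)
  if (is.null(X)) X <- matrix(0, length(y), 0L)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(Z) != n || nrow(X) != n) stop("y, X and Z are not aligned")
  if (anyNA(y) || any(!is.finite(y))) stop("y must be complete and finite")
  if (anyNA(Z)) stop("Z contains missing dosages; run mean_impute() first")

  # prior scale: E(sigma_j2) = vc_prior / ((1 - pi) * sum 2p(1-p))
  vc_prior <- if (is.null(cfg$vc_prior)) 0.5 * var(y) else cfg$vc_prior
  pbar <- colMeans(Z) / 2
  sum2pq <- sum(2 * pbar * (1 - pbar))
  pi_for_scale <- switch(model, bayesA = 0, bayesB = cfg$pi_fixed,
                         bayesCpi = cfg$pi_init, bayesR = 0)
  Sa2 <- cfg$Sa2
  if (is.null(Sa2)) {
    e_sj2 <- vc_prior / max((1 - pi_for_scale) * sum2pq, .Machine$double.eps)
    Sa2 <- derive_scale(cfg$v_df, e_sj2)
  }
  comp_var <- c(0, 1e-4, 1e-3, 1e-2) * vc_prior

  Zc <- if (cfg$center) sweep(Z, 2L, colMeans(Z), `-`) else Z
  model_code <- match(model, c("bayesA", "bayesB", "bayesCpi", "bayesR")) - 1L
  pi_init <- switch(model, bayesA = 0, bayesB = cfg$pi_fixed,
                    bayesCpi = cfg$pi_init, bayesR = 0)
  pi_update <- model == "bayesCpi" && !isFALSE(cfg$pi_update)
  set.seed(cfg$seed)
  out <- .gibbs_wgr(y, X, Zc, model_code, cfg$n_iter, cfg$burn_in, cfg$thin,
                    pi_init, pi_update, cfg$v_df, Sa2,
                    comp_var, isTRUE(cfg$update_vg),
                    if (is.null(cfg$sigma_e2_init)) var(y) / 2 else cfg$sigma_e2_init,
                    isTRUE(cfg$fix_se2), isTRUE(cfg$fix_marker_var),
                    model == "bayesCpi" && is.null(cfg$Sa2), vc_prior, sum2pq)
  traces <- out$traces
  colnames(traces) <- c("sigma_e2", if (model == "bayesR") "p1" else "pi", "var_g")
  structure(list(model = model,
                 alpha_mean = setNames(out$alpha_mean, colnames(Z)),
                 b_mean = setNames(out$b_mean, colnames(X)),
                 pi_mean = if (model == "bayesB") cfg$pi_fixed else out$pi_mean,
                 incl_prob = out$incl_prob,
                 comp_prob = out$comp_prob,
                 mix_props = out$mix_props,
                 sigma_e2_mean = out$sigma_e2_mean,
                 genetic_variance_mean = out$genetic_variance_mean,
                 traces = traces, Sa2 = Sa2, n_kept = out$n_kept,
                 config = cfg),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior_summary [%s]: %d markers, pi_mean = %.3f, sigma_e2 = %.4g, var_g = %.4g\n",
              x$model, length(x$alpha_mean), x$pi_mean, x$sigma_e2_mean,
              x$genetic_variance_mean))
  if (x$model == "bayesR")
    cat("  mixture proportions:", paste(sprintf("%.3f", x$mix_props), collapse = " "), "\n")
  invisible(x)
}

#' Genomic breeding values from posterior-mean marker effects
#'
#' GEBV_i = sum_j Z_ij alpha_j, an exact matrix-vector product on the
#' stored dosage coding.
#'
#' @param Z N x M dosage matrix.
#' @param alpha_mean length-M vector of (posterior-mean) marker effects, or
#'   a \code{\link{run_sampler}} result.
#' @param sample_ids optional ids for the result rows.
#' @return object of class \code{gebv_result}: data.frame(sample_id, gebv).
#' @export
gebv_from_effects <- function(Z, alpha_mean, sample_ids = rownames(Z)) {
  if (inherits(alpha_mean, "posterior_summary")) {
    method <- alpha_mean$model
    alpha_mean <- alpha_mean$alpha_mean
  } else method <- "marker_effects"
  Z <- as.matrix(Z)
  if (ncol(Z) != length(alpha_mean))
    stop("ncol(Z) != length(alpha_mean)")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(Z)))
  structure(data.frame(sample_id = sample_ids,
                       gebv = drop(Z %*% alpha_mean),
                       stringsAsFactors = FALSE),
            method = method, class = c("gebv_result", "data.frame"))
}
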