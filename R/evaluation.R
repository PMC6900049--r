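#' Balanced k-fold assignments, repeated
#'
#' Uniformly random balanced partition of n samples into k folds, repeated
#' \code{repeats} times; fold sizes differ by at most one. With n = 1217
#' and k = 5 the validation folds have 243-244 animals and the reference
#' sets 973-974, the usual split for this population size.
#'
#' @param n sample count (>= k).
#' @param k folds (default 5).
#' @param repeats independent repetitions (default 10).
#' @param seed integer seed.
#' @return object of class \code{fold_plan}: list(n, k, repeats, seed,
#'   assignments), where assignments is an n x repeats integer matrix of
#'   fold labels.
#' @export
make_fold_plan <- function(n, k = 5L, repeats = 10L, seed = 1L) {
  if (k < 2L) stop("'k' must be >= 2")
  if (n < k) stop("'n' must be >= 'k'")
  set.seed(seed)
  assignments <- vapply(seq_len(repeats), function(r) {
    sample(rep_len(seq_len(k), n))
  }, integer(n))
  structure(list(n = as.integer(n), k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 assignments = assignments),
            class = "fold_plan")
}

#' Corrected phenotypes
#'
#' yhat = y - X b-hat: the phenotype with estimated fixed effects removed,
#' the prediction target in validation.
#'
#' @param y phenotype vector.
#' @param X fixed-effect design.
#' @param b_hat fixed-effect estimates (typically from the full-data animal
#'   model, \code{\link{estimate_fixed_effects}}).
#' @return numeric vector of corrected phenotypes.
#' @export
correct_phenotypes <- function(y, X, b_hat) {
  X <- as.matrix(X)
  if (nrow(X) != length(y) || ncol(X) != length(b_hat))
    stop("y, X and b_hat dimensions do not agree")
  y - drop(X %*% b_hat)
}

#' Predictive ability: Pearson correlation of GEBV and corrected phenotype
#'
#' @param gebv predicted breeding values of the validation animals.
#' @param y_corr their corrected phenotypes.
#' @return the correlation r, or NA with a warning if either vector is
#'   constant (undefined, never silently 0).
#' @export
predictive_ability <- function(gebv, y_corr) {
  if (length(gebv) != length(y_corr)) stop("vectors differ in length")
  if (length(gebv) < 3L) stop("need at least 3 validation animals")
  if (sd(gebv) == 0 || sd(y_corr) == 0) {
    warning("predictive ability undefined: constant input vector")
    return(NA_real_)
  }
  cor(gebv, y_corr)
}

#' Predictive accuracy: ability divided by the square root of heritability
#'
#' r / sqrt(h2), which approximates the correlation between GEBV and the
#' true breeding value.
#'
#' @param r predictive ability.
#' @param h2 trait heritability in (0, 1].
#' @return the accuracy.
#' @export
predictive_accuracy <- function(r, h2) {
  if (!is.finite(h2) || h2 <= 0 || h2 > 1) stop("'h2' must be in (0, 1]")
  r / sqrt(h2)
}

#' Inflation slope of corrected phenotype on GEBV
#'
#' OLS slope of yhat regressed on GEBV; values below 1 indicate inflated
#' (over-dispersed) predictions, values near 1 a well-scaled predictor.
#'
#' @param y_corr corrected phenotypes.
#' @param gebv predicted breeding values.
#' @return the regression slope, or NA with a warning if GEBV is constant.
#' @export
inflation_slope <- function(y_corr, gebv) {
  if (length(gebv) != length(y_corr)) stop("vectors differ in length")
  if (var(gebv) == 0) {
    warning("inflation slope undefined: zero GEBV variance")
    return(NA_real_)
  }
  drop(cov(y_corr, gebv) / var(gebv))
}

#' Mean squared error of prediction
#'
#' (1/N) sum (GEBV_i - yhat_i)^2 between predictions and corrected
#' phenotypes; lower is a better overall fit.
#'
#' @param gebv predicted breeding values.
#' @param y_corr corrected phenotypes.
#' @return the mean squared difference.
#' @export
mean_squared_error <- function(gebv, y_corr) {
  if (!length(gebv)) stop("empty vectors")
  if (length(gebv) != length(y_corr)) stop("vectors differ in length")
  mean((gebv - y_corr)^2)
}

#' Cross-validated evaluation of genomic predictors
#'
#' For every repeat x fold x method: fit on the reference animals (the
#' out-of-fold samples), predict the masked validation animals, and score
#' the predictions against corrected phenotypes with the four criteria
#' (predictive ability, accuracy = ability / sqrt(h2), inflation slope,
#' MSE). Fixed-effect correction and the h2 in the accuracy denominator
#' come from the full-data REML fit by default, the convention that pairs a
#' single per-trait h2 with all folds; per-fold correction is available via
#' \code{correction = "per_fold"}. GBLUP re-estimates variance components
#' on each training fold (no leakage); \code{vc_policy = "full_data"} reuses
#' the full-data fit instead.
#'
#' @param geno complete (mean-imputed) \code{\link{genotype_matrix}},
#'   samples aligned with \code{pheno}.
#' @param pheno a \code{\link{phenotype_table}}.
#' @param trait trait column to evaluate.
#' @param methods character subset of c("gblup", "bayesA", "bayesB",
#'   "bayesCpi", "bayesR").
#' @param plan a \code{\link{make_fold_plan}} over the samples with an
#'   observed trait value; built automatically when NULL.
#' @param mcmc an \code{\link{mcmc_config}} for the Bayesian methods.
#' @param k,repeats,seed fold-plan parameters used when \code{plan} is NULL.
#' @param correction "full_data" (default) or "per_fold" fixed-effect
#'   correction.
#' @param vc_policy "per_fold" (default) or "full_data" variance components
#'   for GBLUP.
#' @param use_age passed to \code{\link{build_fixed_design}}.
#' @return object of class \code{cv_metrics}: data.frame(trait, method,
#'   repeat_id, fold, n_val, ability, accuracy, slope, mse) with the
#'   full-data fit attached as attributes \code{"vc"} (h2 etc.) and
#'   \code{"summary"} (per-method means).
#' @export
run_cross_validation <- function(geno, pheno, trait,
                                 methods = c("gblup", "bayesA", "bayesB",
                                             "bayesCpi", "bayesR"),
                                 plan = NULL, mcmc = mcmc_config(),
                                 k = 5L, repeats = 10L, seed = 1L,
                                 correction = c("full_data", "per_fold"),
                                 vc_policy = c("per_fold", "full_data"),
                                 use_age = NULL) {
  correction <- match.arg(correction)
  vc_policy <- match.arg(vc_policy)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(inherits(geno, "genotype_matrix"), inherits(pheno, "phenotype_table"))
  if (anyNA(geno$dosages)) geno <- mean_impute(geno)

  des <- build_fixed_design(pheno, trait, use_age = use_age)
  ids <- des$sample_ids
  geno_t <- subset_samples(geno, match(ids, geno$sample_ids))
  Z <- geno_t$dosages
  y <- des$y
  X <- des$X
  n <- length(y)
  if (is.null(plan)) plan <- make_fold_plan(n, k, repeats, seed)
  if (plan$n != n) stop("fold plan was built for a different sample count")

  grm <- grm_eigen(vanraden_grm(geno_t))
  vc_full <- fit_reml(y, X, grm)
  h2 <- vc_full$h2
  if (!is.finite(h2) || h2 <= 0) stop("full-data heritability is not positive")
  b_full <- estimate_fixed_effects(y, X, grm, vc_full)
  y_corr_full <- correct_phenotypes(y, X, b_full)

  rows <- list()
  for (rep_i in seq_len(plan$repeats)) {
    fold_of <- plan$assignments[, rep_i]
    for (fold in seq_len(plan$k)) {
      val <- which(fold_of == fold)
      ref <- which(fold_of != fold)
      y_ref <- y[ref]; X_ref <- X[ref, , drop = FALSE]
      X_ref <- X_ref[, apply(X_ref, 2L, function(cl) sd(cl) > 0) |
                       colnames(X_ref) == "(Intercept)", drop = FALSE]
      y_corr <- if (correction == "full_data") y_corr_full[val] else NULL
      vc_fold <- NULL
      for (method in methods) {
        cell <- tryCatch({
          if (method == "gblup") {
            if (vc_policy == "per_fold") {
              if (is.null(vc_fold)) {
                grm_ref <- grm_submatrix(grm, ids[ref])
                vc_fold <- fit_reml(y_ref, X_ref, grm_ref)
              }
              vc_use <- vc_fold
            } else vc_use <- vc_full
            fit <- fit_gblup(y_ref, X_ref, grm, ids[ref], vc_use)
            gebv_val <- fit$gebv[val]
            b_fold <- attr(fit, "b_hat")
          } else {
            cfg <- mcmc
            cfg$seed <- mcmc$seed + 1000L * rep_i + fold
            cfg$vc_prior <- vc_full$sigma_a2
            ps <- run_sampler(method, y_ref, X_ref, Z[ref, , drop = FALSE], cfg)
            gebv_val <- drop(Z[val, , drop = FALSE] %*% ps$alpha_mean)
            b_fold <- ps$b_mean
          }
          if (correction == "per_fold") {
            Xv <- X[val, colnames(X_ref), drop = FALSE]
            y_corr <- correct_phenotypes(y[val], Xv, b_fold)
          }
          ability <- predictive_ability(gebv_val, y_corr)
          data.frame(trait = trait, method = method, repeat_id = rep_i,
                     fold = fold, n_val = length(val), ability = ability,
                     accuracy = predictive_accuracy(ability, h2),
                     slope = inflation_slope(y_corr, gebv_val),
                     mse = mean_squared_error(gebv_val, y_corr))
        }, error = function(e) {
          warning(sprintf("cv cell failed (%s, repeat %d, fold %d): %s",
                          method, rep_i, fold, conditionMessage(e)))
          NULL
        })
        if (!is.null(cell)) rows[[length(rows) + 1L]] <- cell
      }
    }
  }
  if (!length(rows)) stop("cross-validation produced no results")
  tab <- do.call(rbind, rows)
  summ <- aggregate(tab[, c("ability", "accuracy", "slope", "mse")],
                    by = list(trait = tab$trait, method = tab$method), mean)
  structure(tab, vc = vc_full, summary = summ,
            class = c("cv_metrics", "data.frame"))
}

#' Aggregate a metrics table across traits
#'
#' Per-method means over fold-repeats within trait, then the unweighted
#' mean over traits. Values are kept at full precision; rounding to 3
#' decimals belongs to presentation.
#'
#' @param table data.frame with columns trait, method and one or more of
#'   ability, accuracy, slope, mse (e.g. a \code{\link{run_cross_validation}}
#'   result or a transcribed results table in long form).
#' @return data.frame with one row per method and the trait-averaged
#'   metrics, plus \code{n_traits} averaged over.
#' @export
aggregate_metrics <- function(table) {
  table <- as.data.frame(table)
  if (!nrow(table)) stop("empty metrics table")
  metrics <- intersect(c("ability", "accuracy", "slope", "mse"), names(table))
  if (!length(metrics)) stop("no metric columns found")
  per_trait <- aggregate(table[, metrics, drop = FALSE],
                         by = list(trait = table$trait, method = table$method),
                         mean, na.rm = TRUE)
  out <- aggregate(per_trait[, metrics, drop = FALSE],
                   by = list(method = per_trait$method), mean, na.rm = TRUE)
  counts <- aggregate(list(n_traits = per_trait$trait),
                      by = list(method = per_trait$method),
                      function(x) length(unique(x)))
  merge(out, counts, by = "method")
}
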