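#' Build the fixed-effect design matrix for a trait
#'
#' Intercept plus treatment-coded gender, farm and year (first level as
#' reference) and, when \code{use_age}, the centered slaughter-age
#' covariate. Rows are restricted to samples with an observed trait value.
#' Factors that are constant on those rows contribute no columns; aliased
#' columns are dropped with a warning naming them. By convention the age
#' covariate is omitted for average daily gain ("ADG"), which is itself an
#' age-standardized trait.
#'
#' @param pheno a \code{\link{phenotype_table}}.
#' @param trait trait column name.
#' @param use_age include the age covariate; default is TRUE for every
#'   trait except \code{"ADG"}.
#' @return list: \code{X} (full-column-rank matrix), \code{rows} (row
#'   indices into \code{pheno}), \code{sample_ids}, \code{y} (observed
#'   trait values).
#' @export
build_fixed_design <- function(pheno, trait, use_age = NULL) {
  stopifnot(inherits(pheno, "phenotype_table"))
  if (!trait %in% names(pheno)) stop("unknown trait: ", trait)
  if (is.null(use_age)) use_age <- !identical(trait, "ADG")
  rows <- which(!is.na(pheno[[trait]]) & !is.na(pheno$gender) &
                !is.na(pheno$farm) & !is.na(pheno$year) &
                (!use_age | !is.na(pheno$slaughter_age)))
  if (!length(rows)) stop("trait '", trait, "' has no observed values")
  df <- as.data.frame(pheno)[rows, , drop = FALSE]
  X <- matrix(1, length(rows), 1L, dimnames = list(NULL, "(Intercept)"))
  for (fc in c("gender", "farm", "year")) {
    f <- droplevels(factor(df[[fc]]))
    if (nlevels(f) > 1L) {
      mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(fc, levels(f)[-1L])
      X <- cbind(X, mm)
    }
  }
  if (use_age) {
    age <- df$slaughter_age
    if (sd(age) > 0) X <- cbind(X, slaughter_age = age - mean(age))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warning("dropping aliased design column(s): ", paste(aliased, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  list(X = X, rows = rows, sample_ids = df$sample_id, y = df[[trait]])
}

#' REML variance components under the animal model
#'
#' Maximizes the restricted likelihood of y ~ N(Xb, G sigma_a2 + I sigma_e2)
#' by eigendecomposing G once and profiling the restricted likelihood over
#' the single ratio lambda = sigma_a2 / sigma_e2, searched in log space on
#' [1e-6, 1e6] by Brent minimization; sigma_e2 is then recovered in closed
#' form. The standard error of h2 comes from the inverse average-information
#' matrix at the optimum via the delta method. Deterministic: no starting
#' values, no sampling.
#'
#' @param y numeric observation vector (no missing values).
#' @param X full-column-rank fixed-effect design with \code{nrow(X) ==
#'   length(y)}.
#' @param grm a \code{\link{vanraden_grm}} result aligned with \code{y};
#'   if it carries a cached \code{\link{grm_eigen}} decomposition it is
#'   reused.
#' @param tol convergence tolerance on log(lambda) (default 1e-9, i.e.
#'   relative change in lambda below ~1e-9).
#' @return object of class \code{variance_components}: sigma_a2, sigma_e2,
#'   h2, se_h2, loglik, n_iter, converged, boundary.
#' @export
fit_reml <- function(y, X, grm, tol = 1e-9) {
  stopifnot(inherits(grm, "grm"))
  n <- length(y)
  if (any(!is.finite(y))) stop("non-finite values in y")
  if (nrow(X) != n || nrow(grm$values) != n)
    stop("y, X and grm are not aligned (lengths differ)")
  p <- ncol(X)
  if (n <= p) stop("need more observations than fixed-effect columns")
  eg <- if (!is.null(grm$eig)) grm$eig else eigen(grm$values, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (sd(d) < 1e-8 * max(mean(d), 1)) {
    warning("GRM is (numerically) proportional to the identity: only the ",
            "total variance is identifiable; returning a flagged fit")
    return(structure(list(sigma_a2 = NA_real_, sigma_e2 = var(y),
                          h2 = NA_real_, se_h2 = NA_real_,
                          loglik = NA_real_, n_iter = 0L,
                          converged = FALSE, boundary = FALSE),
                     class = "variance_components"))
  }
  ys <- crossprod(eg$vectors, y)
  Xs <- crossprod(eg$vectors, X)

  n_eval <- 0L
  profile <- function(log_lambda) {
    lam <- exp(log_lambda)
    v <- 1 + lam * d                      # V = sigma_e2 * diag(v)
    w <- 1 / v
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    ch <- chol(XtWX)
    b <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- ys - Xs %*% b
    rss <- sum(w * r^2)
    sigma_e2 <- rss / (n - p)
    neg2 <- (n - p) * log(sigma_e2) + sum(log(v)) + 2 * sum(log(diag(ch))) +
      (n - p)
    list(neg2 = neg2, sigma_e2 = sigma_e2, b = b)
  }
  obj <- function(ll) {
    n_eval <<- n_eval + 1L
    profile(ll)$neg2
  }
  lo <- log(1e-6); hi <- log(1e6)
  opt <- optimize(obj, interval = c(lo, hi), tol = tol)
  lam <- exp(opt$minimum)
  fit <- profile(opt$minimum)
  sigma_e2 <- fit$sigma_e2
  sigma_a2 <- lam * sigma_e2
  h2 <- sigma_a2 / (sigma_a2 + sigma_e2)
  boundary <- opt$minimum < lo + 1e-3 || opt$minimum > hi - 1e-3
  loglik <- -0.5 * (opt$objective + (n - p) * log(2 * pi))

  # average-information SE for h2 (delta method); NA at the boundary
  se_h2 <- NA_real_
  if (!boundary) {
    vfull <- sigma_e2 + sigma_a2 * d
    w <- 1 / vfull
    XtWX <- crossprod(Xs, Xs * w)
    applyP <- function(z) {
      t1 <- w * z
      bz <- solve(XtWX, crossprod(Xs, t1))
      t1 - w * (Xs %*% bz)
    }
    u <- applyP(ys)
    gu <- d * u
    ai <- matrix(0, 2, 2)
    ai[1, 1] <- 0.5 * sum(gu * applyP(gu))
    ai[1, 2] <- ai[2, 1] <- 0.5 * sum(gu * applyP(u))
    ai[2, 2] <- 0.5 * sum(u * applyP(u))
    vc_cov <- tryCatch(solve(ai), error = function(e) NULL)
    if (!is.null(vc_cov)) {
      grad <- c(sigma_e2, -sigma_a2) / (sigma_a2 + sigma_e2)^2
      v_h2 <- drop(t(grad) %*% vc_cov %*% grad)
      if (is.finite(v_h2) && v_h2 >= 0) se_h2 <- sqrt(v_h2)
    }
  }
  structure(list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, h2 = h2,
                 se_h2 = se_h2, loglik = loglik, n_iter = n_eval,
                 converged = TRUE, boundary = boundary),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("sigma_a2 = %.4g, sigma_e2 = %.4g, h2 = %.3f (SE %.3f), logLik = %.2f%s\n",
              x$sigma_a2, x$sigma_e2, x$h2, x$se_h2, x$loglik,
              if (isTRUE(x$boundary)) " [at boundary]" else ""))
  invisible(x)
}

#' GLS estimates of fixed effects at the REML optimum
#'
#' b-hat = (X' V^-1 X)^-1 X' V^-1 y with V = G sigma_a2 + I sigma_e2.
#'
#' @param y,X,grm as in \code{\link{fit_reml}}, mutually aligned.
#' @param vc a converged \code{\link{fit_reml}} result.
#' @return named numeric vector of fixed-effect estimates.
#' @export
estimate_fixed_effects <- function(y, X, grm, vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (!isTRUE(vc$converged)) stop("variance components did not converge")
  eg <- if (!is.null(grm$eig)) grm$eig else eigen(grm$values, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  ys <- crossprod(eg$vectors, y)
  Xs <- crossprod(eg$vectors, X)
  w <- 1 / (vc$sigma_e2 + vc$sigma_a2 * d)
  XtWX <- crossprod(Xs, Xs * w)
  b <- tryCatch(solve(XtWX, crossprod(Xs, ys * w)),
                error = function(e) stop("singular X' V^-1 X: ", conditionMessage(e)))
  setNames(drop(b), colnames(X))
}
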