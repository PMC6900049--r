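#' GBLUP breeding-value prediction
#'
#' Fits the animal model y = Xb + g + e on the reference animals, with
#' g ~ N(0, G sigma_a2) and e ~ N(0, I sigma_e2), and predicts GEBVs for
#' every animal in the GRM. Reference GEBVs come from the mixed-model
#' solution g-hat_ref = sigma_a2 G_rr V_rr^-1 (y - X b-hat); animals outside
#' the reference (whose phenotypes are masked) are predicted by the BLUP
#' conditional mean, which equals sigma_a2 G_vr V_rr^-1 (y - X b-hat) --
#' algebraically the same as G_vr G_rr^-1 g-hat_ref, without forming
#' G_rr^-1.
#'
#' @param y_ref phenotypes of the reference animals.
#' @param X_ref fixed-effect design for the reference animals.
#' @param grm GRM over reference plus prediction animals.
#' @param ref_ids sample ids (in \code{grm$sample_ids}) of the reference
#'   animals, in the order of \code{y_ref}.
#' @param vc converged \code{\link{fit_reml}} variance components.
#' @param ridge ridge added to V as a fraction of its mean diagonal if the
#'   plain Cholesky fails (default 1e-6); its use is recorded in the result.
#' @return object of class \code{gebv_result}: data.frame(sample_id, gebv)
#'   plus \code{b_hat} and \code{method = "gblup"} attributes.
#' @export
fit_gblup <- function(y_ref, X_ref, grm, ref_ids, vc, ridge = 1e-6) {
  stopifnot(inherits(grm, "grm"), inherits(vc, "variance_components"))
  if (!isTRUE(vc$converged)) stop("variance components did not converge")
  idx <- match(ref_ids, grm$sample_ids)
  if (anyNA(idx)) stop("unknown reference id: ", ref_ids[which(is.na(idx))[1L]])
  if (length(y_ref) != length(idx) || nrow(X_ref) != length(idx))
    stop("y_ref, X_ref and ref_ids are not aligned")
  g_rr <- grm$values[idx, idx, drop = FALSE]
  v <- vc$sigma_a2 * g_rr
  diag(v) <- diag(v) + vc$sigma_e2
  ch <- tryCatch(chol(v), error = function(e) {
    chol(v + diag(ridge * mean(diag(v)), nrow(v)))
  })
  vinv <- function(z) backsolve(ch, forwardsolve(t(ch), z))
  XtVin <- vinv(X_ref)
  b_hat <- tryCatch(solve(crossprod(X_ref, XtVin), crossprod(XtVin, y_ref)),
                    error = function(e) stop("singular GLS system: ",
                                             conditionMessage(e)))
  r <- y_ref - X_ref %*% b_hat
  u <- vinv(r)
  gebv <- unname(vc$sigma_a2 * drop(grm$values[, idx, drop = FALSE] %*% u))
  structure(data.frame(sample_id = grm$sample_ids, gebv = gebv,
                       stringsAsFactors = FALSE),
            b_hat = setNames(drop(b_hat), colnames(X_ref)),
            method = "gblup", class = c("gebv_result", "data.frame"))
}

#' Ridge-regression marker effects (SNP-BLUP), dual form
#'
#' alpha-hat = W' (W W' + lambda * denominator * I)^-1 (y - X b-hat), with W
#' the column-centered dosage matrix and b-hat the GLS estimate under
#' V proportional to W W' + lambda * denominator * I. With lambda =
#' sigma_e2 / sigma_a2 and the VanRaden denominator this is exactly
#' equivalent to GBLUP with the method-1 G: GEBV = W alpha-hat; the
#' equivalence is exercised in the test suite as an independent check on
#' both solvers.
#'
#' @param y_ref reference phenotypes.
#' @param X_ref fixed-effect design.
#' @param W_ref column-centered reference dosage matrix.
#' @param lambda positive ridge ratio (sigma_e2 / sigma_a2).
#' @param denominator scaling constant; VanRaden's sum 2 p (1 - p) by
#'   default when \code{NULL}, computed from W as if centered at 2p.
#' @return list: \code{alpha} (length-M effects), \code{gebv} (W alpha),
#'   \code{b_hat}.
#' @export
snp_blup <- function(y_ref, X_ref, W_ref, lambda, denominator = NULL) {
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be > 0")
  n <- length(y_ref)
  if (nrow(W_ref) != n || nrow(X_ref) != n)
    stop("y_ref, X_ref and W_ref are not aligned")
  if (is.null(denominator)) denominator <- sum(colSums(W_ref^2)) / n
  k <- tcrossprod(W_ref)
  diag(k) <- diag(k) + lambda * denominator
  ch <- chol(k)
  kin <- function(z) backsolve(ch, forwardsolve(t(ch), z))
  if (ncol(X_ref) > 0L) {
    XtKin <- kin(X_ref)
    b_hat <- solve(crossprod(X_ref, XtKin), crossprod(XtKin, y_ref))
    r <- y_ref - X_ref %*% b_hat
  } else {
    b_hat <- numeric(0)
    r <- y_ref
  }
  u <- kin(r)
  alpha <- unname(drop(crossprod(W_ref, u)))
  list(alpha = alpha, gebv = unname(drop(W_ref %*% alpha)),
       b_hat = setNames(drop(b_hat), colnames(X_ref)))
}
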