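#' VanRaden genomic relationship matrix (method 1)
#'
#' G = W W' / sum_j 2 p_j (1 - p_j), where W is the column-centered dosage
#' matrix (w_ij = z_ij - 2 p_j) and p_j the observed counted-allele
#' frequencies. Under Hardy-Weinberg the mean diagonal is close to 1, so G
#' is on the scale of the pedigree numerator relationship matrix.
#'
#' @param geno complete \code{\link{genotype_matrix}} (mean-imputed if
#'   needed) with at least one polymorphic marker.
#' @param ridge optional nonnegative ridge added as ridge * mean(diag(G)) * I;
#'   0 by default. Solvers that need strict positive definiteness pass a
#'   small value (1e-6) explicitly so every run is reproducible from config.
#' @return an object of class \code{grm}: list(values, sample_ids,
#'   denominator, ridge).
#' @export
vanraden_grm <- function(geno, ridge = 0) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  if (anyNA(d)) stop("genotypes contain missing calls; run mean_impute() first")
  p <- colMeans(d) / 2
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: VanRaden denominator is zero")
  w <- sweep(d, 2L, 2 * p, `-`)
  g <- tcrossprod(w) / denom
  g <- (g + t(g)) / 2  # enforce exact symmetry against float drift
  if (ridge > 0) g <- g + diag(ridge * mean(diag(g)), nrow(g))
  structure(list(values = g, sample_ids = geno$sample_ids,
                 denominator = denom, ridge = ridge),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d x %d, denominator %.4f, mean diagonal %.4f\n",
              nrow(x$values), ncol(x$values), x$denominator,
              mean(diag(x$values))))
  invisible(x)
}

#' Principal submatrix of a GRM
#'
#' @param grm a \code{\link{vanraden_grm}} result.
#' @param ids sample ids to keep, in the requested order.
#' @return a \code{grm} restricted to \code{ids}.
#' @export
grm_submatrix <- function(grm, ids) {
  stopifnot(inherits(grm, "grm"))
  idx <- match(ids, grm$sample_ids)
  if (anyNA(idx)) stop("unknown sample id: ", ids[which(is.na(idx))[1L]])
  structure(list(values = grm$values[idx, idx, drop = FALSE],
                 sample_ids = grm$sample_ids[idx],
                 denominator = grm$denominator, ridge = grm$ridge),
            class = "grm")
}

#' Attach a cached eigendecomposition to a GRM
#'
#' REML profiles the likelihood on the eigenbasis of G; when many fits share
#' one GRM (replicated simulations, cross-validation folds on fixed ids) the
#' decomposition is computed once here and reused by \code{\link{fit_reml}}.
#'
#' @param grm a \code{grm}.
#' @return the same \code{grm} with an \code{eig} element.
#' @export
grm_eigen <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  if (is.null(grm$eig)) grm$eig <- eigen(grm$values, symmetric = TRUE)
  grm
}

#' Write a GRM as a delimited square matrix with an id header
#' @param grm a \code{grm}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_grm <- function(grm, path) {
  m <- grm$values
  dimnames(m) <- list(grm$sample_ids, grm$sample_ids)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GRM written by \code{\link{write_grm}}
#' @param path file path.
#' @return a \code{grm} (denominator unknown, recorded as NA).
#' @export
read_grm <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(df$sample_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(ids, ids)
  structure(list(values = m, sample_ids = ids, denominator = NA_real_,
                 ridge = 0),
            class = "grm")
}
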