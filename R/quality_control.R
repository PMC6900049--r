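#' Counted-allele frequencies
#'
#' Per-marker frequency of the counted allele, p_j = (sum of non-missing
#' dosages) / (2 x non-missing count). The minor allele frequency is
#' min(p, 1 - p).
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @return numeric vector of M frequencies, named by marker id.
#' @export
allele_frequencies <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  ncall <- colSums(!is.na(geno$dosages))
  if (any(ncall == 0L))
    stop("marker with no non-missing calls: ",
         geno$marker_ids[which(ncall == 0L)[1L]])
  setNames(colSums(geno$dosages, na.rm = TRUE) / (2 * ncall), geno$marker_ids)
}

#' Minor allele frequencies
#' @inheritParams allele_frequencies
#' @return numeric vector of MAFs in [0, 0.5].
#' @export
minor_allele_frequencies <- function(geno) {
  p <- allele_frequencies(geno)
  pmin(p, 1 - p)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' (n_AA, n_Aa, n_aa) against the HWE expectation (p^2, 2pq, q^2) at the
#' observed allele frequency. Monomorphic markers return p = 1 by
#' convention (nothing to test).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (dosage 0, 1, 2 respectively).
#' @return the chi-square p-value.
#' @export
hwe_pvalue <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("genotype counts must be nonnegative")
  n <- sum(counts)
  if (n <= 0) stop("total genotype count must be positive")
  p <- (2 * n_aa + n_Aa) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chisq <- sum((counts - expected)^2 / expected)
  pchisq(chisq, df = 1L, lower.tail = FALSE)
}

hwe_pvalues <- function(geno) {
  d <- geno$dosages
  vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]; x <- x[!is.na(x)]
    hwe_pvalue(sum(x == 0), sum(x == 1), sum(x == 2))
  }, 0)
}

#' Pairwise LD as squared Pearson correlation of dosages
#'
#' Computed over pairwise-complete samples. If either vector is constant on
#' the shared set, r2 is defined as 0 (no linear association measurable).
#'
#' @param g_j,g_k dosage vectors of equal length.
#' @return r2 in [0, 1].
#' @export
ld_r2 <- function(g_j, g_k) {
  if (length(g_j) != length(g_k)) stop("dosage vectors differ in length")
  ok <- !is.na(g_j) & !is.na(g_k)
  if (sum(ok) < 2L) stop("fewer than 2 shared non-missing calls")
  x <- g_j[ok]; y <- g_k[ok]
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)^2
}

#' Apply the standard variant filters
#'
#' Keeps markers passing, in order: (1) missing proportion strictly below
#' \code{miss_max}, (2) minor allele frequency strictly above \code{maf_min},
#' (3) Hardy-Weinberg p-value strictly above \code{hwe_min}. All
#' inequalities are strict. Default thresholds are the usual HD-array
#' settings (MAF > 0.05, missingness < 0.05, HWE P > 1e-6).
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param maf_min,miss_max,hwe_min thresholds in [0, 1].
#' @return list with the filtered \code{geno} and a \code{report} data.frame
#'   (one row per stage: stage, threshold, n_in, n_out) carrying per-marker
#'   diagnostics (maf, call_rate, hwe_p) as attribute \code{"diagnostics"}.
#' @export
apply_variant_filters <- function(geno, maf_min = 0.05, miss_max = 0.05,
                                  hwe_min = 1e-6) {
  stopifnot(inherits(geno, "genotype_matrix"))
  thr <- c(maf_min, miss_max, hwe_min)
  if (any(!is.finite(thr)) || any(thr < 0) || any(thr > 1))
    stop("thresholds must lie in [0, 1]")
  n <- nrow(geno$dosages)
  report <- data.frame(stage = character(), threshold = numeric(),
                       n_in = integer(), n_out = integer())
  miss_prop <- colMeans(is.na(geno$dosages))
  diag_all <- data.frame(marker_id = geno$marker_ids,
                         call_rate = 1 - miss_prop,
                         maf = NA_real_, hwe_p = NA_real_)

  keep <- miss_prop < miss_max
  report <- rbind(report, data.frame(stage = "missingness", threshold = miss_max,
                                     n_in = length(keep), n_out = sum(keep)))
  g1 <- subset_markers(geno, keep)

  maf <- minor_allele_frequencies(g1)
  diag_all$maf[match(g1$marker_ids, diag_all$marker_id)] <- maf
  keep2 <- maf > maf_min
  report <- rbind(report, data.frame(stage = "maf", threshold = maf_min,
                                     n_in = length(keep2), n_out = sum(keep2)))
  g2 <- subset_markers(g1, keep2)

  hwe <- hwe_pvalues(g2)
  diag_all$hwe_p[match(g2$marker_ids, diag_all$marker_id)] <- hwe
  keep3 <- hwe > hwe_min
  report <- rbind(report, data.frame(stage = "hwe", threshold = hwe_min,
                                     n_in = length(keep3), n_out = sum(keep3)))
  g3 <- subset_markers(g2, keep3)

  attr(report, "diagnostics") <- diag_all
  list(geno = g3, report = report)
}

#' Windowed LD pruning
#'
#' Greedy left-to-right scan within each chromosome: a marker is dropped if
#' its r2 with any already-kept marker at most \code{window - 1} positions
#' back in marker index exceeds \code{r2_max}; the lower-position marker of
#' a correlated pair is kept. Guarantees that no kept pair within the
#' window exceeds the threshold, and the scan is idempotent.
#'
#' @param geno a \code{\link{genotype_matrix}} sorted by chromosome, position.
#' @param window marker-count window (>= 2); default 100.
#' @param r2_max retain threshold; pairs with r2 > r2_max are pruned
#'   (default 0.995).
#' @return list with the pruned \code{geno} and \code{kept} marker ids.
#' @export
ld_prune <- function(geno, window = 100L, r2_max = 0.995) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (window < 2L) stop("'window' must be >= 2")
  m <- ncol(geno$dosages)
  keep <- logical(m)
  for (chr in unique(geno$chromosome)) {
    idx <- which(geno$chromosome == chr)
    kept_chr <- integer(0)
    for (j in idx) {
      recent <- kept_chr[kept_chr >= j - (window - 1L)]
      drop <- FALSE
      for (k in recent) {
        if (ld_r2(geno$dosages[, j], geno$dosages[, k]) > r2_max) {
          drop <- TRUE
          break
        }
      }
      if (!drop) {
        keep[j] <- TRUE
        kept_chr <- c(kept_chr, j)
      }
    }
  }
  list(geno = subset_markers(geno, keep), kept = geno$marker_ids[keep])
}

#' Mean-impute missing dosages
#'
#' Missing entries at marker j are replaced by the marker's mean observed
#' dosage 2 p_j (real-valued); observed entries are untouched. A stand-in
#' for haplotype-based imputation, adequate at the low missingness the QC
#' filters enforce.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @return a complete \code{\link{genotype_matrix}} (entries in [0, 2]).
#' @export
mean_impute <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  if (!anyNA(d)) return(geno)
  ncall <- colSums(!is.na(d))
  if (any(ncall == 0L))
    stop("marker with no non-missing calls: ",
         geno$marker_ids[which(ncall == 0L)[1L]])
  mu <- colSums(d, na.rm = TRUE) / ncall
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2L]]
  out <- geno
  out$dosages <- d
  out
}
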