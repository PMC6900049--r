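#' Published reference results for 20 beef-cattle traits
#'
#' Result tables transcribed from a genomic-prediction study of 20 growth,
#' carcass and meat-quality traits in 1217 Chinese Simmental beef cattle
#' (~459k HD-array SNPs after QC; five predictors under 5-fold
#' cross-validation repeated 10 times): per-trait variance components and
#' heritabilities, predictive abilities and accuracies, and inflation
#' slopes and MSEs. They serve as fixtures for consistency checks on the
#' metric and aggregation code (e.g. accuracy = ability / sqrt(h2) holds
#' cell-wise, and the published trait-averaged summaries are reproduced by
#' \code{\link{aggregate_metrics}}).
#'
#' Trait codes drift across the published tables: the silverside cut
#' appears as ER (SI in the trait summary) and conical muscle as CM (BI in
#' the slope/MSE table). The loader maps everything onto the canonical
#' codes used by the variance-component table (ER, CM).
#'
#' @return list of three data.frames: \code{variance_components} (trait,
#'   sigma_a2, sigma_e2, h2, se_h2), \code{ability_accuracy} and
#'   \code{slope_mse} (wide, one column per method).
#' @export
transcribed_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "cattleGP",
                                  mustWork = TRUE)
  rd <- function(f) read.table(path(f), header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, check.names = FALSE)
  vc <- rd("reference_variance_components.tsv")
  aa <- rd("reference_ability_accuracy.tsv")
  sm <- rd("reference_slope_mse.tsv")
  sm$trait[sm$trait == "BI"] <- "CM"  # canonical code for conical muscle
  list(variance_components = vc, ability_accuracy = aa, slope_mse = sm)
}

#' Reference results in long (trait x method) form
#'
#' Pivots \code{\link{transcribed_tables}} to one row per trait x method
#' with columns ability, accuracy, slope, mse and h2, the shape
#' \code{\link{aggregate_metrics}} consumes.
#'
#' @return data.frame with columns trait, method, ability, accuracy, slope,
#'   mse, h2.
#' @export
reference_results_long <- function() {
  tabs <- transcribed_tables()
  methods <- c("GBLUP", "BayesA", "BayesB", "BayesCpi", "BayesR")
  out <- do.call(rbind, lapply(methods, function(m) {
    data.frame(trait = tabs$ability_accuracy$trait, method = m,
               ability = tabs$ability_accuracy[[paste0("ability_", m)]],
               accuracy = tabs$ability_accuracy[[paste0("accuracy_", m)]],
               stringsAsFactors = FALSE)
  }))
  sm <- do.call(rbind, lapply(methods, function(m) {
    data.frame(trait = tabs$slope_mse$trait, method = m,
               slope = tabs$slope_mse[[paste0("slope_", m)]],
               mse = tabs$slope_mse[[paste0("mse_", m)]],
               stringsAsFactors = FALSE)
  }))
  out <- merge(out, sm, by = c("trait", "method"), all.x = TRUE, sort = FALSE)
  merge(out, tabs$variance_components[, c("trait", "h2")], by = "trait",
        all.x = TRUE, sort = FALSE)
}
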