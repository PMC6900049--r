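#' Pipeline configuration
#'
#' Declarative description of a full run: input paths, QC thresholds, trait
#' and method lists, MCMC settings, fold-plan parameters and one global
#' seed that fans out deterministically to per-stage seeds (so a subset of
#' the pipeline can be rerun reproducibly on its own).
#'
#' @param genotypes path to a PLINK RAW (or VCF) genotype file.
#' @param phenotypes path to a delimited phenotype table.
#' @param output_dir directory for result tables and the manifest.
#' @param format genotype format, "plink_raw" or "vcf".
#' @param traits trait columns to analyse; default all in the phenotype
#'   table.
#' @param methods predictor subset of c("gblup","bayesA","bayesB",
#'   "bayesCpi","bayesR").
#' @param maf_min,miss_max,hwe_min QC thresholds (strict inequalities).
#' @param ld_window,ld_r2 LD-pruning window (marker count) and r2
#'   threshold; \code{ld_prune = FALSE} skips pruning.
#' @param ld_prune run windowed LD pruning (default TRUE).
#' @param k,repeats cross-validation folds and repetitions.
#' @param mcmc an \code{\link{mcmc_config}}.
#' @param seed global integer seed.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(genotypes, phenotypes, output_dir,
                            format = "plink_raw", traits = NULL,
                            methods = c("gblup", "bayesA", "bayesB",
                                        "bayesCpi", "bayesR"),
                            maf_min = 0.05, miss_max = 0.05, hwe_min = 1e-6,
                            ld_window = 100L, ld_r2 = 0.995, ld_prune = TRUE,
                            k = 5L, repeats = 10L, mcmc = mcmc_config(),
                            seed = 1L) {
  if (!is.character(genotypes) || !file.exists(genotypes))
    stop("genotype path does not exist: ", genotypes)
  if (!is.character(phenotypes) || !file.exists(phenotypes))
    stop("phenotype path does not exist: ", phenotypes)
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 output_dir = output_dir, format = format, traits = traits,
                 methods = methods, maf_min = maf_min, miss_max = miss_max,
                 hwe_min = hwe_min, ld_window = as.integer(ld_window),
                 ld_r2 = ld_r2, ld_prune = isTRUE(ld_prune),
                 k = as.integer(k), repeats = as.integer(repeats),
                 mcmc = mcmc, seed = as.integer(seed)),
            class = "pipeline_config")
}

# deterministic per-stage seed below 2^31
stage_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- sum(as.numeric(utf8ToInt(key)) * seq_along(utf8ToInt(key)) * 2654435)
  as.integer((seed * 7919 + h) %% (.Machine$integer.max - 1L)) + 1L
}

#' Run the full genomic-prediction pipeline
#'
#' QC -> mean imputation -> GRM -> per-trait REML -> per-trait x method
#' cross-validation, writing three delimited result tables (variance
#' components/heritability; ability/accuracy; slope/MSE) and a manifest of
#' seeds, thresholds and stage counts. Rerunning with an identical config
#' reproduces the tables byte for byte.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a list with the three result data.frames, the QC
#'   report and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))

  geno <- read_genotypes(config$genotypes, config$format)
  pheno <- read_phenotypes(config$phenotypes)
  log_stage("input", "%d samples x %d markers; %d phenotyped",
            nrow(geno$dosages), ncol(geno$dosages), nrow(pheno))
  al <- align_samples(geno, pheno, quiet = TRUE)
  geno <- al$geno; pheno <- al$pheno

  qc <- apply_variant_filters(geno, config$maf_min, config$miss_max,
                              config$hwe_min)
  geno <- qc$geno
  report <- qc$report
  if (config$ld_prune) {
    pr <- ld_prune(geno, config$ld_window, config$ld_r2)
    report <- rbind(report,
                    data.frame(stage = "ld_prune", threshold = config$ld_r2,
                               n_in = ncol(geno$dosages),
                               n_out = ncol(pr$geno$dosages)))
    geno <- pr$geno
  }
  log_stage("qc", "%d markers retained", ncol(geno$dosages))
  geno <- mean_impute(geno)
  grm <- grm_eigen(vanraden_grm(geno))
  log_stage("grm", "mean diagonal %.3f", mean(diag(grm$values)))

  traits <- if (is.null(config$traits)) attr(pheno, "traits") else config$traits
  vc_rows <- list(); cv_tabs <- list()
  for (trait in traits) {
    des <- build_fixed_design(pheno, trait)
    grm_t <- grm_submatrix(grm, des$sample_ids)
    vc <- fit_reml(des$y, des$X, grm_t)
    vc_rows[[trait]] <- data.frame(trait = trait, n = length(des$y),
                                   sigma_a2 = vc$sigma_a2,
                                   sigma_e2 = vc$sigma_e2, h2 = vc$h2,
                                   se_h2 = vc$se_h2)
    log_stage("reml", "%s: h2 = %.3f (SE %.3f)", trait, vc$h2, vc$se_h2)
    plan <- make_fold_plan(length(des$y), config$k, config$repeats,
                           stage_seed(config$seed, "cv", trait))
    mc <- config$mcmc
    mc$seed <- stage_seed(config$seed, "mcmc", trait)
    cv <- run_cross_validation(geno, pheno, trait, config$methods,
                               plan = plan, mcmc = mc)
    cv_tabs[[trait]] <- as.data.frame(cv)
  }
  vc_tab <- do.call(rbind, vc_rows)
  cv_all <- do.call(rbind, cv_tabs)
  per_tm <- aggregate(cv_all[, c("ability", "accuracy", "slope", "mse")],
                      by = list(trait = cv_all$trait, method = cv_all$method),
                      mean, na.rm = TRUE)
  ability_tab <- reshape_wide(per_tm, c("ability", "accuracy"))
  slope_tab <- reshape_wide(per_tm, c("slope", "mse"))

  wt <- function(df, f) {
    p <- file.path(config$output_dir, f)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  wt(vc_tab, "variance_components.tsv")
  wt(ability_tab, "ability_accuracy.tsv")
  wt(slope_tab, "slope_mse.tsv")
  wt(report, "qc_report.tsv")
  manifest <- data.frame(
    key = c("package_version", "seed", "maf_min", "miss_max", "hwe_min",
            "ld_window", "ld_r2", "k", "repeats", "n_samples", "n_markers",
            "methods", "traits"),
    value = c(as.character(utils::packageVersion("cattleGP")), config$seed,
              config$maf_min, config$miss_max, config$hwe_min,
              config$ld_window, config$ld_r2, config$k, config$repeats,
              nrow(geno$dosages), ncol(geno$dosages),
              paste(config$methods, collapse = ","),
              paste(traits, collapse = ",")))
  wt(manifest, "manifest.tsv")
  invisible(list(variance_components = vc_tab, ability_accuracy = ability_tab,
                 slope_mse = slope_tab, qc_report = report,
                 manifest = manifest, metrics = cv_all))
}

# trait x method long -> wide with <metric>_<method> columns
reshape_wide <- function(per_tm, metrics) {
  methods <- unique(per_tm$method)
  out <- data.frame(trait = unique(per_tm$trait), stringsAsFactors = FALSE)
  for (met in metrics) for (m in methods) {
    col <- paste0(met, "_", m)
    sel <- per_tm[per_tm$method == m, c("trait", met)]
    out[[col]] <- sel[[met]][match(out$trait, sel$trait)]
  }
  out
}
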