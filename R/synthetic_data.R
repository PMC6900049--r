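#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: panel dimensions,
#' allele-frequency range, local linkage disequilibrium, missingness, the
#' marker-effect architecture, target heritability, and the fixed-effect
#' layout (gender/farm/year levels plus a slaughter-age covariate).
#'
#' The LD model is a first-order haplotype-copying chain: each individual
#' carries two haplotypes and the allele at marker j+1 copies the allele at
#' marker j with probability \code{ld_decay}, else is drawn fresh from that
#' marker's allele frequency. One parameter, monotone adjacent-marker r2,
#' cheap to simulate; it does not attempt coalescent-realistic long-range LD.
#'
#' @param n_individuals,n_markers panel dimensions (N, M).
#' @param maf_range length-2 numeric, allele-frequency range in (0, 0.5].
#' @param ld_decay copy probability in [0, 1) between adjacent markers.
#' @param architecture marker-effect prior the generator mirrors:
#'   \code{"normal"} (every marker from one normal), \code{"point_normal"}
#'   (zero with probability \code{pi_true}, else normal), or
#'   \code{"four_component"} (normal mixture with relative variances
#'   0, 1e-4, 1e-3, 1e-2 of the genetic variance).
#' @param pi_true point-normal only: prior probability a marker effect is 0.
#' @param component_props four_component only: mixture proportions (sum 1).
#' @param heritability_true target h2, strictly inside (0, 1).
#' @param fixed_effect_levels named integer vector: number of levels for
#'   gender, farm, year.
#' @param age_covariate_range slaughter-age range in days.
#' @param missing_rate proportion of calls set missing, completely at random.
#' @param seed integer seed; all generator functions are reproducible from it.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 500, n_markers = 2000,
                       maf_range = c(0.05, 0.5), ld_decay = 0.5,
                       architecture = c("normal", "point_normal", "four_component"),
                       pi_true = 0.95,
                       component_props = c(0.90, 0.05, 0.03, 0.02),
                       heritability_true = 0.4,
                       fixed_effect_levels = c(gender = 2L, farm = 5L, year = 6L),
                       age_covariate_range = c(540, 730),
                       missing_rate = 0, seed = 1L) {
  architecture <- match.arg(architecture)
  chk_num <- function(x, nm) {
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
      stop("sim_config: non-finite value in '", nm, "'")
  }
  chk_num(n_individuals, "n_individuals"); chk_num(n_markers, "n_markers")
  chk_num(maf_range, "maf_range"); chk_num(ld_decay, "ld_decay")
  chk_num(pi_true, "pi_true"); chk_num(heritability_true, "heritability_true")
  chk_num(missing_rate, "missing_rate"); chk_num(age_covariate_range, "age_covariate_range")
  if (n_individuals < 1) stop("sim_config: 'n_individuals' must be >= 1")
  if (n_markers < 1) stop("sim_config: 'n_markers' must be >= 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("sim_config: 'maf_range' must lie in (0, 0.5] with lower <= upper")
  if (ld_decay < 0 || ld_decay >= 1) stop("sim_config: 'ld_decay' must be in [0, 1)")
  if (pi_true < 0 || pi_true > 1) stop("sim_config: 'pi_true' must be in [0, 1]")
  if (heritability_true <= 0 || heritability_true >= 1)
    stop("sim_config: 'heritability_true' must be strictly inside (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("sim_config: 'missing_rate' must be in [0, 1)")
  if (length(component_props) != 4 || any(component_props < 0) ||
      abs(sum(component_props) - 1) > 1e-8)
    stop("sim_config: 'component_props' must be 4 nonnegative proportions summing to 1")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_markers = as.integer(n_markers),
                 maf_range = maf_range, ld_decay = ld_decay,
                 architecture = architecture, pi_true = pi_true,
                 component_props = component_props,
                 heritability_true = heritability_true,
                 fixed_effect_levels = fixed_effect_levels,
                 age_covariate_range = age_covariate_range,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# one haplotype panel: alleles 0/1, haplotype-copying chain along markers
sim_haplotypes <- function(n_hap, p, ld) {
  m <- length(p)
  h <- matrix(0L, n_hap, m)
  h[, 1L] <- rbinom(n_hap, 1L, p[1L])
  if (m > 1L) for (j in 2:m) {
    copy <- runif(n_hap) < ld
    fresh <- rbinom(n_hap, 1L, p[j])
    h[, j] <- ifelse(copy, h[, j - 1L], fresh)
  }
  h
}

#' Simulate a genotype panel
#'
#' Draws per-marker allele frequencies uniformly from \code{maf_range},
#' simulates two haplotypes per individual under the haplotype-copying LD
#' chain, sums them to 0/1/2 dosages, and masks calls completely at random
#' at \code{missing_rate}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a \code{\link{genotype_matrix}} with attribute
#'   \code{"target_freq"}, the per-marker frequencies handed to the chain.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals; m <- cfg$n_markers
  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  dos <- sim_haplotypes(n, p, cfg$ld_decay) + sim_haplotypes(n, p, cfg$ld_decay)
  storage.mode(dos) <- "double"
  if (cfg$missing_rate > 0) {
    mask <- runif(n * m) < cfg$missing_rate
    dos[mask] <- NA_real_
  }
  g <- genotype_matrix(dos, sample_ids = sprintf("ind%04d", seq_len(n)),
                       marker_ids = sprintf("snp%05d", seq_len(m)),
                       chromosome = rep("1", m), position = seq_len(m))
  attr(g, "target_freq") <- p
  g
}

#' Simulate marker effects under a genetic architecture
#'
#' Draws raw effects from the configured architecture, then rescales them so
#' the realized variance of the breeding values Z alpha over the simulated
#' individuals equals \code{genetic_variance} exactly (zeros stay zero).
#'
#' Architectures: \code{normal} draws every effect from one normal;
#' \code{point_normal} zeroes each effect independently with probability
#' \code{pi_true}; \code{four_component} assigns markers to a 4-component
#' normal mixture with variances (0, 1e-4, 1e-3, 1e-2) x genetic_variance
#' and proportions \code{component_props}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param genetic_variance target variance of Z alpha (> 0).
#' @param geno complete \code{\link{genotype_matrix}} used for the rescaling;
#'   if missing, a panel is simulated from \code{cfg}.
#' @return numeric vector of M effects, with attribute \code{"components"}
#'   (mixture assignment, four_component only).
#' @export
simulate_marker_effects <- function(cfg, genetic_variance, geno = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.finite(genetic_variance) || genetic_variance <= 0)
    stop("'genetic_variance' must be > 0")
  if (is.null(geno)) geno <- simulate_genotypes(cfg)
  if (anyNA(geno$dosages)) geno <- mean_impute(geno)
  m <- cfg$n_markers
  set.seed(cfg$seed + 1L)
  comp <- NULL
  alpha <- switch(cfg$architecture,
    normal = rnorm(m),
    point_normal = {
      a <- rnorm(m)
      a[runif(m) < cfg$pi_true] <- 0
      a
    },
    four_component = {
      comp <- sample.int(4L, m, replace = TRUE, prob = cfg$component_props)
      sdv <- sqrt(c(0, 1e-4, 1e-3, 1e-2) * genetic_variance)
      rnorm(m, sd = sdv[comp])
    })
  g <- as.vector(geno$dosages %*% alpha)
  vg <- var(g)
  if (vg > 0) alpha <- alpha * sqrt(genetic_variance / vg)
  if (!is.null(comp)) attr(alpha, "components") <- comp
  alpha
}

#' Simulate phenotypes from genotypes and true marker effects
#'
#' Builds y = Xb + g + e, with g = Z alpha on the (mean-imputed) dosage
#' coding, fixed effects for gender/farm/year drawn once per level with
#' spread equal to the phenotypic SD, a slaughter-age covariate with a small
#' fixed slope, and residuals e ~ N(0, sigma_e2) where sigma_e2 is set from
#' the realized var(g) so that var(g) / (var(g) + sigma_e2) equals
#' \code{heritability_true} by construction.
#'
#' @param geno complete (or to-be-mean-imputed) \code{\link{genotype_matrix}}.
#' @param marker_effects length-M vector of true effects (e.g. from
#'   \code{\link{simulate_marker_effects}}).
#' @param cfg a \code{\link{sim_config}}.
#' @param trait_name column name for the simulated trait.
#' @return list with \code{pheno} (a \code{\link{phenotype_table}} with the
#'   trait, factors and age) and \code{truth} (marker_effects,
#'   breeding_values, fixed_effects, variance_components c(sigma_a2,
#'   sigma_e2)).
#' @export
simulate_phenotypes <- function(geno, marker_effects, cfg, trait_name = "trait") {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "genotype_matrix"))
  if (length(marker_effects) != ncol(geno$dosages))
    stop("marker_effects length does not match the number of markers")
  if (anyNA(geno$dosages)) geno <- mean_impute(geno)
  set.seed(cfg$seed + 2L)
  n <- nrow(geno$dosages)
  g <- as.vector(geno$dosages %*% marker_effects)
  sigma_a2 <- var(g)
  h2 <- cfg$heritability_true
  sigma_e2 <- if (sigma_a2 > 0) sigma_a2 * (1 - h2) / h2 else 1
  sigma_p <- sqrt(sigma_a2 + sigma_e2)

  lv <- cfg$fixed_effect_levels
  fac <- lapply(c(gender = "gender", farm = "farm", year = "year"), function(nm) {
    k <- max(1L, as.integer(lv[[nm]]))
    factor(paste0(substr(nm, 1, 1), sample.int(k, n, replace = TRUE)))
  })
  age <- runif(n, cfg$age_covariate_range[1], cfg$age_covariate_range[2])
  # per-level values with spread sigma_p; age slope a small fixed multiple
  lev_effects <- lapply(fac, function(f) setNames(rnorm(nlevels(f), sd = sigma_p),
                                                  levels(f)))
  age_slope <- 0.1 * sigma_p / max(sd(age), 1e-8)
  xb <- Reduce(`+`, Map(function(f, ef) ef[as.character(f)], fac, lev_effects))
  xb <- as.vector(xb) + age_slope * (age - mean(age))
  e <- rnorm(n, sd = sqrt(sigma_e2))
  y <- xb + g + e

  df <- data.frame(sample_id = geno$sample_ids, gender = fac$gender,
                   farm = fac$farm, year = fac$year, slaughter_age = age,
                   stringsAsFactors = FALSE)
  df[[trait_name]] <- y
  truth <- list(marker_effects = marker_effects, breeding_values = g,
                fixed_effects = c(unlist(lev_effects), age_slope = age_slope),
                variance_components = c(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2))
  list(pheno = phenotype_table(df, traits = trait_name), truth = truth)
}

#' Simulate a complete dataset (genotypes, effects, phenotypes)
#'
#' Convenience wrapper running the three generator stages with one config.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param genetic_variance target var(Z alpha); default 1.
#' @param trait_name trait column name.
#' @return list with \code{geno}, \code{pheno}, \code{truth}.
#' @export
simulate_dataset <- function(cfg, genetic_variance = 1, trait_name = "trait") {
  geno <- simulate_genotypes(cfg)
  geno_c <- if (anyNA(geno$dosages)) mean_impute(geno) else geno
  alpha <- simulate_marker_effects(cfg, genetic_variance, geno_c)
  sim <- simulate_phenotypes(geno_c, alpha, cfg, trait_name)
  list(geno = geno, pheno = sim$pheno, truth = sim$truth)
}
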