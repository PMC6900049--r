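---
title: "Genomic prediction in cattleGP: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction in cattleGP: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cattleGP)
```

cattleGP implements a complete desk-scale genomic-selection analysis for
quantitative traits in beef cattle: variant quality control, the VanRaden
genomic relationship matrix, animal-model REML, and five whole-genome
regression predictors (GBLUP, BayesA, BayesB, BayesCpi, BayesR) evaluated
by repeated k-fold cross-validation. This vignette documents the models,
the tunable parameters, the synthetic-data generator that makes everything
testable, and the design decisions taken where the methodology was
genuinely open.

## The model

All predictors share the linear model

$$ y = Xb + Zg + e, $$

where $y$ are trait records, $X$ is the fixed-effect design (intercept,
gender, farm and year of measurement as treatment-coded factors, and the
centered slaughter-age covariate), and $e \sim N(0, I\sigma_e^2)$. The
interpretation of $Zg$ differs by method:

* **GBLUP / REML.** $g$ is a vector of animal breeding values with
  $g \sim N(0, G\sigma_a^2)$, where $G$ is the genomic relationship matrix
  (VanRaden method 1): $G = WW'/\sum_j 2p_j(1-p_j)$ with $W$ the
  column-centered 0/1/2 dosage matrix and $p_j$ the observed counted-allele
  frequencies. Mean diagonal of $G$ is close to 1 on an unrelated panel in
  Hardy-Weinberg proportions.
* **Bayesian alphabet.** $Z$ is the $N \times M$ dosage matrix and $g$ a
  vector of $M$ marker effects $\alpha_j$ whose prior defines the method:
  BayesA gives every marker its own variance
  $\sigma_j^2 \sim \chi^{-2}(v, v S_a^2)$; BayesB mixes a spike at zero
  (probability $\pi$, fixed) with the BayesA slab; BayesCpi uses one common
  effect variance and estimates $\pi$ under a uniform prior; BayesR mixes
  four normal components with variances $(0, 10^{-4}, 10^{-3}, 10^{-2})
  \times \sigma_g^2$ and Dirichlet(1,1,1,1)-distributed proportions.
  Genomic breeding values are $\mathrm{GEBV}_i = \sum_j Z_{ij}
  \bar\alpha_j$ with $\bar\alpha$ the posterior-mean effects.

The age covariate is omitted for average daily gain (ADG), which is itself
an age-standardized trait; every other trait includes it by default.

## REML by eigen-profile

`fit_reml()` eigendecomposes $G$ once, rotates the model into the
eigenbasis, and profiles the restricted likelihood over the single ratio
$\lambda = \sigma_a^2/\sigma_e^2$; $\sigma_e^2$ then has a closed form.
The profile is maximized by Brent search on $\log\lambda \in
[\log 10^{-6}, \log 10^6]$ to a tolerance of $10^{-9}$; estimates at the
search edge are flagged (`boundary = TRUE`), not errored. This is exact
and derivative-free, and at $n \approx 10^3$ it is faster and more robust
than general AI-REML iterations; a GRM numerically proportional to the
identity leaves only the total variance identifiable and is flagged
explicitly. The standard error of $h^2$ comes from the inverse
average-information matrix at the optimum via the delta method, the same
quantity ASReml-class software reports. The test suite checks the profile
optimum against a direct solve/determinant grid-search oracle on small
fixtures, agreement better than $10^{-4}$ in $h^2$.

Heritability is reported as $h^2 = \sigma_a^2 / (\sigma_a^2 +
\sigma_e^2)$, and the GLS fixed-effect estimates at the optimum define the
corrected phenotypes $\hat y = y - X\hat b$ used throughout validation.

## GBLUP and its SNP-BLUP identity

GBLUP solves the mixed model on the reference animals and predicts masked
animals by the BLUP conditional mean $\hat g_{val} = \sigma_a^2 G_{vr}
V_{rr}^{-1}(y - X\hat b)$, algebraically identical to
$G_{vr}G_{rr}^{-1}\hat g_{ref}$ but cheaper and with the masking explicit.
With the method-1 scaling, GBLUP is exactly equivalent to ridge regression
on centered markers (SNP-BLUP) with ridge $\lambda = \sigma_e^2 /
\sigma_a^2$ times the VanRaden denominator; the package implements both
routes and the suite asserts their agreement to $10^{-6}$ relative error,
which validates the two solvers against each other. Linear solves use
Cholesky factorizations; a ridge of $10^{-6}$ of the mean diagonal is
added only if a factorization fails, and recorded.

By default variance components are re-estimated on each training fold
(no information leaks from validation records); `vc_policy = "full_data"`
reproduces the cheaper convention since published analyses rarely state
which was used.

## The Gibbs samplers

The four Bayesian models run in one C++ single-site Gibbs kernel. Default
chain settings are 50,000 cycles with 10,000 discarded as burn-in; scalar
traces are thinned to every 10th cycle, while posterior means of marker
effects use every post-burn-in cycle. Marker update order is fixed
ascending for reproducibility, and all randomness flows through R's RNG so
a run is reproducible from `set.seed()` alone.

Choices the model descriptions leave open, and what the package does:

* **Indicator sampling (BayesB/Cpi/R).** Inclusion indicators and mixture
  labels are sampled with the marker effect integrated out of the
  conditional (the GenSel/Habier approach). This replaces the original
  Metropolis-Hastings step with a Gibbs draw that has the identical
  stationary distribution and mixes better.
* **Prior scale.** $S_a^2 = (v-2)\,E(\sigma_j^2)/v$ with $v = 4.2$. The
  expected marker variance is derived from a genetic variance (the REML
  estimate when available, `vc_prior`) as $E(\sigma_j^2) = \sigma_a^2 /
  ((1-\pi)\sum_j 2p_jq_j)$, with $\pi = 0$ for BayesA and the fixed $\pi$
  for BayesB. For BayesCpi, where $\pi$ is itself sampled, the scale is
  re-derived each cycle from the current $\pi$ so the prior stays
  consistent with the genetic variance it encodes; with a fixed
  scale derived from an arbitrary starting $\pi$ the recovered $\pi$ is
  biased toward inclusion when the start is far too dense.
* **BayesB's $\pi$** is fixed at 0.95 by default and configurable; it is a
  modelling assumption, not an estimate.
* **Residual variance prior** is the flat scaled-inverse-chi-square
  convention (df $= -2$, scale 0), so $\sigma_e^2$ is drawn from
  $e'e/\chi^2_{n-2}$ and stays positive by construction.
* **BayesR's $\sigma_g^2$** defining the component variances is fixed at
  `vc_prior` (the REML estimate) by default; `update_vg = TRUE` refreshes
  it each cycle from the realized genetic variance, a variant that also
  appears in the literature.
* **Column centering.** Marker columns are centered before sampling (the
  intercept absorbs the shift; marker effects are unchanged). GEBVs are
  computed on the stored dosage coding, so only the irrelevant intercept
  differs.

The conjugate single-marker case (all variances fixed) has an analytic
posterior; the suite checks the sampler against it to Monte-Carlo
precision, and checks BayesCpi with $\pi$ forced to zero against SNP-BLUP.

## Cross-validated evaluation

`make_fold_plan()` draws balanced uniformly random partitions: with
1217 animals and $k = 5$, validation folds hold 243-244 animals and
reference sets 973-974, repeated 10 times. For every repeat, fold and
method the harness trains on the reference animals, predicts the masked
validation animals, and scores four criteria against corrected phenotypes:

* **Predictive ability** $r(\mathrm{GEBV}, \hat y)$;
* **Predictive accuracy** $r/\sqrt{h^2}$, approximating the correlation
  with true breeding values;
* **Inflation slope**, the OLS slope of $\hat y$ on GEBV (1 = well
  scaled, below 1 = inflated predictions);
* **MSE**, the mean of squared differences. One published formulation
  omits the square, but the quantity's name and its role as an overall
  fit measure force the squared version; the package implements the
  squared error.

Corrected phenotypes and the $h^2$ in the accuracy denominator come from
the full-data REML fit by default -- the convention that pairs one
per-trait $h^2$ with all folds -- with per-fold correction available by
flag. Aggregation is the simple mean of per-fold statistics within trait,
then the unweighted mean over traits; rounding to 3 decimals happens only
at presentation.

The package ships transcribed result tables from a published
genomic-prediction study of 20 growth, carcass and meat-quality traits in
1217 Chinese Simmental beef cattle (`transcribed_tables()`). They are used
as consistency fixtures: the cell-wise identity accuracy = ability
$/\sqrt{h^2}$ holds to 0.002 across all 100 trait-method cells, and
`aggregate_metrics()` reproduces the published trait-averaged summaries
(BayesR mean ability 0.225, mean accuracy 0.378, GBLUP mean slope 0.89).
Trait codes drift across the published tables (the silverside cut appears
as SI and ER, conical muscle as CM and BI); the loader maps everything to
one canonical registry. Where the source's running text and its variance
table disagree on a heritability, the table values are used: they are the
ones consistent with the published ability/accuracy ratios.

## The synthetic-data generator

Every statistical claim in the test suite is exercised on data from
`simulate_dataset()`, which emulates the structure the models assume:

* **Genotypes.** Per-marker allele frequencies drawn uniformly from
  `maf_range` (default 0.05-0.5); two haplotypes per individual from a
  first-order copying chain (allele at marker $j+1$ copies marker $j$'s
  allele with probability `ld_decay`, else is drawn fresh), summed to
  dosages; missingness completely at random. One parameter gives monotone
  adjacent-marker $r^2$; the chain makes no attempt at coalescent-realistic
  long-range LD, pedigree structure or genotyping-error models, so tests
  passing here say nothing about, e.g., imputation quality on real arrays.
* **Marker effects.** Drawn from the architecture each prior assumes
  (normal; point-normal with zero probability `pi_true`; four-component
  mixture), then rescaled so the realized variance of $Z\alpha$ equals the
  target genetic variance exactly. Enforcing the target on the realized
  rather than expected variance makes parameter-recovery tests sharp.
* **Phenotypes.** $y = Xb + g + e$ with gender/farm/year level effects
  drawn once per level with spread equal to the phenotypic SD, an age
  covariate on 540-730 days with a small fixed slope (0.1 phenotypic SD
  per age SD), and $\sigma_e^2$ set from the realized $\mathrm{var}(g)$ so
  that $\mathrm{var}(g)/(\mathrm{var}(g)+\sigma_e^2)$ equals the target
  heritability by construction. No published magnitudes exist for these
  fixed effects; the defaults are conventions, chosen once.

## Problem sizes used by the checks

The statistical checks run at sizes where each estimand is identifiable
yet a full run stays comfortable on a laptop: REML recovery uses one
simulated panel of 500 individuals by 5000 markers per heritability level
(0.1 and 0.47) with 500 replicates each, redrawing marker effects and
noise per replicate so the eigendecomposition is shared across fits (on an
unrelated panel the per-replicate sd of the estimate is about 0.15, so
replication is what makes the bias check informative); BayesCpi recovery
uses
point-normal panels of 800 by 1000 at 20,000 cycles, averaged over three
replicate panels because single-panel posterior means spread by about 0.05
across data realizations; the cross-validation harness runs 5 folds by
10 repeats by 5 methods at 500 by 2000 with shortened chains (400 cycles),
which is enough to exercise every code path and the exact
accuracy/ability identity, though not to saturate Bayesian accuracy.

## Known limitations

* **BayesR mixture proportions are weakly identified at desk scale.** The
  zero component and the $10^{-4}\sigma_g^2$ component are statistically
  indistinguishable unless $n \cdot 2pq \cdot 10^{-4}\sigma_g^2 /
  \sigma_e^2$ approaches 1 (tens of thousands of individuals at moderate
  heritability): the per-marker log-Bayes-factor separating them is
  $O(10^{-4})$ at $n = 600$, so the posterior on the proportions stays
  close to its Dirichlet prior in the flat directions and the posterior
  mean of the zero-component mass does not converge to the generating
  value. The recoverable quantities -- the combined mass of the two
  large-variance components, per-marker classifications of large-effect
  markers, and the genetic variance -- are the ones the unit suite
  asserts. GEBV accuracy is essentially unaffected, because markers the
  mixture cannot place carry negligible effects either way.
* The LD-pruning scan is quadratic in window size and runs in plain R;
  at HD-array scale (hundreds of thousands of markers) one would reuse
  the standard PLINK implementation instead.
* Single-trait models only: no maternal effects, no multi-trait REML, no
  single-step blending with pedigree information.

## Reproducibility

`run_pipeline()` fans one global seed out deterministically to per-stage
seeds (hashes of stage name and trait), so any stage can be rerun in
isolation with identical results; the manifest written next to the result
tables records seeds, thresholds and stage counts. Sampler runs are
bit-reproducible from their chain seed, and the acceptance script
(`scripts/acceptance.R`) recomputes every headline number from scratch
under a caller-supplied seed.
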