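---
title: "Partitioning variance in circadian cortisol reaction norms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning variance in circadian cortisol reaction norms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Urinary cortisol in wild primates follows a strong circadian curve: levels
peak around waking and decline through the day. An individual's circadian
profile — its average level (intercept), and the linear and quadratic
slopes of log cortisol against time of day — is a *reaction norm*, and the
question this package addresses is where the variation in those reaction
norms comes from: consistent individual differences (repeatability),
additive genetic effects (narrow-sense heritability via an animal model),
the non-genetic maternal environment, and shared community-level ecology.

The pipeline has five stages, each exposed as ordinary functions and also
through a small command-line wrapper (`inst/cli/cortherit`):

1. **Pedigree**: `read_pedigree()` validates dam/sire links (acyclicity,
   founder promotion) and `additive_relationship_matrix()` builds the
   additive genetic relationship matrix A by the Henderson tabular method,
   `A[i,i] = 1 + 0.5 A[dam,sire]`,
   `A[i,j] = 0.5 (A[j,dam] + A[j,sire])`, with unknown parents treated as
   unrelated, non-inbred founders. An independent, exponential-time
   recursive kinship oracle (`kinship_oracle()`) exists purely to
   cross-check the tabular implementation in tests.
2. **Preprocessing**: `prepare_samples()` applies the specific-gravity
   correction `C_sg = C_raw (SG_pop - 1)/(SG_sample - 1)`, assigns female
   reproductive states from birth records (pregnant in the 240 days before
   any birth; lactating for 1095 days after; cycling otherwise), applies
   the exclusion rules (pregnant females, sickness/injury days, immature
   samples after maternal loss, unassignable states), keeps only
   individual-years with at least 3 samples spanning 6+ hours and both
   morning and afternoon, and encodes covariates.
3. **Models**: `build_model()`/`fit_model()` declare and fit the Gaussian
   hierarchical models in JAGS — a null model (community, community-year
   and project intercepts), an individual-intercepts model, an individual
   reaction-norms model (random circadian slopes), and animal models in
   which every term carries reaction-norm slopes and a `genetic` term has
   covariance `A ⊗ Σ_genetic`.
4. **Decomposition**: `trait_repeatability()`, `rn_repeatability()`,
   `between_within_partition()`, `within_group_heritability()` and
   `trait_heritability()` turn posterior covariance draws into proportions
   with credible intervals.
5. **Permutation null**: `run_permutation_null()` reshuffles individual
   identities *within* communities in A (with concordant reassignment of
   mothers) and refits the animal model per permutation, yielding
   exceedance probabilities for the genetic share, the maternal share, and
   their difference.

## Model and priors

All models share the response `y` (natural log of SG-corrected cortisol,
log ng/ml SG) and the fixed-effect structure: every covariate
(five-level demographic class, z-scored age, circannual sine and cosine,
z-scored adult sex ratio and community size, assay method) enters in
interaction with both the linear (`t`) and quadratic (`t2`) circadian
terms. `t` is the z-score of hours since midnight and `t2` its square —
squaring *after* standardization keeps slope variances on a stable scale
across datasets. The demographic factor is treatment-coded with adult
males as the reference level; this affects the interpretation of
individual fixed-effect coefficients but none of the variance partitions.

Priors follow weakly-regularizing practice for this model family:
`Normal(0, 1)` on fixed effects, half-Student-t(3, 0, 10) on every random
effect (and residual) standard deviation, and a uniform LKJ(1) prior on
the 3×3 correlation matrices of the random reaction-norm terms. JAGS has
no native LKJ density, so the LKJ(1) prior is realized exactly through
the partial-correlation C-vine: the two lag-one correlations get
`Beta(1.5, 1.5)` marginals rescaled to (−1, 1), the lag-two *partial*
correlation gets `Beta(1, 1)`, and the implied Cholesky factor of the
correlation matrix is assembled in closed form. Simulation confirms the
implied marginal of every correlation matches the LKJ(1) theoretical
`Beta(1.5, 1.5)` marginal.

All random effects are non-centered: latent standard normals are scaled
by their standard deviations (and, for slope terms, by the Cholesky
factor of Σ). The genetic term additionally left-multiplies by the lower
Cholesky factor of A, giving effects with covariance `A ⊗ Σ_genetic`
while sampling only independent normals. If A is numerically singular
(duplicate founder lines), a `1e-8` diagonal jitter is applied once
before factorization. The default sampler settings are four chains of
4000 iterations with half devoted to warm-up; calibration experiments and
permutation refits use shorter single chains.

Convergence is summarized by split-Rhat and effective sample size over
all fixed effects, standard deviations and correlations; any Rhat at or
above 1.1 triggers a warning (never a silent success).

## Derived quantities

Writing `V_f,c` for the variance of factor `f` in reaction-norm component
`c ∈ {intercept, linear, quadratic}` (the matching diagonal entry of that
factor's Σ), each quantity is computed *per posterior draw* and then
summarized by the median and equal-tailed 95% interval — ratios of
medians would understate the uncertainty of a ratio:

* long-term trait repeatability: `V_individual / V_total` with
  `V_total = V_individual + V_IDyear + V_group + V_groupyear`;
  short-term adds `V_IDyear` to the numerator;
* reaction-norm repeatability of component `c`:
  `V_individual,c / (V_individual,c + V_IDyear,c)`;
* between-community share: `V_group,c / (V_group,c + V_within,c)` with
  `V_within,c = V_genetic,c + V_mother,c + V_groupyear,c +
  V_individual,c + V_IDyear,c`;
* within-community genetic heritability `h² = V_genetic,c / V_within,c`
  and maternal effect `m² = V_mother,c / V_within,c` (the five
  within-community shares sum to one by construction);
* trait heritability (slope-free model only):
  `V_genetic / (V_genetic + V_mother + V_groupyear + V_individual +
  V_IDyear + V_residual)`.

The technical `project` term is excluded from every denominator by
default; `include_technical = TRUE` reproduces the alternative convention
in which it is part of the within-community variance (this lowers the
maternal estimate). Draws with a zero denominator propagate as missing
and are dropped from summaries with a count — never coerced to zero.

## Permutation null

Credible intervals on variance shares are bounded below by zero, so
"different from zero" needs a reference distribution. The null here
reshuffles individual identities within their communities in A
(`A_perm = P A Pᵀ` for a within-community permutation `P`) and assigns
each individual the mother of the individual whose identity it took, so
genetic and maternal relationships remain concordant; group-level
environmental structure, the spectrum of A, and the distribution of
maternal sibship sizes are all preserved. The animal model is refit per
permutation and the posterior-median `h²`, `m²` and `m² − h²` recorded.
Exceedance probabilities are one-sided (`≥` observed, ties counting
toward the null, which is conservative); lower-tail counts are reported
alongside so either reading convention is available.

Permutation refits may use shorter chains than the observed fit, since
only posterior medians feed the null. A refit is excluded from the counts
(and logged) if it errors or if the split-Rhat of the standard deviations
that enter the shares reaches `rhat_threshold` (default 1.5). The looser
default is deliberate: at single-short-chain settings a strict 1.1 gate
rejects most refits *even on true-null data where the refits are
statistically exchangeable with the observed fit* — there it measures
chain length, not fit pathology. Main fits keep the 1.1 warning
threshold. Only individuals present in the sample table are permuted;
unsampled pedigree ancestors keep their labels, which cannot change the
likelihood.

## The simulator

`simulate_study()` emulates the study system: five communities of ~34
individuals by default, founders plus two offspring waves with dams and
sires drawn within the community, one to several sampling years with a
dozen-plus samples per individual-year, clock times drawn from the
diurnal observation window (06:00–18:00, with one guaranteed morning and
one late-afternoon sample per individual-year so the sampling-span filter
passes by construction), an assay-method changeover date, circannual
dates, and per-community size and sex-ratio covariates. Log cortisol is
drawn from the same generative model the fits assume
(`y = Xβ + Σ_f Z_f u_f + ε`, genetic effects `N(0, A ⊗ Σ_genetic)`), and
raw concentrations are produced by *inverting* the SG correction against
the empirical SG population mean, so the raw tables round-trip through
`prepare_samples()` to reproduce `y` exactly. Every childless adult
female receives a pre-window birth record so reproductive states are
always assignable — samples survive the exclusion rules by construction,
and tests corrupt schedules deliberately when exercising the filters.

`ground_truth_decomposition()` applies the share formulas directly to the
configured Σ diagonals, giving exact targets for parameter recovery. What
the simulator does *not* emulate: non-Gaussian residuals, assay batch
drift beyond the two-level method factor, dominance-rank dynamics,
seasonal sampling gaps, and mortality/demographic turnover. Passing
recovery tests therefore demonstrates correctness of the estimation
machinery under the assumed model, not robustness to real-data
violations of it.

## Calibration experiment sizes

The test suite runs three simulation-based experiments, scaled to desk
hardware; sizes are package design choices:

* **Parameter recovery**: 20 replicates of 3 communities × 15
  individuals × 2 years × ~10 samples/year (≈900 samples), intercept-only
  variance structure with true within-community shares m² = 0.2,
  h² = 0.1, fit with the slope-free animal model (single chains of 4000
  iterations). Checked: 90% posterior intervals cover the true shares in
  at least 80% of replicates, and the median absolute error of m² stays
  below 0.15. The intercept shares are the estimand; generating zero
  slope variance and fitting the slope-free variant keeps the experiment
  correctly specified at a fraction of the cost of the full 3×3 model,
  whose machinery is exercised separately.
* **Permutation calibration**: with zero true maternal and genetic
  variance, the observed m² should sit unremarkably inside its own
  permutation distribution (exceedance > 0.1 in most replicates); with a
  true maternal share of 0.3 the exceedance should be small (≤ 0.1 in
  most replicates), using 20 permutations per replicate. The power
  arm uses communities of 14 with half founders — enough known-mother
  sibships for the maternal variance to be identifiable at all at this
  scale — and a within-community variance total of 0.8 on the log scale;
  with many fewer mothers the *realized* maternal variance of a replicate
  varies so much around its nominal value that no procedure could rank it
  reliably against its own null.
* **Model comparison**: data simulated with strong individual-intercept
  variance must prefer the intercepts model over the null by more than
  twice the standard error of the elpd difference (PSIS-LOO).

## Numerical and design notes

* Natural log for the cortisol transform; the base affects scale, not
  variance ratios.
* The SG population mean is computed per site over retained samples,
  with a configurable override.
* "Morning" is strictly before 12:00, "afternoon" at or after;
  configurable in `filter_config()`.
* Pregnancy takes precedence over lactation when windows overlap —
  pregnant samples are excluded anyway, so precedence maximizes
  exclusion safety.
* Calendar years define the year facet of `group_year`/`id_year`;
  individuals crossing age 12 switch demographic class at the sample
  level.
* Individuals sampled but absent from the pedigree are appended as
  founders (with a warning); individuals without a known mother receive
  unique singleton mother levels, which contribute to the maternal
  variance estimate only weakly.
* PSIS-LOO uses the generalized-Pareto tail fit of Zhang & Stephens
  (2009) with the conventional k > 0.7 reliability warning, implemented
  in-package; tail smoothing assumes draws are roughly independent
  (r_eff is not estimated).
* The within-year repeatability literature this design follows contains
  one internal inconsistency (a printed 0.07 vs 0.08 for the same
  quantity); the package simply reports its computed value.

## Known limitations

Heritability estimates from pedigrees of this depth carry wide credible
intervals; the permutation null is the primary guard against
over-reading them. The covariance *shares* between intercept and slope
components are estimated by the models (the off-diagonals of each Σ) but
no decomposition of covariance into proportions is provided, as there is
no standard formula for it. Dominance rank enters only as an optional
user-supplied covariate; rank inference itself is out of scope.
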