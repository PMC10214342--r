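# cortherit

Variance partitioning for circadian cortisol reaction norms in wild,
group-living primates: repeatability, narrow-sense heritability, non-genetic
maternal effects, and shared community effects, from longitudinal urinary
cortisol samples and a behavioral/genetic pedigree.

## What it does

Urinary cortisol declines through the day; an individual's circadian
profile is a reaction norm with an intercept (average level) and linear and
quadratic slopes against time of day. `cortherit` asks where variation in
those reaction norms comes from, using Bayesian hierarchical models fitted
with JAGS:

* **Pedigree → A matrix.** `read_pedigree()` validates dam/sire tables;
  `additive_relationship_matrix()` builds the additive genetic relationship
  matrix A by the Henderson tabular method
  (entries are twice the kinship coefficient; the diagonal is 1 + the
  inbreeding coefficient).
* **Preprocessing.** `prepare_samples()` corrects concentrations for
  specific gravity, `C_sg = C_raw (SG_pop − 1)/(SG_sample − 1)`, assigns
  female reproductive states from birth records (pregnant 240 d before a
  birth, lactating 1095 d after, else cycling), excludes pregnant-female,
  sickness-day and post-maternal-loss immature samples, keeps only
  individual-years with ≥ 3 samples spanning ≥ 6 h across morning and
  afternoon, and encodes circadian, circannual and z-scored covariates.
* **Hierarchical models.** `build_model()` / `fit_model()` fit a null
  model, an individual-intercepts model, an individual reaction-norms model
  (random circadian slopes), and animal models where every random term
  carries `{intercept, t, t²}` slopes with an unstructured 3×3 covariance
  (half-Student-t(3, 0, 10) scales, LKJ(1) correlations) and the genetic
  term has covariance A ⊗ Σ_genetic. Models are compared with an
  in-package PSIS-LOO (`loo()`, `loo_compare()`).
* **Decomposition.** Per posterior draw: long-/short-term trait
  repeatability `V_ind / V_total`, reaction-norm repeatability
  `V_ind / (V_ind + V_IDyear)`, the between-community share
  `V_group / (V_group + V_within)`, within-community heritability
  `h² = V_genetic / V_within` and maternal effect
  `m² = V_mother / V_within`, and (slope-free model) trait heritability
  with residual variance in the denominator.
* **Permutation null.** `run_permutation_null()` reshuffles individual
  identities within communities in A with concordant maternal
  reassignment, refits the animal model per permutation, and reports
  one-sided exceedance probabilities for `h²`, `m²` and `m² − h²`.
* **Simulator.** `simulate_study()` generates pedigrees, sampling
  schedules and cortisol values from the same generative model with known
  variance components (`ground_truth_decomposition()`), so the whole
  pipeline is testable without any field data.

## Worked example

```r
library(cortherit)

## a small synthetic study: 3 communities x 14 individuals, 2 years,
## known ground truth (m2 = 0.3, h2 = 0.05 within communities)
cfg <- simulation_config(
  n_groups = 3, individuals_per_group = 14, n_years = 2,
  samples_per_individual_year = 12, founders_fraction = 0.5,
  Sigma_group = c(0.34, 0, 0), Sigma_group_year = c(0.24, 0, 0),
  Sigma_project = c(0.01, 0, 0), Sigma_individual = c(0.16, 0, 0),
  Sigma_id_year = c(0.12, 0, 0), Sigma_mother = c(0.24, 0, 0),
  Sigma_genetic = c(0.04, 0, 0), sigma2_residual = 0.35)
sim  <- simulate_study(cfg, seed = 7)
prep <- prepare_samples(sim$samples, sim$events, pedigree = sim$pedigree)
A    <- additive_relationship_matrix(attr(prep, "pedigree"))

fit <- fit_model(build_model(prep, "trait_heritability", A = A), prep,
                 sampler_settings(chains = 1, iterations = 3000,
                                  warmup = 800, seed = 1,
                                  monitor_mu = FALSE))
vc <- variance_components(fit)
wg <- within_group_heritability(vc, "intercept")
round(c(m2 = wg$m2_maternal$median, m2_lo = wg$m2_maternal$lo,
        m2_hi = wg$m2_maternal$hi, h2 = wg$h2_genetic$median), 3)
#>    m2 m2_lo m2_hi    h2
#> 0.311 0.044 0.685 0.143
```

The maternal share of within-community intercept variance is estimated at
0.31 (95% CI 0.04–0.69) against a simulated truth of 0.30, and the genetic
share at 0.14 against a truth of 0.05 — wide intervals are expected from a
pedigree this small. `run_permutation_null()` then asks whether shares like
these could arise from the pedigree/community structure alone.

A thin command-line wrapper (`inst/cli/cortherit`) exposes the same
pipeline as `simulate`, `preprocess`, `fit`, `decompose`, `permute` and
`report` stages operating on CSV/JSON artifacts.

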