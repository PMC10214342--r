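## Small simulation configurations used across model-level tests. Variance
## magnitudes are kept moderate so short chains mix; community count is 3
## to keep fits light.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_groups = 3, individuals_per_group = 10, n_years = 2,
         samples_per_individual_year = 6,
         Sigma_group = c(0.4, 0.02, 0.01),
         Sigma_group_year = c(0.12, 0.01, 0.01),
         Sigma_project = c(0.01, 0.001, 0.001),
         Sigma_individual = c(0.10, 0.02, 0.01),
         Sigma_id_year = c(0.06, 0.01, 0.01),
         Sigma_mother = c(0.08, 0.01, 0.01),
         Sigma_genetic = c(0.04, 0.01, 0.01),
         sigma2_residual = 0.3),
    list(...))
  do.call(simulation_config, args)
}

quick_settings <- function(chains = 1, iterations = 1200, warmup = 400,
                           seed = 1, monitor_mu = FALSE,
                           block_sampler = FALSE) {
  sampler_settings(chains = chains, iterations = iterations,
                   warmup = warmup, seed = seed, monitor_mu = monitor_mu,
                   block_sampler = block_sampler)
}

## Hand-built variance-component draws for formula tests: each argument a
## draws x components matrix (or vector for intercept-only).
fake_vc <- function(..., residual = NULL, variant = "full_heritability") {
  comps <- lapply(list(...), function(m) {
    if (is.null(dim(m))) m <- matrix(m, ncol = 1L,
                                     dimnames = list(NULL, "intercept"))
    m
  })
  if (is.null(residual)) residual <- rep(0.5, nrow(comps[[1L]]))
  structure(list(components = comps, residual = residual,
                 variant = variant), class = "cort_vc")
}

comp3 <- function(i, l, q) {
  matrix(c(i, l, q), ncol = 3L,
         dimnames = list(NULL, c("intercept", "linear", "quadratic")))
}
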