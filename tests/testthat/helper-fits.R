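## Lazily computed, session-cached MCMC fixtures shared across test files.
.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, force(expr), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

cached_tiny_sim <- function() {
  cached("tiny_sim", simulate_study(tiny_config(), seed = 101))
}

cached_trait_fit <- function() {
  cached("trait_fit", {
    sim <- cached_tiny_sim()
    spec <- build_model(sim$prepared, "trait_heritability", A = sim$A)
    suppressWarnings(fit_model(spec, sim$prepared,
                               quick_settings(iterations = 1400,
                                              warmup = 400, seed = 7)))
  })
}
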