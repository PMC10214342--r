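test_that("model variants declare the documented random structures", {
  sim <- cached_tiny_sim()
  prep <- sim$prepared

  null <- build_model(prep, "null")
  expect_equal(null$random,
               c(group = 1, group_year = 1, project = 1))
  intercepts <- build_model(prep, "intercepts")
  expect_equal(length(intercepts$random), 5L)
  expect_true(all(intercepts$random == 1))
  rn <- build_model(prep, "reaction_norms")
  expect_equal(rn$random[["individual"]], 3)
  expect_equal(rn$random[["id_year"]], 3)
  expect_equal(rn$random[["group"]], 1)
  full <- build_model(prep, "full_heritability", A = sim$A)
  expect_equal(length(full$random), 7L)
  expect_true(all(full$random == 3))
  trait <- build_model(prep, "trait_heritability", A = sim$A)
  expect_true(all(trait$random == 1))
  expect_setequal(names(trait$random),
                  c("group", "group_year", "project", "individual",
                    "id_year", "mother", "genetic"))

  ## animal models demand A; the dominance variant demands the rank column
  expect_error(build_model(prep, "full_heritability"), "relatedness matrix")
  expect_error(build_model(prep, "dominance_heritability", A = sim$A),
               "dominance")
  expect_output(print(full), "full_heritability")
})

test_that("fits are reproducible under a fixed seed", {
  sim <- cached_tiny_sim()
  spec <- build_model(sim$prepared, "intercepts")
  st <- quick_settings(iterations = 700, warmup = 300, seed = 42)
  f1 <- suppressWarnings(fit_model(spec, sim$prepared, st))
  f2 <- suppressWarnings(fit_model(spec, sim$prepared, st))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$vc, f2$vc)
})

test_that("fit_model validates inputs before sampling", {
  sim <- cached_tiny_sim()
  prep <- sim$prepared
  one_group <- prep[prep$group == "g1", , drop = FALSE]
  spec <- build_model(prep, "null")
  expect_error(suppressWarnings(fit_model(spec, one_group)),
               "has a single level")
  bad <- prep
  bad$y[1L] <- NaN
  expect_error(fit_model(spec, bad), "non-finite response")
})

test_that("fixed effects are recovered when random variances are zero", {
  zero <- lapply(1:7, function(i) c(0, 0, 0))
  names(zero) <- paste0("Sigma_", c("group", "group_year", "project",
                                    "individual", "id_year", "mother",
                                    "genetic"))
  cfg <- do.call(tiny_config, c(zero, list(sigma2_residual = 0.2)))
  sim <- simulate_study(cfg, seed = 55)
  spec <- build_model(sim$prepared, "null")
  fit <- suppressWarnings(
    fit_model(spec, sim$prepared, quick_settings(iterations = 1400,
                                                 warmup = 400, seed = 2)))
  truth <- sim$truth$beta[colnames(fit$beta)]
  post_mean <- colMeans(fit$beta)
  post_sd <- apply(fit$beta, 2L, stats::sd)
  expect_true(all(abs(post_mean - truth) < 3.5 * post_sd))
})

test_that("zero individual variance is recovered as a near-zero share", {
  cfg <- tiny_config(Sigma_individual = c(0, 0, 0),
                     Sigma_id_year = c(0.15, 0, 0))
  sim <- simulate_study(cfg, seed = 66)
  spec <- build_model(sim$prepared, "intercepts")
  fit <- suppressWarnings(
    fit_model(spec, sim$prepared, quick_settings(iterations = 1400,
                                                 warmup = 400, seed = 3)))
  vc <- variance_components(fit)
  total <- vc$components$individual[, 1L] + vc$components$id_year[, 1L] +
    vc$components$group_year[, 1L] + vc$components$group[, 1L] +
    vc$residual
  share <- stats::median(vc$components$individual[, 1L] / total)
  expect_lt(share, 0.10)
})

test_that("an identity A makes the genetic term act as an individual term", {
  ## with A = I the genetic/individual split is unidentified, but their sum
  ## is the among-individual variance and should still be recovered
  cfg <- tiny_config(Sigma_genetic = c(0, 0, 0),
                     Sigma_individual = c(0.15, 0, 0),
                     founders_fraction = 1)
  sim <- simulate_study(cfg, seed = 77)
  expect_equal(unname(sim$A), diag(nrow(sim$A)))
  spec <- build_model(sim$prepared, "trait_heritability", A = sim$A)
  fit <- suppressWarnings(
    fit_model(spec, sim$prepared, quick_settings(iterations = 1600,
                                                 warmup = 500, seed = 4)))
  vc <- variance_components(fit)
  combined <- stats::median(vc$components$genetic[, 1L] +
                            vc$components$individual[, 1L])
  expect_lt(abs(combined - 0.15), 0.12)
})

test_that("row order of the dataset does not change posterior summaries", {
  sim <- cached_tiny_sim()
  spec <- build_model(sim$prepared, "intercepts")
  st <- quick_settings(iterations = 1400, warmup = 400, seed = 9)
  f1 <- suppressWarnings(fit_model(spec, sim$prepared, st))
  perm <- sample(nrow(sim$prepared))
  f2 <- suppressWarnings(fit_model(spec, sim$prepared[perm, ], st))
  v1 <- stats::median(variance_components(f1)$components$individual[, 1L])
  v2 <- stats::median(variance_components(f2)$components$individual[, 1L])
  expect_lt(abs(v1 - v2), 0.35 * max(v1, v2, 0.02))
  expect_lt(abs(stats::median(f1$sigma) - stats::median(f2$sigma)), 0.05)
})

test_that("relatedness factorization retries with jitter on singular A", {
  A <- matrix(1, 2, 2)  # perfectly correlated duplicate founders
  dimnames(A) <- list(c("a", "b"), c("a", "b"))
  L <- cortherit:::chol_lower_jitter(A)
  expect_equal(L %*% t(L), A, tolerance = 1e-6)
})
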