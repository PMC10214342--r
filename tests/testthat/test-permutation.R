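make_plan <- function(groups, n_perm = 5, seed = 1) {
  permutation_plan(groups, n_permutations = n_perm, seed = seed)
}

test_that("permutation plans are within-group bijections, reproducible", {
  gm <- stats::setNames(rep(c("gA", "gB"), each = 6),
                        sprintf("i%02d", 1:12))
  p1 <- make_plan(gm, n_perm = 10, seed = 3)
  p2 <- make_plan(gm, n_perm = 10, seed = 3)
  expect_identical(p1$permutations, p2$permutations)
  p3 <- make_plan(gm, n_perm = 10, seed = 4)
  expect_false(identical(p1$permutations, p3$permutations))
  for (pi_ in p1$permutations) {
    expect_setequal(unname(pi_), names(pi_))
    expect_true(all(gm[pi_] == gm[names(pi_)]))
  }
})

test_that("permuting identities relabels A and mothers concordantly", {
  set.seed(31)
  df <- random_pedigree_df(14, p_unknown = 0.2)
  ped <- as_pedigree(df)
  A <- additive_relationship_matrix(ped)
  ids <- ped$records$individual
  gm <- stats::setNames(rep(c("gA", "gB"), length.out = length(ids)), ids)
  mother_map <- stats::setNames(ped$records$dam, ids)
  plan <- make_plan(gm, n_perm = 8, seed = 6)

  ## identity permutation leaves everything unchanged
  plan$permutations[[1L]] <- stats::setNames(ids, ids)
  id_res <- permute_identities(plan, 1L, A, mother_map)
  expect_equal(id_res$A_perm, A)
  expect_equal(id_res$mother_map_perm, mother_map)

  ## a transposition swaps the two rows/columns and the two mothers
  same_g <- ids[gm == "gA"][1:2]
  swap <- stats::setNames(ids, ids)
  swap[same_g] <- rev(same_g)
  plan$permutations[[2L]] <- swap
  tr <- permute_identities(plan, 2L, A, mother_map)
  expect_equal(tr$A_perm[same_g[1L], same_g[1L]], A[same_g[2L], same_g[2L]])
  other <- setdiff(ids, same_g)
  expect_equal(tr$A_perm[same_g[1L], other], A[same_g[2L], other])
  expect_equal(unname(tr$mother_map_perm[same_g]),
               unname(mother_map[rev(same_g)]))

  for (p in 3:8) {
    res <- permute_identities(plan, p, A, mother_map)
    ## similarity transform: eigenvalues and within-group entry multisets
    expect_equal(sort(eigen(res$A_perm, symmetric = TRUE)$values),
                 sort(eigen(A, symmetric = TRUE)$values), tolerance = 1e-10)
    gA <- ids[gm == "gA"]
    expect_equal(sort(as.vector(res$A_perm[gA, gA])),
                 sort(as.vector(A[gA, gA])))
    ## concordance: permuted maternal sibs are permuted genetic sibs
    mm <- res$mother_map_perm
    for (i in ids) for (j in ids) {
      if (i != j && !is.na(mm[i]) && !is.na(mm[j]) && mm[i] == mm[j])
        expect_gte(res$A_perm[i, j], 0.25)
    }
  }

  ## moving an individual across groups is refused
  bad <- stats::setNames(ids, ids)
  a <- ids[gm == "gA"][1L]; b <- ids[gm == "gB"][1L]
  bad[c(a, b)] <- c(b, a)
  plan$permutations[[3L]] <- bad
  expect_error(permute_identities(plan, 3L, A, mother_map),
               "across communities")
})

test_that("exceedance counting treats ties conservatively", {
  observed <- data.frame(component = "intercept", h2 = 0.1, m2 = 0.30,
                         diff = 0.20)
  perms <- data.frame(component = "intercept",
                      h2 = c(0.05, 0.02, 0.01, 0.30),
                      m2 = c(0.10, 0.30, 0.05, 0.02),
                      diff = c(0.05, 0.28, 0.04, -0.28),
                      permutation = 1:4, converged = TRUE, failed = FALSE)
  ex <- cortherit:::exceedance_counts(observed, perms)
  ## observed m2 equals one permuted value: the tie counts toward the null
  expect_equal(ex$p_m2, 1 / 4)
  ## observed diff larger than all permuted values
  expect_equal(ex$diff_ge, 1L)   # 0.28 >= 0.20
  expect_equal(ex$p_h2, 1 / 4)   # one tie at 0.30
  ## failed permutations are excluded from the denominator
  perms$failed[4L] <- TRUE
  ex2 <- cortherit:::exceedance_counts(observed, perms)
  expect_equal(ex2$n_valid, 3L)

  fake <- structure(list(observed = observed,
                         exceedance = cbind(ex, n_valid = 4L)),
                    class = "permutation_result")
  expect_equal(difference_test(fake, "intercept"), ex$p_diff)
  expect_error(difference_test(fake, "linear"), "not present")
})

test_that("a symmetric null puts the observed statistic near the middle", {
  observed <- data.frame(component = "intercept", h2 = 0, m2 = 0, diff = 0)
  perms <- data.frame(component = "intercept", h2 = 0, m2 = 0,
                      diff = seq(-1, 1, length.out = 200),
                      permutation = 1:200, converged = TRUE, failed = FALSE)
  ex <- cortherit:::exceedance_counts(observed, perms)
  expect_equal(ex$p_diff, 0.5)
})

test_that("the permutation null machinery runs end to end", {
  sim <- cached_tiny_sim()
  fit <- cached_trait_fit()
  gm <- stats::setNames(sim$prepared$group, sim$prepared$individual)
  gm <- gm[!duplicated(names(gm))]
  plan <- permutation_plan(gm, n_permutations = 2, seed = 11)
  res <- run_permutation_null(sim$prepared, sim$A, plan,
                              settings = quick_settings(iterations = 900,
                                                        warmup = 400),
                              observed_fit = fit)
  expect_s3_class(res, "permutation_result")
  expect_lte(res$exceedance$n_valid, 2L)
  expect_true(all(c("h2", "m2", "diff") %in% names(res$observed)))
  expect_output(print(res), "permutations")

  ## an empty plan yields an observed-only result and an empty null
  plan0 <- permutation_plan(gm, n_permutations = 0, seed = 11)
  res0 <- run_permutation_null(sim$prepared, sim$A, plan0,
                               observed_fit = fit)
  expect_null(res0$permutations)
  expect_true(is.na(res0$exceedance$p_m2))
  expect_error(difference_test(res0), "empty")
})
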