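#' Plan a within-community identity permutation null
#'
#' Describes the resampling scheme used to test whether maternal and
#' genetic variance shares exceed what pedigree structure alone would
#' produce: individual identities are reshuffled within their communities
#' in the additive genetic matrix, so group-level environmental and social
#' structure is preserved while genetic (and, concordantly, maternal)
#' relationships are randomized.
#'
#' @param group_membership Named character vector: individual -> community.
#' @param n_permutations Number of permutations (the study design uses
#'   100).
#' @param seed Integer seed; the permutation sequence is fully reproducible
#'   from it.
#' @return Object of class \code{permutation_plan} with the permutations
#'   pre-drawn (list of named character vectors mapping each individual to
#'   the individual whose identity it takes).
#' @export
permutation_plan <- function(group_membership, n_permutations = 100,
                             seed = 1) {
  stopifnot(n_permutations >= 0, !is.null(names(group_membership)))
  ids <- names(group_membership)
  set.seed(seed)
  perms <- lapply(seq_len(n_permutations), function(p) {
    pi <- ids
    names(pi) <- ids
    for (g in unique(group_membership)) {
      members <- ids[group_membership == g]
      pi[members] <- sample(members)
    }
    pi
  })
  structure(list(group_membership = group_membership,
                 n_permutations = as.integer(n_permutations), seed = seed,
                 permutations = perms),
            class = "permutation_plan")
}

#' Apply one identity permutation to A and the maternal map
#'
#' Relabels individuals inside the additive genetic matrix according to a
#' within-community permutation \eqn{\pi}: the permuted matrix satisfies
#' \eqn{A^{perm}_{ij} = A_{\pi(i)\pi(j)}} (a similarity transform
#' \eqn{P A P^\top}), and each individual inherits the mother of
#' \eqn{\pi(i)}, so that individuals who become genetic siblings under the
#' permutation also share a mother — maternal and genetic relationships
#' stay concordant. The sample table itself is never touched.
#'
#' @param plan A \code{permutation_plan}.
#' @param permutation_index Which permutation of the plan to apply.
#' @param A Relatedness matrix covering at least the planned individuals.
#' @param mother_map Named character vector individual -> mother
#'   (\code{NA} for unknown).
#' @return List with \code{A_perm} and \code{mother_map_perm}.
#' @export
permute_identities <- function(plan, permutation_index, A, mother_map) {
  stopifnot(inherits(plan, "permutation_plan"),
            permutation_index >= 1,
            permutation_index <= plan$n_permutations)
  pi_ <- plan$permutations[[permutation_index]]
  ids <- names(pi_)
  miss <- setdiff(ids, rownames(A))
  if (length(miss) > 0L)
    stop("relatedness matrix lacks individual(s): ",
         paste(miss, collapse = ", "))
  gm <- plan$group_membership
  if (any(gm[pi_[ids]] != gm[ids]))
    stop("permutation moves individuals across communities")
  A_perm <- A
  A_perm[ids, ids] <- A[pi_[ids], pi_[ids]]
  mm <- mother_map
  mm[ids] <- mother_map[pi_[ids]]
  list(A_perm = A_perm, mother_map_perm = mm)
}

#' Run the permutation null for maternal and genetic effects
#'
#' Fits the observed animal model, then refits it once per permutation
#' with the permuted relatedness matrix and concordantly permuted maternal
#' identities, recording the posterior-median within-community genetic
#' share (h2), maternal share (m2) and their difference (m2 - h2) for each
#' fitted reaction-norm component. Exceedance probabilities count the
#' permutations whose statistic is greater than or equal to the observed
#' one (ties count toward the null); the complementary lower-tail count is
#' reported as well. Permutation refits that fail or do not converge are
#' recorded and excluded from the counts, never silently dropped.
#'
#' @param dataset Prepared dataset (\code{cort_data}) with a \code{mother}
#'   column.
#' @param A Relatedness matrix.
#' @param plan A [permutation_plan()] covering the sampled individuals.
#' @param variant Animal-model variant to refit (default
#'   \code{"trait_heritability"}; permutation refits typically use the
#'   lighter variant and shorter chains, since only posterior medians feed
#'   the null).
#' @param settings [sampler_settings()] for the permutation refits.
#' @param observed_fit Optional pre-computed observed fit (same variant);
#'   when absent it is fitted with \code{settings}.
#' @param include_technical Passed to the share calculations.
#' @param rhat_threshold Split-Rhat gate applied to the share-relevant
#'   standard deviations of each permutation refit. The default (1.5) is
#'   looser than the 1.1 used to flag main fits: refits run on reduced
#'   chains, where split-Rhat reflects chain length more than data
#'   pathology, and only posterior medians of the shares feed the null.
#' @return Object of class \code{permutation_result}: observed shares,
#'   per-permutation shares, exceedance counts and proportions, and the
#'   failure log.
#' @export
run_permutation_null <- function(dataset, A, plan,
                                 variant = "trait_heritability",
                                 settings = sampler_settings(),
                                 observed_fit = NULL,
                                 include_technical = FALSE,
                                 rhat_threshold = 1.5) {
  stopifnot(inherits(plan, "permutation_plan"))
  if (!"mother" %in% names(dataset))
    stop("dataset lacks the 'mother' column (prepare with a pedigree)")
  mother_map <- stats::setNames(dataset$mother, dataset$individual)
  mother_map <- mother_map[!duplicated(names(mother_map))]

  shares_of <- function(fit) {
    vc <- variance_components(fit)
    comps <- colnames(vc$components$genetic)
    do.call(rbind, lapply(comps, function(c_) {
      wg <- within_group_heritability(vc, c_, include_technical)
      data.frame(component = c_, h2 = wg$h2_genetic$median,
                 m2 = wg$m2_maternal$median,
                 diff = stats::median(wg$draws$m2_maternal -
                                      wg$draws$h2_genetic))
    }))
  }
  refit <- function(A_use, mm, perm_seed) {
    df <- dataset
    mm_named <- mm[df$individual]
    unk <- is.na(mm_named)
    mm_named[unk] <- paste0("unk.", df$individual[unk])
    df$mother <- unname(mm_named)
    st <- settings
    st$seed <- perm_seed
    spec <- build_model(df, variant, A = A_use)
    fit_model(spec, df, st)
  }

  if (is.null(observed_fit)) {
    observed_fit <- refit(A, mother_map, settings$seed)
  } else if (!identical(observed_fit$spec$variant, variant)) {
    stop("observed_fit variant (", observed_fit$spec$variant,
         ") differs from the permutation variant (", variant, ")")
  }
  observed <- shares_of(observed_fit)

  perm_rows <- list(); failures <- integer(0)
  for (p in seq_len(plan$n_permutations)) {
    perm <- permute_identities(plan, p, A, mother_map)
    res <- tryCatch({
      f <- suppressWarnings(refit(perm$A_perm, perm$mother_map_perm,
                                  settings$seed + p))
      s <- shares_of(f)
      s$permutation <- p
      s$converged <- shares_converged(f, rhat_threshold)
      s
    }, error = function(e) NULL)
    if (is.null(res) || !all(res$converged)) {
      failures <- c(failures, p)
      if (!is.null(res)) {
        res$failed <- TRUE
        perm_rows[[length(perm_rows) + 1L]] <- res
      }
    } else {
      res$failed <- FALSE
      perm_rows[[length(perm_rows) + 1L]] <- res
    }
  }
  perms <- if (length(perm_rows) > 0L) do.call(rbind, perm_rows) else NULL

  exceedance <- exceedance_counts(observed, perms)

  structure(list(observed = observed, permutations = perms,
                 exceedance = exceedance, failures = failures,
                 plan = plan, variant = variant,
                 observed_fit = observed_fit),
            class = "permutation_result")
}

## One-sided exceedance counts per component: permuted statistics greater
## than OR EQUAL to the observed count toward the null (conservative tie
## handling); the lower-tail counts are reported alongside so either
## reading convention is available.
exceedance_counts <- function(observed, perms) {
  do.call(rbind, lapply(seq_len(nrow(observed)), function(i) {
    c_ <- observed$component[i]
    ok <- if (is.null(perms)) NULL
          else perms[!perms$failed & perms$component == c_, , drop = FALSE]
    n_ok <- if (is.null(ok)) 0L else nrow(ok)
    count <- function(stat) {
      if (n_ok == 0L) return(c(NA_integer_, NA_integer_))
      c(sum(ok[[stat]] >= observed[[stat]][i]),
        sum(ok[[stat]] < observed[[stat]][i]))
    }
    h <- count("h2"); m <- count("m2"); d <- count("diff")
    data.frame(component = c_, n_valid = n_ok,
               h2_ge = h[1L], h2_lt = h[2L],
               m2_ge = m[1L], m2_lt = m[2L],
               diff_ge = d[1L], diff_lt = d[2L],
               p_h2 = h[1L] / n_ok, p_m2 = m[1L] / n_ok,
               p_diff = d[1L] / n_ok)
  }))
}

## Convergence gate for permutation refits: only the standard deviations
## entering the within-community shares need to have mixed; slow-mixing
## nuisance scales (e.g. a 3-level community term) do not invalidate the
## permuted statistic.
shares_converged <- function(fit, threshold = 1.1) {
  d <- fit$diagnostics
  rel <- grepl("^sd_(genetic|mother|group_year|individual|id_year|project)",
               d$parameter)
  rh <- d$rhat[rel]
  all(is.na(rh) | rh < threshold)
}

#' Exceedance probability of the maternal-minus-genetic difference
#'
#' The share of valid permutations whose (m2 - h2) difference is at least
#' the observed difference for a component; ties count toward the null.
#'
#' @param result A \code{permutation_result}.
#' @param component Reaction-norm component.
#' @return Single proportion.
#' @export
difference_test <- function(result, component = "intercept") {
  stopifnot(inherits(result, "permutation_result"))
  row <- result$exceedance[result$exceedance$component == component, ]
  if (nrow(row) == 0L)
    stop("component '", component, "' not present in the permutation result")
  if (is.na(row$n_valid) || row$n_valid == 0L)
    stop("no valid permutations: the null distribution is empty")
  row$p_diff
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Within-community identity-permutation null (",
      x$plan$n_permutations, " permutations, variant ", x$variant, ")\n",
      sep = "")
  if (length(x$failures) > 0L)
    cat("  failed/non-converged permutations:",
        paste(x$failures, collapse = ", "), "\n")
  print(merge(x$observed, x$exceedance, by = "component"))
  invisible(x)
}
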