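#' Configuration of the generative simulator
#'
#' Describes a synthetic study: the community structure, pedigree depth,
#' sampling effort, fixed effects, and the ground-truth covariance of every
#' random-effect term on the reaction-norm scale (3x3 matrices over
#' intercept, linear and quadratic circadian components). Defaults emulate
#' the structure of the real study system: five communities of roughly 34
#' sampled individuals, multi-year sampling with a dozen-plus samples per
#' individual-year, a declining circadian log-cortisol curve, dominant
#' between-community variance on reaction-norm intercepts and small
#' genetic/maternal within-community shares. Calibration experiments use
#' far smaller settings.
#'
#' @param n_groups Number of communities.
#' @param individuals_per_group Sampled individuals per community.
#' @param n_years Sampling years per individual.
#' @param founders_fraction Fraction of each community's individuals that
#'   are pedigree founders (unknown parents).
#' @param samples_per_individual_year Mean samples per individual-year
#'   (Poisson, truncated at the sampling-span minimum of 3).
#' @param circadian Population-level curve: named vector with
#'   \code{intercept} (log ng/ml SG at the mean sampling hour),
#'   \code{t} and \code{t2} (effects of the z-scored hour and its square).
#' @param beta_main,beta_interaction Default magnitudes of the remaining
#'   fixed effects (main effects and their interactions with t/t2).
#' @param Sigma_group,Sigma_group_year,Sigma_project,Sigma_individual,Sigma_id_year,Sigma_mother,Sigma_genetic
#'   3x3 PSD ground-truth covariance matrices (intercept, linear,
#'   quadratic), or length-3 vectors taken as diagonals.
#' @param sigma2_residual Residual variance of log cortisol.
#' @param start_date First sampling date.
#' @param changeover_date Assay-method changeover: samples before it are
#'   \code{"old"}, at or after it \code{"new"}.
#' @param sg_range Range of per-sample specific gravity values.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_groups = 5, individuals_per_group = 34,
                              n_years = 3, founders_fraction = 0.4,
                              samples_per_individual_year = 12,
                              circadian = c(intercept = log(50), t = -0.35,
                                            t2 = 0.08),
                              beta_main = 0.1, beta_interaction = 0.05,
                              Sigma_group = c(3.9, 0.034, 0.005),
                              Sigma_group_year = c(0.089, 0.008, 0.007),
                              Sigma_project = c(0.005, 0.001, 0.001),
                              Sigma_individual = c(0.0024, 0.001, 0.0008),
                              Sigma_id_year = c(0.0156, 0.0034, 0.007),
                              Sigma_mother = c(0.0096, 0.0018, 0.0006),
                              Sigma_genetic = c(0.0012, 0.001, 0.0008),
                              sigma2_residual = 0.35,
                              start_date = as.Date("2010-01-01"),
                              changeover_date = as.Date("2011-07-01"),
                              sg_range = c(1.005, 1.035)) {
  as_sigma <- function(x, nm) {
    if (is.matrix(x)) {
      stopifnot(all(dim(x) == c(3L, 3L)))
      S <- (x + t(x)) / 2
    } else {
      stopifnot(length(x) == 3L)
      S <- diag(as.numeric(x), 3L)
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop("ground-truth covariance '", nm, "' is not positive semi-definite")
    dimnames(S) <- rep(list(c("intercept", "linear", "quadratic")), 2L)
    S
  }
  cfg <- list(n_groups = n_groups,
              individuals_per_group = individuals_per_group,
              n_years = n_years, founders_fraction = founders_fraction,
              samples_per_individual_year = samples_per_individual_year,
              circadian = circadian, beta_main = beta_main,
              beta_interaction = beta_interaction,
              Sigma = list(group = as_sigma(Sigma_group, "group"),
                           group_year = as_sigma(Sigma_group_year,
                                                 "group_year"),
                           project = as_sigma(Sigma_project, "project"),
                           individual = as_sigma(Sigma_individual,
                                                 "individual"),
                           id_year = as_sigma(Sigma_id_year, "id_year"),
                           mother = as_sigma(Sigma_mother, "mother"),
                           genetic = as_sigma(Sigma_genetic, "genetic")),
              sigma2_residual = sigma2_residual, start_date = start_date,
              changeover_date = changeover_date, sg_range = sg_range)
  stopifnot(n_groups >= 1, individuals_per_group >= 4, n_years >= 1,
            founders_fraction > 0, founders_fraction <= 1,
            samples_per_individual_year >= 3, sigma2_residual >= 0)
  structure(cfg, class = "simulation_config")
}

## Symmetric PSD square root (handles singular ground-truth covariances,
## e.g. zero slope variance).
matrix_sqrt_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
}

#' Simulate a multi-community pedigree
#'
#' Builds, per community, a set of founders followed by two waves of
#' offspring whose dams and sires are drawn uniformly among the community's
#' adults alive at the offspring's birth. Offspring of the same dam create
#' maternal sibships; shared sires create paternal half-sibs; founders are
#' mutually unrelated. Returns the pedigree together with individual birth
#' dates, sexes, groups and the dam (mother) map.
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements \code{pedigree} (a \code{pedigree}),
#'   \code{info} (data frame: individual, group, sex, birth_date) and
#'   \code{mother_map} (named character vector, \code{NA} for founders).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  recs <- list(); info <- list()
  for (g in seq_len(cfg$n_groups)) {
    gname <- paste0("g", g)
    N <- cfg$individuals_per_group
    n_found <- max(4L, round(cfg$founders_fraction * N))
    n_off <- N - n_found
    id <- sprintf("%s.i%02d", gname, seq_len(N))
    sex <- rep(c("female", "male"), length.out = N)
    ## founders are mature adults; offspring split between an adult wave
    ## and an immature wave so both age classes are sampled
    birth <- rep(cfg$start_date, N)
    birth[seq_len(n_found)] <- cfg$start_date -
      round(stats::runif(n_found, 20, 40) * 365.25)
    dam <- sire <- rep(NA_character_, N)
    if (n_off > 0L) {
      off_idx <- n_found + seq_len(n_off)
      adult_wave <- off_idx[seq_len(ceiling(n_off / 2))]
      young_wave <- setdiff(off_idx, adult_wave)
      birth[adult_wave] <- cfg$start_date -
        round(stats::runif(length(adult_wave), 13, 19) * 365.25)
      birth[young_wave] <- cfg$start_date -
        round(stats::runif(length(young_wave), 2.5, 11) * 365.25)
      for (i in off_idx) {
        eligible <- which(birth <= birth[i] - round(14 * 365.25) &
                          seq_len(N) != i)
        fem <- eligible[sex[eligible] == "female"]
        mal <- eligible[sex[eligible] == "male"]
        if (length(fem) > 0L) dam[i] <- id[sample_one(fem)]
        if (length(mal) > 0L) sire[i] <- id[sample_one(mal)]
      }
    }
    recs[[g]] <- data.frame(individual = id, dam = dam, sire = sire,
                            group = gname, sex = sex,
                            stringsAsFactors = FALSE)
    info[[g]] <- data.frame(individual = id, group = gname, sex = sex,
                            birth_date = birth, stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  info <- do.call(rbind, info)
  ped <- as_pedigree(recs)
  mother_map <- stats::setNames(recs$dam, recs$individual)
  list(pedigree = ped, info = info, mother_map = mother_map)
}

## sample() with the scalar-x surprise removed
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Simulate longitudinal urinary cortisol samples
#'
#' Generates sampling schedules that satisfy the preprocessing inclusion
#' criteria by construction (at least three samples per individual-year,
#' morning and afternoon hours, span of six hours or more), encodes the
#' covariates through the same preparation chain used for real data, and
#' then draws log cortisol from the generative hierarchical model
#' \deqn{y = X\beta + \sum_f Z_f u_f + \varepsilon}, with genetic effects
#' distributed as \eqn{N(0, A \otimes \Sigma_{genetic})} and every other
#' term \eqn{N(0, I \otimes \Sigma_f)}. Raw concentrations are obtained by
#' inverting the specific-gravity correction so the dataset round-trips
#' through [prepare_samples()].
#'
#' @param sim_ped Output of [simulate_pedigree()].
#' @param cfg A [simulation_config()].
#' @return An object of class \code{cort_simulation}: raw \code{samples}
#'   and \code{events} tables, \code{pedigree}, \code{mother_map},
#'   relatedness matrix \code{A} (all pedigree individuals), the encoded
#'   \code{prepared} dataset, and \code{truth} (fixed effects, realized
#'   random effects, the config and its analytic variance decomposition).
#' @export
simulate_cortisol <- function(sim_ped, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  info <- sim_ped$info
  n_ind <- nrow(info)

  ## reproductive events: real births from the pedigree plus a past birth
  ## for childless adult females so reproductive state is always assignable
  recs <- sim_ped$pedigree$records
  born <- info$birth_date[match(recs$individual, info$individual)]
  events <- data.frame(mother = recs$dam, offspring = recs$individual,
                       birth_date = born,
                       mother_death_date = as.Date(NA),
                       stringsAsFactors = FALSE)
  events <- events[!is.na(events$mother), , drop = FALSE]
  ## every female who is adult at any point of the sampling window needs an
  ## assignable reproductive state
  window_end <- cfg$start_date + cfg$n_years * 365L
  adult_f <- info$individual[info$sex == "female" &
                             info$birth_date <= window_end - 12 * 365.25]
  childless <- setdiff(adult_f, events$mother)
  if (length(childless) > 0L)
    events <- rbind(events, data.frame(
      mother = childless, offspring = paste0("off.", childless),
      birth_date = cfg$start_date - round(4 * 365.25),
      mother_death_date = as.Date(NA), stringsAsFactors = FALSE))

  ## sampling schedule satisfying the span criteria by construction
  rows <- vector("list", n_ind)
  group_sizes <- stats::setNames(
    round(seq(10, 50, length.out = cfg$n_groups)),
    paste0("g", seq_len(cfg$n_groups)))
  sites <- stats::setNames(
    rep(c("Tai", "Budongo"), length.out = cfg$n_groups),
    paste0("g", seq_len(cfg$n_groups)))
  for (i in seq_len(n_ind)) {
    per_year <- lapply(seq_len(cfg$n_years), function(yr) {
      k <- max(3L, stats::rpois(1L, cfg$samples_per_individual_year))
      hours <- c(stats::runif(1, 6, 10), stats::runif(1, 16, 18),
                 stats::runif(k - 2L, 6, 18))
      dates <- cfg$start_date + (yr - 1L) * 365L +
        sample.int(360L, k, replace = TRUE)
      data.frame(individual = info$individual[i], group = info$group[i],
                 date = dates, time = hours, stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, per_year)
  }
  samples <- do.call(rbind, rows)
  n <- nrow(samples)
  year <- format(samples$date, "%Y")
  gy <- paste(samples$group, year, sep = ".")
  sr_levels <- stats::setNames(stats::runif(length(unique(gy)), 0.3, 1.0),
                               unique(gy))
  samples$sample_id <- sprintf("s%06d", seq_len(n))
  samples$project <- paste0("proj.", sites[samples$group])
  samples$specific_gravity <- stats::runif(n, cfg$sg_range[1L],
                                           cfg$sg_range[2L])
  samples$lcms_method <- ifelse(samples$date < cfg$changeover_date,
                                "old", "new")
  samples$age_years <- as.numeric(samples$date -
    info$birth_date[match(samples$individual, info$individual)]) / 365.25
  samples$sex <- info$sex[match(samples$individual, info$individual)]
  samples$group_size <- unname(group_sizes[samples$group]) +
    as.integer(factor(year)) - 1L
  samples$sex_ratio <- unname(sr_levels[gy])
  samples$sick_flag <- FALSE
  samples$site <- unname(sites[samples$group])
  samples$cortisol_raw <- 1  # placeholder until y is drawn

  prep <- prepare_samples(samples, events, pedigree = sim_ped$pedigree)
  if (nrow(prep) != n)
    stop("internal error: simulated schedule did not pass its own filters")

  ## generative draw on the encoded design
  X <- fixed_design(prep, standard_fixed_covariates())
  beta <- stats::setNames(rep(cfg$beta_main, ncol(X)), colnames(X))
  beta[grepl(":", names(beta))] <- cfg$beta_interaction
  beta["(Intercept)"] <- cfg$circadian[["intercept"]]
  beta["t"] <- cfg$circadian[["t"]]
  beta["t2"] <- cfg$circadian[["t2"]]

  W <- cbind(1, prep$t, prep$t2)
  A <- additive_relationship_matrix(attr(prep, "pedigree"))
  u <- list()
  contrib <- as.vector(X %*% beta)
  for (f in names(cfg$Sigma)) {
    col <- if (identical(f, "genetic")) "individual" else f
    fac <- factor(prep[[col]])
    q <- nlevels(fac)
    Shalf <- matrix_sqrt_psd(cfg$Sigma[[f]])
    Z <- matrix(stats::rnorm(q * 3L), q, 3L)
    U <- if (identical(f, "genetic")) {
      Asub <- A[levels(fac), levels(fac), drop = FALSE]
      chol_lower_jitter(Asub) %*% Z %*% Shalf
    } else {
      Z %*% Shalf
    }
    rownames(U) <- levels(fac)
    colnames(U) <- c("intercept", "linear", "quadratic")
    u[[f]] <- U
    contrib <- contrib + rowSums(U[as.integer(fac), , drop = FALSE] * W)
  }
  y <- contrib + stats::rnorm(n, 0, sqrt(cfg$sigma2_residual))

  ## invert the SG correction so preprocessing reproduces y exactly
  stats_ <- attr(prep, "reference_stats")
  pop_mean <- stats_$sg_population_mean[prep$site]
  raw <- exp(y) * (prep$specific_gravity - 1) / (pop_mean - 1)
  samples$cortisol_raw[match(prep$sample_id, samples$sample_id)] <- raw
  prep$cortisol_raw <- raw
  prep$cortisol_sg <- exp(y)
  prep$y <- y

  structure(list(samples = samples, events = events,
                 pedigree = attr(prep, "pedigree"),
                 mother_map = sim_ped$mother_map, A = A, prepared = prep,
                 truth = list(beta = beta, u = u, config = cfg,
                              decomposition = ground_truth_decomposition(cfg))),
            class = "cort_simulation")
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper: [simulate_pedigree()] then [simulate_cortisol()],
#' under a single seed.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @return A \code{cort_simulation}; see [simulate_cortisol()].
#' @export
simulate_study <- function(cfg = simulation_config(), seed = 1) {
  set.seed(seed)
  simulate_cortisol(simulate_pedigree(cfg), cfg)
}

#' Analytic variance decomposition of a simulation configuration
#'
#' Applies the package's repeatability and heritability formulas directly
#' to the ground-truth covariance diagonals of a configuration, yielding
#' the exact target values that estimates should recover.
#'
#' @param cfg A [simulation_config()].
#' @return Nested list: per reaction-norm component, the between/within
#'   split, the five within-group shares, and reaction-norm repeatability;
#'   plus intercept-scale trait repeatabilities and trait heritability
#'   (with residual).
#' @export
ground_truth_decomposition <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  S <- cfg$Sigma
  out <- list()
  for (c_ in c("intercept", "linear", "quadratic")) {
    v <- vapply(S, function(m) m[c_, c_], numeric(1L))
    within <- v[["genetic"]] + v[["mother"]] + v[["group_year"]] +
      v[["individual"]] + v[["id_year"]]
    out[[c_]] <- list(
      between_group = v[["group"]] / (v[["group"]] + within),
      within_group = within / (v[["group"]] + within),
      h2_genetic = v[["genetic"]] / within,
      m2_maternal = v[["mother"]] / within,
      p_group_year = v[["group_year"]] / within,
      p_individual = v[["individual"]] / within,
      p_id_year = v[["id_year"]] / within,
      rn_repeatability = v[["individual"]] /
        (v[["individual"]] + v[["id_year"]]))
  }
  vi <- vapply(S, function(m) m["intercept", "intercept"], numeric(1L))
  vtot <- vi[["individual"]] + vi[["id_year"]] + vi[["group"]] +
    vi[["group_year"]]
  out$trait <- list(
    repeatability_long = vi[["individual"]] / vtot,
    repeatability_short = (vi[["individual"]] + vi[["id_year"]]) / vtot,
    heritability = vi[["genetic"]] /
      (vi[["genetic"]] + vi[["mother"]] + vi[["group_year"]] +
       vi[["individual"]] + vi[["id_year"]] + cfg$sigma2_residual))
  out
}
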