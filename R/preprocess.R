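#' Filtering and classification thresholds
#'
#' Bundles the thresholds used when cleaning a raw sample table: the
#' gestation window used to flag pregnancy (days before a birth), the
#' lactation window (days after a birth, set by the average resumption of
#' cycling), the age of social maturity separating adults from immatures,
#' and the per-individual-per-year sampling criteria needed to characterize
#' a circadian profile (minimum number of samples, minimum hour span between
#' earliest and latest sample, and the clock hour splitting morning from
#' afternoon).
#'
#' @param pregnancy_window_days Days before any birth during which the
#'   mother is classed pregnant. Default 240.
#' @param lactation_window_days Days after any birth during which the mother
#'   is classed lactating. Default 1095.
#' @param adult_age_years Age (years) at and above which an individual is an
#'   adult. Default 12.
#' @param min_samples_per_year Minimum samples per individual-year. Default 3.
#' @param min_span_hours Minimum span (hours) between the earliest and
#'   latest sample in an individual-year. Default 6.
#' @param morning_cutoff_hour Samples strictly before this hour count as
#'   morning, at or after as afternoon. Default 12.
#' @return An object of class \code{filter_config}.
#' @export
filter_config <- function(pregnancy_window_days = 240,
                          lactation_window_days = 1095,
                          adult_age_years = 12,
                          min_samples_per_year = 3,
                          min_span_hours = 6,
                          morning_cutoff_hour = 12) {
  cfg <- list(pregnancy_window_days = pregnancy_window_days,
              lactation_window_days = lactation_window_days,
              adult_age_years = adult_age_years,
              min_samples_per_year = min_samples_per_year,
              min_span_hours = min_span_hours,
              morning_cutoff_hour = morning_cutoff_hour)
  if (!all(vapply(cfg, function(x) is.numeric(x) && length(x) == 1L && x > 0,
                  logical(1L))))
    stop("all filter_config fields must be positive scalars")
  structure(cfg, class = "filter_config")
}

#' Specific-gravity correction of a urinary hormone concentration
#'
#' Corrects a raw urinary concentration for hydration-driven dilution using
#' the specific gravity (SG) of the sample relative to the population mean
#' SG:
#' \deqn{C_{corrected} = C_{raw} \times
#'   \frac{SG_{population\ mean} - 1}{SG_{sample} - 1}}
#'
#' @param raw Raw concentration (ng/ml); vectorized.
#' @param sg_sample Specific gravity of each sample (unitless, > 1).
#' @param sg_population_mean Population mean specific gravity (> 1).
#' @return Corrected concentration (ng/ml SG). Samples with
#'   \code{sg_sample <= 1} are degenerate (the correction divides by
#'   \code{sg_sample - 1}) and yield \code{NA}.
#' @examples
#' sg_correct(10, 1.04, 1.02) # 5
#' @export
sg_correct <- function(raw, sg_sample, sg_population_mean) {
  if (any(sg_population_mean <= 1))
    stop("sg_population_mean must exceed 1.0")
  out <- raw * (sg_population_mean - 1) / (sg_sample - 1)
  out[sg_sample <= 1] <- NA_real_
  out
}

#' Assign the reproductive state of a female at a sampling date
#'
#' A female is pregnant during the gestation window preceding any birth of
#' her offspring, lactating during the lactation window following any
#' birth, and cycling at any other time. Pregnancy takes precedence when a
#' new conception overlaps a previous lactation window. A female with no
#' recorded births cannot be assigned a state and yields \code{NA}.
#'
#' @param female Identifier of the (adult) female.
#' @param sample_date \code{Date} of sampling (vectorized).
#' @param events Reproductive-event table: columns \code{mother},
#'   \code{offspring}, \code{birth_date} and optionally
#'   \code{mother_death_date}.
#' @param cfg A [filter_config()].
#' @return Character vector: \code{"pregnant"}, \code{"lactating"},
#'   \code{"cycling"}, or \code{NA} if unassignable.
#' @export
assign_reproductive_state <- function(female, sample_date, events,
                                      cfg = filter_config()) {
  events <- normalize_events(events)
  births <- events$birth_date[events$mother == female]
  if (length(births) == 0L)
    return(rep(NA_character_, length(sample_date)))
  sample_date <- as.Date(sample_date)
  vapply(as.list(sample_date), function(d) {
    if (any(d >= births - cfg$pregnancy_window_days & d < births))
      return("pregnant")
    if (any(d >= births & d <= births + cfg$lactation_window_days))
      return("lactating")
    "cycling"
  }, character(1L))
}

normalize_events <- function(events) {
  need <- c("mother", "offspring", "birth_date")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0L)
    stop("event table lacks column(s): ", paste(miss, collapse = ", "))
  events$birth_date <- as.Date(events$birth_date)
  if (!"mother_death_date" %in% names(events))
    events$mother_death_date <- as.Date(NA)
  events$mother_death_date <- as.Date(events$mother_death_date)
  events
}

#' Apply sample-level exclusion rules
#'
#' Flags and removes samples that would bias a circadian cortisol profile:
#' degenerate specific gravity, non-positive raw concentrations, samples
#' from the day an individual showed sickness or injury, samples collected
#' from an immature individual after the death of its mother, samples from
#' pregnant females, and samples from adult females whose reproductive
#' state cannot be assigned. Rules are evaluated jointly on the full table,
#' so their outcome does not depend on any ordering.
#'
#' @param samples Sample table (see [read_samples()] for the schema).
#' @param events Reproductive-event table; see
#'   [assign_reproductive_state()].
#' @param cfg A [filter_config()].
#' @return A list with \code{retained} (samples that pass, with a
#'   \code{reproductive_state} column added for adult females),
#'   \code{excluded} (failing samples with a \code{exclusion_reason}
#'   column), and \code{log} (named counts per rule).
#' @export
apply_exclusions <- function(samples, events, cfg = filter_config()) {
  samples <- normalize_samples(samples)
  events <- normalize_events(events)
  n <- nrow(samples)
  adult <- samples$age_years >= cfg$adult_age_years
  female <- samples$sex == "female"

  state <- rep(NA_character_, n)
  af <- which(adult & female)
  for (id in unique(samples$individual[af])) {
    rows <- af[samples$individual[af] == id]
    state[rows] <- assign_reproductive_state(id, samples$date[rows],
                                             events, cfg)
  }

  death <- events$mother_death_date[match(samples$individual,
                                          events$offspring)]
  lost_mother <- !is.na(death) & samples$date >= death

  reason <- rep(NA_character_, n)
  flag <- function(cond, label) {
    hit <- cond & is.na(reason)
    reason[hit] <<- label
  }
  flag(samples$specific_gravity <= 1, "sg_invalid")
  flag(samples$cortisol_raw <= 0, "nonpositive_cortisol")
  flag(samples$sick_flag, "sick")
  flag(!adult & lost_mother, "maternal_loss")
  flag(adult & female & !is.na(state) & state == "pregnant", "pregnant")
  flag(adult & female & is.na(state), "state_unassignable")

  keep <- is.na(reason)
  retained <- samples[keep, , drop = FALSE]
  retained$reproductive_state <- state[keep]
  excluded <- samples[!keep, , drop = FALSE]
  excluded$exclusion_reason <- reason[!keep]
  log <- table(factor(reason[!keep],
                      levels = c("sg_invalid", "nonpositive_cortisol",
                                 "sick", "maternal_loss", "pregnant",
                                 "state_unassignable")))
  list(retained = retained, excluded = excluded,
       log = stats::setNames(as.integer(log), names(log)))
}

#' Keep only individual-years with an informative sampling schedule
#'
#' An individual-year is retained only if it has at least
#' \code{min_samples_per_year} samples, at least one morning and one
#' afternoon sample (relative to \code{morning_cutoff_hour}), and its
#' earliest and latest samples are at least \code{min_span_hours} apart.
#' Anything less cannot support a quadratic circadian slope.
#'
#' @inheritParams apply_exclusions
#' @return The retained samples; the dropped individual-year labels are
#'   attached as attribute \code{"dropped_id_years"}.
#' @export
sampling_span_filter <- function(samples, cfg = filter_config()) {
  samples <- normalize_samples(samples)
  year <- format(samples$date, "%Y")
  id_year <- paste(samples$individual, year, sep = ".")
  ok <- vapply(split(samples$hours, id_year), function(h) {
    length(h) >= cfg$min_samples_per_year &&
      (max(h) - min(h)) >= cfg$min_span_hours &&
      any(h < cfg$morning_cutoff_hour) &&
      any(h >= cfg$morning_cutoff_hour)
  }, logical(1L))
  keep <- ok[id_year]
  out <- samples[keep, , drop = FALSE]
  attr(out, "dropped_id_years") <- names(ok)[!ok]
  out
}

#' Encode model covariates
#'
#' Turns a filtered sample table into the model-ready dataset: the response
#' \code{y} (natural log of SG-corrected cortisol, log ng/ml SG), the
#' z-scored hours-since-midnight \code{t} and its square \code{t2},
#' z-scored age, sex ratio and group size, circannual sine/cosine of the
#' day of year, the five-level demographic class, and the composite
#' \code{group_year} and \code{id_year} grouping labels. Quadratic time is
#' the square of the already z-scored linear time, so slope estimates are
#' comparable across runs. Z-scoring statistics (and the SG population
#' means actually used) are stored in the \code{"reference_stats"}
#' attribute; passing them back in re-encodes a dataset identically.
#'
#' @param samples Filtered sample table (must carry a
#'   \code{reproductive_state} column for adult females, as produced by
#'   [apply_exclusions()]).
#' @param cfg A [filter_config()].
#' @param sg_population_mean Optional override: a single mean SG, or a named
#'   vector by site. By default the mean SG is computed per site over the
#'   supplied (i.e. retained) samples; with no \code{site} column a single
#'   pooled mean is used.
#' @param reference_stats Optional statistics from a previous encoding.
#' @param mother_map Optional named character vector mapping individual to
#'   mother identity. Individuals without a known mother are given unique
#'   singleton mother levels (\code{"unk.<id>"}).
#' @return A \code{data.frame} of class \code{cort_data} with the encoded
#'   columns appended, and attribute \code{reference_stats}.
#' @export
encode_covariates <- function(samples, cfg = filter_config(),
                              sg_population_mean = NULL,
                              reference_stats = NULL,
                              mother_map = NULL) {
  samples <- normalize_samples(samples)
  df <- as.data.frame(samples)
  if (!"site" %in% names(df)) df$site <- "all"

  if (!is.null(reference_stats)) {
    stats_ <- reference_stats
  } else {
    sg_mean <- if (is.null(sg_population_mean)) {
      tapply(df$specific_gravity, df$site, mean)
    } else if (is.null(names(sg_population_mean))) {
      stats::setNames(rep(sg_population_mean[1L],
                          length(unique(df$site))), unique(df$site))
    } else sg_population_mean
    zstat <- function(x) list(mean = mean(x), sd = stats::sd(x))
    stats_ <- list(sg_population_mean = sg_mean,
                   hours = zstat(df$hours),
                   age = zstat(df$age_years),
                   sex_ratio = zstat(df$sex_ratio),
                   group_size = zstat(df$group_size))
  }
  zscore <- function(x, s) (x - s$mean) / s$sd

  corrected <- sg_correct(df$cortisol_raw, df$specific_gravity,
                          as.numeric(stats_$sg_population_mean[df$site]))
  bad <- is.na(corrected) | corrected <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with non-positive corrected cortisol ",
            "dropped during encoding")
    df <- df[!bad, , drop = FALSE]
    corrected <- corrected[!bad]
  }
  df$cortisol_sg <- corrected
  df$y <- log(corrected)
  df$t <- zscore(df$hours, stats_$hours)
  df$t2 <- df$t^2
  df$age_z <- zscore(df$age_years, stats_$age)
  df$sexratio_z <- zscore(df$sex_ratio, stats_$sex_ratio)
  df$groupsize_z <- zscore(df$group_size, stats_$group_size)
  doy <- as.POSIXlt(df$date)$yday + 1
  df$season_sin <- sin(2 * pi * doy / 365.25)
  df$season_cos <- cos(2 * pi * doy / 365.25)
  year <- format(df$date, "%Y")
  df$group_year <- paste(df$group, year, sep = ".")
  df$id_year <- paste(df$individual, year, sep = ".")

  if (!"reproductive_state" %in% names(df))
    df$reproductive_state <- NA_character_
  adult <- df$age_years >= cfg$adult_age_years
  df$demographic <- ifelse(!adult,
                           paste("immature", df$sex),
                           ifelse(df$sex == "male", "adult male",
                                  paste(df$reproductive_state, "female")))
  df$demographic <- factor(df$demographic,
                           levels = c("adult male", "cycling female",
                                      "lactating female", "immature male",
                                      "immature female"))
  if (anyNA(df$demographic))
    stop("unclassifiable demographic for some samples (check sex and ",
         "reproductive_state columns)")
  df$lcms_method <- factor(df$lcms_method, levels = c("old", "new"))

  if (!is.null(mother_map)) {
    mm <- mother_map[df$individual]
    unk <- is.na(mm)
    mm[unk] <- paste0("unk.", df$individual[unk])
    df$mother <- unname(mm)
  }
  rownames(df) <- NULL
  structure(df, reference_stats = stats_,
            class = c("cort_data", "data.frame"))
}

#' Read a raw sample table from CSV
#'
#' Expected columns: \code{sample_id}, \code{individual}, \code{group},
#' \code{project}, \code{date} (ISO), \code{time} (\code{HH:MM},
#' \code{HH:MM:SS} or decimal hours), \code{cortisol_raw} (ng/ml),
#' \code{specific_gravity}, \code{lcms_method} (\code{old}/\code{new}),
#' \code{age_years}, \code{sex} (\code{male}/\code{female}),
#' \code{group_size}, \code{sex_ratio}, \code{sick_flag}
#' (\code{TRUE}/\code{FALSE}); optional \code{site} and \code{dominance}.
#'
#' @param path CSV path.
#' @return A validated sample \code{data.frame} with \code{date} as
#'   \code{Date} and a numeric \code{hours} column.
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  normalize_samples(df)
}

normalize_samples <- function(df) {
  need <- c("sample_id", "individual", "group", "project", "date", "time",
            "cortisol_raw", "specific_gravity", "lcms_method", "age_years",
            "sex", "group_size", "sex_ratio", "sick_flag")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  df$hours <- parse_hours(df$time)
  if (any(df$hours < 0 | df$hours >= 24, na.rm = TRUE))
    stop("clock times must lie in [0, 24)")
  df$sick_flag <- as.logical(df$sick_flag)
  for (col in c("individual", "group", "project", "sex"))
    df[[col]] <- as.character(df[[col]])
  df
}

parse_hours <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    sum(p * c(1, 1 / 60, 1 / 3600)[seq_along(p)])
  }, numeric(1L))
}

#' Prepare a raw sample table for modelling
#'
#' Runs the full preparation chain: exclusion rules
#' ([apply_exclusions()]), the per-individual-year sampling-span filter
#' ([sampling_span_filter()]), and covariate encoding
#' ([encode_covariates()]). When a pedigree is supplied, each sampled
#' individual's dam defines the \code{mother} column (unknown mothers get
#' singleton levels) and individuals absent from the pedigree are appended
#' as founders.
#'
#' @inheritParams apply_exclusions
#' @param pedigree Optional \code{pedigree} object.
#' @param ... Passed to [encode_covariates()].
#' @return A \code{cort_data} data frame with attributes
#'   \code{reference_stats}, \code{exclusion_log} and (when a pedigree was
#'   given) \code{pedigree}.
#' @export
prepare_samples <- function(samples, events, cfg = filter_config(),
                            pedigree = NULL, ...) {
  excl <- apply_exclusions(samples, events, cfg)
  kept <- sampling_span_filter(excl$retained, cfg)
  mother_map <- NULL
  if (!is.null(pedigree)) {
    pedigree <- suppressWarnings(
      ensure_in_pedigree(pedigree, kept$individual, kept$group))
    mother_map <- stats::setNames(pedigree$records$dam,
                                  pedigree$records$individual)
  }
  out <- encode_covariates(kept, cfg, mother_map = mother_map, ...)
  attr(out, "exclusion_log") <- excl$log
  attr(out, "dropped_id_years") <- attr(kept, "dropped_id_years")
  attr(out, "pedigree") <- pedigree
  out
}

#' Write a prepared dataset to CSV
#'
#' One row per retained sample with all encoded columns; the z-scoring
#' reference statistics are written alongside as JSON
#' (\code{<path>.stats.json}) so later encodings can reuse them.
#'
#' @param data A \code{cort_data} object.
#' @param path CSV output path.
#' @export
write_prepared <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  st <- attr(data, "reference_stats")
  if (!is.null(st))
    jsonlite::write_json(st, paste0(path, ".stats.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
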