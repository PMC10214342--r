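test_that("specific-gravity correction follows the dilution formula", {
  expect_equal(sg_correct(10, 1.04, 1.02), 5)
  expect_equal(sg_correct(7, 1.02, 1.02), 7)
  expect_equal(sg_correct(3, 1.01, 1.02), 6)
  ## homogeneous of degree 1 in the raw concentration
  raw <- c(1, 5, 12.3)
  expect_equal(sg_correct(3 * raw, 1.03, 1.02), 3 * sg_correct(raw, 1.03, 1.02))
  ## degenerate SG flagged, invalid population mean fatal
  expect_true(is.na(sg_correct(10, 1.0, 1.02)))
  expect_error(sg_correct(10, 1.02, 0.99), "exceed 1.0")
})

test_that("reproductive states follow the gestation and lactation windows", {
  birth <- as.Date("2010-01-01")
  events <- data.frame(mother = "F1", offspring = "O1", birth_date = birth)
  state <- function(offset) {
    assign_reproductive_state("F1", birth + offset, events)
  }
  expect_equal(state(-100), "pregnant")
  expect_equal(state(-240), "pregnant")   # window is 240 days inclusive
  expect_equal(state(500), "lactating")
  expect_equal(state(1095), "lactating")
  expect_equal(state(1200), "cycling")
  ## pregnancy takes precedence over a still-open lactation window
  events2 <- rbind(events, data.frame(mother = "F1", offspring = "O2",
                                      birth_date = birth + 900))
  expect_equal(assign_reproductive_state("F1", birth + 700, events2),
               "pregnant")
  ## no recorded births -> unassignable
  expect_true(is.na(assign_reproductive_state("F2", birth, events)))
})

test_that("exclusion rules drop the right samples and log counts", {
  birth <- as.Date("2012-03-01")
  events <- data.frame(
    mother = c("F1", "F2", "F3"),
    offspring = c("O1", "O2", "O3"),
    birth_date = c(birth, as.Date("2000-01-01"), as.Date("2004-01-01")),
    mother_death_date = as.Date(c(NA, NA, "2010-06-01")))
  samples <- rbind(
    make_samples(2, individual = "F1", sex = "female", age_years = 18,
                 date = birth - 50),                       # pregnant x2
    make_samples(1, individual = "M1", sick_flag = TRUE),  # sick
    make_samples(1, individual = "O3", sex = "male", age_years = 8,
                 date = as.Date("2010-07-01")),            # after maternal loss
    make_samples(6, individual = "F2", sex = "female", age_years = 25,
                 date = as.Date("2010-06-01")))            # lactating? no: cycling
  res <- apply_exclusions(samples, events)
  expect_equal(nrow(res$retained), 6L)
  expect_equal(res$log[["pregnant"]], 2L)
  expect_equal(res$log[["sick"]], 1L)
  expect_equal(res$log[["maternal_loss"]], 1L)
  expect_equal(res$log[["state_unassignable"]], 0L)
  expect_setequal(unique(res$retained$individual), "F2")

  ## orphan sampled before the mother's death is retained
  before <- apply_exclusions(
    make_samples(1, individual = "O3", sex = "male", age_years = 7,
                 date = as.Date("2009-01-01")), events)
  expect_equal(nrow(before$retained), 1L)

  ## individual orphaned in immaturity keeps all its adult samples
  adult_orphan <- apply_exclusions(
    make_samples(1, individual = "O3", sex = "male", age_years = 14,
                 date = as.Date("2016-07-01")), events)
  expect_equal(nrow(adult_orphan$retained), 1L)

  ## adult female without any event history -> distinct reason code
  unknown <- apply_exclusions(
    make_samples(1, individual = "F9", sex = "female", age_years = 20),
    events)
  expect_equal(nrow(unknown$retained), 0L)
  expect_equal(unknown$log[["state_unassignable"]], 1L)
})

test_that("exclusion outcome does not depend on row order", {
  birth <- as.Date("2012-03-01")
  events <- data.frame(mother = "F1", offspring = "O1", birth_date = birth)
  samples <- rbind(
    make_samples(2, individual = "F1", sex = "female", age_years = 18,
                 date = birth - 10),
    make_samples(3, individual = "M1", sick_flag = c(TRUE, FALSE, FALSE)))
  res1 <- apply_exclusions(samples, events)
  res2 <- apply_exclusions(samples[rev(seq_len(nrow(samples))), ], events)
  expect_setequal(res1$retained$sample_id, res2$retained$sample_id)
  expect_equal(res1$log, res2$log)
})

test_that("sampling-span filter enforces n, span and morning/afternoon", {
  keep <- sampling_span_filter(make_samples(3, time = c(7, 10, 14)))
  expect_equal(nrow(keep), 3L)
  drop_span <- sampling_span_filter(make_samples(3, time = c(7, 8, 12.5)))
  expect_equal(nrow(drop_span), 0L)
  expect_equal(attr(drop_span, "dropped_id_years"), "M1.2010")
  drop_pm <- sampling_span_filter(make_samples(3, time = c(6, 7, 11)))
  expect_equal(nrow(drop_pm), 0L)
  drop_n <- sampling_span_filter(make_samples(2, time = c(7, 14)))
  expect_equal(nrow(drop_n), 0L)
  ## criterion is per individual-year: a good year survives a bad one
  two_years <- rbind(
    make_samples(3, time = c(7, 10, 14), date = as.Date("2010-06-01")),
    make_samples(2, time = c(7, 8), date = as.Date("2011-06-01")))
  keep2 <- sampling_span_filter(two_years)
  expect_equal(unique(format(keep2$date, "%Y")), "2010")
})

test_that("covariate encoding produces the documented transforms", {
  samples <- rbind(
    make_samples(3, time = c("06:45", "10:00", "14:30"),
                 date = as.Date("2010-06-01")),
    make_samples(3, time = c(7, 11, 15), date = as.Date("2011-06-01")))
  samples$individual <- "M1"
  enc <- encode_covariates(samples)
  expect_equal(enc$hours[1], 6.75)
  expect_equal(enc$y, log(enc$cortisol_sg))
  expect_equal(mean(enc$t), 0, tolerance = 1e-12)
  expect_equal(stats::sd(enc$t), 1, tolerance = 1e-12)
  expect_equal(enc$t2, enc$t^2)
  expect_equal(length(unique(enc$id_year)), 2L)
  expect_equal(length(unique(enc$individual)), 1L)
  expect_equal(levels(enc$demographic)[1], "adult male")

  ## quarter-period day of year -> sine ~ 1, cosine ~ 0
  doy91 <- make_samples(1, date = as.Date("2010-01-01") + round(365.25 / 4) - 1)
  enc91 <- encode_covariates(rbind(samples, doy91))
  expect_equal(enc91$season_sin[nrow(enc91)], 1, tolerance = 0.01)
  expect_equal(enc91$season_cos[nrow(enc91)], 0, tolerance = 0.02)
})

test_that("re-encoding with stored reference stats is idempotent", {
  samples <- make_samples(4, time = c(7, 9, 13, 16))
  enc <- encode_covariates(samples)
  stats_ <- attr(enc, "reference_stats")
  enc2 <- encode_covariates(enc, reference_stats = stats_)
  for (col in c("y", "t", "t2", "age_z", "sexratio_z", "groupsize_z"))
    expect_equal(enc2[[col]], enc[[col]])
})

test_that("prepare_samples chains filters, encoding and the pedigree", {
  ped <- as_pedigree(data.frame(
    individual = c("F1", "M0", "M1"),
    dam = c(NA, NA, "F1"),
    sire = c(NA, NA, "M0")))
  samples <- make_samples(3, time = c(7, 10, 14))
  prep <- prepare_samples(samples, no_events(), pedigree = ped)
  expect_s3_class(prep, "cort_data")
  expect_equal(nrow(prep), 3L)
  expect_equal(unique(prep$mother), "F1")
  expect_named(attr(prep, "exclusion_log"))
  ## sampled individual absent from pedigree becomes a founder with a
  ## singleton mother level
  samples2 <- make_samples(3, individual = "ZZ", time = c(7, 10, 14))
  prep2 <- prepare_samples(samples2, no_events(), pedigree = ped)
  expect_equal(unique(prep2$mother), "unk.ZZ")
  expect_true("ZZ" %in% attr(prep2, "pedigree")$records$individual)
})
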