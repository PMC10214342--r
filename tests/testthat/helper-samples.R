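## Minimal sample-table rows for preprocessing tests. Defaults describe an
## unremarkable adult male sample; override fields as needed.
make_samples <- function(n = 1, individual = "M1", group = "g1",
                         project = "p1", date = as.Date("2010-06-01"),
                         time = 9, cortisol_raw = 40,
                         specific_gravity = 1.02, lcms_method = "old",
                         age_years = 20, sex = "male", group_size = 20,
                         sex_ratio = 0.5, sick_flag = FALSE, ...) {
  df <- data.frame(sample_id = paste0("s", seq_len(n)),
                   individual = individual, group = group, project = project,
                   date = date, time = time, cortisol_raw = cortisol_raw,
                   specific_gravity = specific_gravity,
                   lcms_method = lcms_method, age_years = age_years,
                   sex = sex, group_size = group_size, sex_ratio = sex_ratio,
                   sick_flag = sick_flag, stringsAsFactors = FALSE, ...)
  df$sample_id <- paste0("s", seq_len(nrow(df)))
  df
}

no_events <- function() {
  data.frame(mother = character(0), offspring = character(0),
             birth_date = as.Date(character(0)),
             mother_death_date = as.Date(character(0)))
}
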