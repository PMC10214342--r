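## Random pedigree generator used by property tests: each non-founder picks
## a dam and sire uniformly among earlier individuals of the right sex (or
## unknown, with some probability), so arbitrary inbreeding loops can arise.
random_pedigree_df <- function(n, p_unknown = 0.3, n_founders = max(2L, n %/% 4L)) {
  sex <- sample(rep(c("female", "male"), length.out = n))
  id <- sprintf("I%02d", seq_len(n))
  dam <- sire <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i <= n_founders) next
    earlier <- seq_len(i - 1L)
    fem <- id[earlier][sex[earlier] == "female"]
    mal <- id[earlier][sex[earlier] == "male"]
    if (length(fem) > 0L && stats::runif(1) > p_unknown)
      dam[i] <- sample(fem, 1L)
    if (length(mal) > 0L && stats::runif(1) > p_unknown)
      sire[i] <- sample(mal, 1L)
  }
  data.frame(individual = id, dam = dam, sire = sire,
             group = "g1", sex = sex, stringsAsFactors = FALSE)
}

trio_pedigree <- function() {
  as_pedigree(data.frame(
    individual = c("O", "F1", "F2"),
    dam = c("F1", NA, NA),
    sire = c("F2", NA, NA),
    group = "g1",
    sex = c("female", "female", "male")))
}
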