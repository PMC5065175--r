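# Builders for hand-crafted participant records: every dictionary column
# present, screens all-negative by default, so tests flip exactly the
# fields they are about.

make_records <- function(n = 1, age = 40, country = "cameroon",
                         cluster_id = 1L, sex = "male") {
  rec <- data.frame(
    id = sprintf("p%04d", seq_len(n)),
    cluster_id = rep_len(as.integer(cluster_id), n),
    country = country,
    age = rep_len(as.integer(age), n),
    sex = rep_len(sex, n),
    respondent_type = "self",
    stringsAsFactors = FALSE
  )
  for (col in paste0("wg_", c(wg_child_core(), wg_adult_core(), wg_noncore()))) {
    rec[[col]] <- 0L
  }
  rec <- rec[, unique(names(rec))]
  a <- rec$age
  rec$va_denominator <- ifelse(a >= 5, 6, NA_real_)
  rec$fix_and_follow <- ifelse(a < 2, TRUE, NA)
  rec$counts_fingers <- ifelse(a >= 2 & a < 5, TRUE, NA)
  rec$oae_pass_left <- TRUE
  rec$oae_pass_right <- TRUE
  rec$pta_better_ear <- NA_real_
  rec$msi_screen_positive <- FALSE
  rec$msi_exam_grade <- NA_character_
  rec$gtc_seizures_12m <- 0L
  for (j in 1:9) rec[[paste0("phq9_", j)]] <- ifelse(a >= 18, 0L, NA_integer_)
  rec$phq9_administered_full <- ifelse(a >= 18, FALSE, NA)
  rec$single_question_disability <- NA
  for (j in 1:21) rec[[paste0("part_", j)]] <- NA_integer_
  rec
}

# a small synthetic cohort for property tests
small_cohort <- function(country = "cameroon", seed = 1, ...) {
  generate_cohort(cohort_config(country, n_clusters = 4L, cluster_size = 25L,
                                ...), seed = seed)
}
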