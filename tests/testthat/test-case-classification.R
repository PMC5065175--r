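# Composite case definitions and the Category A/B/C decomposition.

test_that("self-report case definition applies threshold and domain count", {
  rec <- make_records(4, age = 40)
  rec$wg_walking <- c(3L, 1L, 1L, 0L)
  rec$wg_seeing <- c(0L, 1L, 1L, 0L)
  rec$wg_hearing <- c(0L, 1L, 0L, 0L)
  expect_equal(is_self_reported_case(rec), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(is_self_reported_case(rec, threshold = "some", min_domains = 2),
               c(FALSE, TRUE, TRUE, FALSE))
  baby <- make_records(1, age = 1)
  expect_false(is_self_reported_case(baby))
})

test_that("non-core responses never make a self-reported case", {
  rec <- make_records(1, age = 40)
  rec$wg_pain <- 3L
  rec$wg_anxiety <- 3L
  expect_false(is_self_reported_case(rec))
  expect_false(is_self_reported_case(rec, threshold = "some"))
})

test_that("clinical case definition is moderate-plus impairment or condition", {
  rec <- screen_cohort(make_records(1, age = 40))
  expect_false(is_clinical_case(rec))

  hear <- make_records(1, age = 40)
  hear$oae_pass_left <- FALSE; hear$oae_pass_right <- FALSE
  hear$pta_better_ear <- 50
  expect_true(is_clinical_case(screen_cohort(hear)))

  msi_mild <- make_records(1, age = 40)
  msi_mild$msi_screen_positive <- TRUE; msi_mild$msi_exam_grade <- "mild"
  expect_false(is_clinical_case(screen_cohort(msi_mild)))

  epi <- make_records(1, age = 40)
  epi$gtc_seizures_12m <- 3L
  expect_true(is_clinical_case(screen_cohort(epi)))

  dep <- make_records(1, age = 40)
  for (j in 1:5) dep[[paste0("phq9_", j)]] <- 3L
  expect_true(is_clinical_case(screen_cohort(dep)))      # composite 15
  expect_false(is_clinical_case(screen_cohort(dep), "severe"))

  infant <- make_records(1, age = 1)
  infant$fix_and_follow <- FALSE
  expect_true(is_clinical_case(screen_cohort(infant)))   # unclassified counts
})

test_that("a record missing one screen is classifiable on the others", {
  rec <- make_records(1, age = 40)
  rec$va_denominator <- NA_real_                 # vision screen missing
  rec$msi_screen_positive <- TRUE; rec$msi_exam_grade <- "severe"
  s <- screen_cohort(rec)
  expect_true(is.na(s$vision_grade))
  expect_true(s$partial_screen)
  expect_true(is_clinical_case(s))
})

test_that("category decomposition by inclusion-exclusion matches the totals", {
  expect_equal(category_decompose(373, 197, 294), c(A = 79L, B = 118L, C = 176L))
  expect_equal(category_decompose(437, 258, 376), c(A = 61L, B = 197L, C = 179L))
  expect_error(category_decompose(100, 10, 20), "inconsistent")
})

test_that("cohort classification partitions cases, matching brute-force set algebra", {
  for (s in 1:4) {
    coh <- small_cohort(seed = s)
    rec <- screen_cohort(coh$records)
    cc <- classify_cohort(rec)
    sr <- is_self_reported_case(rec)
    cl <- is_clinical_case(rec)
    expect_equal(cc$counts[["A"]], sum(sr & !cl))
    expect_equal(cc$counts[["B"]], sum(sr & cl))
    expect_equal(cc$counts[["C"]], sum(cl & !sr))
    expect_equal(cc$counts[["total_cases"]],
                 cc$counts[["A"]] + cc$counts[["B"]] + cc$counts[["C"]])
    expect_equal(cc$counts[["self_reported"]],
                 cc$counts[["A"]] + cc$counts[["B"]])
    expect_equal(cc$counts[["clinical"]],
                 cc$counts[["B"]] + cc$counts[["C"]])
    # categories are a partition
    expect_true(all(cc$status$category %in% c("A", "B", "C", "none")))
  }
})

test_that("an empty cohort classifies to all-zero counts", {
  rec <- screen_cohort(make_records(2, age = 40)[0, ])
  cc <- classify_cohort(rec)
  expect_true(all(cc$counts == 0))
})

test_that("self-report counts are monotone over the threshold lattice", {
  for (s in 1:3) {
    rec <- screen_cohort(small_cohort(seed = s)$records)
    n_some1 <- sum(is_self_reported_case(rec, "some", 1))
    n_some2 <- sum(is_self_reported_case(rec, "some", 2))
    n_alot1 <- sum(is_self_reported_case(rec, "a_lot", 1))
    expect_gte(n_some1, n_some2)
    expect_gte(n_some2, n_alot1)
  }
})

test_that("two-stage strategy matches per-record enumeration and dominates self-report", {
  for (s in 1:3) {
    rec <- screen_cohort(small_cohort(seed = s)$records)
    cc <- classify_cohort(rec)
    st <- cc$status
    for (th in c("some", "a_lot", "cannot_do")) {
      got <- evaluate_two_stage_strategy(rec, th, cc)
      # independent enumeration
      maxlev <- rep(NA_integer_, nrow(rec))
      for (i in seq_len(nrow(rec))) {
        core <- core_domains(rec$age[i])
        if (length(core)) {
          maxlev[i] <- max(unlist(rec[i, paste0("wg_", core)]), 0L)
        }
      }
      screened <- !is.na(maxlev) & maxlev >= report_rank(th)
      identified <- st$self_reported | (st$clinical & screened)
      expect_equal(got$identified, sum(identified))
      expect_equal(got$sensitivity, sum(identified) / cc$counts[["total_cases"]])
      expect_equal(got$clinical_screens_required, sum(screened))
      expect_gte(got$sensitivity,
                 cc$counts[["self_reported"]] / cc$counts[["total_cases"]])
    }
    # lowering the screen threshold never lowers sensitivity
    sens <- vapply(c("cannot_do", "a_lot", "some"), function(th) {
      evaluate_two_stage_strategy(rec, th, cc)$sensitivity
    }, numeric(1))
    expect_true(all(diff(sens) >= 0))
  }
})

test_that("a cascade that screens nobody extra reduces to self-report sensitivity", {
  rec <- make_records(3, age = 40)
  rec$wg_seeing <- c(3L, 0L, 0L)      # one self-reported case
  rec$gtc_seizures_12m <- c(0L, 5L, 0L) # one clinical-only case, reports nothing
  rec <- screen_cohort(rec)
  cc <- classify_cohort(rec)
  got <- evaluate_two_stage_strategy(rec, "cannot_do", cc)
  expect_equal(got$sensitivity,
               cc$counts[["self_reported"]] / cc$counts[["total_cases"]])
})

test_that("single-question comparison counts proportions directly", {
  rec <- screen_cohort(small_cohort("india", seed = 2)$records)
  cc <- classify_cohort(rec)
  got <- compare_single_question(rec, cc)
  yes <- rec$single_question_disability
  expect_equal(got$prevalence, mean(yes))
  expect_equal(got$of_clinical_cases_yes, mean(yes[cc$status$clinical]))
  expect_equal(got$of_self_reported_cases_yes, mean(yes[cc$status$self_reported]))
  expect_equal(got$of_yes_neither,
               mean(!cc$status$clinical[yes] & !cc$status$self_reported[yes]))
  # not collected in the Cameroon arm
  cam <- screen_cohort(small_cohort("cameroon", seed = 1)$records)
  expect_error(compare_single_question(cam), "not collected")
})

test_that("all-no single question yields zero proportions", {
  rec <- make_records(4, age = 40)
  rec$gtc_seizures_12m <- c(3L, 0L, 0L, 0L)
  rec$single_question_disability <- FALSE
  rec <- screen_cohort(rec)
  got <- compare_single_question(rec)
  expect_equal(got$prevalence, 0)
  expect_equal(got$of_clinical_cases_yes, 0)
  expect_true(is.nan(got$of_yes_neither))
})
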