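# Instrument graders: worked examples at the protocol thresholds and
# boundary/monotonicity properties over measurement grids.

test_that("vision grading follows the Snellen thresholds", {
  expect_equal(classify_vision(30, va_denominator = 18), "none")
  expect_equal(classify_vision(30, va_denominator = 24), "moderate")
  expect_equal(classify_vision(30, va_denominator = 120), "severe") # 3/60
  expect_equal(classify_vision(30, va_denominator = 121), "profound")
  expect_equal(classify_vision(1, fix_and_follow = TRUE), "none")
  expect_equal(classify_vision(1, fix_and_follow = FALSE),
               "impaired_unclassified")
  expect_equal(classify_vision(3, counts_fingers = FALSE),
               "impaired_unclassified")
  expect_error(classify_vision(30), "va_denominator")
  expect_error(classify_vision(1), "fix_and_follow")
  expect_error(classify_vision(3), "counts_fingers")
})

test_that("vision grade changes exactly at 6/18, 6/60 and 3/60 and is monotone", {
  eps <- 1e-6
  expect_equal(classify_vision(rep(30, 2), va_denominator = c(18, 18 + eps)),
               c("none", "moderate"))
  expect_equal(classify_vision(rep(30, 2), va_denominator = c(60, 60 + eps)),
               c("moderate", "severe"))
  expect_equal(classify_vision(rep(30, 2), va_denominator = c(120, 120 + eps)),
               c("severe", "profound"))
  dens <- seq(6, 300, by = 0.5)
  ranks <- severity_rank(classify_vision(rep(30, length(dens)),
                                         va_denominator = dens))
  expect_true(all(diff(ranks) >= 0))
})

test_that("hearing grading follows the dBA thresholds by age band", {
  expect_equal(classify_hearing(40, FALSE, FALSE, pta_better_ear = 40), "none")
  expect_equal(classify_hearing(10, FALSE, FALSE, pta_better_ear = 40),
               "moderate")
  expect_equal(classify_hearing(2, TRUE, TRUE), "none")
  expect_equal(classify_hearing(2, FALSE, FALSE), "impaired_unclassified")
  expect_equal(classify_hearing(40, FALSE, FALSE, pta_better_ear = 81),
               "profound")
  expect_equal(classify_hearing(40, TRUE, FALSE), "none") # one ear passes
  expect_error(classify_hearing(40, FALSE, FALSE), "pta_better_ear")
})

test_that("hearing grade changes exactly at 35/41, 61 and 81 dBA and is monotone", {
  eps <- 1e-6
  expect_equal(classify_hearing(rep(10, 2), FALSE, FALSE,
                                pta_better_ear = c(35 - eps, 35)),
               c("none", "moderate"))
  expect_equal(classify_hearing(rep(40, 2), FALSE, FALSE,
                                pta_better_ear = c(41 - eps, 41)),
               c("none", "moderate"))
  for (age in c(10, 40)) {
    expect_equal(classify_hearing(rep(age, 2), FALSE, FALSE,
                                  pta_better_ear = c(61 - eps, 61)),
                 c("moderate", "severe"))
    expect_equal(classify_hearing(rep(age, 2), FALSE, FALSE,
                                  pta_better_ear = c(81 - eps, 81)),
                 c("severe", "profound"))
    grid <- seq(0, 100, by = 0.25)
    ranks <- severity_rank(classify_hearing(rep(age, length(grid)), FALSE,
                                            FALSE, pta_better_ear = grid))
    expect_true(all(diff(ranks) >= 0))
  }
})

test_that("msi grading passes the exam grade through on a positive screen", {
  expect_equal(classify_msi(25, FALSE), "none")
  expect_equal(classify_msi(25, TRUE, "severe"), "severe")
  expect_equal(classify_msi(5, TRUE, "mild"), "mild")
  expect_error(classify_msi(25, TRUE), "exam_grade")
  expect_error(classify_msi(25, TRUE, "profound"), "invalid MSI")
})

test_that("epilepsy screen is three or more seizures in 12 months", {
  expect_equal(classify_epilepsy(c(0, 2, 3, 10)), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(classify_epilepsy(-1))
})

test_that("PHQ-9 composite and bands follow the standard cut-offs", {
  expect_equal(score_phq9(rep(0, 9), 40), data.frame(composite = 0L, band = "none"))
  expect_equal(score_phq9(rep(3, 9), 40), data.frame(composite = 27L, band = "severe"))
  expect_equal(score_phq9(c(1, 1, 2, 0, 0, 0, 0, 0, 0), 40)$composite, 4L)
  expect_equal(score_phq9(c(1, 1, 2, 0, 0, 0, 0, 0, 0), 40)$band, "none")
  # band boundaries
  expect_equal(phq9_band(c(4, 5, 9, 10, 14, 15, 19, 20, 27)),
               c("none", "mild", "mild", "moderate", "moderate",
                 "moderately_severe", "moderately_severe", "severe", "severe"))
  # negative screen: items 4-9 not administered and counted as zero
  expect_equal(score_phq9(c(0, 0, 0, NA, NA, NA, NA, NA, NA), 40)$composite, 0L)
  expect_error(score_phq9(rep(0, 9), 10), "adults")
  expect_error(score_phq9(c(4, rep(0, 8)), 40), "0..3")
})

test_that("Washington Group scoring uses core domains only, with nested sets", {
  r <- stats::setNames(rep("no_difficulty", length(wg_adult_core())),
                       wg_adult_core())
  s <- score_wg(r, age = 40)
  expect_equal(s$max_core_level, "no_difficulty")
  expect_equal(lengths(s$domains_at_or_above), c(some = 0L, a_lot = 0L,
                                                 cannot_do = 0L))
  r["seeing"] <- "a_lot"
  s <- score_wg(r, age = 40)
  expect_equal(s$max_core_level, "a_lot")
  expect_equal(s$domains_at_or_above$a_lot, "seeing")
  # non-core domains never contribute
  s2 <- score_wg(c(stats::setNames(rep("no_difficulty", 10), wg_adult_core()),
                   pain = "cannot_do"), age = 40)
  expect_equal(s2$max_core_level, "no_difficulty")
  # ages 0-1: no tool
  s0 <- score_wg(c(seeing = "cannot_do"), age = 1)
  expect_true(s0$no_tool)
  expect_true(is.na(s0$max_core_level))
})

test_that("score_wg equals a brute-force maximum with nested threshold sets", {
  set.seed(42)
  for (i in 1:25) {
    age <- sample(c(3, 10, 25, 70), 1)
    core <- core_domains(age)
    r <- stats::setNames(sample(0:3, length(core), replace = TRUE), core)
    s <- score_wg(r, age = age)
    expect_equal(s$max_core_level, report_levels()[max(r) + 1])
    sets <- s$domains_at_or_above
    expect_true(all(sets$cannot_do %in% sets$a_lot))
    expect_true(all(sets$a_lot %in% sets$some))
    expect_setequal(sets$a_lot, names(r)[r >= 2])
  }
})

test_that("participation scores span the stated ranges and refuse missing items", {
  expect_equal(participation_score(rep(1, 21), "adult"), 21L)
  expect_equal(participation_score(rep(4, 21), "adult"), 84L)
  expect_equal(participation_score(rep(4, 15), "child"), 60L)
  expect_equal(participation_score(rep("inability_to_perform", 15), "child"), 60L)
  expect_error(participation_score(c(rep(1, 20), NA), "adult"), "missing")
  expect_error(participation_score(rep(1, 15), "adult"), "21")
  expect_error(participation_score(rep(5, 21), "adult"), "1..4")
})
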