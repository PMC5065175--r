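# The cohort generator: determinism, structural contracts, agreement
# with the analytic expectations, and the behaviour of the reporting
# model's under-reporting parameter.

test_that("generation is deterministic and byte-identical under (config, seed)", {
  cfg <- cohort_config("india", n_clusters = 3L, cluster_size = 15L)
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_participants(a$records, f1)
  write_participants(b$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  c_ <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a$records, c_$records))
})

test_that("full response yields exactly clusters x size records", {
  coh <- generate_cohort(cohort_config("cameroon", n_clusters = 2L,
                                       cluster_size = 10L,
                                       response_rate = 1), seed = 1)
  expect_equal(nrow(coh$records), 20L)
  expect_equal(sort(unique(coh$records$cluster_id)), 1:2)
  # truth rows align with records
  expect_identical(coh$records$id, coh$truth$id)
})

test_that("invalid configurations are rejected before generation", {
  expect_error(cohort_config("cameroon", nonsense = 1), "unknown config")
  bad <- cohort_config("cameroon")
  bad$impairment$vision$ladder <- c(mild = 0.9, moderate = 0.9,
                                    severe = 0, profound = 0)
  expect_error(generate_cohort(bad, 1), "sum to 1")
  bad2 <- cohort_config("cameroon")
  bad2$response_rate <- 0
  expect_error(generate_cohort(bad2, 1))
})

test_that("measurements are consistent with the latent grades", {
  coh <- small_cohort(seed = 3, response_rate = 1)
  rec <- screen_cohort(coh$records)
  tr <- coh$truth
  # moderate-or-worse latent sensory/physical state is recovered by the
  # classifiers; mild latent sensory states classify as unimpaired
  lat_rank <- function(x) match(x, severity_grades()) - 1L
  adult5 <- rec$age >= 5
  expect_equal(severity_at_least(rec$vision_grade, "moderate"),
               lat_rank(tr$vision_latent) >= 2)
  expect_equal(severity_at_least(rec$hearing_grade, "moderate"),
               lat_rank(tr$hearing_latent) >= 2)
  expect_equal(rec$msi_grade, tr$msi_latent)
  expect_equal(severity_rank(rec$vision_grade)[adult5],
               ifelse(lat_rank(tr$vision_latent) >= 2,
                      lat_rank(tr$vision_latent), 0)[adult5])
})

test_that("identity reporting gives perfect agreement on matched domains", {
  cfg <- cohort_config("cameroon", n_clusters = 3L, cluster_size = 30L,
                       age_band_probs = c(0, 0, 0.25, 0.25, 0.2, 0.1,
                                          0.1, 0.05, 0.05),
                       epilepsy = list(base = -30, age_slope = 0),
                       depression = list(base = -30, age_slope = 0,
                                         noise_sd = 0.1,
                                         item_cuts = c(2, 4, 6)),
                       reporting = list(identity = TRUE))
  coh <- generate_cohort(cfg, seed = 4)
  cc <- classify_cohort(screen_cohort(coh$records))
  expect_equal(cc$counts[["A"]], 0)
  expect_equal(cc$counts[["C"]], 0)
})

test_that("analytic expectations have the stated degenerate limits", {
  off <- list(base = -50, age_slope = 0, ladder = c(mild = 0, moderate = 1,
                                                    severe = 0, profound = 0))
  flat <- function(p) list(base = stats::qlogis(p), age_slope = 0,
                           ladder = c(mild = 0, moderate = 1, severe = 0,
                                      profound = 0))
  none <- cohort_config("cameroon",
                        impairment = list(vision = off, hearing = off, msi = off),
                        epilepsy = list(base = -50, age_slope = 0),
                        depression = list(base = -50, age_slope = 0,
                                          noise_sd = 0.1, item_cuts = c(2, 4, 6)),
                        frailty_sd = 0, cluster_sd = 0)
  ae <- analytic_expectations(none)
  expect_equal(ae$vision, 0, tolerance = 1e-12)
  expect_equal(ae$clinical, 0, tolerance = 1e-12)
  expect_equal(ae$epilepsy, 0, tolerance = 1e-12)

  one <- cohort_config("cameroon",
                       impairment = list(vision = flat(0.1), hearing = off,
                                         msi = off),
                       epilepsy = list(base = -50, age_slope = 0),
                       depression = list(base = -50, age_slope = 0,
                                         noise_sd = 0.1, item_cuts = c(2, 4, 6)),
                       frailty_sd = 0, cluster_sd = 0)
  expect_equal(analytic_expectations(one)$clinical, 0.1, tolerance = 1e-9)

  two <- cohort_config("cameroon",
                       impairment = list(vision = flat(0.1), hearing = flat(0.1),
                                         msi = off),
                       epilepsy = list(base = -50, age_slope = 0),
                       depression = list(base = -50, age_slope = 0,
                                         noise_sd = 0.1, item_cuts = c(2, 4, 6)),
                       frailty_sd = 0, cluster_sd = 0)
  expect_equal(analytic_expectations(two)$clinical, 1 - 0.9^2, tolerance = 1e-9)
})

test_that("generated cohorts recover the analytic expectations", {
  cfg <- cohort_config("cameroon")
  ae <- analytic_expectations(cfg)
  reps <- 8
  got <- sapply(200 + seq_len(reps), function(s) {
    rec <- screen_cohort(generate_cohort(cfg, seed = s)$records)
    cc <- classify_cohort(rec)
    c(clinical = cc$counts[["clinical"]] / nrow(rec),
      self = cc$counts[["self_reported"]] / nrow(rec),
      overall = cc$counts[["total_cases"]] / nrow(rec))
  })
  for (q in c("clinical", "self", "overall")) {
    target <- switch(q, clinical = ae$clinical, self = ae$self_reported,
                     overall = ae$overall)
    se <- stats::sd(got[q, ]) / sqrt(reps)
    expect_lt(abs(mean(got[q, ]) - target), 4 * se + 0.002)
  }
})

test_that("raising sensory under-reporting raises the clinical-only share", {
  share_c <- vapply(c(0, 0.45, 0.9), function(ur) {
    cfg <- cohort_config("cameroon",
                         reporting = list(underreport = c(vision = ur,
                                                          hearing = ur,
                                                          msi = 0)))
    shares <- vapply(1:3, function(s) {
      rec <- screen_cohort(generate_cohort(cfg, seed = s)$records)
      cc <- classify_cohort(rec)
      sens <- severity_at_least(rec$vision_grade, "moderate") |
        severity_at_least(rec$hearing_grade, "moderate")
      idx <- sens & cc$status$clinical
      mean(cc$status$category[idx] == "C")
    }, numeric(1))
    mean(shares)
  }, numeric(1))
  expect_true(all(diff(share_c) > 0))
})

test_that("the default design induces a cluster design effect near the assumed 1.4", {
  deffs <- vapply(1:12, function(s) {
    rec <- screen_cohort(generate_cohort(cohort_config("cameroon"),
                                         seed = 1000 + s)$records)
    cc <- classify_cohort(rec)
    estimate_prevalence(cc$status$category != "none", rec$cluster_id)$deff
  }, numeric(1))
  expect_gt(mean(deffs), 1.1)
  expect_lt(mean(deffs), 1.7)
})
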