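# Synthetic survey cohorts. The generator emulates the structure of a
# two-country, all-age, two-stage cluster disability survey: 51 clusters
# of 80 enumerated persons, ~87-88% response, a banded age/sex structure,
# latent impairment severities per clinical domain with steep age
# gradients, measurement values drawn inside the latent grade's band (so
# the instrument classifiers recover the grade), an ordered-categorical
# reporting model linking latent severity to reported difficulty with
# domain-specific under-reporting (the "hierarchy of disability"),
# participation scores increasing with severity and reporting, and a
# cluster random effect inducing a design effect around 1.4.

#' Configuration for a synthetic survey cohort
#'
#' Returns the full generative parameter set. Defaults are calibrated so
#' that, in expectation, the cohort reproduces the magnitudes reported by
#' all-age disability surveys in the two settings: overall disability
#' prevalence around 10--12%, clinical prevalence (8--10%) exceeding
#' significant self-report prevalence (5--7%), a Category B overlap of a
#' third to a half of cases, and a design effect near 1.4. See the
#' methods vignette for the calibration rationale.
#'
#' @param country `"cameroon"` or `"india"`; selects the age/sex
#'   structure, response rate and condition prevalences of that setting.
#' @param ... Named overrides for any top-level config entry (e.g.
#'   `n_clusters = 2`, `response_rate = 1`) or a whole sub-list (e.g.
#'   `reporting = ...`).
#' @return Object of class `cohort_config` (a named list).
#' @export
#' @examples
#' cfg <- cohort_config("cameroon", n_clusters = 2, cluster_size = 10)
cohort_config <- function(country = c("cameroon", "india"), ...) {
  country <- match.arg(country)
  cam <- country == "cameroon"
  cfg <- list(
    country = country,
    n_clusters = 51L,
    cluster_size = 80L,
    response_rate = if (cam) 0.87 else 0.88,
    # proportions per ten-year age band 0-9 ... 80-89
    age_band_probs = if (cam) {
      c(0.35, 0.23, 0.11, 0.07, 0.06, 0.06, 0.05, 0.04, 0.03)
    } else {
      c(0.19, 0.19, 0.18, 0.14, 0.11, 0.09, 0.07, 0.02, 0.01)
    },
    prop_female = if (cam) 0.59 else 0.52,
    # latent impairment model per clinical domain: P(any impairment) =
    # plogis(base + age_slope * age + cluster effect + frailty); severity
    # ladder conditional on impairment (msi has no profound level)
    impairment = list(
      vision = list(base = if (cam) -8.69 else -7.96, age_slope = 0.095,
                    ladder = c(mild = 0.30, moderate = 0.46,
                               severe = 0.10, profound = 0.14)),
      hearing = list(base = if (cam) -7.58 else -7.28, age_slope = 0.090,
                     ladder = c(mild = 0.32, moderate = 0.47,
                                severe = 0.12, profound = 0.09)),
      msi = list(base = if (cam) -6.47 else -6.59, age_slope = 0.070,
                 ladder = c(mild = 0.33, moderate = 0.50,
                            severe = 0.17, profound = 0))
    ),
    epilepsy = list(base = if (cam) -4.96 else -4.0, age_slope = 0),
    # PHQ-9 item model (adults): person liability eta ~ N(base +
    # age_slope*age + 0.5*frailty, noise_sd); each item is an ordered
    # draw with cumulative cut-offs item_cuts
    depression = list(base = if (cam) -1.88 else -1.32, age_slope = 0.012,
                      noise_sd = 2, item_cuts = c(2, 4, 6)),
    frailty_sd = if (cam) 1.15 else 1.4,
    cluster_sd = if (cam) 0.50 else 0.45,
    # ordered-categorical reporting model: latent w = alpha +
    # domain offset + age_coef*age + frailty_coef*frailty +
    # cluster_coef*cluster effect + severity effect + logistic noise,
    # cut at cuts into no difficulty / some / a lot / cannot do.
    # Severity effect: grade_coef * latent grade rank * (1 - underreport)
    # in the matched domain; msi spreads over walking/upper body/fine
    # motor with the given weights.
    reporting = list(
      cuts = c(-0.8, 2.9, 6.0),
      alpha = if (cam) -4.1 else -4.5,
      domain_offsets = c(walking = 0.4, remembering = 0.4, pain = 2.2,
                         fatigue = 1.8, anxiety = 1.2, depression = 1.0),
      age_coef = 0.03,
      frailty_coef = 0.3,
      cluster_coef = 0.5,
      grade_coef = if (cam) 2.2 else 2.4,
      underreport = if (cam) c(vision = 0.5, hearing = 0.5, msi = 0) else
        c(vision = 0.08, hearing = 0.08, msi = 0),
      msi_domain_weights = c(walking = 1, upper_body = 0.5, fine_motor = 0.5),
      dep_coef = 3, epi_coef = 0.5,
      dep_domains = c("remembering", "concentrating", "understanding",
                      "self_care"),
      epi_domains = c("understanding", "learning", "remembering"),
      identity = FALSE
    ),
    # participation items for cases: item latent = base +
    # adult_offset*(age>=17) + sev_coef*max severity rank +
    # report_coef*self-reported + person effect + logistic noise,
    # cut at cuts into scores 1..4
    participation = list(cuts = c(0, 2, 4), base = -3.7, adult_offset = 1.27,
                         sev_coef = 0.93, report_coef = 0.87,
                         person_sd = 1.1),
    # direct single disability question (administered in India)
    single_question = list(enabled = !cam, base = -5.3, grade_coef = 1.2,
                           report_coef = 2.6),
    # synthetic census frame for PPS cluster selection
    census = list(n_units = 150L, mean_log = 6.4, sd_log = 0.5)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @keywords internal
validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_clusters >= 1, cfg$cluster_size >= 1,
            cfg$response_rate > 0, cfg$response_rate <= 1,
            length(cfg$age_band_probs) == 9,
            all(cfg$age_band_probs >= 0),
            abs(sum(cfg$age_band_probs) - 1) < 1e-8,
            cfg$prop_female >= 0, cfg$prop_female <= 1,
            cfg$frailty_sd >= 0, cfg$cluster_sd >= 0)
  for (d in names(cfg$impairment)) {
    lad <- cfg$impairment[[d]]$ladder
    if (any(lad < 0) || abs(sum(lad) - 1) > 1e-8) {
      stop("severity ladder for ", d, " must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

# severity rank helper for latent grades: none=0 ... profound=4
.latent_rank <- function(x) match(x, severity_grades()) - 1L

# draw latent grades for one domain: plogis liability, ladder conditional
.draw_latent_grades <- function(par, age, re) {
  n <- length(age)
  p <- stats::plogis(par$base + par$age_slope * age + re)
  impaired <- stats::runif(n) < p
  grade <- rep("none", n)
  if (any(impaired)) {
    cum <- cumsum(par$ladder)
    u <- stats::runif(sum(impaired))
    grade[impaired] <- severity_grades()[findInterval(u, cum,
                                                      left.open = TRUE) + 2L]
  }
  grade
}

#' Generate a synthetic survey cohort
#'
#' Draws a full participant table plus the latent truth that produced it.
#' Cluster labels come from a PPS selection over a synthetic census
#' frame, one compact segment is chosen per cluster, ages and sexes
#' follow the configured band structure, instrument measurements are
#' drawn inside the latent grade's band, Washington Group responses come
#' from the ordered reporting model, participation items are generated
#' for cases (ages 5+), and enumerated persons are dropped independently
#' at one minus the response rate. The output is a deterministic function
#' of `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Master integer seed; independent substreams are derived
#'   for cluster selection, segment choice and person-level generation.
#' @return Object of class `synthetic_cohort`: list with `records` (raw
#'   participant data frame, see [data_dictionary()]), `truth` (latent
#'   state per respondent), and `clusters` (selected census units with
#'   segment counts and choices).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config("cameroon", n_clusters = 2,
#'                                      cluster_size = 10,
#'                                      response_rate = 1), seed = 1)
#' nrow(coh$records)
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  cfg <- config
  set.seed(seed)
  streams <- sample.int(.Machine$integer.max - 1L, 4L)

  # census frame and PPS cluster selection
  set.seed(streams[1])
  pops <- pmax(cfg$cluster_size,
               round(stats::rlnorm(cfg$census$n_units, cfg$census$mean_log,
                                   cfg$census$sd_log)))
  units <- data.frame(name = sprintf("unit_%03d", seq_len(cfg$census$n_units)),
                      population = pops, stringsAsFactors = FALSE)
  selected <- pps_select_clusters(units, cfg$n_clusters, seed = streams[2])

  # one compact segment per selected cluster
  set.seed(streams[3])
  segs <- lapply(selected$population, compact_segment_sample,
                 segment_size = cfg$cluster_size)
  clusters <- data.frame(cluster_id = seq_len(cfg$n_clusters),
                         census_unit = selected$name,
                         population = selected$population,
                         n_segments = vapply(segs, `[[`, 1L, "n_segments"),
                         segment = vapply(segs, `[[`, 1L, "segment"),
                         stringsAsFactors = FALSE)

  # person-level generation
  set.seed(streams[4])
  n <- cfg$n_clusters * cfg$cluster_size
  cluster_id <- rep(seq_len(cfg$n_clusters), each = cfg$cluster_size)
  band <- sample.int(9L, n, replace = TRUE, prob = cfg$age_band_probs)
  age <- (band - 1L) * 10L + sample.int(10L, n, replace = TRUE) - 1L
  sex <- ifelse(stats::runif(n) < cfg$prop_female, "female", "male")
  u <- stats::rnorm(cfg$n_clusters, 0, cfg$cluster_sd)
  u_i <- u[cluster_id]
  f <- stats::rnorm(n, 0, cfg$frailty_sd)

  lat <- lapply(cfg$impairment, .draw_latent_grades, age = age, re = u_i + f)
  rv <- .latent_rank(lat$vision)
  rh <- .latent_rank(lat$hearing)
  rm_ <- .latent_rank(lat$msi)

  # --- measurements inside the latent grade's band ---
  va <- rep(NA_real_, n)
  fixfollow <- rep(NA, n)
  fingers <- rep(NA, n)
  older <- age >= 5
  dec_lo <- c(VA_NONE, VA_NONE, VA_MODERATE, VA_SEVERE, 0.01)[rv + 1L]
  dec_hi <- c(1.0, 0.5, VA_NONE, VA_MODERATE, VA_SEVERE)[rv + 1L]
  dec <- dec_lo + stats::runif(n) * (dec_hi - dec_lo) * 0.999
  # record the chart reading to two decimals, kept inside the grade band
  den_lo <- c(6, 6, 18.01, 60.01, 120.01)[rv + 1L]
  den_hi <- c(18, 18, 60, 120, 600)[rv + 1L]
  va[older] <- pmin(pmax(round(6 / dec[older], 2), den_lo[older]),
                    den_hi[older])
  fixfollow[age < 2] <- rv[age < 2] < 2L
  fingers[age >= 2 & age < 5] <- rv[age >= 2 & age < 5] < 2L

  oae_fail <- rh >= 2L
  oae_l <- !oae_fail
  oae_r <- !oae_fail
  pta <- rep(NA_real_, n)
  need_pta <- oae_fail & age >= 4
  lo <- ifelse(age < 18, 35, 41)
  pta_lo <- ifelse(rh == 2L, lo, ifelse(rh == 3L, 61, 81))
  pta_hi <- ifelse(rh == 2L, 60.9, ifelse(rh == 3L, 80.9, 95))
  pta[need_pta] <- round(pta_lo[need_pta] +
    stats::runif(sum(need_pta)) * (pta_hi[need_pta] - pta_lo[need_pta]), 1)

  msi_screen <- rm_ >= 1L
  msi_exam <- ifelse(msi_screen, lat$msi, NA_character_)

  p_epi <- stats::plogis(cfg$epilepsy$base + cfg$epilepsy$age_slope * age)
  epi <- stats::runif(n) < p_epi
  gtc <- as.integer(ifelse(epi, 3L + stats::rpois(n, 2),
                           stats::rbinom(n, 2L, 0.03)))

  # PHQ-9 (adults)
  adult <- age >= 18
  dep_eta <- rep(NA_real_, n)
  phq <- matrix(NA_integer_, n, 9L)
  adm_full <- rep(NA, n)
  if (any(adult)) {
    na <- sum(adult)
    eta <- cfg$depression$base + cfg$depression$age_slope * age[adult] +
      0.5 * f[adult] + stats::rnorm(na, 0, cfg$depression$noise_sd)
    dep_eta[adult] <- eta
    e <- matrix(stats::rlogis(na * 9L), na, 9L)
    w <- eta + e
    cuts <- cfg$depression$item_cuts
    items <- (w > cuts[1]) + (w > cuts[2]) + (w > cuts[3])
    full <- rowSums(items[, 1:3, drop = FALSE] > 0) > 0
    items[!full, 4:9] <- NA_integer_
    phq[adult, ] <- items
    adm_full[adult] <- full
  }
  phq_score <- rep(NA_integer_, n)
  if (any(adult)) {
    tmp <- phq[adult, , drop = FALSE]
    tmp[is.na(tmp)] <- 0L
    phq_score[adult] <- as.integer(rowSums(tmp))
  }
  dep_case <- !is.na(phq_score) & phq_score >= 15

  # --- Washington Group reporting model ---
  rp <- cfg$reporting
  doms <- wg_all_domains()
  wg <- matrix(NA_integer_, n, length(doms), dimnames = list(NULL, doms))
  matched_rank <- list(seeing = rv, hearing = rh)
  if (rp$identity) {
    for (d in doms) wg[, d] <- 0L
    wg[, "seeing"] <- ifelse(rv >= 2L, 2L, 0L)
    wg[, "hearing"] <- ifelse(rh >= 2L, 2L, 0L)
    wg[, "walking"] <- ifelse(rm_ >= 2L, 2L, 0L)
  } else {
    off <- function(d) if (d %in% names(rp$domain_offsets)) rp$domain_offsets[[d]] else 0
    base_lin <- rp$alpha + rp$age_coef * age + rp$frailty_coef * f +
      rp$cluster_coef * u_i
    for (d in doms) {
      lin <- base_lin + off(d)
      if (d == "seeing") {
        lin <- lin + rp$grade_coef * (1 - rp$underreport[["vision"]]) * rv
      } else if (d == "hearing") {
        lin <- lin + rp$grade_coef * (1 - rp$underreport[["hearing"]]) * rh
      } else if (d %in% names(rp$msi_domain_weights)) {
        lin <- lin + rp$grade_coef * (1 - rp$underreport[["msi"]]) *
          rp$msi_domain_weights[[d]] * rm_
      }
      if (d %in% rp$dep_domains) lin <- lin + rp$dep_coef * dep_case
      if (d %in% rp$epi_domains) lin <- lin + rp$epi_coef * epi
      w <- lin + stats::rlogis(n)
      wg[, d] <- (w > rp$cuts[1]) + (w > rp$cuts[2]) + (w > rp$cuts[3])
    }
  }
  # age-appropriate domain sets; ages 0-1 have no tool
  child <- age >= 2 & age < 18
  for (d in doms) {
    applicable <- (child & d %in% c(wg_child_core(), wg_noncore())) |
      (adult & d %in% c(wg_adult_core(), wg_noncore()))
    wg[!applicable, d] <- NA_integer_
  }

  records <- data.frame(
    id = sprintf("%s-%02d-%03d", substr(cfg$country, 1, 2), cluster_id,
                 stats::ave(cluster_id, cluster_id, FUN = seq_along)),
    cluster_id = cluster_id, country = cfg$country, age = age, sex = sex,
    respondent_type = ifelse(age < 8, "caregiver", "self"),
    stringsAsFactors = FALSE
  )
  for (d in doms) records[[paste0("wg_", d)]] <- wg[, d]
  records$va_denominator <- va
  records$fix_and_follow <- fixfollow
  records$counts_fingers <- fingers
  records$oae_pass_left <- oae_l
  records$oae_pass_right <- oae_r
  records$pta_better_ear <- pta
  records$msi_screen_positive <- msi_screen
  records$msi_exam_grade <- msi_exam
  records$gtc_seizures_12m <- gtc
  for (j in 1:9) records[[paste0("phq9_", j)]] <- phq[, j]
  records$phq9_administered_full <- adm_full

  # case status drives the single question and participation items
  screened <- screen_cohort(records)
  sr <- is_self_reported_case(screened)
  cl <- is_clinical_case(screened)
  max_rank <- pmax(severity_rank(screened$vision_grade),
                   severity_rank(screened$hearing_grade),
                   severity_rank(screened$msi_grade), na.rm = FALSE)
  max_rank <- pmax(max_rank, 3L * epi, 3L * dep_case)

  sq <- rep(NA, n)
  if (isTRUE(cfg$single_question$enabled)) {
    qp <- cfg$single_question
    p_yes <- stats::plogis(qp$base + qp$grade_coef * max_rank +
                             qp$report_coef * sr)
    sq <- stats::runif(n) < p_yes
  }
  records$single_question_disability <- sq

  part <- matrix(NA_integer_, n, 21L)
  pc <- cfg$participation
  is_case <- (sr | cl) & age >= 5
  if (any(is_case)) {
    lam <- pc$base + pc$adult_offset * (age >= 17) + pc$sev_coef * max_rank +
      pc$report_coef * sr + stats::rnorm(n, 0, pc$person_sd)
    n_items <- ifelse(age >= 17, 21L, 15L)
    for (j in 1:21) {
      fill <- is_case & j <= n_items
      if (any(fill)) {
        w <- lam[fill] + stats::rlogis(sum(fill))
        part[fill, j] <- 1L + (w > pc$cuts[1]) + (w > pc$cuts[2]) +
          (w > pc$cuts[3])
      }
    }
  }
  for (j in 1:21) records[[paste0("part_", j)]] <- part[, j]

  truth <- data.frame(id = records$id, cluster_id = cluster_id,
                      vision_latent = lat$vision, hearing_latent = lat$hearing,
                      msi_latent = lat$msi, epilepsy_true = epi,
                      dep_eta = dep_eta, frailty = f, cluster_effect = u_i,
                      stringsAsFactors = FALSE)

  keep <- stats::runif(n) < cfg$response_rate
  structure(list(records = records[keep, , drop = FALSE],
                 truth = truth[keep, , drop = FALSE],
                 clusters = clusters),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d respondents in %d clusters (%s)\n",
              nrow(x$records), length(unique(x$records$cluster_id)),
              x$records$country[1]))
  invisible(x)
}

# P(PHQ-9 screened composite >= threshold | eta) for a grid of eta
# values, by convolving the 9 ordered-item pmfs and accounting for the
# three-item screen (items 4-9 count 0 when items 1-3 are all zero).
.phq9_case_prob <- function(eta, cuts, threshold = 15) {
  vapply(eta, function(e) {
    p_ge <- stats::plogis(e - cuts)
    pmf <- c(1 - p_ge[1], p_ge[1] - p_ge[2], p_ge[2] - p_ge[3], p_ge[3])
    conv <- function(a, b) {
      out <- numeric(length(a) + length(b) - 1)
      for (i in seq_along(a)) {
        out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
      }
      out
    }
    s3 <- Reduce(conv, rep(list(pmf), 3))
    s6 <- Reduce(conv, rep(list(pmf), 6))
    # total >= threshold and at least one of the first three items > 0
    sum(vapply(seq_along(s3)[-1] - 1, function(v) {
      tail_idx <- max(threshold - v, 0) + 1
      s3[v + 1] * sum(s6[min(tail_idx, length(s6)):length(s6)]) *
        (tail_idx <= length(s6))
    }, numeric(1)))
  }, numeric(1))
}

#' Analytic prevalence expectations for a cohort configuration
#'
#' Marginalises the generative model over the age distribution and the
#' person- and cluster-level random effects (by quadrature) to give
#' closed-form expected prevalences per instrument and per case
#' definition, without simulation. Exact for zero random-effect SDs;
#' quadrature-accurate otherwise.
#'
#' @param config A [cohort_config()].
#' @param n_nodes Number of quadrature nodes per random effect.
#' @return Named list of expected proportions: `vision`, `hearing`,
#'   `msi` (moderate-or-greater, including unclassified infant-screen
#'   impairment), `epilepsy`, `depression`, `clinical`, `self_reported`,
#'   `overall`.
#' @export
analytic_expectations <- function(config, n_nodes = 21L) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  ages <- 0:89
  w_age <- rep(cfg$age_band_probs / 10, each = 10)

  gauss_nodes <- function(sd, k) {
    if (sd == 0) return(list(x = 0, w = 1))
    x <- seq(-5, 5, length.out = k)
    w <- stats::dnorm(x)
    list(x = x * sd, w = w / sum(w))
  }
  fq <- gauss_nodes(cfg$frailty_sd, n_nodes)
  uq <- gauss_nodes(cfg$cluster_sd, max(7L, n_nodes %/% 2L))

  # cells: age x frailty x cluster effect
  grid <- expand.grid(age = ages, fi = seq_along(fq$x), ui = seq_along(uq$x))
  a <- grid$age
  f <- fq$x[grid$fi]
  u <- uq$x[grid$ui]
  w <- w_age[a + 1] * fq$w[grid$fi] * uq$w[grid$ui]

  p_any <- lapply(cfg$impairment, function(par) {
    stats::plogis(par$base + par$age_slope * a + u + f)
  })
  modplus_frac <- vapply(cfg$impairment, function(par) {
    sum(par$ladder[c("moderate", "severe", "profound")])
  }, numeric(1))
  p_mod <- Map(function(p, fr) p * fr, p_any, as.list(modplus_frac))

  p_epi <- stats::plogis(cfg$epilepsy$base + cfg$epilepsy$age_slope * a)

  # depression: integrate the person noise on eta per (age, frailty)
  adult <- a >= 18
  p_dep <- numeric(length(a))
  if (any(adult)) {
    zq <- gauss_nodes(cfg$depression$noise_sd, n_nodes)
    eta_grid <- seq(-12, 18, by = 0.25)
    case_tab <- .phq9_case_prob(eta_grid, cfg$depression$item_cuts)
    mu <- cfg$depression$base + cfg$depression$age_slope * a[adult] +
      0.5 * f[adult]
    acc <- numeric(sum(adult))
    for (j in seq_along(zq$x)) {
      acc <- acc + zq$w[j] *
        stats::approx(eta_grid, case_tab, xout = mu + zq$x[j], rule = 2)$y
    }
    p_dep[adult] <- acc
  }

  p_no_clin <- (1 - p_mod$vision) * (1 - p_mod$hearing) * (1 - p_mod$msi) *
    (1 - p_epi) * (1 - p_dep)
  clinical <- sum(w * (1 - p_no_clin))

  # reporting: P(level < a_lot | domain, cell), marginalised over the
  # latent grades. The three msi-matched domains share one latent grade
  # and are marginalised jointly; seeing/hearing each carry their own.
  rp <- cfg$reporting
  off <- function(d) if (d %in% names(rp$domain_offsets)) rp$domain_offsets[[d]] else 0
  base_lin <- rp$alpha + rp$age_coef * a + rp$frailty_coef * f +
    rp$cluster_coef * u
  grade_probs <- function(par, p) {
    # columns: none, mild, moderate, severe, profound
    cbind(1 - p, outer(p, par$ladder))
  }
  gp <- Map(grade_probs, cfg$impairment, p_any)
  core_mask <- function(d) {
    (a >= 2 & a < 18 & d %in% wg_child_core()) | (a >= 18 & d %in% wg_adult_core())
  }
  doms <- union(wg_child_core(), wg_adult_core())
  flag_eff <- function(d, dep, epi) {
    (d %in% rp$dep_domains) * rp$dep_coef * dep +
      (d %in% rp$epi_domains) * rp$epi_coef * epi
  }
  # P(every core domain below `cut` | cell, dep flag, epi flag);
  # clinical_free additionally conditions all latent grades on < moderate
  p_all_below <- function(cut, dep, epi, clinical_free = FALSE) {
    restrict <- function(gpm) {
      if (clinical_free) gpm[, 1:2, drop = FALSE] / rowSums(gpm[, 1:2, drop = FALSE])
      else gpm
    }
    sensory <- function(domain, gpm, ur) {
      gpm <- restrict(gpm)
      eff <- rp$grade_coef * (1 - ur) * (seq_len(ncol(gpm)) - 1)
      lin0 <- base_lin + off(domain) + flag_eff(domain, dep, epi)
      pb <- 0
      for (g in seq_len(ncol(gpm))) {
        pb <- pb + gpm[, g] * (1 - stats::plogis(lin0 + eff[g] - cut))
      }
      ifelse(core_mask(domain), pb, 1)
    }
    out <- sensory("seeing", gp$vision, rp$underreport[["vision"]]) *
      sensory("hearing", gp$hearing, rp$underreport[["hearing"]])
    # msi group: product over applicable domains within each grade
    gpm <- restrict(gp$msi)
    msi_acc <- 0
    for (g in seq_len(ncol(gpm))) {
      prod_g <- rep(1, length(a))
      for (d in names(rp$msi_domain_weights)) {
        eff_g <- rp$grade_coef * (1 - rp$underreport[["msi"]]) *
          rp$msi_domain_weights[[d]] * (g - 1)
        lin0 <- base_lin + off(d) + flag_eff(d, dep, epi)
        pb <- 1 - stats::plogis(lin0 + eff_g - cut)
        prod_g <- prod_g * ifelse(core_mask(d), pb, 1)
      }
      msi_acc <- msi_acc + gpm[, g] * prod_g
    }
    out <- out * msi_acc
    # remaining (unmatched) core domains
    rest <- setdiff(doms, c("seeing", "hearing", names(rp$msi_domain_weights)))
    for (d in rest) {
      lin0 <- base_lin + off(d) + flag_eff(d, dep, epi)
      pb <- 1 - stats::plogis(lin0 - cut)
      out <- out * ifelse(core_mask(d), pb, 1)
    }
    out
  }
  p_no_sr <- 0
  for (dep in 0:1) for (epi in 0:1) {
    cw <- (dep * p_dep + (1 - dep) * (1 - p_dep)) *
      (epi * p_epi + (1 - epi) * (1 - p_epi))
    p_no_sr <- p_no_sr + cw * p_all_below(rp$cuts[2], dep, epi)
  }
  self_reported <- sum(w * (1 - p_no_sr))

  # overall: jointly not clinical and not self-reported (no epilepsy or
  # depression; all grades below moderate, reporting conditioned on that)
  p_none <- (1 - p_mod$vision) * (1 - p_mod$hearing) * (1 - p_mod$msi) *
    (1 - p_epi) * (1 - p_dep) *
    p_all_below(rp$cuts[2], 0, 0, clinical_free = TRUE)
  overall <- sum(w * (1 - p_none))

  list(vision = sum(w * p_mod$vision), hearing = sum(w * p_mod$hearing),
       msi = sum(w * p_mod$msi), epilepsy = sum(w * p_epi),
       depression = sum(w * p_dep), clinical = clinical,
       self_reported = self_reported, overall = overall)
}
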