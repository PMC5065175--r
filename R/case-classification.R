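# Composite case definitions. A participant is a "clinical" case on any
# moderate-or-greater clinical impairment (vision, hearing, MSI) or a
# severe potentially disabling health condition (epilepsy, depression),
# and a "self-reported" case on significant reported functional
# limitation ("a lot of difficulty" or "cannot do") in any core domain.
# Cases decompose into Category A (self-report only), B (both) and C
# (clinical only).

#' Apply the clinical screens across a cohort
#'
#' Computes graded instrument results for every participant record from
#' the raw measurement columns, tolerating missing screens: a record
#' missing the inputs of one screen receives `NA` for that grade and is
#' flagged as partially screened, remaining classifiable on the other
#' screens.
#'
#' @param records Participant data frame (see [data_dictionary()]).
#' @return `records` with columns `vision_grade`, `hearing_grade`,
#'   `msi_grade`, `epilepsy_case`, `phq9_composite`, `phq9_band`, and
#'   logical `partial_screen` added (or refreshed).
#' @export
screen_cohort <- function(records) {
  n <- nrow(records)
  partial <- logical(n)

  vg <- rep(NA_character_, n)
  infant <- records$age < 2
  toddler <- records$age >= 2 & records$age < 5
  older <- records$age >= 5
  ok <- (infant & !is.na(records$fix_and_follow)) |
    (toddler & !is.na(records$counts_fingers)) |
    (older & !is.na(records$va_denominator))
  if (any(ok)) {
    vg[ok] <- classify_vision(records$age[ok], records$va_denominator[ok],
                              records$fix_and_follow[ok],
                              records$counts_fingers[ok])
  }
  partial <- partial | !ok

  hg <- rep(NA_character_, n)
  has_oae <- !is.na(records$oae_pass_left) & !is.na(records$oae_pass_right)
  need_pta <- has_oae & !records$oae_pass_left & !records$oae_pass_right &
    records$age >= 4
  ok <- has_oae & (!need_pta | !is.na(records$pta_better_ear))
  if (any(ok)) {
    hg[ok] <- classify_hearing(records$age[ok], records$oae_pass_left[ok],
                               records$oae_pass_right[ok],
                               records$pta_better_ear[ok])
  }
  partial <- partial | !ok

  mg <- rep(NA_character_, n)
  ok <- !is.na(records$msi_screen_positive) &
    (!records$msi_screen_positive | !is.na(records$msi_exam_grade))
  if (any(ok)) {
    mg[ok] <- classify_msi(records$age[ok], records$msi_screen_positive[ok],
                           records$msi_exam_grade[ok])
  }
  partial <- partial | !ok

  ep <- classify_epilepsy(ifelse(is.na(records$gtc_seizures_12m), 0L,
                                 records$gtc_seizures_12m))
  partial <- partial | is.na(records$gtc_seizures_12m)

  comp <- rep(NA_integer_, n)
  band <- rep(NA_character_, n)
  adult <- records$age >= 18
  items <- as.matrix(records[paste0("phq9_", 1:9)])
  ok <- adult & rowSums(is.na(items[, 1:3, drop = FALSE])) == 0
  if (any(ok)) {
    sc <- score_phq9(items[ok, , drop = FALSE], records$age[ok])
    comp[ok] <- sc$composite
    band[ok] <- sc$band
  }
  partial <- partial | (adult & !ok)

  records$vision_grade <- vg
  records$hearing_grade <- hg
  records$msi_grade <- mg
  records$epilepsy_case <- ep
  records$phq9_composite <- comp
  records$phq9_band <- band
  records$partial_screen <- partial
  records
}

# n x domain integer matrix of core-domain report codes, with domains not
# applicable at a record's age set NA (ages 0-1: all NA).
#' @keywords internal
wg_core_code_matrix <- function(records) {
  doms <- union(wg_child_core(), wg_adult_core())
  m <- as.matrix(records[paste0("wg_", doms)])
  colnames(m) <- doms
  child <- records$age >= 2 & records$age < 18
  adult <- records$age >= 18
  for (d in doms) {
    keep <- (child & d %in% wg_child_core()) | (adult & d %in% wg_adult_core())
    m[!keep, d] <- NA_integer_
  }
  m
}

#' Maximum reported core-domain level per record
#'
#' @param records Participant data frame.
#' @return Integer vector of report-level codes (0--3); `NA` for ages
#'   0--1 (no tool) or when no core response was recorded.
#' @export
wg_max_core <- function(records) {
  if (nrow(records) == 0L) return(integer(0))
  m <- wg_core_code_matrix(records)
  out <- suppressWarnings(apply(m, 1L, max, na.rm = TRUE))
  out[!is.finite(out)] <- NA_integer_
  as.integer(out)
}

#' @keywords internal
wg_core_count_at_least <- function(records, threshold) {
  th <- report_rank(threshold)
  m <- wg_core_code_matrix(records)
  rowSums(m >= th, na.rm = TRUE)
}

#' Self-reported case definition
#'
#' A record is a self-reported case when at least `min_domains` core
#' domains are reported at or above `threshold` ("cannot do" counts above
#' "a lot"). Ages 0--1 are never self-reported cases (no tool exists).
#'
#' @param records Participant data frame.
#' @param threshold Report level: `"a_lot"` (the recommended cut-off,
#'   default) or `"some"` (the expanded definitions).
#' @param min_domains Minimum number of core domains at or above the
#'   threshold.
#' @return Logical vector.
#' @export
is_self_reported_case <- function(records, threshold = "a_lot",
                                  min_domains = 1L) {
  stopifnot(report_rank(threshold) %in% 1:3, min_domains >= 1)
  wg_core_count_at_least(records, threshold) >= min_domains &
    records$age >= 2
}

#' Clinical case definition
#'
#' A record is a clinical case on a moderate or greater vision, hearing
#' or musculoskeletal impairment (`"impaired_unclassified"` infant-screen
#' results count), epilepsy, or a PHQ-9 band at or above
#' `depression_case_band`. Missing grades do not preclude classification
#' on the remaining screens.
#'
#' @param records Participant data frame with screen grades (see
#'   [screen_cohort()]).
#' @param depression_case_band PHQ-9 band defining a clinical depression
#'   case; default `"moderately_severe"` (composite >= 15).
#' @return Logical vector.
#' @export
is_clinical_case <- function(records, depression_case_band = "moderately_severe") {
  imp <- function(g) !is.na(g) & severity_rank(g) >= 2L
  dep <- !is.na(records$phq9_band) &
    phq9_band_rank(records$phq9_band) >= phq9_band_rank(depression_case_band)
  imp(records$vision_grade) | imp(records$hearing_grade) |
    imp(records$msi_grade) |
    (!is.na(records$epilepsy_case) & records$epilepsy_case) | dep
}

#' Classify a cohort into the Category A/B/C decomposition
#'
#' @param records Participant data frame; screen grades are computed with
#'   [screen_cohort()] if absent.
#' @param threshold,min_domains Self-report definition, see
#'   [is_self_reported_case()].
#' @param depression_case_band See [is_clinical_case()].
#' @return An object of class `case_classification`: a list with `status`
#'   (data frame: `id`, `self_reported`, `clinical`, `category` in
#'   `A`/`B`/`C`/`none`) and `counts` (named vector: `n`, `total_cases`,
#'   `self_reported`, `clinical`, `A`, `B`, `C`).
#' @export
classify_cohort <- function(records, threshold = "a_lot", min_domains = 1L,
                            depression_case_band = "moderately_severe") {
  if (is.null(records$vision_grade)) records <- screen_cohort(records)
  sr <- is_self_reported_case(records, threshold, min_domains)
  cl <- is_clinical_case(records, depression_case_band)
  category <- ifelse(sr & cl, "B", ifelse(sr, "A", ifelse(cl, "C", "none")))
  counts <- c(n = nrow(records), total_cases = sum(sr | cl),
              self_reported = sum(sr), clinical = sum(cl),
              A = sum(category == "A"), B = sum(category == "B"),
              C = sum(category == "C"))
  structure(list(status = data.frame(id = records$id, self_reported = sr,
                                     clinical = cl, category = category,
                                     stringsAsFactors = FALSE),
                 counts = counts),
            class = "case_classification")
}

#' @export
print.case_classification <- function(x, ...) {
  ct <- x$counts
  cat("Cohort case classification\n")
  cat(sprintf("  n = %d, cases = %d (%.1f%%)\n", ct["n"], ct["total_cases"],
              100 * ct["total_cases"] / ct["n"]))
  cat(sprintf("  self-reported = %d, clinical = %d\n",
              ct["self_reported"], ct["clinical"]))
  cat(sprintf("  Category A (self-report only) = %d\n", ct["A"]))
  cat(sprintf("  Category B (both)             = %d\n", ct["B"]))
  cat(sprintf("  Category C (clinical only)    = %d\n", ct["C"]))
  invisible(x)
}

#' Category decomposition from marginal totals
#'
#' Inclusion--exclusion on published (or otherwise aggregated) totals:
#' with `total = A + B + C`, `self_reported = A + B` and
#' `clinical = B + C`, the overlap is
#' `B = self_reported + clinical - total`.
#'
#' @param total_cases,self_reported,clinical Marginal case counts.
#' @return Named integer vector `c(A, B, C)`.
#' @export
#' @examples
#' category_decompose(373, 197, 294) # A 79, B 118, C 176
category_decompose <- function(total_cases, self_reported, clinical) {
  b <- self_reported + clinical - total_cases
  a <- self_reported - b
  c_ <- clinical - b
  if (any(c(a, b, c_) < 0)) {
    stop("inconsistent totals: negative category count", call. = FALSE)
  }
  c(A = as.integer(a), B = as.integer(b), C = as.integer(c_))
}

#' Evaluate the two-stage screening strategy
#'
#' Stage one administers the self-report tool to everyone; stage two
#' clinically screens all who report at least `screen_threshold` in any
#' core domain. A person with a disability is identified when they are a
#' self-reported case, or a clinical case whose maximum reported core
#' level reaches the screen threshold.
#'
#' @param records Participant data frame.
#' @param screen_threshold Report level that triggers the clinical
#'   screen; default `"some"`.
#' @param classification Optional precomputed [classify_cohort()] result
#'   (with default definitions) to avoid re-screening.
#' @return List with `identified`, `total_cases`, `sensitivity`, and
#'   `clinical_screens_required` (the stage-two workload).
#' @export
evaluate_two_stage_strategy <- function(records, screen_threshold = "some",
                                        classification = NULL) {
  if (is.null(records$vision_grade)) records <- screen_cohort(records)
  if (is.null(classification)) classification <- classify_cohort(records)
  st <- classification$status
  th <- report_rank(screen_threshold)
  maxlev <- wg_max_core(records)
  screened_in <- !is.na(maxlev) & maxlev >= th
  identified <- st$self_reported | (st$clinical & screened_in)
  total <- sum(st$self_reported | st$clinical)
  list(identified = sum(identified), total_cases = total,
       sensitivity = if (total > 0) sum(identified) / total else NA_real_,
       clinical_screens_required = sum(screened_in))
}

#' Single-question disability screen comparison
#'
#' Compares the direct question "Do you consider yourself (your child) to
#' have a disability?" against the composite case definitions.
#'
#' @param records Participant data frame with a logical
#'   `single_question_disability` column (collected in India only).
#' @param classification Optional precomputed [classify_cohort()] result.
#' @return List of proportions: `prevalence` (affirmative answers),
#'   `of_clinical_cases_yes`, `of_self_reported_cases_yes`, and
#'   `of_yes_neither` (affirmative answerers who are neither type of
#'   case; `NaN` when nobody answers yes).
#' @export
compare_single_question <- function(records, classification = NULL) {
  sq <- records$single_question_disability
  if (is.null(sq) || all(is.na(sq))) {
    stop("single_question_disability was not collected for this cohort",
         call. = FALSE)
  }
  if (is.null(records$vision_grade)) records <- screen_cohort(records)
  if (is.null(classification)) classification <- classify_cohort(records)
  st <- classification$status
  yes <- !is.na(sq) & sq
  list(prevalence = mean(yes),
       of_clinical_cases_yes = mean(yes[st$clinical]),
       of_self_reported_cases_yes = mean(yes[st$self_reported]),
       of_yes_neither = mean(!st$clinical[yes] & !st$self_reported[yes]))
}
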