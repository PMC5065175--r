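# Instrument scoring: each clinical screen and the self-report modules are
# turned into graded results. Thresholds follow the survey protocol:
# vision by presenting Snellen acuity in the better eye, hearing by
# better-ear pure-tone average after a failed OAE screen, musculoskeletal
# impairment by physiotherapist exam grade, epilepsy by reported
# generalised tonic-clonic seizure count, depression by PHQ-9 composite.

VA_NONE <- 6 / 18   # decimal acuity at or above which vision is unimpaired
VA_MODERATE <- 6 / 60
VA_SEVERE <- 3 / 60

.missing_error <- function(field, who) {
  stop("missing required measurement '", field, "' for ", who, call. = FALSE)
}

#' Grade vision impairment from a visual acuity screen
#'
#' Ages 5 and over are graded on presenting decimal acuity (6/x Snellen at
#' six metres) in the better eye: no impairment at or above 6/18, moderate
#' below 6/18 down to 6/60, severe below 6/60 down to 3/60, profound
#' (blind) below 3/60. Children under 2 are screened by fix-and-follow and
#' ages 2--4 by finger counting; a failed infant/toddler screen yields
#' `"impaired_unclassified"` (impairment present, severity not graded).
#'
#' @param age Age in years (vectorised; other arguments are recycled).
#' @param va_denominator Snellen denominator x in 6/x, required for ages
#'   5 and over.
#' @param fix_and_follow Logical, required under age 2: can the infant fix
#'   and follow?
#' @param counts_fingers Logical, required for ages 2--4: can the child
#'   count fingers?
#' @return Character vector of severity grades (see [severity_grades()]).
#' @export
#' @examples
#' classify_vision(30, va_denominator = 18) # "none"
#' classify_vision(30, va_denominator = 24) # "moderate"
#' classify_vision(1, fix_and_follow = FALSE) # "impaired_unclassified"
classify_vision <- function(age, va_denominator = NULL,
                            fix_and_follow = NULL, counts_fingers = NULL) {
  n <- length(age)
  stopifnot(all(age >= 0))
  va_denominator <- rep_len(if (is.null(va_denominator)) NA_real_ else va_denominator, n)
  fix_and_follow <- rep_len(if (is.null(fix_and_follow)) NA else fix_and_follow, n)
  counts_fingers <- rep_len(if (is.null(counts_fingers)) NA else counts_fingers, n)

  out <- character(n)
  infant <- age < 2
  toddler <- age >= 2 & age < 5
  older <- age >= 5

  if (any(infant & is.na(fix_and_follow))) .missing_error("fix_and_follow", "age < 2")
  if (any(toddler & is.na(counts_fingers))) .missing_error("counts_fingers", "ages 2-4")
  if (any(older & is.na(va_denominator))) .missing_error("va_denominator", "ages 5+")
  if (any(older & !is.na(va_denominator) & va_denominator <= 0)) {
    stop("va_denominator must be positive", call. = FALSE)
  }

  out[infant] <- ifelse(fix_and_follow[infant], "none", "impaired_unclassified")
  out[toddler] <- ifelse(counts_fingers[toddler], "none", "impaired_unclassified")
  if (any(older)) {
    dec <- 6 / va_denominator[older]
    out[older] <- ifelse(dec >= VA_NONE, "none",
                  ifelse(dec >= VA_MODERATE, "moderate",
                  ifelse(dec >= VA_SEVERE, "severe", "profound")))
  }
  out
}

#' Grade hearing impairment from OAE and pure-tone audiometry
#'
#' Ages 0--3 are screened by oto-acoustic emissions only: failure in both
#' ears yields `"impaired_unclassified"`, otherwise `"none"`. From age 4,
#' an OAE pass in at least one ear is unimpaired; a bilateral failure is
#' graded on the better-ear pure-tone average: children (4--17) are
#' unimpaired below 35 dBA and adults (18+) below 41 dBA; both groups are
#' moderate up to 60, severe 61--80, and profound (deaf) above 80 dBA.
#'
#' @param age Age in years (vectorised).
#' @param oae_pass_left,oae_pass_right Logical OAE pass per ear.
#' @param pta_better_ear Better-ear pure-tone average in dBA, required at
#'   ages 4+ when both ears failed the OAE.
#' @return Character vector of severity grades.
#' @export
#' @examples
#' classify_hearing(40, FALSE, FALSE, pta_better_ear = 40) # "none"
#' classify_hearing(10, FALSE, FALSE, pta_better_ear = 40) # "moderate"
classify_hearing <- function(age, oae_pass_left, oae_pass_right,
                             pta_better_ear = NULL) {
  n <- length(age)
  stopifnot(all(age >= 0))
  oae_pass_left <- rep_len(oae_pass_left, n)
  oae_pass_right <- rep_len(oae_pass_right, n)
  pta_better_ear <- rep_len(if (is.null(pta_better_ear)) NA_real_ else pta_better_ear, n)
  if (any(is.na(oae_pass_left) | is.na(oae_pass_right))) {
    .missing_error("oae_pass_left/right", "all ages")
  }

  both_fail <- !oae_pass_left & !oae_pass_right
  out <- rep("none", n)
  young <- age < 4
  out[young & both_fail] <- "impaired_unclassified"

  need_pta <- !young & both_fail
  if (any(need_pta & is.na(pta_better_ear))) {
    .missing_error("pta_better_ear", "ages 4+ with bilateral OAE failure")
  }
  if (any(need_pta)) {
    pta <- pta_better_ear[need_pta]
    thr_none <- ifelse(age[need_pta] < 18, 35, 41)
    out[need_pta] <- ifelse(pta < thr_none, "none",
                     ifelse(pta < 61, "moderate",
                     ifelse(pta < 81, "severe", "profound")))
  }
  out
}

#' Grade musculoskeletal impairment
#'
#' A positive report-based screen triggers a physiotherapist examination
#' with standardised observation of activities; the exam grade (none,
#' mild, moderate, severe -- no profound level exists for MSI) passes
#' through. A negative screen is unimpaired.
#'
#' @param age Age in years (vectorised; not used by the grading rule but
#'   kept for a uniform screen interface).
#' @param screen_positive Logical: any affirmative screening answer?
#' @param exam_grade Physiotherapist grade, required when the screen is
#'   positive; one of `"none"`, `"mild"`, `"moderate"`, `"severe"`.
#' @return Character vector of severity grades.
#' @export
#' @examples
#' classify_msi(25, FALSE) # "none"
#' classify_msi(25, TRUE, "severe") # "severe"
classify_msi <- function(age, screen_positive, exam_grade = NULL) {
  n <- max(length(age), length(screen_positive))
  age <- rep_len(age, n)
  screen_positive <- rep_len(screen_positive, n)
  exam_grade <- rep_len(if (is.null(exam_grade)) NA_character_ else exam_grade, n)
  stopifnot(all(age >= 0))
  if (any(screen_positive & is.na(exam_grade))) {
    .missing_error("exam_grade", "screen-positive participants")
  }
  valid <- c("none", "mild", "moderate", "severe")
  bad <- screen_positive & !is.na(exam_grade) & !(exam_grade %in% valid)
  if (any(bad)) {
    stop("invalid MSI exam grade(s): ",
         paste(unique(exam_grade[bad]), collapse = ", "), call. = FALSE)
  }
  ifelse(screen_positive, exam_grade, "none")
}

#' Epilepsy case screen
#'
#' A participant screens positive for epilepsy when three or more
#' generalised tonic-clonic seizures are reported in the past 12 months.
#'
#' @param gtc_seizures_12m Non-negative seizure count (vectorised).
#' @return Logical vector.
#' @export
#' @examples
#' classify_epilepsy(c(0, 2, 3)) # FALSE FALSE TRUE
classify_epilepsy <- function(gtc_seizures_12m) {
  stopifnot(all(gtc_seizures_12m >= 0, na.rm = TRUE))
  gtc_seizures_12m >= 3
}

#' Score the PHQ-9 depression screen
#'
#' Adults answer three screening items, with the remaining six
#' administered only when the screen is positive. The composite is the sum
#' of administered item scores (non-administered items count 0), range
#' 0--27, banded with the standard PHQ-9 cut-offs.
#'
#' @param items Numeric vector of 9 item scores (each 0--3), or an
#'   n-by-9 matrix for several respondents. Items 4--9 may be `NA` when
#'   not administered.
#' @param age Age in years; the instrument is administered to adults
#'   (18+) only.
#' @param administered_full Logical: were items 4--9 administered? By
#'   default inferred as "any of the first three items positive".
#' @return A data frame with columns `composite` (0--27) and `band`
#'   (`"none"`, `"mild"`, `"moderate"`, `"moderately_severe"`,
#'   `"severe"`).
#' @export
#' @examples
#' score_phq9(rep(3, 9), age = 40) # composite 27, band "severe"
#' score_phq9(c(1, 1, 2, 0, 0, 0, 0, 0, 0), age = 40) # composite 4, "none"
score_phq9 <- function(items, age, administered_full = NULL) {
  if (is.vector(items)) items <- matrix(items, nrow = 1L)
  stopifnot(ncol(items) == 9L)
  n <- nrow(items)
  age <- rep_len(age, n)
  if (any(age < 18)) {
    stop("PHQ-9 not administered: depression screening is for adults (18+) only",
         call. = FALSE)
  }
  if (any(items < 0 | items > 3, na.rm = TRUE)) {
    stop("PHQ-9 item scores must be integers in 0..3", call. = FALSE)
  }
  screen <- items[, 1:3, drop = FALSE]
  if (any(is.na(screen))) {
    .missing_error("items 1-3", "all PHQ-9 respondents")
  }
  if (is.null(administered_full)) {
    administered_full <- rowSums(screen > 0) > 0
  }
  administered_full <- rep_len(administered_full, n)
  rest <- items[, 4:9, drop = FALSE]
  rest[is.na(rest)] <- 0
  rest[!administered_full, ] <- 0
  composite <- as.integer(rowSums(screen) + rowSums(rest))
  data.frame(composite = composite, band = phq9_band(composite),
             stringsAsFactors = FALSE)
}

#' @rdname score_phq9
#' @param composite PHQ-9 composite score (0--27).
#' @export
phq9_band <- function(composite) {
  stopifnot(all(composite >= 0 & composite <= 27, na.rm = TRUE))
  as.character(cut(composite, breaks = c(-1, 4, 9, 14, 19, 27),
                   labels = c("none", "mild", "moderate",
                              "moderately_severe", "severe")))
}

#' @keywords internal
phq9_band_rank <- function(band) {
  match(band, c("none", "mild", "moderate", "moderately_severe", "severe")) - 1L
}

#' Score a Washington Group response set
#'
#' Returns the maximum reported level over the age-appropriate core
#' domains, and for each threshold level the set of core domains at or
#' above it. Non-core domains (pain, fatigue, anxiety, depression) never
#' contribute. Ages 0--1 have no tool and yield an empty result flagged
#' `no_tool`.
#'
#' @param responses Named vector of report levels (labels or 0--3 codes),
#'   named by domain.
#' @param age Age in years (scalar).
#' @param country `"cameroon"` or `"india"` (retained for respondent-type
#'   context; the domain sets switch child to adult at the 18th birthday
#'   in both countries).
#' @return A list with `max_core_level` (label, `NA` when no tool),
#'   `domains_at_or_above` (named list of domain sets for thresholds
#'   `some`, `a_lot`, `cannot_do`), `core_domains`, and `no_tool`.
#' @export
#' @examples
#' r <- c(seeing = "a_lot", hearing = "no_difficulty", walking = "some")
#' score_wg(r, age = 40)$max_core_level # "a_lot"
score_wg <- function(responses, age, country = c("cameroon", "india")) {
  country <- match.arg(country)
  stopifnot(length(age) == 1L, age >= 0)
  core <- core_domains(age)
  if (length(core) == 0L) {
    return(list(max_core_level = NA_character_,
                domains_at_or_above = list(some = character(0),
                                           a_lot = character(0),
                                           cannot_do = character(0)),
                core_domains = character(0), no_tool = TRUE))
  }
  unknown <- setdiff(names(responses), wg_all_domains())
  if (length(unknown)) {
    stop("unknown domain(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  r <- report_rank(responses)
  names(r) <- names(responses)
  r <- r[intersect(names(r), core)]
  r <- r[!is.na(r)]
  max_level <- if (length(r)) max(r) else 0L
  sets <- lapply(c(some = 1L, a_lot = 2L, cannot_do = 3L),
                 function(th) names(r)[r >= th])
  list(max_core_level = report_levels()[max_level + 1L],
       domains_at_or_above = sets,
       core_domains = core, no_tool = FALSE)
}

#' Participation restriction score
#'
#' Sums per-item ordinal scores over the activity/participation item set:
#' each item scores 1 (no difficulty), 2 (moderate difficulty), 3 (severe
#' difficulty) or 4 (inability to perform). The child form has 15 items
#' (range 15--60) and the adult form 21 items (range 21--84). Higher
#' scores denote greater participation restriction. Missing items are an
#' error; no imputation is performed.
#'
#' @param responses Numeric vector of item scores in 1..4, or a character
#'   vector of the response labels.
#' @param form `"adult"` (21 items) or `"child"` (15 items).
#' @return Integer score.
#' @export
#' @examples
#' participation_score(rep(1, 21), form = "adult") # 21
#' participation_score(rep(4, 15), form = "child") # 60
participation_score <- function(responses, form = c("adult", "child")) {
  form <- match.arg(form)
  n_items <- if (form == "adult") 21L else 15L
  labels <- c("no_difficulty", "moderate_difficulty",
              "severe_difficulty", "inability_to_perform")
  if (is.character(responses)) {
    responses <- match(responses, labels)
  }
  if (length(responses) != n_items) {
    stop("expected ", n_items, " items for the ", form, " form, got ",
         length(responses), call. = FALSE)
  }
  if (any(is.na(responses))) {
    .missing_error("participation items", "scored participants")
  }
  if (any(responses < 1 | responses > 4)) {
    stop("participation item scores must be in 1..4", call. = FALSE)
  }
  as.integer(sum(responses))
}
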