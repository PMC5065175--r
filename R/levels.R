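# Ordered vocabularies shared across the package: Washington Group report
# levels, clinical severity grades, and the core/non-core domain sets.

#' Washington Group report levels
#'
#' The four ordered response options used by the Washington Group
#' functioning questions, from least to most limited.
#'
#' @return Character vector `c("no_difficulty", "some", "a_lot",
#'   "cannot_do")`, in increasing order of limitation.
#' @export
#' @examples
#' report_levels()
report_levels <- function() {
  c("no_difficulty", "some", "a_lot", "cannot_do")
}

#' Clinical severity grades
#'
#' Ordered impairment severity grades used by the clinical screens.
#' `"impaired_unclassified"` is the outcome of infant/toddler screens
#' (fix-and-follow, finger counting, OAE-only) that detect impairment
#' without grading it; for case-definition purposes it counts as at least
#' moderate but it is excluded from severity-specific tabulations.
#'
#' @param include_unclassified Append `"impaired_unclassified"`?
#' @return Character vector of grades in increasing severity.
#' @export
#' @examples
#' severity_grades()
severity_grades <- function(include_unclassified = FALSE) {
  g <- c("none", "mild", "moderate", "severe", "profound")
  if (include_unclassified) g <- c(g, "impaired_unclassified")
  g
}

#' @keywords internal
report_rank <- function(x) {
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% 0:3)
    if (any(bad)) {
      stop("invalid report level code(s): ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
    return(as.integer(x))
  }
  r <- match(as.character(x), report_levels()) - 1L
  bad <- !is.na(x) & is.na(r)
  if (any(bad)) {
    stop("invalid report level(s): ",
         paste(unique(as.character(x)[bad]), collapse = ", "), call. = FALSE)
  }
  r
}

# Severity rank on the none(0) < mild(1) < moderate(2) < severe(3) <
# profound(4) scale. "impaired_unclassified" ranks as moderate when
# `unclassified = "moderate"` (the case-definition convention) and as NA
# when `unclassified = "na"` (severity tabulations).
#' @keywords internal
severity_rank <- function(x, unclassified = c("moderate", "na")) {
  unclassified <- match.arg(unclassified)
  x <- as.character(x)
  r <- match(x, severity_grades()) - 1L
  iu <- !is.na(x) & x == "impaired_unclassified"
  r[iu] <- if (unclassified == "moderate") 2L else NA_integer_
  bad <- !is.na(x) & is.na(r) & !iu
  if (any(bad)) {
    stop("invalid severity grade(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  r
}

#' Compare severity grades against a threshold
#'
#' @param x Character vector of severity grades (see [severity_grades()]).
#' @param grade Threshold grade.
#' @return Logical vector: is `x` at or above `grade`?
#'   `"impaired_unclassified"` compares as moderate.
#' @export
#' @examples
#' severity_at_least(c("mild", "moderate", "impaired_unclassified"), "moderate")
severity_at_least <- function(x, grade = "moderate") {
  severity_rank(x) >= severity_rank(grade)
}

#' Washington Group core domain sets
#'
#' Core functioning domains entering the self-report case definition, by
#' age group: the child functioning module applies from age 2 to 17 and
#' the adult extended set from 18 up. Ages 0--1 have no tool.
#'
#' @param age Age in completed years.
#' @return Character vector of core domain names for that age (empty for
#'   ages 0--1).
#' @export
#' @examples
#' core_domains(10)
#' core_domains(40)
core_domains <- function(age) {
  stopifnot(length(age) == 1L, age >= 0)
  if (age < 2) return(character(0))
  if (age < 18) return(wg_child_core())
  wg_adult_core()
}

#' @rdname core_domains
#' @export
wg_child_core <- function() {
  c("seeing", "hearing", "walking", "self_care", "understanding",
    "being_understood", "learning", "remembering")
}

#' @rdname core_domains
#' @export
wg_adult_core <- function() {
  c("seeing", "hearing", "walking", "understanding", "being_understood",
    "remembering", "concentrating", "self_care", "upper_body", "fine_motor")
}

#' @rdname core_domains
#' @export
wg_noncore <- function() {
  c("pain", "fatigue", "anxiety", "depression")
}

#' @keywords internal
wg_all_domains <- function() {
  union(union(wg_child_core(), wg_adult_core()), wg_noncore())
}

#' @keywords internal
wg_columns <- function() {
  paste0("wg_", wg_all_domains())
}
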