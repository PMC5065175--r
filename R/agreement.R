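# Agreement between self-reported functional limitation and clinical
# screening: the matched-domain cross-tabulation, logistic regression on
# the predictors of concordance among clinical cases, participation-score
# comparisons between the case categories, and sweeps over alternative
# self-report case definitions.

MATCHED_ADULT <- c("seeing", "hearing", "walking", "upper_body", "fine_motor")
MATCHED_CHILD <- c("seeing", "hearing", "walking")

#' Cross-tabulation of clinical severity versus reported limitation
#'
#' Rows are the maximum reported level over the functioning domains
#' directly matched to clinical screens (seeing; hearing; and
#' walking/upper body strength/fine motor skills for adults, walking only
#' for children), collapsed to none / some / a lot-or-cannot. Columns are
#' the most severe clinical grade among vision, hearing and MSI,
#' collapsed to none / mild / moderate / severe-profound. Restricted to
#' ages 5 and over; records missing any clinical severity are excluded
#' and counted.
#'
#' @param records Participant data frame (screened with
#'   [screen_cohort()] if grades are absent).
#' @param min_age Minimum age, default 5.
#' @return Object of class `crosstab`: list with `counts` (3 x 4
#'   matrix), `row_pct` (percentages to the nearest whole percent),
#'   `n`, and `n_excluded` (missing-severity records).
#' @export
matched_domain_crosstab <- function(records, min_age = 5) {
  if (is.null(records$vision_grade)) records <- screen_cohort(records)
  records <- records[records$age >= min_age, , drop = FALSE]

  sev <- pmax(severity_rank(records$vision_grade, unclassified = "na"),
              severity_rank(records$hearing_grade, unclassified = "na"),
              severity_rank(records$msi_grade, unclassified = "na"))
  excluded <- is.na(sev)
  records <- records[!excluded, , drop = FALSE]
  sev <- sev[!excluded]

  adult <- records$age >= 18
  rep_m <- as.matrix(records[paste0("wg_", MATCHED_ADULT)])
  rep_m[!adult, !(MATCHED_ADULT %in% MATCHED_CHILD)] <- NA_integer_
  rep_max <- suppressWarnings(apply(rep_m, 1L, max, na.rm = TRUE))
  rep_max[!is.finite(rep_max)] <- 0L

  row_lab <- c("none", "some", "a_lot_cannot")
  col_lab <- c("none", "mild", "moderate", "severe_profound")
  rows <- factor(ifelse(rep_max >= 2, "a_lot_cannot",
                        ifelse(rep_max == 1, "some", "none")),
                 levels = row_lab)
  cols <- factor(ifelse(sev >= 3, "severe_profound",
                        ifelse(sev == 2, "moderate",
                               ifelse(sev == 1, "mild", "none"))),
                 levels = col_lab)
  counts <- table(rows, cols)
  counts <- matrix(as.integer(counts), 3, 4, dimnames = list(row_lab, col_lab))
  row_pct <- round_half_up(100 * counts / pmax(rowSums(counts), 1L), 0)
  structure(list(counts = counts, row_pct = row_pct,
                 n = sum(counts), n_excluded = sum(excluded)),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat("Clinical severity vs reported limitation (n =", x$n, ";",
      x$n_excluded, "missing-severity records excluded)\n")
  print(x$counts)
  invisible(x)
}

#' Closed-form odds ratio for a 2 x 2 table
#'
#' Cross-product odds ratio with the Woolf (log-scale Wald) confidence
#' interval. Cell layout: `a` exposed cases, `b` exposed non-cases, `c`
#' unexposed cases, `d` unexposed non-cases.
#'
#' @param a,b,c,d Cell counts.
#' @param conf Confidence level.
#' @return List with `or`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' odds_ratio_2x2(19, 9, 73, 136)$or # 3.93
odds_ratio_2x2 <- function(a, b, c, d, conf = 0.95) {
  stopifnot(all(c(a, b, c, d) >= 0))
  or <- unname((a * d) / (b * c))
  se <- unname(sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se))
}

# covariates used by the concordance model
.concordance_frame <- function(records, classification,
                               depression_case_band = "moderately_severe") {
  st <- classification$status
  keep <- st$clinical
  rec <- records[keep, , drop = FALSE]
  sr <- st$self_reported[keep]

  imp <- function(g) !is.na(g) & severity_rank(g) >= 2L
  v <- imp(rec$vision_grade)
  h <- imp(rec$hearing_grade)
  m <- imp(rec$msi_grade)
  e <- !is.na(rec$epilepsy_case) & rec$epilepsy_case
  dep <- !is.na(rec$phq9_band) &
    phq9_band_rank(rec$phq9_band) >= phq9_band_rank(depression_case_band)

  n_types <- v + h + m + e
  type <- ifelse(n_types >= 2, "multiple",
          ifelse(v, "vision",
          ifelse(h, "hearing",
          ifelse(m, "musculoskeletal",
          ifelse(e, "epilepsy", "depression")))))

  # severity: most severe grade among case-level impairments; epilepsy
  # and depression are treated as severe health conditions; unclassified
  # infant-screen impairment has no grade and is excluded
  sev_rank <- pmax(severity_rank(rec$vision_grade, unclassified = "na"),
                   severity_rank(rec$hearing_grade, unclassified = "na"),
                   severity_rank(rec$msi_grade, unclassified = "na"),
                   na.rm = TRUE)
  sev_rank[!is.finite(sev_rank)] <- NA_integer_
  sev_rank[(e | dep) & (is.na(sev_rank) | sev_rank < 3)] <- 3L
  sev_rank[!is.na(sev_rank) & sev_rank < 2] <- NA_integer_  # below case level
  has_iu <- (!is.na(rec$vision_grade) & rec$vision_grade == "impaired_unclassified") |
    (!is.na(rec$hearing_grade) & rec$hearing_grade == "impaired_unclassified")
  sev_rank[has_iu & !(e | dep) & is.na(sev_rank)] <- NA_integer_

  data.frame(
    self_reported = sr,
    age_band = cut(rec$age, breaks = c(-Inf, 17, 33, 49, 65, Inf),
                   labels = c("2-17", "18-33", "34-49", "50-65", "66+")),
    sex = factor(rec$sex, levels = c("male", "female")),
    severity = factor(c("moderate", "severe", "profound")[sev_rank - 1L],
                      levels = c("moderate", "severe", "profound")),
    type = factor(type, levels = c("vision", "musculoskeletal", "hearing",
                                   "epilepsy", "multiple", "depression")),
    stringsAsFactors = FALSE
  )
}

#' Predictors of self-reporting among clinical cases
#'
#' Logistic regression of "also being a self-reported case" on age band
#' (reference 34--49), sex, impairment severity (reference moderate;
#' epilepsy and depression count as severe health conditions) and
#' impairment type (reference vision; two or more case-level conditions
#' are "multiple"), fitted among clinical cases. Records with missing
#' severity are excluded; depression-only cases are excluded by default
#' (they are typically too sparse). Separation (an unbounded
#' coefficient) is flagged rather than silently reported with a CI.
#'
#' @param records Participant data frame.
#' @param classification Optional precomputed [classify_cohort()] result.
#' @param exclude_depression_only Drop depression-only cases? Default
#'   TRUE.
#' @param conf Confidence level for the Wald intervals.
#' @return Data frame with columns `term`, `or`, `ci_low`, `ci_high`,
#'   `p`, `separation` (per-term flag for unbounded coefficients, whose
#'   CIs are suppressed); attribute `n` gives the analysed sample size
#'   and attribute `all_separated` is `TRUE` when the outcome is
#'   constant and no model can be fitted.
#' @export
concordance_regression <- function(records, classification = NULL,
                                   exclude_depression_only = TRUE,
                                   conf = 0.95) {
  if (is.null(records$vision_grade)) records <- screen_cohort(records)
  if (is.null(classification)) classification <- classify_cohort(records)
  df <- .concordance_frame(records, classification)
  df <- df[!is.na(df$severity), , drop = FALSE]
  if (exclude_depression_only) df <- df[df$type != "depression", , drop = FALSE]
  df$type <- droplevels(df$type)
  df$age_band <- stats::relevel(df$age_band, ref = "34-49")
  # drop constant covariates (small cohorts)
  covars <- c("age_band", "sex", "severity", "type")
  covars <- covars[vapply(df[covars], function(x) length(unique(x[!is.na(x)])) > 1,
                          logical(1))]
  if (length(covars) == 0) stop("no non-constant covariates", call. = FALSE)
  fml <- stats::reformulate(covars, response = "self_reported")
  if (length(unique(df$self_reported)) < 2) {
    return(structure(data.frame(term = character(0), or = numeric(0),
                                ci_low = numeric(0), ci_high = numeric(0),
                                p = numeric(0), separation = logical(0)),
                     n = nrow(df), all_separated = TRUE))
  }
  fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  separation <- !fit$converged | abs(sm[, "Estimate"]) > 10 |
    sm[, "Std. Error"] > 100
  out <- data.frame(term = rownames(sm), or = exp(sm[, "Estimate"]),
                    ci_low = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
                    ci_high = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
                    p = sm[, "Pr(>|z|)"], separation = separation,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$ci_low[out$separation] <- NA_real_
  out$ci_high[out$separation] <- NA_real_
  attr(out, "n") <- nrow(df)
  attr(out, "all_separated") <- FALSE
  out
}

#' Participation scores by case category
#'
#' Mean and SD of the participation restriction score per case category
#' (A, B, C) and age group (children 5--16, adults 17+), with two-sample
#' t-tests for the two stated contrasts: Category A versus B and B
#' versus C. Pooled-variance (Student) tests by default; Welch via
#' `var_equal = FALSE`. Categories with fewer than two scored
#' observations yield a flagged, undefined test.
#'
#' @param records Participant data frame containing participation item
#'   columns (`part_1` ... `part_21`).
#' @param classification Optional precomputed [classify_cohort()] result.
#' @param var_equal Pooled-variance t-test? Default TRUE.
#' @return List with `summary` (data frame: age_group, category, n,
#'   mean, sd) and `tests` (data frame: age_group, contrast, t, df, p,
#'   defined).
#' @export
participation_comparison <- function(records, classification = NULL,
                                     var_equal = TRUE) {
  if (is.null(records$vision_grade)) records <- screen_cohort(records)
  if (is.null(classification)) classification <- classify_cohort(records)
  st <- classification$status

  items <- as.matrix(records[paste0("part_", 1:21)])
  n_ans <- rowSums(!is.na(items))
  score <- ifelse(n_ans > 0, rowSums(items, na.rm = TRUE), NA_real_)

  age_group <- ifelse(records$age >= 17, "adults_17plus",
               ifelse(records$age >= 5, "children_5_16", NA_character_))
  df <- data.frame(category = st$category, age_group = age_group,
                   score = score, stringsAsFactors = FALSE)
  df <- df[df$category %in% c("A", "B", "C") & !is.na(df$age_group) &
             !is.na(df$score), , drop = FALSE]

  cells <- expand.grid(age_group = c("children_5_16", "adults_17plus"),
                       category = c("A", "B", "C"), stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    s <- df$score[df$age_group == cells$age_group[i] &
                    df$category == cells$category[i]]
    data.frame(age_group = cells$age_group[i], category = cells$category[i],
               n = length(s), mean = mean(s), sd = stats::sd(s),
               stringsAsFactors = FALSE)
  }))

  contrasts <- list(c("A", "B"), c("B", "C"))
  tests <- do.call(rbind, lapply(c("children_5_16", "adults_17plus"), function(g) {
    do.call(rbind, lapply(contrasts, function(ct) {
      x <- df$score[df$age_group == g & df$category == ct[1]]
      y <- df$score[df$age_group == g & df$category == ct[2]]
      if (length(x) < 2 || length(y) < 2) {
        return(data.frame(age_group = g,
                          contrast = paste(ct, collapse = "_vs_"),
                          t = NA_real_, df = NA_real_, p = NA_real_,
                          defined = FALSE, stringsAsFactors = FALSE))
      }
      tt <- stats::t.test(x, y, var.equal = var_equal)
      data.frame(age_group = g, contrast = paste(ct, collapse = "_vs_"),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, defined = TRUE, stringsAsFactors = FALSE)
    }))
  }))
  list(summary = summ, tests = tests)
}

#' Sweep over alternative self-report case definitions
#'
#' Re-classifies the cohort under each alternative self-report definition
#' and reports the resulting self-report and overall prevalences, and the
#' share of baseline Category C (clinical-only) cases that the
#' alternative re-classifies into Category B.
#'
#' @param records Participant data frame.
#' @param definitions Named list of definitions, each a list with
#'   `threshold` and `min_domains`. The default sweep covers the
#'   baseline ("a lot"/any domain) and the two expansions: "some" in any
#'   domain, and "some" in any two domains.
#' @return Data frame: definition, threshold, min_domains,
#'   self_report_prevalence, overall_prevalence,
#'   share_baseline_C_to_B.
#' @export
definition_sweep <- function(records,
                             definitions = list(
                               alot_any = list(threshold = "a_lot", min_domains = 1),
                               some_two = list(threshold = "some", min_domains = 2),
                               some_any = list(threshold = "some", min_domains = 1))) {
  if (is.null(records$vision_grade)) records <- screen_cohort(records)
  baseline <- classify_cohort(records)
  base_c <- baseline$status$category == "C"
  n <- nrow(records)
  out <- lapply(names(definitions), function(nm) {
    d <- definitions[[nm]]
    cc <- classify_cohort(records, threshold = d$threshold,
                          min_domains = d$min_domains)
    data.frame(definition = nm, threshold = d$threshold,
               min_domains = d$min_domains,
               self_report_prevalence = cc$counts[["self_reported"]] / n,
               overall_prevalence = cc$counts[["total_cases"]] / n,
               share_baseline_C_to_B =
                 if (any(base_c)) mean(cc$status$self_reported[base_c]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
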