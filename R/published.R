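# Published aggregate counts from the two-country, all-age,
# population-based disability survey (North-West Cameroon 2013; Telangana
# State, India 2014) that this package's analysis pipeline reproduces,
# plus arithmetic re-derivation checks of the published percentages.

#' Round half away from zero
#'
#' Publication-style rounding: exact halves round up, unlike base
#' [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.5) # 1
round_half_up <- function(x, digits = 0) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

#' Published survey counts
#'
#' Aggregate counts as printed by the source survey, used as fixed inputs
#' for arithmetic re-derivation: total respondents, case totals by
#' definition, 50-plus subgroup counts, the clinical-severity versus
#' reported-limitation cross-tabulation (ages 5+), and the Cameroon
#' severity 2 x 2 among clinical cases (severe versus moderate by
#' self-report status).
#'
#' @return Nested list by country. Per country: `n`, `cases`,
#'   `self_reported`, `clinical`, `n_50plus`, `cases_50plus`, `printed`
#'   (the published percentages), and `crosstab` (counts with published
#'   row percentages). Cameroon additionally carries `severity_2x2`.
#' @export
published_counts <- function() {
  list(
    cameroon = list(
      n = 3567L, cases = 373L, self_reported = 197L, clinical = 294L,
      n_50plus = 636L, cases_50plus = 214L,
      printed = list(overall_pct = 10.5, self_reported_pct = 5.9,
                     clinical_pct = 8.4, age50plus_pct = 33.6,
                     category_share_pct = c(A = 21, B = 33, C = 47)),
      crosstab = list(
        counts = matrix(c(1555L, 52L, 33L, 3L,
                          790L, 247L, 106L, 16L,
                          28L, 26L, 64L, 35L), nrow = 3, byrow = TRUE,
                        dimnames = list(c("none", "some", "a_lot_cannot"),
                                        c("none", "mild", "moderate",
                                          "severe_profound"))),
        printed_row_pct = matrix(c(95, 3, 2, 1,
                                   68, 21, 9, 1,
                                   18, 17, 42, 23), nrow = 3, byrow = TRUE),
        printed_total_pct = c(80, 11, 7, 2)),
      # clinical cases: severe vs moderate impairment by self-report status
      severity_2x2 = c(severe_self_report = 19L, severe_clinical_only = 9L,
                       moderate_self_report = 73L,
                       moderate_clinical_only = 136L)
    ),
    india = list(
      n = 3574L, cases = 437L, self_reported = 258L, clinical = 376L,
      n_50plus = 668L, cases_50plus = 256L,
      printed = list(overall_pct = 12.2, self_reported_pct = 7.5,
                     clinical_pct = 10.5, age50plus_pct = 38.3,
                     category_share_pct = c(A = 14, B = 45, C = 41)),
      crosstab = list(
        counts = matrix(c(1769L, 162L, 16L, 10L,
                          499L, 410L, 82L, 34L,
                          12L, 43L, 89L, 92L), nrow = 3, byrow = TRUE,
                        dimnames = list(c("none", "some", "a_lot_cannot"),
                                        c("none", "mild", "moderate",
                                          "severe_profound"))),
        printed_row_pct = matrix(c(90, 8, 1, 1,
                                   49, 40, 8, 3,
                                   5, 18, 38, 39), nrow = 3, byrow = TRUE),
        printed_total_pct = c(71, 19, 6, 4))
    )
  )
}

#' Arithmetic re-derivation of the published percentages
#'
#' Recomputes every published percentage that is a pure function of the
#' published counts -- overall and 50-plus prevalence, Category A/B/C
#' shares (by inclusion--exclusion on the marginal case totals), and the
#' cross-tabulation row percentages -- applies publication rounding, and
#' compares with the printed value. Two published figures are known not
#' to equal their count-derived value and are reported honestly with
#' `match = FALSE`: the Cameroon Category B share (printed 33, counts
#' give 118/373 = 32) and one near-zero Cameroon cross-tab cell (3/1643,
#' printed 1). Published self-report/clinical sub-prevalences use
#' denominators that the counts do not recover (flagged in `note`, not
#' treated as mismatches of arithmetic).
#'
#' @return Data frame: `country`, `quantity`, `computed`, `printed`,
#'   `match`, `note`.
#' @export
#' @examples
#' chk <- published_checks()
#' subset(chk, !match)
published_checks <- function() {
  pc <- published_counts()
  rows <- list()
  add <- function(country, quantity, computed, printed, note = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      country = country, quantity = quantity, computed = computed,
      printed = printed, match = isTRUE(all.equal(computed, printed)),
      note = note, stringsAsFactors = FALSE)
  }
  for (ctry in names(pc)) {
    x <- pc[[ctry]]
    add(ctry, "overall_prevalence_pct",
        round_half_up(100 * x$cases / x$n, 1), x$printed$overall_pct)
    add(ctry, "prevalence_50plus_pct",
        round_half_up(100 * x$cases_50plus / x$n_50plus, 1),
        x$printed$age50plus_pct)
    dec <- category_decompose(x$cases, x$self_reported, x$clinical)
    for (cat in c("A", "B", "C")) {
      add(ctry, paste0("category_", cat, "_share_pct"),
          round_half_up(100 * dec[[cat]] / x$cases, 0),
          unname(x$printed$category_share_pct[cat]),
          if (ctry == "cameroon" && cat == "B") {
            "printed share does not equal inclusion-exclusion on printed totals"
          } else "")
    }
    add(ctry, "self_reported_prevalence_pct",
        round_half_up(100 * x$self_reported / x$n, 1),
        x$printed$self_reported_pct,
        "published denominator not recoverable from printed counts")
    add(ctry, "clinical_prevalence_pct",
        round_half_up(100 * x$clinical / x$n, 1), x$printed$clinical_pct,
        "published denominator not recoverable from printed counts")
    ct <- x$crosstab$counts
    pct <- round_half_up(100 * ct / rowSums(ct), 0)
    for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
      add(ctry, sprintf("crosstab_%s_%s_pct", rownames(ct)[i], colnames(ct)[j]),
          pct[i, j], x$crosstab$printed_row_pct[i, j],
          if (ctry == "cameroon" && i == 1 && j == 4) {
            "near-zero cell printed as 1"
          } else "")
    }
    tot <- round_half_up(100 * colSums(ct) / sum(ct), 0)
    for (j in seq_len(ncol(ct))) {
      add(ctry, sprintf("crosstab_total_%s_pct", colnames(ct)[j]),
          unname(tot[j]), x$crosstab$printed_total_pct[j])
    }
  }
  do.call(rbind, rows)
}
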