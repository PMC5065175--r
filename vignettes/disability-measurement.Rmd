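---
title: "Measuring disability in population-based cluster surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring disability in population-based cluster surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Within the WHO International Classification of Functioning, Disability and
Health (ICF), disability spans impairments of body function and structure,
activity limitations, and participation restrictions. Population surveys
measure it by two largely disjoint traditions: self-reported functional
limitation (the Washington Group questions, asking "how much difficulty do
you have seeing / hearing / walking / ...?" on a four-level scale), and
objective clinical screening (visual acuity, audiometry, musculoskeletal
examination, and screens for potentially disabling conditions such as
epilepsy and depression). `icfsurvey` implements both measurement arms of an
all-age, two-country (North-West Cameroon and Telangana, India), two-stage
cluster survey design, their combination into composite case definitions,
and the analyses that quantify how far the two arms identify the same
people.

The package's case definitions are:

* **clinical case** — any moderate-or-greater clinical impairment (vision,
  hearing, musculoskeletal), or a severe potentially disabling health
  condition (epilepsy: three or more generalised tonic-clonic seizures in
  12 months; depression: PHQ-9 at or above a configurable band);
* **self-reported case** — "a lot of difficulty" or "cannot do" in at least
  one core Washington Group domain (a configurable threshold and domain
  count support the expanded "some difficulty" definitions);
* **Category A / B / C** — self-report-only, both, and clinical-only cases;
  a partition of all cases that drives the agreement analyses.

## Instrument scoring

Grading rules follow the survey protocol exactly, and the package treats
them as hard boundaries (unit tests probe each threshold from both sides):

| Screen | Ages | Rule |
|---|---|---|
| Vision | 5+ | presenting Snellen acuity, better eye: none >= 6/18; moderate < 6/18, >= 6/60; severe < 6/60, >= 3/60; profound < 3/60 |
| Vision | < 2 / 2–4 | fix-and-follow / finger counting; failure = impairment of undetermined severity |
| Hearing | 4+ | OAE, then better-ear pure-tone average if both ears fail: none < 35 dBA (children) or < 41 dBA (adults); moderate to 60; severe 61–80; profound > 80 |
| Hearing | 0–3 | OAE only; bilateral failure = impairment of undetermined severity |
| MSI | all | report screen, then physiotherapist grade (none/mild/moderate/severe) passes through |
| Epilepsy | all | >= 3 generalised tonic-clonic seizures in 12 months |
| Depression | 18+ | PHQ-9 composite 0–27 with the standard bands |

Three grading decisions were genuinely open and are resolved as follows:

* **Undetermined infant/toddler severity.** Failed fix-and-follow, finger
  counting, or infant OAE screens return `"impaired_unclassified"`. For the
  clinical case definition this counts as at least moderate; severity-specific
  tabulations exclude it, which is why the cross-tabulation and the
  concordance regression restrict to ages with gradable severity and count
  the exclusions.
* **PHQ-9 bands.** The instrument's standard bands (0–4 none, 5–9 mild,
  10–14 moderate, 15–19 moderately severe, 20–27 severe) are used. The
  screen-to-full-administration rule (administer items 4–9 when any of the
  first three is positive) is the default and configurable; non-administered
  items count zero.
* **Depression case threshold.** The protocol calls a *severe* potentially
  disabling condition a case; we default `depression_case_band` to
  `"moderately_severe"` (composite >= 15), exposed as configuration because
  the source materials do not pin the band unambiguously.
* **Hearing has no mild audiometric band** in the protocol table even though
  mild hearing impairment was recorded in the field; the classifier follows
  the table (below 35/41 dBA is "none"), so in synthetic data the clinical
  "mild" column of the cross-tabulation is populated by MSI only.

Participation restriction is scored 1 (no difficulty) to 4 (inability to
perform) per item and summed — 15 items for children (range 15–60), 21 for
adults (21–84). The per-item 1–4 convention is ours; it is the unique
integer scoring consistent with the published maxima.

## Survey design and estimation

`sample_size()` is the standard normal-approximation prevalence formula
with relative precision, inflated by design effect and anticipated
non-response: for p = 0.04, 20% relative precision, 95% confidence,
deff 1.4 and 20% non-response it returns 4,034 (ceiling of 4,033.5). The
survey this package models printed a target of 4,056 for the same inputs;
the extra ~0.5% is an unrecoverable rounding path, which we document rather
than reverse-engineer.

Cluster selection is systematic probability-proportionate-to-size over a
census frame (`pps_select_clusters()`); a property test verifies the
empirical selection law against the size-proportional probabilities by
chi-square goodness of fit. Within a cluster, `compact_segment_sample()`
divides the map into population/80 segments (rounded half-up, minimum one
— "approximately 80 people" is not exact) and picks one uniformly.

`estimate_prevalence()` assumes the self-weighted design: the point
estimate is the plain sample proportion, and only the variance uses the
clustering, via the between-cluster Taylor-linearised estimator

$$\widehat{var}(\hat p) = \frac{k}{k-1}\,
  \frac{\sum_i (y_i - \hat p\, m_i)^2}{(\sum_i m_i)^2},$$

with cluster case totals $y_i$, sizes $m_i$, and $k$ clusters. The 95% CI
is computed on the logit scale and back-transformed with a $t_{k-1}$
quantile — the default behaviour of standard survey software — with a plain
Wald interval available by flag. The design effect is this variance over
the binomial variance at the same $n$. Degenerate inputs (a single
cluster, or $\hat p \in \{0, 1\}$) are flagged with an undefined CI and a
conventional deff of 1 rather than silently extrapolated.

Calibration of this estimator is checked by simulation with a
beta-binomial cluster model (`simulate_cluster_flags()`), whose ICC is
exact by construction: at 51 clusters of 70, true prevalence 10% and ICC
tuned to deff 1.4, the 95% CI covers truth in ~95% of 500 replicates, and
with ICC 0 the mean design effect is ~1.

## The synthetic cohort generator

No participant-level data from the source survey are available, so every
analysis stage is exercised on synthetic cohorts whose *structure* — not
merely whose marginals — mimics the study:

1. **Frame and design.** 51 clusters of 80 enumerated persons per country,
   drawn by PPS from a synthetic census; one compact segment per cluster;
   independent person-level non-response at 13% (Cameroon) / 12% (India).
2. **Demographics.** Ten-year age bands with the published band
   proportions per country (uniform within band) and the published sex
   ratios.
3. **Latent impairment.** Per clinical domain, P(any impairment) =
   plogis(base + slope x age + cluster effect + frailty), with a severity
   ladder conditional on impairment. The age slopes (~0.07–0.095 per year)
   give the steep, roughly exponential age gradient characteristic of
   sensory and physical impairment. A shared person-level frailty (SD
   1.15 / 1.4 on the log-odds scale) induces comorbidity — the "multiple
   impairments" rate of roughly 2% — and a cluster random effect (SD
   0.50 / 0.45) induces a design effect near the 1.4 the design assumed.
4. **Measurements.** Drawn inside the latent grade's band (acuity uniform
   in the grade's decimal-acuity interval, recorded to two decimals;
   pure-tone average uniform in the grade's dBA band, one decimal), so the
   instrument classifiers recover the latent grade exactly and boundary
   behaviour is testable. Infant screens fail iff the latent grade is
   moderate-plus.
5. **Reporting.** Washington Group levels come from an ordered-categorical
   model: a latent continuous score (domain intercept + 0.03 x age +
   frailty and cluster terms + severity effect + logistic noise) cut at
   fixed thresholds for some / a lot / cannot do. The severity effect is
   `grade_coef x latent rank x (1 - underreport_domain)`. The
   `underreport` parameter implements the "hierarchy of disability":
   sensory impairments are reported far below physical ones. Calibrated
   defaults (Cameroon 0.5, India 0.08, MSI 0) make moderate sensory
   impairment most often yield "some" rather than "a lot", reproduce
   Category shares of roughly 21/32/47% (Cameroon) and 14/45/41% (India),
   and give two-stage cascade sensitivities above 0.9 against "a
   lot"-only sensitivities near 0.55. Cognitive-domain reporting is
   driven by depression and epilepsy status, which creates self-report-only
   cases in domains with no matching clinical screen, as observed.
6. **Downstream items.** PHQ-9 items are ordered draws from a person
   liability (so the three-item screen and composite arise mechanically);
   participation items increase with maximum severity and with being a
   self-reported case, making Category B adults the most restricted group;
   the direct single-question screen (India arm) is a logistic function of
   severity and self-report status, affirmed by only ~4% of the sample.

All generative parameters live in `cohort_config()` and were fixed once
against the published magnitudes (instrument prevalences, case-definition
prevalences, category shares, design effect); they are not fitted to any
particular generated cohort. `analytic_expectations()` marginalises the
same model by quadrature over age, frailty and cluster effect — exact when
the random-effect SDs are zero — and is the oracle for parameter-recovery
tests.

**What the generator does not emulate:** household structure and geography;
interviewer and translation effects; measurement error in the clinical
screens beyond band-uniform draws (notably the false positives that field
OAE testing suffers under background noise); respondent-type effects
(caregiver versus self-report is recorded but does not shift reporting);
and item-level Washington Group wording. Passing tests therefore
demonstrate the correctness of the analysis pipeline and the internal
consistency of the measurement model, not the field validity of the
instruments.

## Agreement analyses

* `matched_domain_crosstab()` tabulates the most severe clinical grade
  (vision/hearing/MSI; severe and profound collapsed) against the maximum
  reported level in the directly matched domains, restricted to ages 5+
  with gradable severity. For adults the MSI-matched report set is
  walking, upper-body strength and fine motor skills; the child module has
  no upper-body/fine-motor items, so for ages 5–17 walking alone is
  matched (a documented choice, configurable in spirit via the matched
  sets at the top of the module).
* `concordance_regression()` fits, among clinical cases, a logistic model
  of *also being a self-reported case* on age band (34–49 reference), sex,
  severity (moderate reference) and impairment type (vision reference;
  two-plus conditions are "multiple"). Epilepsy and depression are treated
  as severe conditions for the severity covariate, since the case
  definition classes them as severe; depression-only cases are excluded by
  default as sparse. Separation — an unbounded coefficient, detected by
  non-convergence, |log OR| > 10 or SE > 100 — flags the term and
  suppresses its CI; a constant outcome flags the whole fit. A saturated
  2x2 fit reproduces the closed-form cross-product odds ratio to 1e-6,
  which is the oracle used in tests.
* `participation_comparison()` compares mean participation scores across
  Categories A/B/C within children (5–16) and adults (17+), using
  pooled-variance Student t-tests for A-vs-B and B-vs-C because that is
  the analysis the design names; Welch is available by flag. Cells with
  fewer than two scores yield a flagged, undefined test.
* `definition_sweep()` re-classifies the cohort under the expanded
  self-report definitions ("some difficulty in any domain", "some in any
  two") and reports prevalences plus the share of baseline clinical-only
  cases that each expansion re-classifies into Category B. Monotonicity
  over the threshold lattice is a tested invariant.

## Numerical and interface choices

* Report levels and severity grades are ordered vocabularies
  (`report_levels()`, `severity_grades()`); comparisons go through rank
  helpers so that `"impaired_unclassified"` can count as moderate for case
  purposes yet be excluded from severity tables.
* Publication-style rounding (`round_half_up()`) is used when comparing
  against published percentages; two published figures that are not
  count-derivable (one category share and one near-zero cross-tab cell)
  are reported honestly as mismatches by `published_checks()`, and the
  published self-report/clinical sub-prevalences use denominators the
  printed counts do not recover, so they are flagged rather than asserted.
* Ties for the "most severe" impairment across domains break toward
  vision, then hearing, then MSI, for type attribution only (severity is
  compared on the common grade order).
* Every stochastic operation takes an explicit seed; `generate_cohort()`
  derives independent substreams for cluster selection, segment choice and
  person-level generation from one master seed, so cohorts are
  byte-reproducible.
* Tests run on deliberately small problem sizes — four-cluster cohorts for
  oracles, tiny three-cluster cohorts for the thousand-fold set-algebra
  sweep, 500 replicates for estimator calibration, full-size cohorts only
  where the published magnitudes are the point — keeping the default suite
  under a minute of simulation-heavy work while exercising every path.

## Limitations

The generator's reporting model is a single-index ordered-logit caricature:
it reproduces the qualitative overlap structure and calibrated aggregate
shares, but no claim is made that its parameters are identifiable from, or
transportable to, real Washington Group data. Published adjusted odds
ratios cannot be reproduced exactly without the original microdata; the
package reproduces the printed-count arithmetic exactly and the
model-based quantities structurally. The sampling layer omits
finite-population corrections, stratification and weighting, which the
self-weighted design it models does not use.
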