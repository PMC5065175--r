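# Two-stage cluster-survey design and estimation: sample size for a
# prevalence survey, probability-proportionate-to-size (PPS) cluster
# selection, compact segment sampling within clusters, and cluster-robust
# (Taylor-linearised) prevalence estimation with design effects.

#' Sample size for a cluster prevalence survey
#'
#' Standard normal-approximation sample size for estimating a prevalence
#' `p` to a relative precision, inflated by the design effect and the
#' anticipated non-response:
#' `ceiling(z^2 p (1 - p) / (rel_precision * p)^2 * deff / (1 - nonresponse))`
#' with `z` the standard-normal quantile at `(1 + confidence) / 2`.
#'
#' @param p Anticipated prevalence (0 < p < 1).
#' @param rel_precision Relative precision, e.g. `0.2` for a 95% CI
#'   half-width of 20% of `p`.
#' @param confidence Confidence level, default `0.95`.
#' @param deff Assumed design effect (>= 1), default 1.
#' @param nonresponse Anticipated non-response proportion, default 0.
#' @return Required number of enumerated participants (integer).
#' @export
#' @examples
#' sample_size(0.5, rel_precision = 0.1) # classic n = 385
#' sample_size(0.04, 0.20, deff = 1.4, nonresponse = 0.20)
sample_size <- function(p, rel_precision, confidence = 0.95, deff = 1,
                        nonresponse = 0) {
  if (!(p > 0 && p < 1)) stop("p must be in (0, 1)", call. = FALSE)
  if (!(rel_precision > 0 && rel_precision < 1)) {
    stop("rel_precision must be in (0, 1)", call. = FALSE)
  }
  if (!(confidence > 0 && confidence < 1)) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  if (deff < 1) stop("deff must be >= 1", call. = FALSE)
  if (!(nonresponse >= 0 && nonresponse < 1)) {
    stop("nonresponse must be in [0, 1)", call. = FALSE)
  }
  z <- stats::qnorm((1 + confidence) / 2)
  n <- z^2 * p * (1 - p) / (rel_precision * p)^2 * deff / (1 - nonresponse)
  as.integer(ceiling(n))
}

#' Systematic PPS cluster selection
#'
#' Selects `k` clusters with probability proportionate to size by
#' systematic sampling: the cumulative population is divided into `k`
#' equal intervals, a single uniform random start determines one
#' selection point per interval, and the unit whose cumulative range
#' contains each point is selected. Units larger than the sampling
#' interval may be selected more than once.
#'
#' @param units Data frame with columns `name` and `population`
#'   (positive).
#' @param k Number of clusters to select (`k <= nrow(units)`).
#' @param seed Optional integer seed for the random start.
#' @return Data frame of the `k` selections (rows of `units`, in
#'   selection order) with a `point` column giving each selection point.
#' @export
pps_select_clusters <- function(units, k, seed = NULL) {
  stopifnot(is.data.frame(units), all(c("name", "population") %in% names(units)))
  if (any(units$population <= 0)) stop("populations must be positive", call. = FALSE)
  if (k > nrow(units)) stop("k must not exceed the number of units", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  total <- sum(units$population)
  interval <- total / k
  start <- stats::runif(1, 0, interval)
  points <- start + (seq_len(k) - 1) * interval
  idx <- findInterval(points, cumsum(units$population)) + 1L
  out <- units[idx, , drop = FALSE]
  out$point <- points
  rownames(out) <- NULL
  out
}

#' Compact segment selection within a cluster
#'
#' The cluster map is divided into segments of approximately
#' `segment_size` people -- the segment count is the population divided
#' by the segment size, rounded half-up, minimum one -- and one segment
#' is selected uniformly at random for exhaustive enumeration.
#'
#' @param cluster_population Cluster population (>= `segment_size`).
#' @param segment_size Target segment size, default 80.
#' @param seed Optional integer seed.
#' @return List with `n_segments` and the selected `segment` (1-based).
#' @export
compact_segment_sample <- function(cluster_population, segment_size = 80,
                                   seed = NULL) {
  stopifnot(cluster_population >= segment_size)
  if (!is.null(seed)) set.seed(seed)
  n_segments <- max(1L, as.integer(floor(cluster_population / segment_size + 0.5)))
  list(n_segments = n_segments,
       segment = sample.int(n_segments, 1L))
}

#' Cluster-robust prevalence estimate
#'
#' Point estimate and 95% confidence interval for a proportion under a
#' self-weighted cluster sample. The point estimate is the plain sample
#' proportion; its variance uses the between-cluster Taylor-linearised
#' estimator: with cluster case totals \eqn{y_i}, cluster sizes
#' \eqn{m_i} and \eqn{k} clusters,
#' \deqn{\widehat{var}(\hat p) = \frac{k}{k-1}
#'   \frac{\sum_i (y_i - \hat p m_i)^2}{(\sum_i m_i)^2}.}
#' The CI is computed on the logit scale and back-transformed, using a
#' t quantile with `k - 1` degrees of freedom (a plain Wald interval is
#' available via `ci_method = "wald"`). The design effect is the ratio of
#' this variance to the binomial variance `p(1-p)/n` of a simple random
#' sample of the same size.
#'
#' @param case_flags Logical (or 0/1) case indicator per participant.
#' @param cluster_ids Cluster identifier per participant.
#' @param conf Confidence level, default 0.95.
#' @param ci_method `"logit"` (default) or `"wald"`.
#' @return Object of class `prevalence_estimate`: list with `point`,
#'   `ci_low`, `ci_high`, `se`, `n`, `n_clusters`, `deff`, and
#'   `degenerate` (TRUE when a CI is undefined: a single cluster, or a
#'   point estimate of exactly 0 or 1, for which `deff` is reported as 1
#'   by convention).
#' @export
#' @examples
#' set.seed(1)
#' cl <- rep(1:20, each = 30)
#' estimate_prevalence(stats::rbinom(600, 1, 0.1), cl)
estimate_prevalence <- function(case_flags, cluster_ids, conf = 0.95,
                                ci_method = c("logit", "wald")) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(case_flags) == length(cluster_ids))
  y <- as.numeric(case_flags)
  stopifnot(all(y %in% c(0, 1)))
  n <- length(y)
  m_i <- tapply(y, cluster_ids, length)
  y_i <- tapply(y, cluster_ids, sum)
  k <- length(m_i)
  p <- sum(y_i) / n

  degenerate <- k < 2 || p == 0 || p == 1
  if (degenerate) {
    est <- list(point = p, ci_low = NA_real_, ci_high = NA_real_,
                se = NA_real_, n = n, n_clusters = k, deff = 1,
                degenerate = TRUE)
    return(structure(est, class = "prevalence_estimate"))
  }

  v <- k / (k - 1) * sum((y_i - p * m_i)^2) / n^2
  se <- sqrt(v)
  deff <- v / (p * (1 - p) / n)
  tq <- stats::qt(1 - (1 - conf) / 2, df = k - 1)
  if (ci_method == "logit" && se > 0) {
    l <- stats::qlogis(p)
    se_l <- se / (p * (1 - p))
    ci <- stats::plogis(l + c(-1, 1) * tq * se_l)
  } else {
    ci <- pmin(1, pmax(0, p + c(-1, 1) * tq * se))
  }
  structure(list(point = p, ci_low = ci[1], ci_high = ci[2], se = se,
                 n = n, n_clusters = k, deff = deff, degenerate = FALSE),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Prevalence %.1f%% (n = %d, %d cluster%s; CI undefined)\n",
                100 * x$point, x$n, x$n_clusters,
                if (x$n_clusters == 1) "" else "s"))
  } else {
    cat(sprintf("Prevalence %.1f%% (95%% CI %.1f-%.1f), n = %d, %d clusters, deff = %.2f\n",
                100 * x$point, 100 * x$ci_low, 100 * x$ci_high,
                x$n, x$n_clusters, x$deff))
  }
  invisible(x)
}

#' Intracluster correlation implied by a design effect
#'
#' For equal cluster sizes `m`, `deff = 1 + (m - 1) * icc`.
#'
#' @param deff Target design effect (>= 1).
#' @param cluster_size Cluster size `m`.
#' @return The intracluster correlation.
#' @export
#' @examples
#' icc_for_deff(1.4, 70)
icc_for_deff <- function(deff, cluster_size) {
  stopifnot(deff >= 1, cluster_size > 1)
  (deff - 1) / (cluster_size - 1)
}

#' Simulate clustered binary outcomes with a known ICC
#'
#' Beta-binomial cluster simulation: cluster-level probabilities are drawn
#' from a Beta distribution with mean `p` and intracluster correlation
#' `icc` (so the expected design effect at cluster size `m` is
#' `1 + (m - 1) * icc`), and individual case flags are Bernoulli within
#' clusters. With `icc = 0` the draw is plain binomial.
#'
#' @param n_clusters,cluster_size Design dimensions.
#' @param p True prevalence.
#' @param icc Intracluster correlation in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Data frame with `cluster_id` and logical `case`.
#' @export
simulate_cluster_flags <- function(n_clusters, cluster_size, p, icc = 0,
                                   seed = NULL) {
  stopifnot(p > 0, p < 1, icc >= 0, icc < 1)
  if (!is.null(seed)) set.seed(seed)
  if (icc == 0) {
    p_i <- rep(p, n_clusters)
  } else {
    a <- p * (1 - icc) / icc
    b <- (1 - p) * (1 - icc) / icc
    p_i <- stats::rbeta(n_clusters, a, b)
  }
  data.frame(cluster_id = rep(seq_len(n_clusters), each = cluster_size),
             case = stats::runif(n_clusters * cluster_size) <
               rep(p_i, each = cluster_size))
}
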