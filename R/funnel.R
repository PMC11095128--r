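#' Funnel-plot prediction limits around a benchmark
#'
#' Prediction limits for the observed event rate of a hospital whose true
#' rate equals the benchmark, as a function of its volume.  The default
#' `"exact"` method works on the binomial count scale: the upper limit is
#' the smallest count whose upper tail probability under
#' `Binomial(n, p0)` is at most `(1 - level)/2`, the lower limit the
#' largest count whose lower tail is at most `(1 - level)/2`.  A count on a
#' limit is still consistent with the benchmark (classification flags only
#' counts strictly outside), so the exact region is conservative --
#' deliberately so, because at audit volumes (n around 20) and rare events
#' (mortality around 0.6%) the normal approximation is badly
#' anticonservative.  The `"normal"` method `p0 +/- z * sqrt(p0(1-p0)/n)`
#' is provided for comparability with common funnel-plot software.
#'
#' Degenerate benchmarks (`p0` of 0 or 1) put all null probability mass on
#' one count; both limits collapse onto it.
#'
#' @param p0 Benchmark proportion.
#' @param volumes Integer volumes (>= 1) at which to evaluate the limits.
#' @param level Prediction level, default 0.95.
#' @param method `"exact"` (binomial) or `"normal"`.
#' @return Data frame of class `funnel_curve`: `volume`, `lower`, `upper`
#'   (rates) and, for the exact method, `lower_count`, `upper_count`.
#'   Attributes `p0`, `level`, `method`.
#' @examples
#' funnel_limits(0.027, c(20, 50, 100, 200))
#' @export
funnel_limits <- function(p0, volumes, level = 0.95,
                          method = c("exact", "normal")) {
  method <- match.arg(method)
  check_probability(p0, "p0")
  if (length(p0) != 1) stop("'p0' must be a single benchmark", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop("'level' must be in (0, 1)", call. = FALSE)
  if (any(volumes < 1)) stop("'volumes' must be at least 1", call. = FALSE)
  volumes <- as.integer(volumes)
  a2 <- (1 - level) / 2
  if (method == "normal") {
    z <- stats::qnorm(1 - a2)
    hw <- z * sqrt(p0 * (1 - p0) / volumes)
    out <- data.frame(volume = volumes,
                      lower = pmax(0, p0 - hw),
                      upper = pmin(1, p0 + hw))
  } else {
    lims <- vapply(volumes, function(n) exact_limit_counts(p0, n, a2),
                   c(lower = 0, upper = 0))
    out <- data.frame(volume = volumes,
                      lower = lims["lower", ] / volumes,
                      upper = lims["upper", ] / volumes,
                      lower_count = as.integer(lims["lower", ]),
                      upper_count = as.integer(lims["upper", ]))
  }
  structure(out, p0 = p0, level = level, method = method,
            class = c("funnel_curve", "data.frame"))
}

# Exact two-sided binomial limit counts with tail mass <= a2 on each side.
exact_limit_counts <- function(p0, n, a2) {
  if (p0 == 0) return(c(lower = 0, upper = 0))
  if (p0 == 1) return(c(lower = n, upper = n))
  # upper: smallest c with P(X >= c) <= a2
  u <- stats::qbinom(1 - a2, n, p0) + 1L
  while (u - 1L >= 0L &&
         1 - stats::pbinom(u - 2L, n, p0) <= a2) u <- u - 1L
  u <- min(u, n)
  # lower: largest c with P(X <= c) <= a2 (0 when even c = 0 exceeds a2,
  # meaning no count can fall below the limit)
  l <- stats::qbinom(a2, n, p0)
  if (stats::pbinom(l, n, p0) > a2) l <- l - 1L
  while (l + 1L <= n && stats::pbinom(l + 1L, n, p0) <= a2) l <- l + 1L
  l <- max(l, 0L)
  c(lower = as.numeric(l), upper = as.numeric(u))
}

#' Classify hospitals against funnel-plot limits
#'
#' A hospital is an outlier when its observed rate falls strictly outside
#' the prediction limits at its own volume; counts exactly on a limit are
#' `WITHIN`.  For adverse indicators (direction `"increase"`) performance
#' is `WORSE` above the upper limit; for composite outcomes (direction
#' `"decrease"`) `WORSE` lies below the lower limit.  Better-than-benchmark
#' deviations are classified `BETTER` and reported, but national
#' benchmarking deliberately acts on the worse side only.  The exact method
#' compares event counts, so classification cannot drift across a boundary
#' through floating-point representation of rates.
#'
#' @param summaries Data frame with columns `numerator` and `denominator`
#'   (e.g. rows of [indicator_summaries()]), or `rate` and `denominator`
#'   for the normal method.
#' @param p0 Benchmark proportion.
#' @param direction `"increase"` or `"decrease"` (which side is adverse).
#' @param level Prediction level, default 0.95.
#' @param method `"exact"` or `"normal"`.
#' @return `summaries` with added columns `rate`, `lower`, `upper` and
#'   `status` (`"WITHIN"`, `"WORSE"`, `"BETTER"`, or `"UNDEFINED"` for
#'   empty denominators).
#' @examples
#' s <- data.frame(hospital_id = c("A", "B"), numerator = c(1, 9),
#'                 denominator = c(30, 30))
#' classify_outliers(s, p0 = 0.05, direction = "increase")
#' @export
classify_outliers <- function(summaries, p0,
                              direction = c("increase", "decrease"),
                              level = 0.95, method = c("exact", "normal")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  if (!"denominator" %in% names(summaries))
    stop("'summaries' needs a 'denominator' column", call. = FALSE)
  if (!"numerator" %in% names(summaries)) {
    if (!"rate" %in% names(summaries))
      stop("'summaries' needs 'numerator' or 'rate'", call. = FALSE)
    summaries$numerator <- summaries$rate * summaries$denominator
  }
  n <- summaries$denominator
  x <- summaries$numerator
  rate <- ifelse(n > 0, x / n, NA_real_)
  lower <- upper <- rep(NA_real_, length(n))
  status <- rep("UNDEFINED", length(n))
  ok <- which(n > 0)
  for (i in ok) {
    lim <- funnel_limits(p0, n[i], level, method)
    lower[i] <- lim$lower; upper[i] <- lim$upper
    if (method == "exact") {
      above <- x[i] > lim$upper_count
      below <- x[i] < lim$lower_count
    } else {
      above <- rate[i] > lim$upper
      below <- rate[i] < lim$lower
    }
    status[i] <- if (direction == "increase") {
      if (above) "WORSE" else if (below) "BETTER" else "WITHIN"
    } else {
      if (below) "WORSE" else if (above) "BETTER" else "WITHIN"
    }
  }
  out <- summaries
  out$rate <- rate
  out$lower <- lower
  out$upper <- upper
  out$status <- status
  out
}

#' Empirical probability of flagging a designated outlier hospital
#'
#' Simulates the designated hospital of an outlier scenario over many
#' seeded replicates, summarises the targeted indicator each time, and
#' reports the fraction of replicates in which the hospital is classified
#' `WORSE` than the benchmark.  Because every hospital draws from its own
#' RNG substream, simulating the designated hospital alone yields exactly
#' the records it would have inside the full registry, so replicates stay
#' cheap at any registry size.
#'
#' Classifier `"test"` applies the two-sided arcsine one-sample proportion
#' test (the package's design test; a rejection with the deviation on the
#' adverse side counts as `WORSE`).  Classifier `"funnel"` applies
#' exact-binomial funnel limits at the replicate's denominator.
#'
#' @param scenario A `sim_config`, normally from [scenario_with_outlier()];
#'   the targeted hospital/indicator are read from its `outlier` attribute
#'   unless given explicitly.
#' @param p0 Benchmark proportion the hospital is judged against.
#' @param replicates Number of replicates.
#' @param seed Seed governing all replicates.
#' @param classifier `"test"` or `"funnel"`.
#' @param level Prediction level for the funnel classifier.
#' @param spec [power_spec()] for the test classifier.
#' @param los_thresholds Optional fixed LOS thresholds for composite
#'   indicators (defaults to thresholds computed from the replicate's own
#'   records, which is only meaningful for large volumes).
#' @param hospital_id,procedure,indicator Override the scenario attribute.
#' @return List: `rate` (detection probability), `replicates`, `worse`
#'   (logical vector), plus the scenario descriptors.
#' @export
detection_rate <- function(scenario, p0, replicates = 2000, seed = 1L,
                           classifier = c("test", "funnel"), level = 0.95,
                           spec = power_spec(), los_thresholds = NULL,
                           hospital_id = NULL, procedure = NULL,
                           indicator = NULL) {
  classifier <- match.arg(classifier)
  meta <- attr(scenario, "outlier")
  hospital_id <- hospital_id %||% meta$hospital_id
  procedure <- match_procedure(procedure %||% meta$procedure)
  indicator <- match_indicator(indicator %||% meta$indicator)
  if (is.null(hospital_id))
    stop("no designated hospital: pass 'hospital_id' or use scenario_with_outlier()",
         call. = FALSE)
  direction <- indicator_direction(indicator)
  profiles <- scenario$profiles[
    scenario$profiles$hospital_id == hospital_id &
      scenario$profiles$procedure == procedure, , drop = FALSE]
  if (nrow(profiles) != 1)
    stop("designated hospital has no profile for this procedure",
         call. = FALSE)
  worse <- logical(replicates)
  for (r in seq_len(replicates)) {
    master <- substream_seed(seed, paste0("replicate-", r))
    rec <- preserve_rng(simulate_hospital(profiles, scenario$years, master))
    if (indicator == "MORTALITY") {
      x <- sum(mortality_flag(rec)); n <- nrow(rec)
    } else if (indicator == "MAJOR_MORBIDITY") {
      x <- sum(major_morbidity_flag(rec)); n <- nrow(rec)
    } else if (indicator == "FTR") {
      f <- ftr_summary(rec); x <- f$numerator; n <- f$denominator
    } else {
      thr <- los_thresholds %||% los_thresholds(rec)
      flags <- composite_flag(rec, thr)
      x <- sum(flags, na.rm = TRUE); n <- sum(!is.na(flags))
    }
    if (n == 0) { worse[r] <- FALSE; next }
    if (classifier == "test") {
      tst <- one_sample_prop_test(x, n, p0, spec)
      adverse_side <- if (direction == "increase") x / n > p0 else x / n < p0
      worse[r] <- tst$reject && adverse_side
    } else {
      cls <- classify_outliers(data.frame(numerator = x, denominator = n),
                               p0, direction, level, "exact")
      worse[r] <- cls$status == "WORSE"
    }
  }
  list(rate = mean(worse), replicates = replicates, worse = worse,
       hospital_id = hospital_id, procedure = procedure,
       indicator = indicator, p0 = p0, classifier = classifier)
}
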