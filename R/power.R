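#' Design parameters for the one-sample proportion test
#'
#' Bundles the two-sided significance level and the power together with the
#' implied standard-normal quantiles that drive every sample-size
#' computation in the package.  Quantiles are kept at double precision
#' rather than the two-decimal textbook values; the difference is below the
#' one-decimal reporting precision but fixing the choice makes results
#' reproducible bit for bit.
#'
#' @param alpha Two-sided significance level, in (0, 1). Default 0.05.
#' @param power Target power (1 - beta), in (0, 1). Default 0.80.
#' @return An object of class `power_spec`: a list with `alpha`, `power`,
#'   `z_alpha` (upper alpha/2 quantile) and `z_beta` (upper 1-power
#'   quantile).
#' @examples
#' power_spec()
#' @export
power_spec <- function(alpha = 0.05, power = 0.80) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single value in (0, 1)", call. = FALSE)
  if (!is.numeric(power) || length(power) != 1 || power <= 0 || power >= 1)
    stop("'power' must be a single value in (0, 1)", call. = FALSE)
  structure(
    list(alpha = alpha, power = power,
         z_alpha = stats::qnorm(1 - alpha / 2),
         z_beta = stats::qnorm(power)),
    class = "power_spec"
  )
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf(
    "One-sample proportion design: alpha = %g (two-sided), power = %g\n",
    x$alpha, x$power))
  cat(sprintf("  z_alpha = %.6f, z_beta = %.6f\n", x$z_alpha, x$z_beta))
  invisible(x)
}

as_power_spec <- function(spec) {
  if (inherits(spec, "power_spec")) spec else power_spec()
}

#' Arcsine effect size for two proportions
#'
#' Cohen's h, the variance-stabilised difference
#' `2*asin(sqrt(p1)) - 2*asin(sqrt(p0))`.  On this scale the sampling
#' variance of a proportion is approximately `1/(4n)` regardless of the
#' rate, which is what makes the sample-size formula a clean closed form
#' even for rare events such as postoperative mortality.
#'
#' @param p0 Benchmark proportion(s) in \[0, 1\].
#' @param p1 Alternative proportion(s) in \[0, 1\].
#' @return Signed effect size; antisymmetric in its arguments.
#' @examples
#' effect_size_h(0.006, 0.056)
#' @export
effect_size_h <- function(p0, p1) {
  check_probability(p0, "p0")
  check_probability(p1, "p1")
  2 * asin(sqrt(p1)) - 2 * asin(sqrt(p0))
}

#' Required total sample size to detect a shifted proportion
#'
#' Minimum total caseload for a two-sided one-sample proportion test of
#' H0: p = p0 against the alternative p = p1 to reach the design power:
#' `n = ((z_alpha + z_beta) / h)^2` with `h = effect_size_h(p0, p1)`.
#' The value is returned continuous; callers decide how to round (see
#' [min_annual_volume()] for the convention used in volume requirements).
#'
#' @inheritParams effect_size_h
#' @param spec A [power_spec()].
#' @return Required total sample size (real-valued, vectorised over `p0`,
#'   `p1`).  `Inf` when `p0 == p1` (no difference is ever detectable).
#' @examples
#' required_n(0.006, 0.056)       # ~75.4: three years of 25 resections
#' @export
required_n <- function(p0, p1, spec = power_spec()) {
  spec <- as_power_spec(spec)
  h <- effect_size_h(p0, p1)
  n <- ((spec$z_alpha + spec$z_beta) / h)^2
  n[h == 0] <- Inf
  n
}

#' Smallest detectable difference at a given hospital volume
#'
#' Inverts the sample-size relation: at total volume `n`, the nearest
#' alternative that the design can distinguish from the benchmark is
#' `p1 = sin^2(asin(sqrt(p0)) + s * (z_alpha + z_beta) / (2 * sqrt(n)))`
#' with `s = +1` when only increases are adverse (mortality, major
#' morbidity, failure to rescue) and `s = -1` for composite outcomes, where
#' a decrease signals worse care.  When the arcsine argument leaves
#' \[0, pi/2\] the alternative saturates at 0 or 1 and the cell is flagged.
#'
#' @param p0 Benchmark proportion. Must leave room on the chosen side
#'   (`p0 < 1` for increases, `p0 > 0` for decreases).
#' @param n Total volume(s), at least 1. Vectorised.
#' @param direction `"increase"` or `"decrease"`.
#' @param spec A [power_spec()].
#' @return A data frame with one row per volume: `p0`, `n`, `direction`,
#'   `p1`, `difference` (|p1 - p0|, as a proportion, full precision),
#'   `points` (the difference in percentage points rounded half-up to one
#'   decimal, the reporting convention), and `saturated`.
#' @examples
#' detectable_difference(0.006, c(20, 50, 100))    # 13.9, 6.8, 4.1 points
#' detectable_difference(0.736, 20, "decrease")    # 30.3 points
#' @export
detectable_difference <- function(p0, n, direction = c("increase", "decrease"),
                                  spec = power_spec()) {
  direction <- match.arg(direction)
  spec <- as_power_spec(spec)
  check_probability(p0, "p0")
  if (length(p0) != 1) stop("'p0' must be a single benchmark", call. = FALSE)
  if (any(n < 1)) stop("'n' must be at least 1", call. = FALSE)
  if (direction == "increase" && p0 >= 1)
    stop("no detectable increase above p0 = 1", call. = FALSE)
  if (direction == "decrease" && p0 <= 0)
    stop("no detectable decrease below p0 = 0", call. = FALSE)
  s <- if (direction == "increase") 1 else -1
  phi <- asin(sqrt(p0)) + s * (spec$z_alpha + spec$z_beta) / (2 * sqrt(n))
  saturated <- phi < 0 | phi > pi / 2
  phi <- pmin(pmax(phi, 0), pi / 2)
  p1 <- sin(phi)^2
  difference <- abs(p1 - p0)
  data.frame(
    p0 = p0, n = as.numeric(n), direction = direction, p1 = p1,
    difference = difference,
    points = round_half_up(100 * difference, 1),
    saturated = saturated
  )
}

#' Minimum annual hospital volume to detect a given absolute difference
#'
#' Total required caseload for detecting `p0 +/- delta`, spread over `years`
#' pooled registration years.  The annual requirement uses
#' `floor(total / years)`: the convention that reproduces the published
#' volume statements for a 5-point mortality increase over three pooled
#' years (25 minor LR, 54 major LR, 48 PD, 25 DP).
#'
#' @param p0 Benchmark proportion.
#' @param delta Absolute difference to detect, > 0.
#' @param direction `"increase"` (adverse indicators) or `"decrease"`
#'   (composite outcomes).
#' @param years Number of pooled registration years, >= 1.
#' @param spec A [power_spec()].
#' @return One-row data frame: `p0`, `p1`, `delta`, `direction`, `years`,
#'   `n_total` (continuous) and `annual_volume`.
#' @examples
#' min_annual_volume(0.027, 0.05, years = 3)               # 48 PDs a year
#' min_annual_volume(0.468, 0.15, "decrease", years = 3)   # 27 PDs a year
#' @export
min_annual_volume <- function(p0, delta, direction = c("increase", "decrease"),
                              years = 1, spec = power_spec()) {
  direction <- match.arg(direction)
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0)
    stop("'delta' must be a single positive difference", call. = FALSE)
  if (!is.numeric(years) || length(years) != 1 || years < 1)
    stop("'years' must be at least 1", call. = FALSE)
  p1 <- if (direction == "increase") p0 + delta else p0 - delta
  if (p1 < 0 || p1 > 1)
    stop(sprintf("configuration error: 'p0 %s delta' leaves [0, 1]",
                 if (direction == "increase") "+" else "-"), call. = FALSE)
  n_total <- required_n(p0, p1, spec)
  data.frame(
    p0 = p0, p1 = p1, delta = delta, direction = direction,
    years = years, n_total = n_total,
    annual_volume = floor(n_total / years)
  )
}

#' Detectable-difference grid across indicators, procedures and volumes
#'
#' Expands a benchmark table into the full grid of smallest detectable
#' differences: adverse indicators invert upwards from the benchmark,
#' composite outcomes downwards.  Missing benchmark entries yield flagged
#' absent cells; the grid is still emitted.
#'
#' @param benchmarks Data frame with columns `procedure`, `indicator` and
#'   `p0` (see [benchmark_table()] or [dutch_hpb_benchmarks()]).
#' @param volumes Total volumes at which to invert. Default
#'   `c(20, 40, 50, 100, 200)`, the current and proposed Dutch minimum
#'   volume standards over one- and two-year periods.
#' @param spec A [power_spec()].
#' @return Data frame with columns `indicator`, `volume`, `procedure`,
#'   `p0`, `direction`, `p1`, `difference`, `points`, `saturated`,
#'   `absent`.
#' @examples
#' threshold_table(dutch_hpb_benchmarks(), volumes = c(20, 50))
#' @export
threshold_table <- function(benchmarks, volumes = c(20, 40, 50, 100, 200),
                            spec = power_spec()) {
  stopifnot(all(c("procedure", "indicator", "p0") %in% names(benchmarks)))
  spec <- as_power_spec(spec)
  grid <- expand.grid(indicator = INDICATORS, volume = volumes,
                      procedure = PROCEDURES, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$indicator, INDICATORS), grid$volume,
                     match(grid$procedure, PROCEDURES)), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    b <- benchmarks[benchmarks$procedure == g$procedure &
                      benchmarks$indicator == g$indicator, , drop = FALSE]
    base <- data.frame(indicator = g$indicator, volume = g$volume,
                       procedure = g$procedure)
    if (nrow(b) == 0 || is.na(b$p0[1])) {
      return(cbind(base, p0 = NA_real_, direction = NA_character_,
                   p1 = NA_real_, difference = NA_real_, points = NA_real_,
                   saturated = NA, absent = TRUE))
    }
    dir <- indicator_direction(g$indicator)
    d <- detectable_difference(b$p0[1], g$volume, dir, spec)
    cbind(base, p0 = d$p0, direction = d$direction, p1 = d$p1,
          difference = d$difference, points = d$points,
          saturated = d$saturated, absent = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Volume requirements across benchmark shift scenarios and pooling windows
#'
#' For every benchmark entry, computes the total and annual caseload needed
#' to detect the published scenarios: a two-fold benchmark rate (adverse
#' indicators only) and absolute 2-, 5- and 15-point shifts -- increases for
#' adverse indicators, decreases for composite outcomes -- over 1, 2, 3, 5
#' and 8 pooled years.
#'
#' @inheritParams threshold_table
#' @param deltas Absolute shifts, as proportions. Default
#'   `c(0.02, 0.05, 0.15)`.
#' @param twofold Include the two-fold-benchmark scenario for adverse
#'   indicators. Default `TRUE`.
#' @param years Pooling windows. Default `c(1, 2, 3, 5, 8)`.
#' @return Data frame: `procedure`, `indicator`, `scenario`, `p0`, `p1`,
#'   `direction`, `years`, `n_total`, `annual_volume`.  Scenarios that push
#'   the alternative outside \[0, 1\] are dropped with a message.
#' @export
volume_requirements <- function(benchmarks, deltas = c(0.02, 0.05, 0.15),
                                twofold = TRUE, years = c(1, 2, 3, 5, 8),
                                spec = power_spec()) {
  stopifnot(all(c("procedure", "indicator", "p0") %in% names(benchmarks)))
  rows <- list()
  for (i in seq_len(nrow(benchmarks))) {
    b <- benchmarks[i, ]
    if (is.na(b$p0)) next
    dir <- indicator_direction(b$indicator)
    scen <- data.frame(
      scenario = sprintf("%s%gpts", if (dir == "increase") "+" else "-",
                         100 * deltas),
      delta = deltas)
    if (twofold && dir == "increase" && b$p0 > 0)
      scen <- rbind(data.frame(scenario = "TWO_FOLD", delta = b$p0), scen)
    for (j in seq_len(nrow(scen))) {
      delta <- scen$delta[j]
      p1 <- if (dir == "increase") b$p0 + delta else b$p0 - delta
      if (p1 < 0 || p1 > 1 || delta == 0) {
        message(sprintf("skipping %s %s %s: alternative outside [0, 1]",
                        b$procedure, b$indicator, scen$scenario[j]))
        next
      }
      for (k in years) {
        mv <- min_annual_volume(b$p0, delta, dir, k, spec)
        rows[[length(rows) + 1]] <- data.frame(
          procedure = b$procedure, indicator = b$indicator,
          scenario = scen$scenario[j], p0 = b$p0, p1 = p1,
          direction = dir, years = k, n_total = mv$n_total,
          annual_volume = mv$annual_volume)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proportion of hospitals whose pooled caseload meets a requirement
#'
#' Compares each hospital's summed volume over the pooling window with the
#' total sample size a scenario requires.
#'
#' @param volumes Either a data frame with columns `hospital_id`, `year`,
#'   `volume` (see [hospital_volumes()]), or a numeric vector of constant
#'   annual volumes (one per hospital, optionally named).
#' @param required_total Required total caseload (may be continuous, as
#'   returned in `n_total` by [min_annual_volume()]).
#' @param years Pooling window: the hospital's volume is summed over the
#'   most recent `years` registry years.
#' @return List of class `adequacy_report`: `proportion`, `n_hospitals`,
#'   `required_total`, `years`, `table` (per-hospital pooled volume and
#'   whether it meets the requirement), `empty` flag.
#' @examples
#' adequacy_report(c(30, 60), required_total = 50)
#' @export
adequacy_report <- function(volumes, required_total, years = 1) {
  if (is.numeric(volumes) && is.null(dim(volumes))) {
    ids <- names(volumes) %||% sprintf("H%02d", seq_along(volumes))
    volumes <- data.frame(hospital_id = rep(ids, each = years),
                          year = rep(seq_len(years), times = length(ids)),
                          volume = rep(as.numeric(volumes), each = years))
  }
  stopifnot(all(c("hospital_id", "year", "volume") %in% names(volumes)))
  if (any(volumes$volume < 0))
    stop("volumes must be non-negative", call. = FALSE)
  if (nrow(volumes) == 0) {
    return(structure(list(proportion = NA_real_, n_hospitals = 0L,
                          required_total = required_total, years = years,
                          table = NULL, empty = TRUE),
                     class = "adequacy_report"))
  }
  last_years <- sort(unique(volumes$year), decreasing = TRUE)[seq_len(
    min(years, length(unique(volumes$year))))]
  pool <- volumes[volumes$year %in% last_years, , drop = FALSE]
  pooled <- tapply(pool$volume, pool$hospital_id, sum)
  ids <- unique(volumes$hospital_id)
  pooled <- ifelse(is.na(pooled[ids]), 0, pooled[ids])
  tab <- data.frame(hospital_id = ids, pooled_volume = as.numeric(pooled),
                    meets = as.numeric(pooled) >= required_total)
  structure(list(proportion = mean(tab$meets), n_hospitals = length(ids),
                 required_total = required_total, years = years,
                 table = tab, empty = FALSE),
            class = "adequacy_report")
}

#' @export
print.adequacy_report <- function(x, ...) {
  if (x$empty) {
    cat("Adequacy report: no hospitals (flagged empty)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Adequacy: %d/%d hospitals (%.1f%%) reach a pooled volume of %.1f over %d year(s)\n",
    sum(x$table$meets), x$n_hospitals, 100 * x$proportion,
    x$required_total, x$years))
  invisible(x)
}

#' Two-sided one-sample proportion test on the arcsine scale
#'
#' The test whose power calculation underlies the whole package:
#' `z = (2*asin(sqrt(x/n)) - 2*asin(sqrt(p0))) * sqrt(n)`, referred to the
#' standard normal.  At the design alternative returned by
#' [detectable_difference()] its rejection rate recovers the design power.
#'
#' @param x Event count.
#' @param n Denominator, >= 1.
#' @param p0 Null (benchmark) proportion.
#' @param spec A [power_spec()]; its `alpha` fixes the rejection threshold.
#' @return List with `estimate`, `statistic` (z), `p.value` and `reject`.
#' @export
one_sample_prop_test <- function(x, n, p0, spec = power_spec()) {
  spec <- as_power_spec(spec)
  if (n < 1 || x < 0 || x > n)
    stop("need 0 <= x <= n with n >= 1", call. = FALSE)
  check_probability(p0, "p0")
  z <- (2 * asin(sqrt(x / n)) - 2 * asin(sqrt(p0))) * sqrt(n)
  list(estimate = x / n, statistic = z,
       p.value = 2 * stats::pnorm(-abs(z)),
       reject = abs(z) > spec$z_alpha)
}
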