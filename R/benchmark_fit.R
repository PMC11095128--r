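#' Fit national benchmarks to a patient-level audit registry
#'
#' The package's central estimator.  Given patient-level records it
#' computes, over the benchmark window: per-hospital and national
#' indicator summaries, the benchmark table (national pooled rates with
#' across-hospital ranges), the length-of-stay percentile thresholds the
#' composites depend on, per-procedure component rates, and per-hospital
#' annual caseloads.  The returned object supports the usual modelling
#' verbs: `coef()` returns the benchmark matrix, `predict()` the
#' detectable-difference grid at chosen volumes, `plot()` a funnel plot,
#' `residuals()` standardised (arcsine-scale) hospital deviations from the
#' benchmark, and `simulate()` regenerates synthetic registries at the
#' fitted rates and volumes -- the parametric-bootstrap null a funnel plot
#' assumes.
#'
#' @param records Registry data frame (see [simulate_registry()] /
#'   [read_registry()]).
#' @param window Benchmark window, an integer vector of years; defaults to
#'   all years present.
#' @return Object of class `hpb_benchmark`.
#' @examples
#' reg <- simulate_registry(audit_sim_config(seed = 5))
#' fit <- hpb_benchmark(reg, window = 2020:2021)
#' coef(fit)
#' predict(fit, volumes = c(20, 50))
#' @export
hpb_benchmark <- function(records, window = NULL) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(REGISTRY_COLUMNS, names(records))
  if (length(missing) > 0)
    stop(sprintf("registry lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  window <- sort(unique(as.integer(window %||% records$year)))
  win_records <- subset_window(records, window)
  if (nrow(win_records) == 0)
    stop("no records inside the benchmark window", call. = FALSE)
  thresholds <- los_thresholds(win_records)
  summaries <- indicator_summaries(win_records, thresholds = thresholds)
  benchmarks <- benchmark_table(win_records, thresholds = thresholds)
  vols <- hospital_volumes(win_records)
  structure(
    list(benchmarks = benchmarks, summaries = summaries,
         thresholds = thresholds,
         exclusions = attr(summaries, "exclusions"),
         components = estimate_components(win_records),
         volumes = vols, window = window,
         n_records = nrow(win_records), call = match.call()),
    class = "hpb_benchmark")
}

# National per-procedure component rates; the generative parameters
# simulate() uses.
estimate_components <- function(records) {
  out <- lapply(intersect(PROCEDURES, unique(records$procedure)),
                function(proc) {
    rp <- records[records$procedure == proc, , drop = FALSE]
    sev <- major_morbidity_flag(rp)
    dth <- mortality_flag(rp)
    m <- mean(rp$los_days); v <- stats::var(rp$los_days)
    data.frame(
      procedure = proc,
      p_severe = mean(sev),
      p_death_given_severe = if (any(sev)) mean(dth[sev]) else 0,
      p_death_given_not_severe = if (any(!sev)) mean(dth[!sev]) else 0,
      p_readmission = mean(rp$readmission),
      p_margin_adequate = if (proc %in% LIVER_PROCEDURES)
        mean(rp$margin_adequate, na.rm = TRUE) else NA_real_,
      p_popf_bc = if (proc %in% PANCREAS_PROCEDURES)
        mean(rp$popf_bc, na.rm = TRUE) else NA_real_,
      p_reoperation = if (proc %in% PANCREAS_PROCEDURES)
        mean(rp$reoperation, na.rm = TRUE) else NA_real_,
      los_median = stats::median(rp$los_days),
      los_size = if (!is.na(v) && v > m) m^2 / (v - m) else 1e6)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' @export
print.hpb_benchmark <- function(x, ...) {
  cat(sprintf("HPB quality-indicator benchmark fit (window %s)\n",
              window_label(x$window)))
  cat(sprintf("  %d records, %d hospitals, %d procedure group(s)\n",
              x$n_records,
              length(unique(x$summaries$hospital_id[
                x$summaries$hospital_id != "NATIONAL"])),
              length(unique(x$benchmarks$procedure))))
  cat("Benchmarks (national pooled rate, %):\n")
  print(round(100 * coef(x), 1))
  invisible(x)
}

#' @export
coef.hpb_benchmark <- function(object, ...) {
  m <- matrix(NA_real_, nrow = length(INDICATORS),
              ncol = length(PROCEDURES),
              dimnames = list(INDICATORS, PROCEDURES))
  b <- object$benchmarks
  for (i in seq_len(nrow(b))) m[b$indicator[i], b$procedure[i]] <- b$p0[i]
  m[, colSums(!is.na(m)) > 0, drop = FALSE]
}

#' @export
summary.hpb_benchmark <- function(object, ...) {
  structure(list(fit = object), class = "summary.hpb_benchmark")
}

#' @export
print.summary.hpb_benchmark <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nAcross-hospital ranges:\n")
  b <- fit$benchmarks
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-8s %-16s %5.1f%% (%.1f-%.1f%%), n = %d\n",
                b$procedure[i], b$indicator[i], 100 * b$p0[i],
                100 * b$min[i], 100 * b$max[i], b$denominator[i]))
  cat("\nLOS thresholds (nearest rank):\n")
  t <- fit$thresholds
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-8s p%2.0f <= %d days\n", t$procedure[i],
                100 * t$level[i], t$threshold[i]))
  if (!is.null(fit$exclusions) && sum(fit$exclusions$excluded) > 0)
    cat(sprintf("\nComposite exclusions (missing components): %d record(s)\n",
                sum(fit$exclusions$excluded)))
  invisible(x)
}

#' @export
predict.hpb_benchmark <- function(object, volumes = c(20, 40, 50, 100, 200),
                                  spec = power_spec(), ...) {
  threshold_table(object$benchmarks, volumes, spec)
}

#' @export
residuals.hpb_benchmark <- function(object, indicator = "MORTALITY",
                                    procedure = "PD", ...) {
  indicator <- match_indicator(indicator)
  procedure <- match_procedure(procedure)
  s <- object$summaries
  s <- s[s$hospital_id != "NATIONAL" & s$indicator == indicator &
           s$procedure == procedure & s$denominator > 0, , drop = FALSE]
  p0 <- object$benchmarks$p0[object$benchmarks$indicator == indicator &
                               object$benchmarks$procedure == procedure]
  z <- (2 * asin(sqrt(s$rate)) - 2 * asin(sqrt(p0))) * sqrt(s$denominator)
  stats::setNames(z, s$hospital_id)
}

#' @export
plot.hpb_benchmark <- function(x, indicator = "MORTALITY", procedure = "PD",
                               level = 0.95, method = "exact", ...) {
  indicator <- match_indicator(indicator)
  procedure <- match_procedure(procedure)
  s <- x$summaries
  s <- s[s$hospital_id != "NATIONAL" & s$indicator == indicator &
           s$procedure == procedure & s$denominator > 0, , drop = FALSE]
  p0 <- x$benchmarks$p0[x$benchmarks$indicator == indicator &
                          x$benchmarks$procedure == procedure]
  grid <- seq(max(1, min(s$denominator) * 0.8),
              max(s$denominator) * 1.1, length.out = 80)
  curve <- funnel_limits(p0, pmax(1, round(grid)), level, method)
  graphics::plot(s$denominator, 100 * s$rate,
                 xlab = "volume (resections in window)",
                 ylab = sprintf("%s rate (%%)", tolower(indicator)),
                 main = sprintf("%s %s funnel, benchmark %.1f%%",
                                procedure, tolower(indicator), 100 * p0),
                 pch = 19, ylim = 100 * range(c(s$rate, curve$lower,
                                                curve$upper, p0)), ...)
  graphics::abline(h = 100 * p0, lty = 1)
  graphics::lines(curve$volume, 100 * curve$lower, lty = 2)
  graphics::lines(curve$volume, 100 * curve$upper, lty = 2)
  invisible(x)
}

#' Simulate registries from a fitted benchmark
#'
#' Builds a generator configuration from the fitted component rates and
#' per-hospital annual volumes and draws `nsim` synthetic registries: the
#' parametric null ("all hospitals perform at the benchmark") underlying
#' funnel-plot limits.
#'
#' @param object A [hpb_benchmark()] fit.
#' @param nsim Number of registries.
#' @param seed Master seed (offset per replicate).
#' @param ... Unused.
#' @return A list of registry data frames (length `nsim`).
#' @export
simulate.hpb_benchmark <- function(object, nsim = 1, seed = 1L, ...) {
  comp <- object$components
  vols <- object$volumes
  # mean annual volume over the window, rounded to whole cases
  agg <- stats::aggregate(volume ~ hospital_id + procedure, data = vols,
                          FUN = function(v) round(mean(v)))
  rows <- lapply(seq_len(nrow(agg)), function(i) {
    cp <- comp[comp$procedure == agg$procedure[i], ]
    hospital_profile(
      hospital_id = agg$hospital_id[i], procedure = agg$procedure[i],
      volume = agg$volume[i], p_severe = cp$p_severe,
      p_death_given_severe = cp$p_death_given_severe,
      p_death_given_not_severe = cp$p_death_given_not_severe,
      p_readmission = cp$p_readmission,
      p_margin_adequate = cp$p_margin_adequate,
      p_popf_bc = cp$p_popf_bc, p_reoperation = cp$p_reoperation,
      los_median = cp$los_median, los_size = min(cp$los_size, 1e6))
  })
  profiles <- do.call(rbind, rows)
  lapply(seq_len(nsim), function(k) {
    cfg <- sim_config(profiles, years = object$window,
                      seed = substream_seed(seed, paste0("sim-", k)),
                      label = "fitted-null")
    simulate_registry(cfg)
  })
}
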