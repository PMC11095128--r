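# Closed vocabularies used throughout: four procedure groups and four
# quality indicators.  Unknown labels are errors, never warnings.
PROCEDURES <- c("MINOR_LR", "MAJOR_LR", "PD", "DP")
LIVER_PROCEDURES <- c("MINOR_LR", "MAJOR_LR")
PANCREAS_PROCEDURES <- c("PD", "DP")
INDICATORS <- c("MORTALITY", "MAJOR_MORBIDITY", "FTR", "COMPOSITE")
ADVERSE_INDICATORS <- c("MORTALITY", "MAJOR_MORBIDITY", "FTR")
TUMOUR_TYPES <- c("CRLM", "HCC", "pCCA", "iCCA")

REGISTRY_COLUMNS <- c("hospital_id", "year", "procedure", "tumour_type",
                      "cd_grade_3a_plus", "death", "readmission", "los_days",
                      "margin_adequate", "popf_bc", "reoperation")

# LOS percentile level per procedure group: liver composites use the 90th
# percentile ("prolonged stay"), pancreas composites the 75th.
los_level <- function(procedure) {
  ifelse(procedure %in% LIVER_PROCEDURES, 0.90, 0.75)
}

match_procedure <- function(procedure) {
  match.arg(procedure, PROCEDURES)
}

match_indicator <- function(indicator) {
  match.arg(indicator, INDICATORS)
}

indicator_direction <- function(indicator) {
  if (indicator %in% ADVERSE_INDICATORS) "increase" else "decrease"
}

# Commercial rounding (half away from zero), used only for reporting:
# detectable differences are printed at one decimal in percentage points
# while all internal values stay at double precision.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Nearest-rank percentile: the ceiling(q * n)-th order statistic.  Always an
# observed value, so with integer LOS the threshold is an integer.
nearest_rank <- function(x, q) {
  x <- sort(x)
  x[max(1L, ceiling(q * length(x)))]
}

# Deterministic per-hospital RNG substream seed.  A stable polynomial hash
# of the hospital label is folded into the master seed, so adding or
# removing a hospital never perturbs the records of any other hospital.
# All arithmetic stays below 2^53, hence exact in doubles.
substream_seed <- function(master, id) {
  bytes <- utf8ToInt(as.character(id))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h <- (h * 69069 + 1) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 + h) %% 2147483647)
}

# Restore the caller's RNG state on exit so seeded simulation functions do
# not clobber the global stream.
preserve_rng <- function(expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

check_probability <- function(x, field) {
  if (length(x) == 0 || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("configuration error: '%s' must be a probability in [0, 1]",
                 field), call. = FALSE)
  }
  invisible(x)
}

window_label <- function(years) {
  years <- sort(unique(as.integer(years)))
  if (length(years) == 1) as.character(years)
  else paste0(min(years), "-", max(years))
}

subset_window <- function(records, window = NULL) {
  if (is.null(window)) return(records)
  records[records$year %in% as.integer(window), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
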