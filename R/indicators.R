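#' Quality-indicator component flags
#'
#' `mortality_flag()` marks death during the initial admission or within 30
#' days of surgery (the registry carries this as a single boolean);
#' `major_morbidity_flag()` marks a Clavien-Dindo grade >= 3a complication.
#' Death without a severe complication is mortality but not morbidity.
#' Both are vectorised over the rows of a registry data frame.
#'
#' @param records Registry data frame (see [simulate_registry()]).
#' @return Logical vector, one element per record.
#' @export
mortality_flag <- function(records) {
  as.logical(records$death)
}

#' @rdname mortality_flag
#' @export
major_morbidity_flag <- function(records) {
  as.logical(records$cd_grade_3a_plus)
}

#' Failure-to-rescue summary
#'
#' Failure to rescue is death among patients with a Clavien-Dindo >= 3a
#' complication: a conditional rate whose denominator is the severely
#' complicated subgroup, not the whole cohort.  With no severe
#' complications the rate is undefined and flagged, not an error.
#'
#' @param records Registry data frame; may be empty.
#' @return One-row data frame: `numerator`, `denominator`, `rate`,
#'   `undefined`.
#' @examples
#' reg <- simulate_registry(audit_sim_config(seed = 3, years = 2021))
#' ftr_summary(reg[reg$procedure == "PD", ])
#' @export
ftr_summary <- function(records) {
  mm <- major_morbidity_flag(records)
  den <- sum(mm)
  num <- sum(mm & mortality_flag(records))
  data.frame(numerator = num, denominator = den,
             rate = if (den > 0) num / den else NA_real_,
             undefined = den == 0)
}

#' Length-of-stay thresholds per procedure group
#'
#' Nearest-rank percentiles of observed length of stay, computed nationally
#' per procedure group over the benchmark window: the 90th percentile for
#' liver resections (the textbook-outcome "prolonged stay" cut-off) and the
#' 75th percentile for pancreatic resections (the ideal-outcome
#' "acceptable stay" cut-off).  Nearest rank means the
#' `ceiling(q * n)`-th order statistic, always an observed integer value.
#'
#' @param records Registry data frame.
#' @param window Optional year subset (integer vector).
#' @return Data frame: `procedure`, `level`, `threshold`.
#' @export
los_thresholds <- function(records, window = NULL) {
  records <- subset_window(records, window)
  procs <- intersect(PROCEDURES, unique(records$procedure))
  out <- lapply(procs, function(proc) {
    x <- records$los_days[records$procedure == proc]
    data.frame(procedure = proc, level = los_level(proc),
               threshold = nearest_rank(x, los_level(proc)))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

threshold_lookup <- function(thresholds, procedure) {
  if (is.data.frame(thresholds)) {
    i <- match(procedure, thresholds$procedure)
    thresholds$threshold[i]
  } else {
    unname(thresholds[procedure])
  }
}

#' Composite outcome flags: textbook outcome and ideal outcome
#'
#' `textbook_outcome_flag()` (liver resections): no severe complication, no
#' death, no readmission, length of stay at or below the 90th-percentile
#' threshold (the boundary day still counts as achieved), and an adequate
#' resection margin.  `ideal_outcome_flag()` (pancreatic resections): no
#' death, no severe complication, no POPF grade B/C, no reoperation, stay
#' at or below the 75th-percentile threshold, and no readmission.
#' `composite_flag()` dispatches per record on the procedure family.
#' Records missing a required component yield `NA` (they are excluded from
#' composite denominators upstream and counted in the exclusion report).
#'
#' @param records Registry data frame restricted to the matching procedure
#'   family (`composite_flag()` accepts both).
#' @param thresholds LOS thresholds from [los_thresholds()] (or a named
#'   vector procedure -> threshold).
#' @return Logical vector (with `NA` for records missing a component).
#' @examples
#' reg <- simulate_registry(audit_sim_config(seed = 3, years = 2021))
#' thr <- los_thresholds(reg)
#' mean(ideal_outcome_flag(reg[reg$procedure == "PD", ], thr))
#' @export
textbook_outcome_flag <- function(records, thresholds) {
  if (!all(records$procedure %in% LIVER_PROCEDURES))
    stop("wrong procedure: textbook outcome applies to liver resections only",
         call. = FALSE)
  thr <- threshold_lookup(thresholds, records$procedure)
  !records$cd_grade_3a_plus & !records$death & !records$readmission &
    records$los_days <= thr & records$margin_adequate
}

#' @rdname textbook_outcome_flag
#' @export
ideal_outcome_flag <- function(records, thresholds) {
  if (!all(records$procedure %in% PANCREAS_PROCEDURES))
    stop("wrong procedure: ideal outcome applies to pancreatic resections only",
         call. = FALSE)
  thr <- threshold_lookup(thresholds, records$procedure)
  !records$death & !records$cd_grade_3a_plus & !records$popf_bc &
    !records$reoperation & records$los_days <= thr & !records$readmission
}

#' @rdname textbook_outcome_flag
#' @export
composite_flag <- function(records, thresholds) {
  out <- rep(NA, nrow(records))
  liver <- records$procedure %in% LIVER_PROCEDURES
  if (any(liver))
    out[liver] <- textbook_outcome_flag(records[liver, , drop = FALSE],
                                        thresholds)
  if (any(!liver))
    out[!liver] <- ideal_outcome_flag(records[!liver, , drop = FALSE],
                                      thresholds)
  out
}

#' Per-hospital and national indicator summaries
#'
#' Computes numerator, denominator and rate of all four quality indicators
#' for every hospital and for the national pool (`hospital_id =
#' "NATIONAL"`), per procedure group, over the given window.  Composite
#' denominators exclude records missing a required component; exclusion
#' counts are attached as attribute `"exclusions"`.
#'
#' @param records Registry data frame.
#' @param window Optional year subset; LOS thresholds are computed on the
#'   same window.
#' @param thresholds Optional precomputed [los_thresholds()]; defaults to
#'   thresholds computed from `records` within `window`.
#' @return Data frame: `hospital_id`, `procedure`, `indicator`, `window`,
#'   `numerator`, `denominator`, `rate`, `undefined`.
#' @export
indicator_summaries <- function(records, window = NULL, thresholds = NULL) {
  records <- subset_window(records, window)
  if (nrow(records) == 0) {
    out <- data.frame(hospital_id = character(), procedure = character(),
                      indicator = character(), window = character(),
                      numerator = integer(), denominator = integer(),
                      rate = numeric(), undefined = logical())
    attr(out, "exclusions") <- data.frame(procedure = character(),
                                          excluded = integer())
    return(out)
  }
  win <- window_label(window %||% records$year)
  if (is.null(thresholds)) thresholds <- los_thresholds(records)
  rows <- list(); excl <- list()
  for (proc in intersect(PROCEDURES, unique(records$procedure))) {
    rp <- records[records$procedure == proc, , drop = FALSE]
    mort <- mortality_flag(rp)
    mm <- major_morbidity_flag(rp)
    comp <- composite_flag(rp, thresholds)
    excl[[proc]] <- data.frame(procedure = proc,
                               excluded = sum(is.na(comp)))
    groups <- c(list(NATIONAL = rep(TRUE, nrow(rp))),
                lapply(stats::setNames(nm = sort(unique(rp$hospital_id))),
                       function(h) rp$hospital_id == h))
    for (g in names(groups)) {
      sel <- groups[[g]]
      tab <- rbind(
        data.frame(indicator = "MORTALITY",
                   numerator = sum(mort[sel]), denominator = sum(sel)),
        data.frame(indicator = "MAJOR_MORBIDITY",
                   numerator = sum(mm[sel]), denominator = sum(sel)),
        data.frame(indicator = "FTR",
                   numerator = sum(mm[sel] & mort[sel]),
                   denominator = sum(mm[sel])),
        data.frame(indicator = "COMPOSITE",
                   numerator = sum(comp[sel], na.rm = TRUE),
                   denominator = sum(!is.na(comp[sel]))))
      rows[[length(rows) + 1]] <- data.frame(
        hospital_id = g, procedure = proc, indicator = tab$indicator,
        window = win, numerator = tab$numerator,
        denominator = tab$denominator,
        rate = ifelse(tab$denominator > 0,
                      tab$numerator / tab$denominator, NA_real_),
        undefined = tab$denominator == 0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusions") <- do.call(rbind, c(excl, make.row.names = FALSE))
  out
}

#' National benchmark table from patient-level records
#'
#' The benchmark of each indicator is the national mean event rate over the
#' window -- the patient-weighted pooled rate (total events over total
#' eligible patients), which is the centre line a funnel plot uses -- with
#' the min-max range of per-hospital rates across hospitals that have at
#' least one eligible denominator case.
#'
#' @inheritParams indicator_summaries
#' @return Data frame: `procedure`, `indicator`, `window`, `numerator`,
#'   `denominator`, `p0`, `min`, `max`, `undefined`.
#' @examples
#' reg <- simulate_registry(audit_sim_config(seed = 3))
#' benchmark_table(reg, window = 2020:2021)
#' @export
benchmark_table <- function(records, window = NULL, thresholds = NULL) {
  summ <- indicator_summaries(records, window, thresholds)
  if (nrow(summ) == 0) {
    return(data.frame(procedure = character(), indicator = character(),
                      window = character(), numerator = integer(),
                      denominator = integer(), p0 = numeric(),
                      min = numeric(), max = numeric(),
                      undefined = logical()))
  }
  nat <- summ[summ$hospital_id == "NATIONAL", , drop = FALSE]
  hosp <- summ[summ$hospital_id != "NATIONAL" & summ$denominator > 0, ,
               drop = FALSE]
  out <- lapply(seq_len(nrow(nat)), function(i) {
    n <- nat[i, ]
    hr <- hosp$rate[hosp$procedure == n$procedure &
                      hosp$indicator == n$indicator]
    data.frame(procedure = n$procedure, indicator = n$indicator,
               window = n$window, numerator = n$numerator,
               denominator = n$denominator, p0 = n$rate,
               min = if (length(hr)) min(hr) else NA_real_,
               max = if (length(hr)) max(hr) else NA_real_,
               undefined = n$undefined)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-hospital annual caseloads from a registry
#'
#' @param records Registry data frame.
#' @param procedure Optional procedure filter.
#' @return Data frame: `hospital_id`, `procedure`, `year`, `volume`.
#' @export
hospital_volumes <- function(records, procedure = NULL) {
  if (!is.null(procedure)) {
    procedure <- match_procedure(procedure)
    records <- records[records$procedure == procedure, , drop = FALSE]
  }
  agg <- stats::aggregate(list(volume = rep(1L, nrow(records))),
                          by = list(hospital_id = records$hospital_id,
                                    procedure = records$procedure,
                                    year = records$year),
                          FUN = sum)
  agg[order(agg$procedure, agg$hospital_id, agg$year), ,
      drop = FALSE] -> agg
  rownames(agg) <- NULL
  agg[, c("hospital_id", "procedure", "year", "volume")]
}
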