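#' Per-hospital generative profile for one procedure group
#'
#' One row of a simulation configuration: a hospital's annual caseload in a
#' procedure group together with the probabilities that generate outcome
#' components.  Death is generated conditionally on a severe
#' (Clavien-Dindo >= 3a) complication, so failure to rescue is a free
#' parameter of the generator rather than a by-product.  Other components
#' (readmission, resection margin, POPF, reoperation) are drawn
#' independently; length of stay follows a negative binomial count
#' distribution parameterised by its median and dispersion (`size`).
#'
#' Liver procedures require `p_margin_adequate`; pancreatic procedures
#' require `p_popf_bc` and `p_reoperation`.  The converse fields must stay
#' `NA`.
#'
#' @param hospital_id Opaque hospital label.
#' @param procedure One of `"MINOR_LR"`, `"MAJOR_LR"`, `"PD"`, `"DP"`.
#' @param volume Annual number of resections (integer >= 0).
#' @param p_severe Probability of a Clavien-Dindo >= 3a complication.
#' @param p_death_given_severe Death probability after a severe
#'   complication (the failure-to-rescue probability).
#' @param p_death_given_not_severe Death probability without a severe
#'   complication. Default 0.
#' @param p_readmission Readmission probability.
#' @param p_margin_adequate Probability of an adequate resection margin
#'   (liver only).
#' @param p_popf_bc Probability of POPF grade B/C (pancreas only).
#' @param p_reoperation Reoperation probability (pancreas only).
#' @param los_median Median length of stay, days.
#' @param los_size Negative-binomial dispersion; smaller is more
#'   overdispersed.
#' @return One-row data frame.
#' @export
hospital_profile <- function(hospital_id, procedure, volume,
                             p_severe, p_death_given_severe,
                             p_death_given_not_severe = 0,
                             p_readmission = 0.1,
                             p_margin_adequate = NA_real_,
                             p_popf_bc = NA_real_,
                             p_reoperation = NA_real_,
                             los_median = 7, los_size = 4) {
  procedure <- match_procedure(procedure)
  if (!is.numeric(volume) || length(volume) != 1 || is.na(volume) ||
      volume < 0 || volume != round(volume))
    stop("configuration error: 'volume' must be a non-negative integer",
         call. = FALSE)
  check_probability(p_severe, "p_severe")
  check_probability(p_death_given_severe, "p_death_given_severe")
  check_probability(p_death_given_not_severe, "p_death_given_not_severe")
  check_probability(p_readmission, "p_readmission")
  liver <- procedure %in% LIVER_PROCEDURES
  if (liver) {
    check_probability(p_margin_adequate, "p_margin_adequate")
    if (!is.na(p_popf_bc) || !is.na(p_reoperation))
      stop("configuration error: 'p_popf_bc'/'p_reoperation' must be NA for liver procedures",
           call. = FALSE)
  } else {
    check_probability(p_popf_bc, "p_popf_bc")
    check_probability(p_reoperation, "p_reoperation")
    if (!is.na(p_margin_adequate))
      stop("configuration error: 'p_margin_adequate' must be NA for pancreatic procedures",
           call. = FALSE)
  }
  if (los_median < 0 || los_size <= 0)
    stop("configuration error: 'los_median' must be >= 0 and 'los_size' > 0",
         call. = FALSE)
  data.frame(hospital_id = as.character(hospital_id), procedure = procedure,
             volume = as.integer(volume), p_severe = p_severe,
             p_death_given_severe = p_death_given_severe,
             p_death_given_not_severe = p_death_given_not_severe,
             p_readmission = p_readmission,
             p_margin_adequate = p_margin_adequate,
             p_popf_bc = p_popf_bc, p_reoperation = p_reoperation,
             los_median = los_median, los_size = los_size)
}

#' Simulation configuration for a synthetic audit registry
#'
#' @param profiles Data frame of [hospital_profile()] rows (stacked with
#'   `rbind`).
#' @param years Registry years (inclusive integer vector), e.g.
#'   `2014:2021`.
#' @param seed Master random seed. Per-hospital substreams are derived from
#'   it by stable hashing of the hospital label, so registries are
#'   reproducible record for record and adding a hospital leaves all
#'   others' records unchanged.
#' @param label Free-text scenario label.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(profiles, years, seed = 1L, label = "registry") {
  if (!is.data.frame(profiles) || nrow(profiles) == 0)
    stop("configuration error: 'profiles' must be a non-empty data frame",
         call. = FALSE)
  needed <- c("hospital_id", "procedure", "volume", "p_severe",
              "p_death_given_severe", "p_death_given_not_severe",
              "p_readmission", "p_margin_adequate", "p_popf_bc",
              "p_reoperation", "los_median", "los_size")
  missing <- setdiff(needed, names(profiles))
  if (length(missing) > 0)
    stop(sprintf("configuration error: profiles lack column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (length(years) == 0 || anyNA(years))
    stop("configuration error: 'years' must be a non-empty year range",
         call. = FALSE)
  # re-validate row-wise so rbind-assembled or hand-edited frames are
  # checked exactly like constructor output
  for (i in seq_len(nrow(profiles))) {
    do.call(hospital_profile, as.list(profiles[i, needed]))
  }
  if (anyDuplicated(profiles[, c("hospital_id", "procedure")]))
    stop("configuration error: duplicated (hospital_id, procedure) profile",
         call. = FALSE)
  # stable within-hospital ordering: procedure enum order decides the draw
  # sequence, so configs assembled in any row order simulate identically
  ord <- order(match(profiles$hospital_id, unique(profiles$hospital_id)),
               match(profiles$procedure, PROCEDURES))
  profiles <- profiles[ord, , drop = FALSE]
  rownames(profiles) <- NULL
  structure(list(profiles = profiles, years = sort(as.integer(years)),
                 seed = as.integer(seed), label = label),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Registry simulation config '%s': %d hospital-procedure profiles, years %s, seed %d\n",
              x$label, nrow(x$profiles), window_label(x$years), x$seed))
  invisible(x)
}

# Mean of a negative binomial with given dispersion whose median equals
# `med`.  The median is a step function of mu; we bracket the mu-interval
# over which the median equals `med` and take its midpoint, keeping the
# mapping deterministic and well inside the plateau.
nb_mu_from_median <- function(med, size) {
  boundary <- function(target) {
    if (target <= 0) return(0)
    lo <- 1e-8; hi <- max(10, 20 * target)
    while (stats::qnbinom(0.5, size = size, mu = hi) < target) hi <- hi * 2
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (stats::qnbinom(0.5, size = size, mu = mid) >= target) hi <- mid
      else lo <- mid
    }
    hi
  }
  (boundary(med) + boundary(med + 1)) / 2
}

# Draw all records of one hospital from its own substream.  Draw order per
# profile and year is fixed (tumour type, severe, death, readmission, LOS,
# then procedure-family fields) so any single probability change only
# affects the corresponding component.
simulate_hospital <- function(profiles_h, years, master_seed) {
  set.seed(substream_seed(master_seed, profiles_h$hospital_id[1]))
  blocks <- list()
  for (i in seq_len(nrow(profiles_h))) {
    p <- profiles_h[i, ]
    if (p$volume == 0) next
    mu <- nb_mu_from_median(p$los_median, p$los_size)
    liver <- p$procedure %in% LIVER_PROCEDURES
    for (yr in years) {
      v <- p$volume
      if (liver) {
        u <- stats::runif(v)
        tumour <- TUMOUR_TYPES[findInterval(u, c(0, 0.6, 0.8, 0.88))]
      } else {
        tumour <- rep(NA_character_, v)
      }
      severe <- stats::runif(v) < p$p_severe
      death <- stats::runif(v) < ifelse(severe, p$p_death_given_severe,
                                        p$p_death_given_not_severe)
      readm <- stats::runif(v) < p$p_readmission
      los <- stats::rnbinom(v, size = p$los_size, mu = mu)
      if (liver) {
        margin <- stats::runif(v) < p$p_margin_adequate
        popf <- rep(NA, v); reop <- rep(NA, v)
      } else {
        margin <- rep(NA, v)
        popf <- stats::runif(v) < p$p_popf_bc
        reop <- stats::runif(v) < p$p_reoperation
      }
      blocks[[length(blocks) + 1]] <- data.frame(
        hospital_id = p$hospital_id, year = yr, procedure = p$procedure,
        tumour_type = tumour, cd_grade_3a_plus = severe, death = death,
        readmission = readm, los_days = as.integer(los),
        margin_adequate = margin, popf_bc = popf, reoperation = reop)
    }
  }
  if (length(blocks) == 0) return(empty_registry())
  do.call(rbind, blocks)
}

empty_registry <- function() {
  data.frame(hospital_id = character(), year = integer(),
             procedure = character(), tumour_type = character(),
             cd_grade_3a_plus = logical(), death = logical(),
             readmission = logical(), los_days = integer(),
             margin_adequate = logical(), popf_bc = logical(),
             reoperation = logical())
}

#' Simulate a synthetic patient-level audit registry
#'
#' Generates one record per resection for every configured
#' hospital-procedure-year cell, with outcome components drawn per the
#' hospital profile.  Identical configurations (including the seed) yield
#' identical registries record for record; each hospital draws from its own
#' substream (see [sim_config()]).
#'
#' @param config A [sim_config()].
#' @param seed Optional master-seed override.
#' @return Registry data frame with columns `hospital_id`, `year`,
#'   `procedure`, `tumour_type`, `cd_grade_3a_plus`, `death`,
#'   `readmission`, `los_days`, `margin_adequate`, `popf_bc`,
#'   `reoperation`.
#' @examples
#' cfg <- sim_config(hospital_profile("A", "PD", 30, p_severe = 0.36,
#'                                    p_death_given_severe = 0.075,
#'                                    p_popf_bc = 0.14, p_reoperation = 0.09),
#'                   years = 2020:2021, seed = 7)
#' reg <- simulate_registry(cfg)
#' nrow(reg)  # 60
#' @export
simulate_registry <- function(config, seed = NULL) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config object", call. = FALSE)
  master <- seed %||% config$seed
  preserve_rng({
    parts <- lapply(unique(config$profiles$hospital_id), function(h) {
      ph <- config$profiles[config$profiles$hospital_id == h, , drop = FALSE]
      simulate_hospital(ph, config$years, master)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

#' Shift one hospital's generative probability to create an outlier
#'
#' Returns a copy of `base` in which a single hospital's generative
#' probability for the targeted indicator is raised by `delta` (adverse
#' indicators) or the implied composite rate lowered by `delta` (composite
#' outcomes); everything else is untouched.
#'
#' Mapping of indicator to knob: `MORTALITY` adds `delta` to both
#' conditional death probabilities, which raises the marginal mortality
#' rate by exactly `delta`; `MAJOR_MORBIDITY` adds to `p_severe`; `FTR`
#' adds to `p_death_given_severe`.  For `COMPOSITE`, the margin-adequacy
#' (liver) or POPF (pancreas) probability is moved by `delta` divided by
#' the pass probability of the remaining components, so the hospital's
#' implied composite rate drops by exactly `delta`.
#'
#' @param base A [sim_config()].
#' @param hospital_id Hospital to modify.
#' @param procedure Procedure group of the modified profile.
#' @param indicator Targeted indicator.
#' @param delta Absolute shift of the indicator rate, >= 0.
#' @return A `sim_config` with attribute `outlier` recording the scenario
#'   (`hospital_id`, `procedure`, `indicator`, `delta`, `direction`).
#' @examples
#' cfg <- audit_sim_config(seed = 1)
#' out <- scenario_with_outlier(cfg, "H01", "PD", "MAJOR_MORBIDITY", 0.15)
#' @export
scenario_with_outlier <- function(base, hospital_id, procedure, indicator,
                                  delta) {
  if (!inherits(base, "sim_config"))
    stop("'base' must be a sim_config object", call. = FALSE)
  procedure <- match_procedure(procedure)
  indicator <- match_indicator(indicator)
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) || delta < 0)
    stop("'delta' must be a single non-negative shift", call. = FALSE)
  pr <- base$profiles
  i <- which(pr$hospital_id == hospital_id & pr$procedure == procedure)
  if (length(i) != 1)
    stop(sprintf("no profile for hospital '%s', procedure %s",
                 hospital_id, procedure), call. = FALSE)
  bump <- function(x, field) {
    if (x < 0 || x > 1)
      stop(sprintf("configuration error: shifted '%s' leaves [0, 1]", field),
           call. = FALSE)
    x
  }
  if (indicator == "MORTALITY") {
    pr$p_death_given_severe[i] <-
      bump(pr$p_death_given_severe[i] + delta, "p_death_given_severe")
    pr$p_death_given_not_severe[i] <-
      bump(pr$p_death_given_not_severe[i] + delta, "p_death_given_not_severe")
  } else if (indicator == "MAJOR_MORBIDITY") {
    pr$p_severe[i] <- bump(pr$p_severe[i] + delta, "p_severe")
  } else if (indicator == "FTR") {
    pr$p_death_given_severe[i] <-
      bump(pr$p_death_given_severe[i] + delta, "p_death_given_severe")
  } else {
    ir <- implied_rates(base)
    comp <- ir$by_hospital
    ch <- comp$composite[comp$hospital_id == hospital_id &
                           comp$procedure == procedure]
    if (procedure %in% LIVER_PROCEDURES) {
      rest <- ch / pr$p_margin_adequate[i]
      pr$p_margin_adequate[i] <-
        bump(pr$p_margin_adequate[i] - delta / rest, "p_margin_adequate")
    } else {
      rest <- ch / (1 - pr$p_popf_bc[i])
      pr$p_popf_bc[i] <- bump(pr$p_popf_bc[i] + delta / rest, "p_popf_bc")
    }
  }
  out <- sim_config(pr, base$years, base$seed,
                    label = sprintf("%s+outlier", base$label))
  attr(out, "outlier") <- list(
    hospital_id = hospital_id, procedure = procedure, indicator = indicator,
    delta = delta, direction = indicator_direction(indicator))
  out
}

#' Analytic indicator rates implied by a simulation configuration
#'
#' Computes, without simulating, the indicator rates that a configuration
#' generates: the oracle against which simulated registries are checked for
#' distributional recovery.  Direct indicators follow from the conditional
#' probability structure (`mortality = p_severe * p_death_given_severe +
#' (1 - p_severe) * p_death_given_not_severe`; pooled FTR is the
#' severity-weighted mean of `p_death_given_severe`).  Composite rates
#' multiply the component pass probabilities, with the length-of-stay term
#' evaluated at the population nearest-rank percentile of the pooled
#' (volume-weighted) LOS mixture.
#'
#' @param config A [sim_config()].
#' @return List with `pooled` (data frame `procedure`, `indicator`,
#'   `rate`), `by_hospital` (per-hospital analytic rates), and
#'   `los_thresholds` (population percentile threshold per procedure).
#' @export
implied_rates <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config object", call. = FALSE)
  pr <- config$profiles
  thr_rows <- list(); hosp_rows <- list(); pooled_rows <- list()
  for (proc in intersect(PROCEDURES, unique(pr$procedure))) {
    pp <- pr[pr$procedure == proc, , drop = FALSE]
    w <- pp$volume
    level <- los_level(proc)
    # population nearest-rank threshold of the volume-weighted LOS mixture
    mus <- vapply(seq_len(nrow(pp)),
                  function(i) nb_mu_from_median(pp$los_median[i],
                                                pp$los_size[i]), 0)
    mix_cdf <- function(x) {
      sum(w * stats::pnbinom(x, size = pp$los_size, mu = mus)) / sum(w)
    }
    q <- 0
    while (mix_cdf(q) < level && q < 100000) q <- q + 1
    thr_rows[[proc]] <- data.frame(procedure = proc, level = level,
                                   threshold = q)
    los_pass <- stats::pnbinom(q, size = pp$los_size, mu = mus)
    mort <- pp$p_severe * pp$p_death_given_severe +
      (1 - pp$p_severe) * pp$p_death_given_not_severe
    no_death <- (1 - pp$p_severe) * (1 - pp$p_death_given_not_severe)
    comp <- if (proc %in% LIVER_PROCEDURES) {
      no_death * (1 - pp$p_readmission) * los_pass * pp$p_margin_adequate
    } else {
      no_death * (1 - pp$p_popf_bc) * (1 - pp$p_reoperation) *
        los_pass * (1 - pp$p_readmission)
    }
    hosp_rows[[proc]] <- data.frame(
      hospital_id = pp$hospital_id, procedure = proc,
      mortality = mort, major_morbidity = pp$p_severe,
      ftr = pp$p_death_given_severe, composite = comp)
    sev <- sum(w * pp$p_severe)
    pooled_rows[[proc]] <- data.frame(
      procedure = proc, indicator = INDICATORS,
      rate = c(sum(w * mort) / sum(w),
               sev / sum(w),
               if (sev > 0) sum(w * pp$p_severe * pp$p_death_given_severe) / sev
               else NA_real_,
               sum(w * comp) / sum(w)))
  }
  list(pooled = do.call(rbind, c(pooled_rows, make.row.names = FALSE)),
       by_hospital = do.call(rbind, c(hosp_rows, make.row.names = FALSE)),
       los_thresholds = do.call(rbind, c(thr_rows, make.row.names = FALSE)))
}
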