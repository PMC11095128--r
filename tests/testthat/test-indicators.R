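test_that("mortality and morbidity flags are the component booleans", {
  rec <- rbind(make_records(1, death = TRUE),
               make_records(1, death = FALSE),
               make_records(1, death = TRUE, severe = FALSE))
  expect_equal(mortality_flag(rec), c(TRUE, FALSE, TRUE))
  # death alone is not major morbidity
  expect_equal(major_morbidity_flag(rec), c(FALSE, FALSE, FALSE))
  cohort <- rbind(make_records(6, death = TRUE), make_records(994))
  expect_equal(mean(mortality_flag(cohort)), 0.006)
})

test_that("failure to rescue is conditional on a severe complication", {
  rec <- rbind(make_records(2, severe = TRUE, death = TRUE),
               make_records(8, severe = TRUE),
               make_records(40))
  f <- ftr_summary(rec)
  expect_equal(f$denominator, 10)
  expect_equal(f$numerator, 2)
  expect_equal(f$rate, 0.2)
  expect_false(f$undefined)
  f0 <- ftr_summary(make_records(25))
  expect_equal(f0$denominator, 0)
  expect_true(f0$undefined)
  expect_true(is.na(f0$rate))
})

test_that("ideal-outcome flags equal the exhaustively enumerated conjunction on a toy cohort", {
  toy <- data.frame(
    hospital_id = "T", year = 2021L, procedure = "PD",
    tumour_type = NA_character_,
    cd_grade_3a_plus = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    death = FALSE,
    readmission = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    los_days = c(5L, 5L, 5L, 5L, 5L, 20L),
    margin_adequate = NA,
    popf_bc = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    reoperation = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  thr <- los_thresholds(toy)
  # nearest rank: ceiling(0.75 * 6) = 5th order statistic of (5,5,5,5,5,20)
  expect_equal(thr$threshold, 5L)
  # truth table: record 1 passes everything; 2-6 each fail exactly one
  # component (severe, readmission, POPF, reoperation, prolonged stay)
  expect_equal(ideal_outcome_flag(toy, thr),
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  s <- indicator_summaries(toy)
  comp <- s[s$hospital_id == "NATIONAL" & s$indicator == "COMPOSITE", ]
  expect_equal(comp$rate, 1 / 6)
})

test_that("a stay exactly on the percentile threshold still achieves the composite", {
  rec <- rbind(make_records(8, procedure = "MINOR_LR", los = 3L),
               make_records(2, procedure = "MINOR_LR", los = 10L))
  thr <- los_thresholds(rec)
  expect_equal(thr$threshold[thr$procedure == "MINOR_LR"], 10L)
  expect_true(all(textbook_outcome_flag(rec, thr)))
})

test_that("composite flags reject records from the wrong procedure family", {
  liver <- make_records(3, procedure = "MINOR_LR")
  panc <- make_records(3, procedure = "PD")
  thr <- los_thresholds(rbind(liver, panc))
  expect_error(textbook_outcome_flag(panc, thr), "wrong procedure")
  expect_error(ideal_outcome_flag(liver, thr), "wrong procedure")
  flags <- composite_flag(rbind(liver, panc), thr)
  expect_equal(length(flags), 6)
  expect_true(all(flags))
})

test_that("benchmarks pool patients, not hospitals, and track per-hospital extremes", {
  rec <- rbind(make_records(50, hospital_id = "A"),
               make_records(5, hospital_id = "B", death = TRUE),
               make_records(45, hospital_id = "B"))
  b <- benchmark_table(rec)
  mort <- b[b$indicator == "MORTALITY", ]
  expect_equal(mort$p0, 0.05)
  expect_equal(mort$min, 0)
  expect_equal(mort$max, 0.1)
  one <- benchmark_table(make_records(50, hospital_id = "A", death = TRUE))
  m1 <- one[one$indicator == "MORTALITY", ]
  expect_equal(c(m1$p0, m1$min, m1$max), c(1, 1, 1))
})

test_that("records missing a composite component are excluded and counted", {
  rec <- make_records(10, procedure = "MINOR_LR")
  rec$margin_adequate[3:4] <- NA
  s <- indicator_summaries(rec)
  comp <- s[s$hospital_id == "NATIONAL" & s$indicator == "COMPOSITE", ]
  expect_equal(comp$denominator, 8)
  excl <- attr(s, "exclusions")
  expect_equal(excl$excluded[excl$procedure == "MINOR_LR"], 2)
  # mortality still uses all records
  expect_equal(s$denominator[s$hospital_id == "NATIONAL" &
                               s$indicator == "MORTALITY"], 10)
})

test_that("simulated cohorts satisfy the structural indicator invariants", {
  reg <- simulate_registry(audit_sim_config(seed = 31, years = 2020:2021))
  thr <- los_thresholds(reg)
  s <- indicator_summaries(reg, thresholds = thr)
  nat <- s[s$hospital_id == "NATIONAL", ]
  hosp <- s[s$hospital_id != "NATIONAL", ]

  # aggregation: national counts are the sums over hospitals
  for (i in seq_len(nrow(nat))) {
    hi <- hosp[hosp$procedure == nat$procedure[i] &
                 hosp$indicator == nat$indicator[i], ]
    expect_equal(sum(hi$numerator), nat$numerator[i])
    expect_equal(sum(hi$denominator), nat$denominator[i])
  }

  for (proc in unique(reg$procedure)) {
    rp <- reg[reg$procedure == proc, ]
    # composite dominance: the conjunction passes at most as often as any
    # single component
    comp_rate <- nat$rate[nat$procedure == proc &
                            nat$indicator == "COMPOSITE"]
    components <- c(mean(!rp$cd_grade_3a_plus), mean(!rp$death),
                    mean(!rp$readmission),
                    mean(rp$los_days <= thr$threshold[thr$procedure == proc]))
    expect_true(all(comp_rate <= components))
    # nearest-rank boundary: at least the percentile mass lies at or below
    expect_gte(mean(rp$los_days <= thr$threshold[thr$procedure == proc]),
               thr$level[thr$procedure == proc])
  }

  # FTR consistency in every stratum: deaths after severe complications are
  # a subset of all deaths, and the FTR denominator is the morbidity count
  for (proc in unique(hosp$procedure)) {
    hp <- hosp[hosp$procedure == proc, ]
    wide <- split(hp, hp$hospital_id)
    for (w in wide) {
      get <- function(ind, col) w[[col]][w$indicator == ind]
      expect_equal(get("FTR", "denominator"),
                   get("MAJOR_MORBIDITY", "numerator"))
      expect_lte(get("FTR", "numerator"), get("MORTALITY", "numerator"))
    }
  }
})

test_that("empty input yields a flagged empty summary, not an error", {
  s <- indicator_summaries(make_records(0))
  expect_equal(nrow(s), 0)
  b <- benchmark_table(make_records(5), window = 1999)
  expect_equal(nrow(b), 0)
})
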