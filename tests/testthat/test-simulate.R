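test_that("degenerate probabilities produce degenerate outcomes", {
  cfg0 <- sim_config(liver_profile("A", volume = 100, p_severe = 0,
                                   p_death_given_severe = 0,
                                   p_death_given_not_severe = 0),
                     years = 2021, seed = 9)
  reg0 <- simulate_registry(cfg0)
  expect_equal(nrow(reg0), 100)
  expect_equal(sum(reg0$death), 0)
  expect_equal(sum(reg0$cd_grade_3a_plus), 0)

  cfg1 <- sim_config(pd_profile("A", volume = 50, p_severe = 1,
                                p_death_given_severe = 1),
                     years = 2021, seed = 9)
  reg1 <- simulate_registry(cfg1)
  expect_equal(nrow(reg1), 50)
  expect_true(all(reg1$cd_grade_3a_plus))
  expect_true(all(reg1$death))
})

test_that("identical configurations yield byte-identical registries", {
  cfg <- audit_sim_config(seed = 11, years = 2021)
  r1 <- simulate_registry(cfg)
  r2 <- simulate_registry(cfg)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_registry(r1, f1); write_registry(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(r1, simulate_registry(cfg, seed = 12)))
})

test_that("record counts equal configured volumes and years", {
  cfg <- audit_sim_config(seed = 4, years = 2020:2021)
  reg <- simulate_registry(cfg)
  for (proc in unique(cfg$profiles$procedure)) {
    expect_equal(sum(reg$procedure == proc),
                 2 * sum(cfg$profiles$volume[cfg$profiles$procedure == proc]))
  }
  expect_true(all(reg$los_days >= 0))
  # conditional fields present exactly for the matching family
  liver <- reg$procedure %in% c("MINOR_LR", "MAJOR_LR")
  expect_false(anyNA(reg$margin_adequate[liver]))
  expect_true(all(is.na(reg$margin_adequate[!liver])))
  expect_false(anyNA(reg$popf_bc[!liver]))
  expect_true(all(is.na(reg$popf_bc[liver])))
})

test_that("each hospital draws from a private substream", {
  cfg <- sim_config(rbind(pd_profile("A", 40), pd_profile("B", 30)),
                    years = 2020:2021, seed = 5)
  reg <- simulate_registry(cfg)
  grown <- sim_config(rbind(pd_profile("A", 40), pd_profile("B", 30),
                            pd_profile("C", 25)),
                      years = 2020:2021, seed = 5)
  reg2 <- simulate_registry(grown)
  for (h in c("A", "B")) {
    expect_equal(strip_rows(reg[reg$hospital_id == h, ]),
                 strip_rows(reg2[reg2$hospital_id == h, ]))
  }
  # changing one hospital's probability leaves the others untouched
  tweaked <- scenario_with_outlier(cfg, "B", "PD", "MAJOR_MORBIDITY", 0.2)
  reg3 <- simulate_registry(tweaked)
  expect_equal(strip_rows(reg[reg$hospital_id == "A", ]),
               strip_rows(reg3[reg3$hospital_id == "A", ]))
})

test_that("empirical rates recover generating probabilities within binomial error", {
  p <- 0.23; n <- 800
  inside <- vapply(1:200, function(s) {
    reg <- simulate_registry(sim_config(pd_profile("A", n, p_severe = p),
                                        years = 2021, seed = 1000 + s))
    abs(mean(reg$cd_grade_3a_plus) - p) <= 4 * sqrt(p * (1 - p) / n)
  }, NA)
  expect_gte(mean(inside), 0.99)
})

test_that("death is generated conditionally on severe complications", {
  cfg <- sim_config(pd_profile("A", 20000, p_severe = 0.5,
                               p_death_given_severe = 0.3,
                               p_death_given_not_severe = 0.02),
                    years = 2021, seed = 77)
  reg <- simulate_registry(cfg)
  sev <- reg$cd_grade_3a_plus
  expect_lt(abs(mean(reg$death[sev]) - 0.3),
            4 * sqrt(0.3 * 0.7 / sum(sev)))
  expect_lt(abs(mean(reg$death[!sev]) - 0.02),
            4 * sqrt(0.02 * 0.98 / sum(!sev)))
})

test_that("configuration errors name the offending field", {
  expect_error(pd_profile("A", 10, p_severe = 1.2), "p_severe")
  expect_error(pd_profile("A", -1), "volume")
  expect_error(hospital_profile("A", "MINOR_LR", 10, 0.1, 0.1,
                                p_margin_adequate = NA), "p_margin_adequate")
  expect_error(hospital_profile("A", "PD", 10, 0.1, 0.1,
                                p_popf_bc = 0.1, p_reoperation = 0.05,
                                p_margin_adequate = 0.9),
               "p_margin_adequate")
  expect_error(sim_config(pd_profile(), years = integer(0)), "years")
  expect_error(sim_config(rbind(pd_profile("A"), pd_profile("A")),
                          years = 2021), "duplicated")
})

test_that("outlier scenarios shift exactly one generative probability", {
  base <- audit_sim_config(seed = 1)
  expect_identical(scenario_with_outlier(base, "H01", "PD",
                                         "MAJOR_MORBIDITY", 0)$profiles,
                   base$profiles)
  out <- scenario_with_outlier(base, "H03", "MINOR_LR",
                               "MAJOR_MORBIDITY", 0.15)
  i <- with(out$profiles, hospital_id == "H03" & procedure == "MINOR_LR")
  expect_equal(out$profiles$p_severe[i], 0.098 + 0.15)
  expect_identical(out$profiles[!i, ], base$profiles[!i, ])
  meta <- attr(out, "outlier")
  expect_equal(meta$hospital_id, "H03")
  expect_equal(meta$direction, "increase")
  expect_error(scenario_with_outlier(base, "H03", "MINOR_LR",
                                     "MAJOR_MORBIDITY", 0.95), "p_severe")
})

test_that("a two-fold mortality outlier doubles the marginal death probability", {
  base <- sim_config(pd_profile("A", 100, p_severe = 0,
                                p_death_given_severe = 0,
                                p_death_given_not_severe = 0.006),
                     years = 2021, seed = 2)
  out <- scenario_with_outlier(base, "A", "PD", "MORTALITY", 0.006)
  expect_equal(out$profiles$p_death_given_not_severe, 0.012)
  expect_equal(implied_rates(out)$pooled$rate[1], 0.012)
})

test_that("composite outliers lower the implied composite rate by exactly delta", {
  base <- audit_sim_config(seed = 1)
  for (case in list(c("H05", "MINOR_LR"), c("H02", "PD"))) {
    out <- scenario_with_outlier(base, case[1], case[2], "COMPOSITE", 0.15)
    pick <- function(ir) {
      bh <- ir$by_hospital
      bh$composite[bh$hospital_id == case[1] & bh$procedure == case[2]]
    }
    expect_equal(pick(implied_rates(out)),
                 pick(implied_rates(base)) - 0.15, tolerance = 1e-12)
  }
})

test_that("implied rates reproduce the conditional probability algebra", {
  pr <- pd_profile("A", 10, p_severe = 0.4, p_death_given_severe = 0.2,
                   p_death_given_not_severe = 0.05, p_readmission = 0.1,
                   p_popf_bc = 0.2, p_reoperation = 0.1)
  ir <- implied_rates(sim_config(pr, years = 2021))
  rate <- function(ind) ir$pooled$rate[ir$pooled$indicator == ind]
  expect_equal(rate("MORTALITY"), 0.4 * 0.2 + 0.6 * 0.05)
  expect_equal(rate("MAJOR_MORBIDITY"), 0.4)
  expect_equal(rate("FTR"), 0.2)
  # composite is the non-LOS pass product scaled by the LOS pass mass,
  # which sits between the percentile level and one
  base_pass <- 0.6 * 0.95 * 0.8 * 0.9 * 0.9
  expect_lt(rate("COMPOSITE"), base_pass)
  expect_gte(rate("COMPOSITE"), base_pass * 0.75)
})
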