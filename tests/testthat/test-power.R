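test_that("arcsine effect size has its closed-form boundary values", {
  expect_equal(effect_size_h(0.2, 0.2), 0)
  expect_equal(effect_size_h(0, 1), pi)
  expect_equal(effect_size_h(0.3, 0.1), -effect_size_h(0.1, 0.3))
  expect_error(effect_size_h(-0.1, 0.5), "p0")
  expect_error(effect_size_h(0.1, 1.5), "p1")
})

test_that("required sample size matches a brute-force power search", {
  spec <- power_spec()
  # independent oracle: numerical search for the smallest n at which the
  # normal-approximation power on the arcsine scale reaches the design
  power_minus_target <- function(n, p0, p1) {
    stats::pnorm(abs(effect_size_h(p0, p1)) * sqrt(n) - spec$z_alpha) -
      spec$power
  }
  for (p0 in c(0.006, 0.075, 0.36, 0.541, 0.736)) {
    for (d in c(0.02, 0.05, 0.15)) {
      p1 <- if (p0 < 0.5) p0 + d else p0 - d
      n_oracle <- stats::uniroot(power_minus_target, c(1, 1e6),
                                 p0 = p0, p1 = p1, tol = 1e-9)$root
      expect_lt(abs(required_n(p0, p1) - n_oracle), 0.5)
    }
  }
})

test_that("sample size diverges monotonically as the alternative approaches the benchmark", {
  expect_true(is.infinite(required_n(0.1, 0.1)))
  ns <- required_n(0.1, c(0.2, 0.15, 0.12, 0.11))
  expect_true(all(diff(ns) > 0))
})

test_that("detectable difference shrinks with volume and round-trips the sample size", {
  d <- detectable_difference(0.027, c(20, 40, 50, 100, 200))
  expect_true(all(diff(d$difference) < 0))
  expect_equal(required_n(0.027, d$p1), d$n, tolerance = 1e-9)
  d2 <- detectable_difference(0.633, c(20, 100), "decrease")
  expect_true(all(d2$p1 < 0.633))
  expect_equal(required_n(0.633, d2$p1), d2$n, tolerance = 1e-9)
})

test_that("detectable difference grows with benchmark variance at fixed volume", {
  p0s <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.45)
  diffs <- vapply(p0s, function(p) detectable_difference(p, 50)$difference, 0)
  expect_true(all(diff(diffs) > 0))
})

test_that("saturated inversions are clipped to the unit interval and flagged", {
  d <- detectable_difference(0.9, 3)
  expect_true(d$saturated)
  expect_equal(d$p1, 1)
  expect_error(detectable_difference(1, 20, "increase"), "p0 = 1")
  expect_error(detectable_difference(0, 20, "decrease"), "p0 = 0")
})

test_that("annual volume requirements floor the pooled total", {
  mv <- min_annual_volume(0.027, 0.05, years = 3)
  expect_equal(mv$annual_volume, floor(mv$n_total / 3))
  expect_equal(min_annual_volume(0.027, 0.05, years = 1)$annual_volume,
               floor(mv$n_total))
  expect_error(min_annual_volume(0.9, 0.2), "\\[0, 1\\]")
})

test_that("threshold grid covers the indicator-volume-procedure cross and flags gaps", {
  grid <- threshold_table(dutch_hpb_benchmarks(), volumes = c(20, 50))
  expect_equal(nrow(grid), 4 * 4 * 2)
  expect_false(any(grid$absent))
  expect_true(all(grid$direction[grid$indicator == "COMPOSITE"] == "decrease"))
  adverse <- grid$indicator != "COMPOSITE"
  expect_true(all(grid$p1[adverse] > grid$p0[adverse]))
  expect_true(all(grid$p1[!adverse] < grid$p0[!adverse]))
  # every column strictly decreases down the volume axis
  full <- threshold_table(dutch_hpb_benchmarks())
  for (ind in unique(full$indicator)) for (proc in unique(full$procedure)) {
    col <- full[full$indicator == ind & full$procedure == proc, ]
    expect_true(all(diff(col$difference[order(col$volume)]) < 0))
  }
  part <- dutch_hpb_benchmarks()
  part <- part[part$procedure != "DP", ]
  g2 <- threshold_table(part, volumes = 20)
  expect_equal(nrow(g2), 16)
  expect_true(all(g2$absent[g2$procedure == "DP"]))
  expect_false(any(g2$absent[g2$procedure != "DP"]))
})

test_that("volume requirements enumerate scenarios with two-fold only on the adverse side", {
  vr <- volume_requirements(dutch_hpb_benchmarks(), years = c(1, 3))
  expect_true(all(vr$scenario[vr$indicator == "COMPOSITE"] != "TWO_FOLD"))
  expect_true("TWO_FOLD" %in% vr$scenario[vr$indicator == "MORTALITY"])
  two <- vr[vr$scenario == "TWO_FOLD" & vr$indicator == "MORTALITY" &
              vr$procedure == "MINOR_LR", ]
  expect_equal(unique(two$p1), 2 * 0.006)
  expect_equal(vr$annual_volume, floor(vr$n_total / vr$years))
})

test_that("adequacy reports the fraction of hospitals with enough pooled volume", {
  expect_equal(adequacy_report(c(30, 60), 50)$proportion, 0.5)
  expect_equal(adequacy_report(c(0, 0, 0), 10)$proportion, 0)
  # 16 of 20 hospitals at 30/year clear the 5-point mortality requirement
  # over three pooled years; 4 at 20/year do not
  req <- min_annual_volume(0.006, 0.05, years = 3)
  rep3 <- adequacy_report(c(rep(30, 16), rep(20, 4)), req$n_total, years = 3)
  expect_equal(rep3$proportion, 0.80)
  empty <- adequacy_report(data.frame(hospital_id = character(),
                                      year = integer(), volume = numeric()),
                           required_total = 5)
  expect_true(empty$empty)
  expect_true(is.na(empty$proportion))
})

test_that("the arcsine one-sample test is two-sided and centred on the benchmark", {
  t0 <- one_sample_prop_test(5, 100, 0.05)
  expect_false(t0$reject)
  expect_equal(t0$statistic, 0)
  t1 <- one_sample_prop_test(20, 100, 0.05)
  expect_true(t1$reject)
  expect_lt(t1$p.value, 0.001)
  expect_lt(one_sample_prop_test(1, 100, 0.1)$statistic, 0)
  expect_error(one_sample_prop_test(5, 3, 0.1), "x <= n")
})
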