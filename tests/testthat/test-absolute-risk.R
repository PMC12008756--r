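test_that("rate-band expansion is piecewise constant on half-open bands", {
  rt <- bc_rate_table(c(18, 50), c(50, 80), c(0.001, 0.002), c(0.003, 0.004))
  py <- expand_rate_table(rt)
  expect_equal(nrow(py), 62L)
  expect_equal(py$incidence[py$age == 49], 0.001)
  expect_equal(py$incidence[py$age == 50], 0.002)
  # single band: constant everywhere
  py1 <- expand_rate_table(flat_rates(0.005, 0))
  expect_true(all(py1$incidence == 0.005))
  # collapsing per-year rates back to the bands recovers the table
  agg <- tapply(py$incidence, findInterval(py$age, rt$age_start), unique)
  expect_equal(as.numeric(agg), rt$incidence)
})

test_that("rate tables with gaps, overlaps or bad coverage are rejected", {
  expect_error(bc_rate_table(c(18, 52), c(50, 80), c(1, 1) / 1e4, c(0, 0)),
               "gap or overlap")
  expect_error(bc_rate_table(c(18, 45), c(50, 80), c(1, 1) / 1e4, c(0, 0)),
               "gap or overlap")
  expect_error(bc_rate_table(20, 80, 1e-4, 0), "cover")
  expect_error(bc_rate_table(18, 80, -1e-4, 0), "non-negative")
})

test_that("rate table file round trip preserves rates on the per-100k scale", {
  rt <- generate_rate_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_rate_table(rt, path)
  back <- read_rate_table(path)
  expect_equal(as.data.frame(back), as.data.frame(rt), tolerance = 1e-12)
})

test_that("baseline calibration divides by the reference-mean relative risk", {
  rt <- flat_rates(0.001, 0)
  b0 <- calibrate_baseline(rt, rep(0, 10))
  expect_true(all(b0$hazard == 0.001))
  b <- calibrate_baseline(rt, c(log(2), log(0.5)))
  expect_equal(b$hazard, rep(0.001 / 1.25, 62))
  # scaling incidence scales the baseline
  b2 <- calibrate_baseline(flat_rates(0.003, 0), c(log(2), log(0.5)))
  expect_equal(b2$hazard, 3 * b$hazard)
  expect_error(calibrate_baseline(rt, numeric(0)), "empty")
})

test_that("calibration identity holds at machine precision at every age", {
  set.seed(4)
  lp <- stats::rnorm(500, 0, 0.8)
  rt <- generate_rate_table()
  b <- calibrate_baseline(rt, lp)
  py <- expand_rate_table(rt)
  for (i in c(1, 20, 45, 62))
    expect_equal(mean(b$hazard[i] * exp(lp)), py$incidence[i],
                 tolerance = 1e-14)
})

test_that("lifetime risk matches closed forms for constant hazards", {
  zero <- rep(0, 62)
  expect_equal(lifetime_risk(3, zero, rep(0.02, 62), age_start = 18), 0)
  one_year <- lifetime_risk(0, rep(0.01, 62), zero, age_start = 18,
                            age_end = 19)
  expect_equal(one_year, 1 - exp(-0.01), tolerance = 1e-14)
  two_year <- lifetime_risk(0, rep(0.01, 62), rep(0.02, 62),
                            age_start = 18, age_end = 20)
  expect_equal(two_year, (1 / 3) * (1 - exp(-0.03)) * (1 + exp(-0.03)),
               tolerance = 1e-12)
  # with no competing mortality and lp = 0 the recursion telescopes exactly
  set.seed(8)
  lam <- stats::runif(62, 0, 0.01)
  full <- lifetime_risk(0, lam, zero, age_start = 18, age_end = 80)
  expect_equal(full, 1 - exp(-sum(lam)), tolerance = 1e-12)
})

test_that("lifetime risk is monotone in lp and bounded in [0, 1)", {
  b <- calibrate_baseline(generate_rate_table(), rep(0, 5))
  lps <- seq(-3, 5, by = 0.5)
  risks <- lifetime_risk(lps, b, age_start = 18)
  expect_true(all(diff(risks) > 0))
  expect_true(all(risks >= 0 & risks < 1))
  # non-increasing in mortality
  hi_m <- lifetime_risk(1, b$hazard, attr(b, "mortality") + 0.05,
                        age_start = 18)
  expect_lt(hi_m, lifetime_risk(1, b, age_start = 18))
})

test_that("risk is additive-consistent across a split age", {
  b <- calibrate_baseline(generate_rate_table(), rnorm(20))
  m <- attr(b, "mortality")
  r_ac <- lifetime_risk(0.7, b$hazard, m, age_start = 20, age_end = 80)
  r_ab <- lifetime_risk(0.7, b$hazard, m, age_start = 20, age_end = 50)
  r_bc <- lifetime_risk(0.7, b$hazard, m, age_start = 50, age_end = 80)
  h <- b$hazard[3:32] * exp(0.7) + m[3:32]  # ages 20..49
  surv_b <- exp(-sum(h))
  expect_equal(r_ac, r_ab + surv_b * r_bc, tolerance = 1e-12)
})

test_that("risk categorization uses half-open threshold bins", {
  th <- c(0.03, 0.05, 0.10)
  expect_equal(categorize_risk(0.029, th), 0L)
  expect_equal(categorize_risk(0.03, th), 1L)
  expect_equal(categorize_risk(0.10, th), 3L)
  expect_equal(categorize_risk(0.05, c(0.03, 0.10)), 1L)
  expect_error(categorize_risk(0.05, c(0.1, 0.05)), "ascending")
  expect_equal(category_labels(c(0.03, 0.10)), c("<3%", "3%-10%", ">=10%"))
})

test_that("age bounds are validated", {
  b <- calibrate_baseline(flat_rates(), 0)
  expect_error(lifetime_risk(0, b, age_start = 17), "age_start")
  expect_error(lifetime_risk(0, b, age_start = 80), "age_start")
  expect_error(lifetime_risk(0, b, age_start = 30, age_end = 85), "age_end")
})
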