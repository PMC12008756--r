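test_that("AUROC is the Mann-Whitney pair statistic with ties at one half", {
  expect_equal(auroc(c(2, 3), c(1, 2.5))$auroc, 0.75)
  expect_equal(auroc(c(5, 6, 7), c(1, 2, 3))$auroc, 1)
  expect_equal(auroc(rep(1, 4), rep(1, 6))$auroc, 0.5)
  expect_error(auroc(numeric(0), 1:3), "non-empty")
})

test_that("AUROC equals exhaustive pairwise brute force, including ties", {
  set.seed(13)
  for (i in 1:10) {
    cs <- round(stats::rnorm(sample(3:60, 1)), 1)  # rounding forces ties
    ct <- round(stats::rnorm(sample(3:60, 1)), 1)
    expect_equal(auroc(cs, ct)$auroc, brute_auroc(cs, ct), tolerance = 1e-14)
  }
})

test_that("AUROC of swapped groups is the complement", {
  set.seed(14)
  cs <- stats::rnorm(30); ct <- stats::rnorm(40)
  expect_equal(auroc(cs, ct)$auroc + auroc(ct, cs)$auroc, 1,
               tolerance = 1e-14)
})

test_that("DeLong variance agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  cs <- stats::rnorm(40, 1); ct <- stats::rnorm(60)
  ours <- auroc(cs, ct)
  ref <- pROC::roc(controls = ct, cases = cs, quiet = TRUE,
                   direction = "<")
  expect_equal(ours$auroc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(ours$se^2, pROC::var(ref, method = "delong"),
               tolerance = 1e-10)
})

test_that("age-adjusted AUROC reduces to the unadjusted AUROC in one stratum", {
  set.seed(16)
  scores <- stats::rnorm(80)
  status <- rep(0:1, 40)
  ages <- stats::runif(80, 40, 49)  # all in a single 10-year bin
  adj <- age_adjusted_auroc(scores, ages, status, seed = 1, n_boot = 50)
  un <- auroc(scores[status == 1], scores[status == 0])
  expect_equal(adj$auroc, un$auroc, tolerance = 1e-14)
})

test_that("two-stratum adjusted AUROC matches hand enumeration", {
  # stratum A (30s): cases {2, 4}, controls {1, 3}; stratum B (50s):
  # cases {10, 30}, controls {20, 40} -- scales differ on purpose
  scores <- c(2, 4, 1, 3, 10, 30, 20, 40)
  status <- c(1, 1, 0, 0, 1, 1, 0, 0)
  ages <- c(35, 36, 37, 38, 55, 56, 57, 58)
  # placement values (share of same-stratum controls above the case):
  # A: case 2 -> 1/2, case 4 -> 0; B: case 10 -> 1, case 30 -> 1/2
  expected <- 1 - mean(c(0.5, 0, 1, 0.5))
  adj <- age_adjusted_auroc(scores, ages, status, seed = 2, n_boot = 50)
  expect_equal(adj$auroc, expected, tolerance = 1e-14)
})

test_that("adjusted AUROC is invariant under monotone score transforms", {
  set.seed(17)
  n <- 200
  ages <- stats::runif(n, 20, 79)
  status <- stats::rbinom(n, 1, 0.4)
  scores <- stats::rnorm(n) + 0.8 * status
  a1 <- age_adjusted_auroc(scores, ages, status, seed = 3, n_boot = 20)
  a2 <- age_adjusted_auroc(exp(2 * scores), ages, status, seed = 3,
                           n_boot = 20)
  expect_equal(a1$auroc, a2$auroc, tolerance = 1e-14)
})

test_that("strata lacking cases or controls are dropped with a warning", {
  scores <- c(1, 2, 3, 4)
  status <- c(1, 0, 1, 1)
  ages <- c(25, 25, 65, 65)  # the 60s stratum has no controls
  expect_warning(adj <- age_adjusted_auroc(scores, ages, status, seed = 4,
                                           n_boot = 20), "dropped")
  expect_equal(adj$auroc, 1 - 1)  # single usable case below its control
  expect_error(age_adjusted_auroc(1:2, c(20, 30), c(1, 0), seed = 1,
                                  n_boot = 10), "stratum")
})

test_that("threshold summary counts and one-decimal percentages conserve", {
  risks <- c(rep(0.01, 343), rep(0.04, 284), rep(0.07, 249), rep(0.15, 120),
             rep(0.01, 10))
  status <- c(rep(1, 996), rep(0, 10))
  ts <- threshold_summary(risks, status)
  cases <- ts[ts$status == "case", ]
  expect_equal(cases$count, c(343, 284, 249, 120))
  expect_equal(cases$pct, c(34.4, 28.5, 25.0, 12.0))
  expect_equal(sum(cases$count), 996)
  expect_lt(abs(sum(cases$pct) - 100), 0.2)
  # all below the first threshold -> 100% in the lowest category
  ctrl <- ts[ts$status == "control", ]
  expect_equal(ctrl$pct, c(100, 0, 0, 0))
})

test_that("reclassification tables conserve counts and percentages", {
  old <- c(0, 0, 1, 1, 2, 2)
  status <- c(1, 0, 1, 0, 1, 0)
  tab <- reclassification_table(old, old, status)
  expect_true(all(tab$cases[upper.tri(tab$cases)] == 0))
  expect_true(all(tab$cases[lower.tri(tab$cases)] == 0))
  expect_equal(sum(tab$cases), 3)
  expect_equal(sum(tab$controls), 3)
  expect_equal(net_reclassification_index(tab), 0)
})

test_that("NRI reaches +2 when every case moves up and every control down", {
  old <- c(0, 0, 2, 2)
  new <- c(1, 1, 0, 0)
  status <- c(1, 1, 0, 0)
  tab <- reclassification_table(old, new, status)
  expect_equal(net_reclassification_index(tab), 2)
})

test_that("NRI is antisymmetric under swapping old and new models", {
  set.seed(18)
  old <- sample(0:2, 100, replace = TRUE)
  new <- sample(0:2, 100, replace = TRUE)
  status <- rep(0:1, 50)
  fwd <- net_reclassification_index(reclassification_table(old, new, status))
  rev <- net_reclassification_index(reclassification_table(new, old, status))
  expect_equal(fwd, -rev, tolerance = 1e-14)
})

test_that("rounding at the reporting layer is half away from zero", {
  expect_equal(round_half_up(c(6.25, 6.35, -6.25), 1), c(6.3, 6.4, -6.3))
  expect_equal(round_half_up(82.134, 1), 82.1)
  expect_equal(round_half_up(0.0805, 3), 0.081)
})
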