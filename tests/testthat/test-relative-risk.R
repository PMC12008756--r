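test_that("parity is encoded as a linear spline with a knot at one child", {
  df <- as.data.frame(make_test_cohort(2, 2, imputed = TRUE))
  df$parity <- c(0, 1, 4, 2)
  x <- encode_covariates(as_bc_cohort(df, imputed = TRUE))
  expect_equal(unname(x[, "first_live_birth"]), c(0, 1, 1, 1))
  expect_equal(unname(x[, "additional_live_births"]), c(0, 0, 3, 1))
})

test_that("height and BMI are encoded per 10 cm and as one category", {
  df <- as.data.frame(make_test_cohort(2, 2, imputed = TRUE))
  df$height_cm <- c(170, 160, 145, 182.5)
  df$bmi <- c(17, 22, 27, 31)
  x <- encode_covariates(as_bc_cohort(df, imputed = TRUE))
  expect_equal(unname(x[, "height_per_10cm"]), c(1, 0, -1.5, 2.25))
  expect_equal(unname(x[, "bmi_under_18.5"]), c(1, 0, 0, 0))
  expect_equal(unname(x[, "bmi_25_29.9"]), c(0, 0, 1, 0))
  expect_equal(unname(x[, "bmi_30plus"]), c(0, 0, 0, 1))
})

test_that("every imputed profile yields exactly one BMI state", {
  co <- impute_missing(generate_cohort(200, 200, seed = 5,
                                       missingness = default_missingness()))
  x <- encode_covariates(co)
  bmi_cols <- c("bmi_under_18.5", "bmi_25_29.9", "bmi_30plus")
  n_ind <- rowSums(x[, bmi_cols])
  in_ref <- co$bmi >= 18.5 & co$bmi < 25
  expect_true(all(n_ind[in_ref] == 0))
  expect_true(all(n_ind[!in_ref] == 1))
})

test_that("encoding refuses unimputed profiles", {
  co <- generate_cohort(5, 5, seed = 1, missingness = list(bmi = 1))
  expect_error(encode_covariates(co), "imput")
})

test_that("PRS is the dosage-weight dot product and is linear in weights", {
  w <- data.frame(variant_id = c("v1", "v2", "v3"),
                  weight = c(0.1, -0.2, 0.3), freq = c(0.2, 0.5, 0.4))
  d <- c(v1 = 0, v2 = 1, v3 = 2)
  expect_equal(compute_prs(d, w), 0.4)
  w0 <- transform(w, weight = 0)
  expect_equal(compute_prs(d, w0), 0)
  w2 <- transform(w, weight = weight * 2)
  expect_equal(compute_prs(d, w2), 0.8)
  expect_error(compute_prs(c(v1 = 2.5, v2 = 1, v3 = 0), w), "\\[0, 2\\]")
})

test_that("missing variants default to the population-mean dosage 2f", {
  w <- data.frame(variant_id = c("v1", "v2"), weight = c(0.5, 0.25),
                  freq = c(0.1, 0.4))
  expect_equal(compute_prs(c(v1 = 1), w), 0.5 + 0.25 * 2 * 0.4)
  expect_error(compute_prs(c(v1 = 1), w, on_missing = "error"), "v2")
})

test_that("hybrid PRS is the subtype-proportion-weighted average", {
  expect_equal(combine_hybrid_prs(0.2, 0.4, 0.5), 0.3)
  expect_equal(combine_hybrid_prs(0.2, 0.4, 1), 0.2)
  # equal subtype scores give that score at any weight
  for (w in c(0, 0.3, 0.77, 1))
    expect_equal(combine_hybrid_prs(0.25, 0.25, w), 0.25)
  expect_error(combine_hybrid_prs(0.2, 0.4, 1.2), "w_erpos")
})

test_that("family-history attenuation: empty sum leaves the log-OR unchanged", {
  co <- make_test_coeffs(fh = 0.47)
  adj <- adjust_family_history(co, "epi_only")
  expect_equal(adj$family_history_adjusted, 0.47)
})

test_that("one SNV of beta 0.2 and frequency 0.5 attenuates 0.47 to 0.46", {
  snv <- data.frame(variant_id = "v1", weight = 0.2, freq = 0.5)
  co <- make_test_coeffs(fh = 0.47, snv = snv)
  adj <- adjust_family_history(co, "prs_only")
  expect_equal(adj$family_history_adjusted, 0.46, tolerance = 1e-12)
})

test_that("attenuation is monotone in added variants and floored at zero", {
  snv1 <- data.frame(variant_id = "v1", weight = 0.2, freq = 0.5)
  snv2 <- rbind(snv1, data.frame(variant_id = "v2", weight = 0.3, freq = 0.3))
  a1 <- adjust_family_history(make_test_coeffs(snv = snv1), "prs_only")
  a2 <- adjust_family_history(make_test_coeffs(snv = snv2), "prs_only")
  expect_lte(a2$family_history_adjusted, a1$family_history_adjusted)
  big <- data.frame(variant_id = "v1", weight = 3, freq = 0.5)
  a3 <- adjust_family_history(make_test_coeffs(fh = 0.1, snv = big), "prs_only")
  expect_equal(a3$family_history_adjusted, 0)
})

test_that("attenuation is idempotent and order-independent across variants", {
  pv <- data.frame(gene = "BRCA1", beta = 2.3, freq = 0.001)
  co <- make_test_coeffs(pv = pv, prs_variance = 0.1)
  once <- adjust_family_history(co, "combined")
  twice <- adjust_family_history(once, "combined")
  expect_equal(once$family_history_adjusted, twice$family_history_adjusted)
  via_other <- adjust_family_history(adjust_family_history(co, "prs_only"),
                                     "combined")
  expect_equal(via_other$family_history_adjusted,
               once$family_history_adjusted)
})

test_that("coefficient sets reject entries without frequencies", {
  expect_error(
    bc_coefficients(make_test_coeffs()$epi,
                    pv = data.frame(gene = "BRCA1", beta = 2.3, freq = NA)),
    "BRCA1")
  expect_error(
    bc_coefficients(make_test_coeffs()$epi,
                    snv_weights = data.frame(variant_id = "v9", weight = 0.1,
                                             freq = NA_real_)),
    "v9")
})

test_that("the all-reference profile has linear predictor zero", {
  df <- as.data.frame(make_test_cohort(1, 1, imputed = TRUE))
  df$parity <- 0; df$breastfeeding_months <- 0; df$prs <- 0
  co <- as_bc_cohort(df, imputed = TRUE)
  coeffs <- adjust_family_history(default_coefficients(), "combined")
  expect_equal(linear_predictor(co, coeffs, "combined"), c(0, 0))
})

test_that("prs_only linear predictor is prs times its coefficient", {
  df <- as.data.frame(make_test_cohort(1, 1, imputed = TRUE))
  df$prs <- c(0.5, -0.1)
  co <- as_bc_cohort(df, imputed = TRUE)
  coeffs <- make_test_coeffs(prs_coef = 1.2)
  expect_equal(linear_predictor(co, coeffs, "prs_only"), c(0.6, -0.12))
})

test_that("combined LP decomposes into epi (attenuated FH) plus genetic parts", {
  co <- impute_missing(generate_cohort(50, 50, seed = 9))
  coeffs <- adjust_family_history(default_coefficients(), "combined")
  lp_combined <- linear_predictor(co, coeffs, "combined")
  lp_genetic <- linear_predictor(co, coeffs, "prs_plus_pv")
  # epi part with the attenuated family-history coefficient substituted
  coeffs_sub <- coeffs
  coeffs_sub$epi[["family_history"]] <- coeffs$family_history_adjusted
  lp_epi_att <- linear_predictor(co, coeffs_sub, "epi_only")
  expect_equal(lp_combined, lp_epi_att + lp_genetic, tolerance = 1e-12)
})

test_that("combined variant demands family-history-adjusted coefficients", {
  co <- make_test_cohort(2, 2, imputed = TRUE)
  expect_error(linear_predictor(co, default_coefficients(), "combined"),
               "adjust_family_history")
})
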