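#' Model variants
#'
#' The four nested relative-risk models: epidemiologic questionnaire factors
#' only, PRS only, PRS plus pathogenic variants, and the combined model with
#' all three components.
#'
#' @format character vector of the four variant names.
#' @export
bc_variants <- c("epi_only", "prs_only", "prs_plus_pv", "combined")

variant_has_epi <- function(variant) variant %in% c("epi_only", "combined")
variant_has_prs <- function(variant) variant %in% c("prs_only", "prs_plus_pv", "combined")
variant_has_pv  <- function(variant) variant %in% c("prs_plus_pv", "combined")

check_variant <- function(variant) {
  if (!is.character(variant) || length(variant) != 1L || !variant %in% bc_variants)
    bc_stop("variant must be one of: %s", paste(bc_variants, collapse = ", "))
  variant
}

#' Encode epidemiologic covariates as model terms
#'
#' Maps raw covariates to the design terms of the relative-risk model:
#' parity enters as a linear spline with a knot at one child
#' (\code{first_live_birth} indicator plus \code{additional_live_births}
#' = max(parity - 1, 0)); height is continuous per 10 cm centered at 160 cm;
#' BMI is categorical (<18.5, 18.5-24.9 reference, 25-29.9, >=30); age at
#' menarche and breastfeeding are continuous, centered at the coefficient
#' set's reference values; the remaining factors are 0/1 (fractional values
#' from mean imputation are accepted).
#'
#' @param cohort an imputed \code{bc_cohort} (or any data frame with the
#'   epidemiologic columns and no missing values in them).
#' @param centering named list of centering constants (see
#'   \code{\link{bc_coefficients}}).
#' @return numeric matrix, one row per participant, columns the
#'   epidemiologic model terms.
#' @export
encode_covariates <- function(cohort,
                              centering = list(age_menarche = 15,
                                               breastfeeding_months = 0,
                                               height_cm = 160)) {
  if (inherits(cohort, "bc_cohort") && !is_imputed(cohort))
    bc_stop("cohort must be imputed before covariate encoding")
  df <- as.data.frame(cohort)
  if (anyNA(df[, bc_epi_fields]))
    bc_stop("missing epidemiologic values; impute or exclude first")
  n <- nrow(df)
  m <- matrix(0, n, length(bc_epi_terms),
              dimnames = list(df$id, bc_epi_terms))
  m[, "age_menarche"] <- df$age_menarche - centering$age_menarche
  m[, "first_live_birth"] <- as.numeric(df$parity >= 1)
  m[, "additional_live_births"] <- pmax(df$parity - 1, 0)
  m[, "breastfeeding_months"] <- df$breastfeeding_months - centering$breastfeeding_months
  m[, "benign_breast_disease"] <- df$benign_breast_disease
  m[, "family_history"] <- df$family_history
  m[, "height_per_10cm"] <- (df$height_cm - centering$height_cm) / 10
  m[, "bmi_under_18.5"] <- as.numeric(df$bmi < 18.5)
  m[, "bmi_25_29.9"] <- as.numeric(df$bmi >= 25 & df$bmi < 30)
  m[, "bmi_30plus"] <- as.numeric(df$bmi >= 30)
  m[, "alcohol"] <- df$alcohol
  m
}

#' Compute a polygenic risk score from dosages and weights
#'
#' Weighted sum of effect-allele dosages, \eqn{\sum_k d_k \beta_k}.
#' Variants present in the weight table but absent from the dosage data are,
#' by default, imputed at their population mean dosage \eqn{2 f_k}
#' (standard practice, keeping scores comparable across panels); strict mode
#' errors instead.
#'
#' @param dosages named numeric vector (one participant) or numeric matrix
#'   (participants x variants, column names = variant ids) of dosages in
#'   [0, 2].
#' @param weights SNV weight table (\code{data.frame} with
#'   \code{variant_id}, \code{weight}, \code{freq}) or a
#'   \code{bc_coefficients} object carrying one.
#' @param on_missing \code{"mean_impute"} (default) or \code{"error"}.
#' @return numeric vector of scores, one per participant.
#' @export
compute_prs <- function(dosages, weights, on_missing = c("mean_impute", "error")) {
  on_missing <- match.arg(on_missing)
  if (inherits(weights, "bc_coefficients")) weights <- weights$snv_weights
  if (is.null(weights)) bc_stop("no SNV weights supplied")
  if (is.null(dim(dosages)))
    dosages <- matrix(dosages, 1, dimnames = list(NULL, names(dosages)))
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE))
    bc_stop("dosages must lie in [0, 2]")
  miss <- setdiff(weights$variant_id, colnames(dosages))
  if (length(miss)) {
    if (on_missing == "error")
      bc_stop("dosages missing for variant(s): %s", paste(miss, collapse = ", "))
    add <- matrix(rep(2 * weights$freq[match(miss, weights$variant_id)],
                      each = nrow(dosages)),
                  nrow(dosages), length(miss), dimnames = list(NULL, miss))
    dosages <- cbind(dosages, add)
  }
  as.numeric(dosages[, weights$variant_id, drop = FALSE] %*% weights$weight)
}

#' Combine ER-subtype PRSs into a hybrid score
#'
#' Weighted average of the estrogen-receptor-positive and -negative subtype
#' scores, weighted by the subtype proportions of the target population.
#'
#' @param prs_erpos,prs_erneg numeric vectors of subtype scores.
#' @param w_erpos proportion of ER-positive disease, in [0, 1].
#' @return numeric vector of hybrid scores.
#' @export
combine_hybrid_prs <- function(prs_erpos, prs_erneg, w_erpos) {
  check_scalar(w_erpos, "w_erpos", 0, 1)
  w_erpos * prs_erpos + (1 - w_erpos) * prs_erneg
}

#' Attenuate the family-history coefficient for modeled heritability
#'
#' When SNVs and pathogenic variants enter the model alongside family
#' history, part of the familial risk they convey is double-counted. The
#' family-history log-OR is therefore attenuated by the polygenic familial
#' component of the modeled variants:
#' \deqn{\beta^A_{FH} = \max\left(0,\; \beta_{FH} - \sum_k f_k(1-f_k)\beta_k^2\right)}
#' summing over the SNVs and PVs active in the model variant. Under
#' Hardy-Weinberg equilibrium \eqn{f_k(1-f_k)\beta_k^2} is half the genotypic
#' log-risk variance of variant \eqn{k} — the share transmitted to a
#' first-degree relative (kinship 1/2) — and equals, to second order, the
#' family-history log-OR induced by that variant alone. When the PRS enters
#' as a precomputed score without a weight table, its contribution is the
#' aggregate equivalent \eqn{\tfrac12 Var(PRS)\,\beta_{PRS}^2}.
#'
#' The adjustment always starts from the stored unadjusted \eqn{\beta_{FH}},
#' so it is idempotent and order-independent across variants.
#'
#' @param coeffs a \code{bc_coefficients} object.
#' @param variant model variant whose genetic terms define the sum; for
#'   \code{"epi_only"} the sum is empty and
#'   \eqn{\beta^A_{FH} = \beta_{FH}}.
#' @return the coefficient set with \code{family_history_adjusted} set.
#' @export
adjust_family_history <- function(coeffs, variant = "combined") {
  stopifnot(inherits(coeffs, "bc_coefficients"))
  check_variant(variant)
  beta_fh <- coeffs$epi[["family_history"]]
  h <- 0
  if (variant_has_prs(variant)) {
    if (!is.null(coeffs$snv_weights)) {
      w <- coeffs$snv_weights
      h <- h + sum(w$freq * (1 - w$freq) * w$weight^2)
    } else if (!is.null(coeffs$prs_variance)) {
      h <- h + 0.5 * coeffs$prs_variance * coeffs$prs_coefficient^2
    } else {
      bc_stop("PRS is active but neither SNV weights nor prs_variance are available")
    }
  }
  if (variant_has_pv(variant) && !is.null(coeffs$pv)) {
    h <- h + sum(coeffs$pv$freq * (1 - coeffs$pv$freq) * coeffs$pv$beta^2)
  }
  coeffs$family_history_adjusted <- max(0, beta_fh - h)
  coeffs$adjusted_for <- variant
  coeffs
}

#' Linear predictor of the relative-risk model
#'
#' Dot product of the encoded covariates active in a model variant with
#' their log odds-ratio coefficients; \code{exp} of the result is the
#' relative risk versus the reference woman (parity 0, height 160 cm, BMI in
#' 18.5-24.9, all binary factors 0, continuous terms at their centering
#' values, PRS 0, no PVs). The family-history term uses the attenuated
#' coefficient \eqn{\beta^A_{FH}} when genetic terms are active in the
#' variant, the unadjusted \eqn{\beta_{FH}} otherwise.
#'
#' @param cohort an imputed \code{bc_cohort}.
#' @param coeffs a \code{bc_coefficients} object; must already be
#'   family-history-adjusted (for this variant) when the variant includes
#'   genetic terms together with epidemiologic terms.
#' @param variant one of \code{\link{bc_variants}}.
#' @return numeric vector of log relative risks, one per participant.
#' @export
linear_predictor <- function(cohort, coeffs, variant = "combined") {
  stopifnot(inherits(coeffs, "bc_coefficients"))
  check_variant(variant)
  df <- as.data.frame(cohort)
  lp <- numeric(nrow(df))

  if (variant_has_epi(variant)) {
    beta <- coeffs$epi
    if (variant_has_prs(variant) || variant_has_pv(variant)) {
      if (is.na(coeffs$family_history_adjusted) ||
          !identical(coeffs$adjusted_for, variant))
        bc_stop("coefficients must be family-history-adjusted for variant '%s'; call adjust_family_history()",
                variant)
      beta[["family_history"]] <- coeffs$family_history_adjusted
    }
    x <- encode_covariates(cohort, coeffs$centering)
    lp <- lp + as.numeric(x %*% beta[colnames(x)])
  }
  if (variant_has_prs(variant)) {
    if (anyNA(df$prs))
      bc_stop("variant '%s' requires a PRS for every participant", variant)
    lp <- lp + df$prs * coeffs$prs_coefficient
  }
  if (variant_has_pv(variant)) {
    if (is.null(coeffs$pv))
      bc_stop("variant '%s' requires PV coefficients", variant)
    for (i in seq_len(nrow(coeffs$pv))) {
      col <- paste0("pv_", coeffs$pv$gene[i])
      carrier <- df[[col]]
      if (anyNA(carrier))
        bc_stop("missing PV carrier status for %s; impute first", coeffs$pv$gene[i])
      lp <- lp + carrier * coeffs$pv$beta[i]
    }
  }
  lp
}
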