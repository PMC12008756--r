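#' Fit a breast-cancer absolute-risk model
#'
#' Constructs an absolute-risk model for one model variant: attenuates the
#' family-history coefficient for the heritability captured by the variant's
#' genetic terms (\code{\link{adjust_family_history}}), computes the linear
#' predictors of the reference sample, and calibrates the age-specific
#' baseline hazard so that the reference-mean hazard reproduces the
#' population incidence (\code{\link{calibrate_baseline}}). The reference
#' sample must consist of controls only: in a case-control study the
#' controls stand in for the source population's risk-factor distribution.
#'
#' @param coefficients a \code{bc_coefficients} object (unadjusted; the
#'   family-history attenuation is applied here).
#' @param rates a \code{bc_rate_table} of population incidence and competing
#'   mortality.
#' @param reference an imputed \code{bc_cohort}; rows with \code{status == 0}
#'   form the reference distribution (an error if none).
#' @param variant one of \code{\link{bc_variants}}.
#' @param age_end upper age of the lifetime projection (default 80).
#' @param age_start optional fixed projection start age; by default each
#'   woman is projected from her own enrollment age.
#' @return object of class \code{bc_risk_model}.
#' @seealso \code{\link{predict.bc_risk_model}}
#' @export
#' @examples
#' cohort <- impute_missing(generate_cohort(100, 100, seed = 1))
#' rates <- generate_rate_table()
#' fit <- bc_risk_model(default_coefficients(), rates, cohort)
#' fit
#' head(predict(fit, cohort))
bc_risk_model <- function(coefficients, rates, reference,
                          variant = "combined", age_end = 80,
                          age_start = NULL) {
  stopifnot(inherits(coefficients, "bc_coefficients"),
            inherits(rates, "bc_rate_table"),
            inherits(reference, "bc_cohort"))
  check_variant(variant)
  if (!is_imputed(reference)) bc_stop("reference cohort must be imputed")
  controls <- reference[reference$status == 0, , drop = FALSE]
  class(controls) <- class(reference)
  attr(controls, "imputed") <- TRUE
  if (nrow(controls) == 0L) bc_stop("reference contains no controls")

  coefficients <- adjust_family_history(coefficients, variant)
  ref_lp <- linear_predictor(controls, coefficients, variant)
  baseline <- calibrate_baseline(rates, ref_lp)

  structure(list(coefficients = coefficients, variant = variant,
                 baseline = baseline, rates = rates,
                 age_end = age_end, age_start = age_start,
                 n_reference = nrow(controls),
                 reference_lp_moments = c(mean = mean(ref_lp),
                                          sd = stats::sd(ref_lp)),
                 call = match.call()),
            class = "bc_risk_model")
}

#' Active coefficients of a fitted risk model
#'
#' @param object a \code{bc_risk_model}.
#' @param ... unused.
#' @return named numeric vector of the log odds ratios active in the model's
#'   variant; the family-history entry is the attenuated coefficient when
#'   genetic terms are active.
#' @export
coef.bc_risk_model <- function(object, ...) {
  co <- object$coefficients
  out <- numeric(0)
  if (variant_has_epi(object$variant)) {
    beta <- co$epi
    if (variant_has_prs(object$variant) || variant_has_pv(object$variant))
      beta[["family_history"]] <- co$family_history_adjusted
    out <- c(out, beta)
  }
  if (variant_has_prs(object$variant))
    out <- c(out, prs = unname(co$prs_coefficient))
  if (variant_has_pv(object$variant) && !is.null(co$pv))
    out <- c(out, stats::setNames(co$pv$beta, paste0("pv_", co$pv$gene)))
  out
}

#' Predict linear predictors, lifetime risks and risk categories
#'
#' @param object a \code{bc_risk_model}.
#' @param newdata an imputed \code{bc_cohort}.
#' @param type \code{"response"} (data frame with lp, risk and category),
#'   \code{"lp"}, \code{"risk"} or \code{"category"}.
#' @param thresholds category thresholds (default 3/5/10 percent).
#' @param ... unused.
#' @return data frame (\code{type = "response"}) with columns \code{id},
#'   \code{variant}, \code{lp}, \code{lifetime_risk}, \code{risk_pct},
#'   \code{category}; otherwise the corresponding vector.
#' @export
predict.bc_risk_model <- function(object, newdata,
                                  type = c("response", "lp", "risk", "category"),
                                  thresholds = c(0.03, 0.05, 0.10), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "bc_cohort"))
  if (!is_imputed(newdata)) bc_stop("newdata must be imputed")
  lp <- linear_predictor(newdata, object$coefficients, object$variant)
  if (type == "lp") return(lp)
  start <- if (is.null(object$age_start)) pmin(floor(newdata$age), 79)
           else rep(object$age_start, nrow(newdata))
  risk <- lifetime_risk(lp, object$baseline, age_start = start,
                        age_end = object$age_end)
  if (type == "risk") return(risk)
  cat_idx <- categorize_risk(risk, thresholds)
  if (type == "category") return(cat_idx)
  data.frame(id = newdata$id, variant = object$variant, lp = lp,
             lifetime_risk = risk, risk_pct = 100 * risk,
             category = category_labels(thresholds)[cat_idx + 1L],
             stringsAsFactors = FALSE)
}

#' @export
print.bc_risk_model <- function(x, ...) {
  cat(sprintf("<bc_risk_model> variant: %s\n", x$variant))
  cat(sprintf("  reference controls: %d (mean relative risk %.4f)\n",
              x$n_reference, attr(x$baseline, "mean_rr")))
  co <- x$coefficients
  if (variant_has_epi(x$variant) &&
      (variant_has_prs(x$variant) || variant_has_pv(x$variant)))
    cat(sprintf("  family-history log-OR: %.4f -> %.4f (attenuated)\n",
                co$epi[["family_history"]], co$family_history_adjusted))
  cat(sprintf("  projection: to age %d, from %s\n", x$age_end,
              if (is.null(x$age_start)) "enrollment age"
              else paste("age", x$age_start)))
  invisible(x)
}

#' @export
summary.bc_risk_model <- function(object, ...) {
  out <- list(variant = object$variant, coef = coef(object),
              n_reference = object$n_reference,
              mean_rr = attr(object$baseline, "mean_rr"),
              lifetime_risk_reference =
                lifetime_risk(object$reference_lp_moments[["mean"]],
                              object$baseline, age_start = 18,
                              age_end = object$age_end))
  class(out) <- "summary.bc_risk_model"
  out
}

#' @export
print.summary.bc_risk_model <- function(x, ...) {
  cat(sprintf("Breast-cancer absolute-risk model (%s)\n", x$variant))
  cat(sprintf("Reference: %d controls, mean relative risk %.4f\n",
              x$n_reference, x$mean_rr))
  cat(sprintf("Lifetime risk (age 18+) at the reference-mean LP: %.2f%%\n",
              100 * x$lifetime_risk_reference))
  cat("Coefficients (log odds ratios):\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' Histogram of predicted lifetime risks by case/control status
#'
#' @param x a \code{bc_risk_model}.
#' @param newdata an imputed \code{bc_cohort}.
#' @param cap upper display cap for the risk axis (default 0.30).
#' @param breaks number of histogram bins.
#' @param ... passed to \code{barplot}.
#' @return invisibly, the binned proportions.
#' @export
plot.bc_risk_model <- function(x, newdata, cap = 0.30, breaks = 30, ...) {
  risk <- pmin(predict(x, newdata, type = "risk"), cap)
  edges <- seq(0, cap, length.out = breaks + 1)
  prop <- function(r) {
    h <- hist(r, breaks = edges, plot = FALSE)
    h$counts / length(r)
  }
  m <- rbind(controls = prop(risk[newdata$status == 0]),
             cases = prop(risk[newdata$status == 1]))
  graphics::barplot(m, beside = TRUE, names.arg = round(100 * edges[-1], 1),
                    xlab = sprintf("Lifetime absolute risk, %% (capped at %.0f%%)",
                                   100 * cap),
                    ylab = "Proportion", legend.text = rownames(m),
                    col = c("grey70", "firebrick"), border = NA, ...)
  invisible(m)
}
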