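#' Calibrate the baseline hazard to population incidence
#'
#' Divides the population incidence at every age by the mean relative risk
#' of a reference sample (controls, supplying the population risk-factor
#' distribution), so that the reference-mean model hazard reproduces the
#' population incidence exactly:
#' \eqn{\lambda_0(t) = \lambda_{pop}(t) / \overline{e^{LP}}} and hence
#' \eqn{\mathrm{mean}_i\, \lambda_0(t) e^{LP_i} = \lambda_{pop}(t)} for
#' every age \eqn{t}.
#'
#' @param rates a \code{bc_rate_table}.
#' @param reference_lp numeric vector of linear predictors of the reference
#'   sample (must be non-empty).
#' @return object of class \code{bc_baseline}: data frame with \code{age}
#'   and \code{hazard}, carrying the mean relative risk as attribute
#'   \code{mean_rr} and the per-year competing mortality as attribute
#'   \code{mortality}.
#' @export
calibrate_baseline <- function(rates, reference_lp) {
  if (length(reference_lp) == 0L) bc_stop("empty reference sample")
  if (anyNA(reference_lp)) bc_stop("reference linear predictors contain NA")
  per_year <- expand_rate_table(rates)
  mean_rr <- mean(exp(reference_lp))
  structure(data.frame(age = per_year$age,
                       hazard = per_year$incidence / mean_rr),
            class = c("bc_baseline", "data.frame"),
            mean_rr = mean_rr, mortality = per_year$mortality)
}

#' Lifetime absolute risk under competing mortality
#'
#' Discrete annual competing-risk recursion. With disease hazard
#' \eqn{\lambda(t) = \lambda_0(t) e^{lp}}, competing mortality \eqn{m(t)}
#' and total hazard \eqn{h(t) = \lambda(t) + m(t)}, the probability of a
#' breast-cancer diagnosis in year \eqn{t} for a woman event-free at its
#' start is \eqn{\frac{\lambda(t)}{h(t)} (1 - e^{-h(t)})} (the standard
#' cause-allocation decomposition, exact for piecewise-constant hazards),
#' and overall survival carries forward as
#' \eqn{S(t+1) = S(t) e^{-h(t)}}. The absolute risk from \code{age_start}
#' to \code{age_end} is the sum of the yearly contributions weighted by
#' \eqn{S(t)}.
#'
#' @param lp log relative risk(s); vectorized.
#' @param baseline a \code{bc_baseline}, or a numeric vector of per-year
#'   baseline hazards for ages 18..79.
#' @param mortality per-year competing mortality for ages 18..79; defaults
#'   to the mortality attached to \code{baseline}.
#' @param age_start projection start age(s), integer, in [18, 80); scalar or
#'   one per element of \code{lp}.
#' @param age_end projection end age, integer, at most 80.
#' @return numeric vector of absolute risks in [0, 1).
#' @export
lifetime_risk <- function(lp, baseline, mortality = NULL,
                          age_start, age_end = 80) {
  if (inherits(baseline, "bc_baseline")) {
    if (is.null(mortality)) mortality <- attr(baseline, "mortality")
    baseline <- baseline$hazard
  }
  if (length(baseline) != 62L || length(mortality) != 62L)
    bc_stop("baseline and mortality must cover ages 18..79 (length 62)")
  age_start <- as.integer(age_start)
  age_end <- as.integer(age_end)
  check_scalar(age_end, "age_end", 19, 80)
  if (any(age_start < 18L) || any(age_start >= age_end))
    bc_stop("require 18 <= age_start < age_end <= 80")
  n <- max(length(lp), length(age_start))
  lp <- rep_len(lp, n)
  age_start <- rep_len(age_start, n)

  rr <- exp(lp)
  risk <- numeric(n)
  surv <- rep(1, n)
  for (t in 18:(age_end - 1L)) {
    active <- age_start <= t
    if (!any(active)) next
    lam <- baseline[t - 17L] * rr[active]
    h <- lam + mortality[t - 17L]
    contrib <- ifelse(h > 0, (lam / h) * (1 - exp(-h)), 0)
    risk[active] <- risk[active] + surv[active] * contrib
    surv[active] <- surv[active] * exp(-h)
  }
  risk
}

#' Assign risk categories by threshold
#'
#' Half-open binning: category \eqn{j} iff
#' \eqn{t_j \le risk < t_{j+1}}; risks below the first threshold fall in
#' category 0.
#'
#' @param risk numeric vector of absolute risks.
#' @param thresholds strictly ascending probabilities in (0, 1).
#' @return integer vector of category indices, 0-based.
#' @export
categorize_risk <- function(risk, thresholds = c(0.03, 0.05, 0.10)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    bc_stop("thresholds must be strictly ascending")
  if (any(thresholds <= 0 | thresholds >= 1))
    bc_stop("thresholds must lie in (0, 1)")
  findInterval(risk, thresholds)
}

#' Labels for threshold categories
#'
#' @param thresholds ascending probabilities.
#' @return character labels like \code{"<3%"}, \code{"3%-5%"}, \code{">=5%"}.
#' @export
category_labels <- function(thresholds) {
  pct <- sub("\\.0$", "", sprintf("%.1f", 100 * thresholds))
  c(paste0("<", pct[1], "%"),
    if (length(pct) > 1)
      paste0(pct[-length(pct)], "%-", pct[-1], "%"),
    paste0(">=", pct[length(pct)], "%"))
}
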