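#' Default marginal distribution parameters for synthetic cohorts
#'
#' Per-status means/SDs and prevalences emulating a Nigerian/West-African
#' hospital-based breast-cancer case-control study: cases are older, taller,
#' breastfeed for fewer months, and carry more pathogenic variants and a
#' higher polygenic score than controls. Covariates are drawn independently
#' within status (only marginal summaries are emulated; see the methods
#' vignette for what this does and does not capture).
#'
#' @return nested list with \code{case} and \code{control} sublists; each
#'   holds \code{mean}/\code{sd} pairs for the continuous fields,
#'   prevalences for the binary fields, and per-gene PV carrier
#'   probabilities. Control-group PV frequencies are small but nonzero so
#'   generated data never yield degenerate infinite odds ratios.
#' @export
cohort_sim_params <- function() {
  list(
    control = list(
      age = c(41.5, 13.8), age_menarche = c(15.3, 2.2), parity = c(3.9, 2.6),
      breastfeeding_months = c(67.0, 54.3), height_cm = c(159, 6.6),
      bmi = c(26.5, 5.8), benign_breast_disease = 0.033,
      family_history = 0.020, alcohol = 0.048, prs = c(0.182, 0.314),
      pv = c(BRCA1 = 0.003, BRCA2 = 0.006, PALB2 = 0.001, ATM = 0.001,
             CHEK2 = 0.0005, BARD1 = 0.001, RAD51C = 0.0005,
             RAD51D = 0.0005, TP53 = 0.001)),
    case = list(
      age = c(49.5, 12.2), age_menarche = c(15.2, 2.0), parity = c(3.8, 2.1),
      breastfeeding_months = c(54.3, 39.4), height_cm = c(162, 7.3),
      bmi = c(26.3, 5.9), benign_breast_disease = 0.051,
      family_history = 0.036, alcohol = 0.082, prs = c(0.268, 0.317),
      pv = c(BRCA1 = 0.027, BRCA2 = 0.018, PALB2 = 0.007, ATM = 0.002,
             CHEK2 = 0.001, BARD1 = 0.003, RAD51C = 0.001,
             RAD51D = 0.001, TP53 = 0.002))
  )
}

#' Default per-field missingness rates for synthetic cohorts
#'
#' Rates chosen to emulate a study of ~1686 participants with sporadic
#' questionnaire missingness and heavy, status-differential missingness of
#' panel sequencing (more cases than controls un-genotyped).
#'
#' @return named list of per-field missingness probabilities; the \code{pv}
#'   entry is a per-status pair applied to all nine genes jointly (a woman
#'   is either panel-sequenced or not).
#' @export
default_missingness <- function() {
  list(family_history = 1 / 1686, age_menarche = 57 / 1686,
       parity = 19 / 1686, height_cm = 46 / 1686, alcohol = 6 / 1686,
       breastfeeding_months = 28 / 1686, bmi = 74 / 1686,
       pv = c(case = 0.572, control = 0.412))
}

# inverse-CDF truncated normal: deterministic, vectorized. The location of
# the underlying normal is shifted so the truncated distribution's mean
# equals `mean` (truncation would otherwise bias heavily censored fields,
# e.g. breastfeeding months at 0).
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  mu <- if (is.finite(lo) || is.finite(hi))
    stats::uniroot(function(m) tmean(m) - mean,
                   interval = mean + c(-6, 6) * sd, tol = 1e-9)$root
  else mean
  plo <- stats::pnorm(lo, mu, sd); phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sd)
}

draw_covariates <- function(n, p) {
  data.frame(
    age = round(rtruncnorm(n, p$age[1], p$age[2], 18, 79), 1),
    age_menarche = round(rtruncnorm(n, p$age_menarche[1], p$age_menarche[2], 8, 25)),
    parity = round(rtruncnorm(n, p$parity[1], p$parity[2], 0, 25)),
    breastfeeding_months = round(rtruncnorm(n, p$breastfeeding_months[1],
                                            p$breastfeeding_months[2], 0, 400), 1),
    benign_breast_disease = stats::rbinom(n, 1, p$benign_breast_disease),
    family_history = stats::rbinom(n, 1, p$family_history),
    height_cm = round(rtruncnorm(n, p$height_cm[1], p$height_cm[2], 120, 200), 1),
    bmi = round(rtruncnorm(n, p$bmi[1], p$bmi[2], 13, 60), 1),
    alcohol = stats::rbinom(n, 1, p$alcohol),
    prs = round(stats::rnorm(n, p$prs[1], p$prs[2]), 6)
  )
}

draw_pv <- function(n, pv_freqs) {
  out <- lapply(bc_genes, function(g)
    stats::rbinom(n, 1, unname(pv_freqs[[g]])))
  names(out) <- paste0("pv_", bc_genes)
  as.data.frame(out)
}

#' Generate a marginal-mode synthetic case-control cohort
#'
#' Draws each covariate independently per status from
#' \code{\link{cohort_sim_params}}: truncated normals for continuous fields
#' (age at least 18, parity rounded and non-negative, months non-negative),
#' Bernoulli draws for binary factors and PV carriers, and a normal PRS.
#' Deterministic given \code{seed}.
#'
#' @param n_cases,n_controls numbers of cases and controls.
#' @param seed integer seed (mandatory).
#' @param params distribution parameters (see \code{\link{cohort_sim_params}}).
#' @param missingness optional per-field missingness rates (see
#'   \code{\link{default_missingness}}); \code{NULL} generates complete data.
#' @return an unimputed \code{bc_cohort}.
#' @export
generate_cohort <- function(n_cases, n_controls, seed,
                            params = cohort_sim_params(),
                            missingness = NULL) {
  if (missing(seed)) bc_stop("a seed is required")
  set.seed(seed)
  draw <- function(n, p, status, prefix) {
    cbind(data.frame(id = sprintf("%s%d", prefix, seq_len(n)),
                     status = rep(status, n)),
          draw_covariates(n, p), draw_pv(n, p$pv))
  }
  df <- rbind(draw(n_controls, params$control, 0, "ctrl_"),
              draw(n_cases, params$case, 1, "case_"))
  cohort <- as_bc_cohort(df, provenance = sprintf("synthetic marginal (seed %d)", seed))
  if (!is.null(missingness))
    cohort <- inject_missingness(cohort, missingness, seed = seed + 1L)
  cohort
}

#' Inject missingness into a cohort
#'
#' Sets each field missing independently with its configured rate. The
#' \code{pv} rate applies to all nine genes jointly (panel sequenced or
#' not) and may differ by status to mimic differential sequencing coverage.
#'
#' @param cohort an unimputed \code{bc_cohort}.
#' @param rates named list: epidemiologic field names mapped to
#'   probabilities, plus optionally \code{pv} (a scalar or a
#'   \code{c(case=, control=)} pair).
#' @param seed integer seed.
#' @return the cohort with missing values injected.
#' @export
inject_missingness <- function(cohort, rates, seed) {
  stopifnot(inherits(cohort, "bc_cohort"))
  if (is_imputed(cohort)) bc_stop("cannot inject missingness into an imputed cohort")
  if (missing(seed)) bc_stop("a seed is required")
  bad <- unlist(rates)[unlist(rates) < 0 | unlist(rates) > 1]
  if (length(bad)) bc_stop("missingness rates must lie in [0, 1]")
  set.seed(seed)
  n <- nrow(cohort)
  out <- cohort
  for (field in setdiff(names(rates), "pv")) {
    if (!field %in% bc_epi_fields && field != "prs")
      bc_stop("unknown field in missingness rates: %s", field)
    out[[field]][stats::runif(n) < rates[[field]]] <- NA_real_
  }
  if (!is.null(rates$pv)) {
    r <- rates$pv
    p <- if (length(r) == 1L) rep(r, n)
         else unname(r[ifelse(out$status == 1, "case", "control")])
    drop <- stats::runif(n) < p
    for (col in bc_pv_cols()) out[[col]][drop] <- NA_real_
  }
  out
}

#' Generate a synthetic age-band rate table
#'
#' Smooth unimodal (Gaussian-in-age) breast-cancer incidence over 5-year
#' bands on [18, 80), scaled so the peak band attains the configured peak
#' rate, with Gompertz-style monotone-increasing competing mortality.
#' Default peak, 64.6 per 100 000, matches the upper range of age-specific
#' incidence reported for Nigeria.
#'
#' @param peak_per_100k peak band incidence per 100 000 person-years.
#' @param peak_age age of peak incidence.
#' @param width Gaussian width (years) of the incidence curve.
#' @param mortality_at_18_per_100k competing mortality at age 18.
#' @param mortality_growth exponential growth rate of mortality per year of
#'   age.
#' @param zero_mortality if \code{TRUE}, competing mortality is identically
#'   zero (useful for closed-form checks).
#' @return a \code{bc_rate_table}.
#' @export
generate_rate_table <- function(peak_per_100k = 64.6, peak_age = 50,
                                width = 15, mortality_at_18_per_100k = 50,
                                mortality_growth = 0.055,
                                zero_mortality = FALSE) {
  check_scalar(peak_per_100k, "peak_per_100k", lo = 1e-9)
  starts <- c(18L, seq(20L, 75L, 5L))
  ends <- c(seq(20L, 75L, 5L), 80L)
  mid <- (starts + ends) / 2
  shape <- exp(-(mid - peak_age)^2 / (2 * width^2))
  incidence <- (peak_per_100k / 1e5) * shape / max(shape)
  mortality <- if (zero_mortality) rep(0, length(mid))
               else (mortality_at_18_per_100k / 1e5) *
                    exp(mortality_growth * (mid - 18))
  bc_rate_table(starts, ends, incidence, mortality)
}

#' Generate a generative-mode cohort with known ground truth
#'
#' Simulates the disease process itself rather than sampling marginals: a
#' source population of control-like covariate vectors is drawn, each
#' woman's true linear predictor is computed from a known coefficient set
#' (combined variant), the baseline hazard is calibrated to the supplied
#' rates against that population, and each life course is simulated year by
#' year (disease vs competing death via the cause-allocation factor) up to
#' the woman's enrollment age. Women diagnosed before enrollment become
#' cases (enrolled at diagnosis age); disease-free survivors become
#' controls; deaths are discarded. The requested numbers of cases and
#' controls are then sampled.
#'
#' @param n_cases,n_controls requested counts.
#' @param seed integer seed (mandatory).
#' @param coefficients the true \code{bc_coefficients} generating the data.
#' @param rates a \code{bc_rate_table}; population incidence among the
#'   simulated subjects matches it by construction.
#' @param params covariate distribution parameters; the \code{control}
#'   sublist describes the source population.
#' @param pool_size number of source-population women to simulate; the
#'   default scales with the expected case yield under the supplied rates.
#' @return an unimputed, complete \code{bc_cohort} with attributes
#'   \code{true_lp} (numeric vector aligned with rows) and
#'   \code{true_variant}.
#' @export
generate_generative_cohort <- function(n_cases, n_controls, seed,
                                       coefficients = default_coefficients(),
                                       rates = generate_rate_table(),
                                       params = cohort_sim_params(),
                                       pool_size = NULL) {
  if (missing(seed)) bc_stop("a seed is required")
  set.seed(seed)
  per_year <- expand_rate_table(rates)
  # rough expected case yield: cumulative incidence to the mean enrollment age
  if (is.null(pool_size)) {
    cum_inc <- sum(per_year$incidence[per_year$age < params$control$age[1] + 10])
    pool_size <- ceiling(max(n_cases / max(cum_inc, 1e-6) * 2.5,
                             n_controls * 1.5))
  }

  pop <- cbind(draw_covariates(pool_size, params$control),
               draw_pv(pool_size, params$control$pv))
  pop$id <- paste0("sim_", seq_len(pool_size))
  pop$status <- 0
  pop_cohort <- as_bc_cohort(pop, provenance = "generative source population",
                             imputed = TRUE)

  coefficients <- adjust_family_history(coefficients, "combined")
  true_lp <- linear_predictor(pop_cohort, coefficients, "combined")
  baseline <- calibrate_baseline(rates, true_lp)

  enroll_age <- floor(pop$age)
  rr <- exp(true_lp)
  alive <- rep(TRUE, pool_size)
  diseased <- rep(FALSE, pool_size)
  diag_age <- rep(NA_integer_, pool_size)
  for (t in 18:79) {
    active <- which(alive & !diseased & enroll_age > t)
    if (!length(active)) next
    lam <- baseline$hazard[t - 17L] * rr[active]
    m <- attr(baseline, "mortality")[t - 17L]
    h <- lam + m
    event <- stats::runif(length(active)) < (1 - exp(-h))
    if (any(event)) {
      ev <- active[event]
      is_disease <- stats::runif(length(ev)) < (lam[event] / h[event])
      diseased[ev[is_disease]] <- TRUE
      diag_age[ev[is_disease]] <- t
      alive[ev[!is_disease]] <- FALSE
    }
  }
  case_idx <- which(diseased)
  ctrl_idx <- which(alive & !diseased)
  if (length(case_idx) < n_cases || length(ctrl_idx) < n_controls)
    bc_stop(paste0("simulated population yielded %d cases and %d controls; ",
                   "need %d and %d — increase pool_size (used %d)"),
            length(case_idx), length(ctrl_idx), n_cases, n_controls, pool_size)
  case_idx <- sort(sample(case_idx, n_cases))
  ctrl_idx <- sort(sample(ctrl_idx, n_controls))

  pop$status[case_idx] <- 1
  pop$age[case_idx] <- diag_age[case_idx]  # cases enroll at diagnosis
  keep <- c(case_idx, ctrl_idx)
  out <- as_bc_cohort(pop[keep, , drop = FALSE],
                      provenance = sprintf("synthetic generative (seed %d)", seed))
  attr(out, "true_lp") <- true_lp[keep]
  attr(out, "true_variant") <- "combined"
  out
}
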