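# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (brute force / Monte-Carlo) that share
# no code with the package internals they check.

# exhaustive pairwise Mann-Whitney AUROC
brute_auroc <- function(cases, controls) {
  tot <- 0
  for (x in cases) for (y in controls)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cases) * length(controls))
}

# Monte-Carlo life-course estimate of absolute risk: simulate each year's
# event as Bernoulli(1 - exp(-h)) and allocate to disease with probability
# lambda/h; returns the estimated probability and its standard error.
mc_lifetime_risk <- function(lp, baseline_hazard, mortality,
                             age_start, age_end, n = 1e5) {
  lam_all <- baseline_hazard * exp(lp)
  alive <- rep(TRUE, n)
  disease <- rep(FALSE, n)
  for (t in age_start:(age_end - 1)) {
    i <- t - 17
    at_risk <- which(alive & !disease)
    if (!length(at_risk)) break
    h <- lam_all[i] + mortality[i]
    if (h <= 0) next
    event <- at_risk[stats::runif(length(at_risk)) < 1 - exp(-h)]
    if (length(event)) {
      is_dis <- stats::runif(length(event)) < lam_all[i] / h
      disease[event[is_dis]] <- TRUE
      alive[event[!is_dis]] <- FALSE
    }
  }
  p <- mean(disease)
  list(estimate = p, se = sqrt(p * (1 - p) / n))
}

# Monte-Carlo estimate of the family-history log-OR induced by a single
# diallelic variant (log-OR beta, allele frequency f) between a proband and
# a first-degree relative sharing one allele identical by descent, in the
# rare-disease limit: log E[e^{b(Gp+Gr)}] - log E[e^{bGp}] - log E[e^{bGr}].
# Standard error by batch means.
fh_pair_logor_sim <- function(beta, f, n = 2e6, batches = 100) {
  a1 <- stats::rbinom(n, 1, f)  # allele shared IBD
  a2 <- stats::rbinom(n, 1, f)
  b <- stats::rbinom(n, 1, f)
  gp <- a1 + a2
  gr <- a1 + b
  est_fun <- function(idx)
    log(mean(exp(beta * (gp[idx] + gr[idx])))) -
      log(mean(exp(beta * gp[idx]))) - log(mean(exp(beta * gr[idx])))
  batch_idx <- split(seq_len(n), rep(seq_len(batches), length.out = n))
  ests <- vapply(batch_idx, est_fun, numeric(1))
  list(estimate = est_fun(seq_len(n)),
       se = stats::sd(ests) / sqrt(batches))
}

# small fully observed cohort built in code
make_test_cohort <- function(n_cases = 5, n_controls = 5, imputed = FALSE) {
  n <- n_cases + n_controls
  df <- data.frame(
    id = paste0("p", seq_len(n)),
    status = rep(c(1, 0), c(n_cases, n_controls)),
    age = seq(30, 60, length.out = n),
    age_menarche = rep(15, n), parity = rep(2, n),
    breastfeeding_months = rep(24, n), benign_breast_disease = rep(0, n),
    family_history = rep(0, n), height_cm = rep(160, n), bmi = rep(22, n),
    alcohol = rep(0, n), prs = seq(-0.2, 0.4, length.out = n)
  )
  for (g in bc_genes) df[[paste0("pv_", g)]] <- 0
  as_bc_cohort(df, provenance = "test", imputed = imputed)
}

# minimal coefficient set with controllable pieces
make_test_coeffs <- function(epi_beta = 0, fh = 0.47, prs_coef = 1,
                             pv = NULL, snv = NULL, prs_variance = 0.1) {
  epi <- stats::setNames(rep(epi_beta, length(bcrisk:::bc_epi_terms)),
                         bcrisk:::bc_epi_terms)
  epi[["family_history"]] <- fh
  bc_coefficients(epi, prs_coefficient = prs_coef, pv = pv,
                  snv_weights = snv, prs_variance = prs_variance)
}

flat_rates <- function(incidence = 0.001, mortality = 0.002) {
  bc_rate_table(18, 80, incidence, mortality)
}
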