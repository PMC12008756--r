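#' Area under the ROC curve with DeLong confidence interval
#'
#' Mann-Whitney estimator: the proportion of case-control pairs in which
#' the case scores higher, ties counting one half. The confidence interval
#' uses the DeLong variance (empirical variance of the case and control
#' placement values).
#'
#' @param case_scores,control_scores numeric vectors of risk scores
#'   (non-empty).
#' @param conf confidence level (default 0.95).
#' @return object of class \code{bc_roc}: list with \code{auroc},
#'   \code{ci_low}, \code{ci_high}, \code{se}, \code{method},
#'   \code{n_cases}, \code{n_controls}.
#' @export
#' @examples
#' auroc(c(2, 3), c(1, 2.5))  # 0.75
auroc <- function(case_scores, control_scores, conf = 0.95) {
  n1 <- length(case_scores); n0 <- length(control_scores)
  if (n1 == 0L || n0 == 0L) bc_stop("both score groups must be non-empty")
  if (anyNA(case_scores) || anyNA(control_scores)) bc_stop("scores contain NA")
  r <- rank(c(case_scores, control_scores))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # DeLong: placement value of each case against all controls and vice versa
  v10 <- vapply(case_scores, function(s)
    mean((s > control_scores) + 0.5 * (s == control_scores)), numeric(1))
  v01 <- vapply(control_scores, function(s)
    mean((case_scores > s) + 0.5 * (case_scores == s)), numeric(1))
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  if (is.na(se)) se <- 0  # single observation in a group
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(auroc = auc,
                 ci_low = max(0, auc - z * se),
                 ci_high = min(1, auc + z * se),
                 se = se, method = "unadjusted",
                 n_cases = n1, n_controls = n0),
            class = "bc_roc")
}

#' Age-adjusted AUROC by stratified placement values
#'
#' Cases and controls with different age distributions confound the ROC
#' comparison. This estimator stratifies by age bin; each case's placement
#' value is the proportion of same-stratum controls scoring above her (ties
#' one half), and the adjusted AUROC is one minus the mean placement value
#' over all cases in usable strata (strata with at least one case and one
#' control; others are dropped with a warning). The confidence interval is a
#' stratified bootstrap percentile interval, resampling cases and controls
#' within stratum.
#'
#' @param scores numeric vector of risk scores.
#' @param ages numeric vector of ages, same length.
#' @param statuses 0/1 vector (1 = case), same length.
#' @param age_bin_width width of the age strata in years (default 10).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap; required, so that reported
#'   intervals are reproducible.
#' @param conf confidence level.
#' @return a \code{bc_roc} with \code{method = "age_adjusted"}.
#' @export
age_adjusted_auroc <- function(scores, ages, statuses, age_bin_width = 10,
                               n_boot = 1000, seed, conf = 0.95) {
  n <- length(scores)
  if (length(ages) != n || length(statuses) != n)
    bc_stop("scores, ages and statuses must have equal length")
  if (missing(seed)) bc_stop("a bootstrap seed is required")
  check_scalar(age_bin_width, "age_bin_width", 1, 100)
  stratum <- floor(ages / age_bin_width)

  placement_mean <- function(scores, statuses, stratum) {
    tot <- 0; n_case <- 0L
    for (s in unique(stratum)) {
      cs <- scores[stratum == s & statuses == 1]
      ct <- scores[stratum == s & statuses == 0]
      if (length(cs) == 0L || length(ct) == 0L) next
      pv <- vapply(cs, function(x)
        mean((ct > x) + 0.5 * (ct == x)), numeric(1))
      tot <- tot + sum(pv); n_case <- n_case + length(cs)
    }
    if (n_case == 0L) return(NA_real_)
    tot / n_case
  }

  usable <- vapply(unique(stratum), function(s)
    any(statuses[stratum == s] == 1) && any(statuses[stratum == s] == 0),
    logical(1))
  if (!any(usable)) bc_stop("no age stratum contains both a case and a control")
  if (!all(usable))
    bc_warn("%d age stratum(s) without both cases and controls dropped",
            sum(!usable))

  auc <- 1 - placement_mean(scores, statuses, stratum)

  boot <- numeric(n_boot)
  old_state <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_state)) assign(".Random.seed", old_state, .GlobalEnv))
  set.seed(seed)
  groups <- split(seq_len(n), list(stratum, statuses), drop = TRUE)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(groups, function(g)
      g[sample.int(length(g), replace = TRUE)]), use.names = FALSE)
    boot[b] <- 1 - placement_mean(scores[idx], statuses[idx], stratum[idx])
  }
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(auroc = auc, ci_low = qs[1], ci_high = qs[2],
                 se = stats::sd(boot, na.rm = TRUE), method = "age_adjusted",
                 n_cases = sum(statuses == 1), n_controls = sum(statuses == 0)),
            class = "bc_roc")
}

#' @export
print.bc_roc <- function(x, ...) {
  cat(sprintf("AUROC (%s): %.3f (95%% CI, %.3f-%.3f); %d cases, %d controls\n",
              x$method, x$auroc, x$ci_low, x$ci_high, x$n_cases, x$n_controls))
  invisible(x)
}

#' Threshold-based risk stratification summary
#'
#' Counts and percentages of cases and controls per risk category.
#' Percentages are rounded half away from zero to one decimal at this
#' reporting layer only.
#'
#' @param risks numeric vector of absolute risks.
#' @param statuses 0/1 vector, same length.
#' @param thresholds ascending probabilities (default 3/5/10 percent).
#' @return data frame with columns \code{status}, \code{category},
#'   \code{count}, \code{pct}.
#' @export
threshold_summary <- function(risks, statuses, thresholds = c(0.03, 0.05, 0.10)) {
  if (length(risks) != length(statuses))
    bc_stop("risks and statuses must have equal length")
  cats <- categorize_risk(risks, thresholds)
  labels <- category_labels(thresholds)
  out <- expand.grid(category = seq_along(labels) - 1L, status = c(0L, 1L))
  out$count <- mapply(function(k, s) sum(cats == k & statuses == s),
                      out$category, out$status)
  totals <- c(`0` = sum(statuses == 0), `1` = sum(statuses == 1))
  out$pct <- round_half_up(100 * out$count / totals[as.character(out$status)], 1)
  data.frame(status = ifelse(out$status == 1, "case", "control"),
             category = labels[out$category + 1L],
             count = out$count, pct = out$pct, stringsAsFactors = FALSE)
}

#' Reclassification table between two models
#'
#' Cross-tabulates old-model versus new-model risk categories separately for
#' cases and controls, with row percentages (half away from zero, one
#' decimal).
#'
#' @param old_cats,new_cats integer category indices (0-based) from
#'   \code{\link{categorize_risk}} under the old and new model.
#' @param statuses 0/1 vector, same length.
#' @param labels category labels; length determines the table dimension.
#' @return object of class \code{bc_reclass}: list with per-status count
#'   matrices (\code{cases}, \code{controls}), row-percentage matrices, and
#'   the labels.
#' @export
reclassification_table <- function(old_cats, new_cats, statuses,
                                   labels = c("<3%", "3%-10%", ">=10%")) {
  n <- length(old_cats)
  if (length(new_cats) != n || length(statuses) != n)
    bc_stop("inputs must have equal length")
  k <- length(labels)
  if (any(c(old_cats, new_cats) < 0 | c(old_cats, new_cats) >= k))
    bc_stop("category index outside label range")
  tab <- function(s) {
    m <- table(factor(old_cats[statuses == s], levels = 0:(k - 1)),
               factor(new_cats[statuses == s], levels = 0:(k - 1)))
    m <- matrix(as.integer(m), k, k, dimnames = list(old = labels, new = labels))
    m
  }
  row_pct <- function(m) {
    p <- 100 * m / pmax(rowSums(m), 1L)
    round_half_up(p, 1)
  }
  m_case <- tab(1); m_ctrl <- tab(0)
  structure(list(cases = m_case, controls = m_ctrl,
                 cases_pct = row_pct(m_case), controls_pct = row_pct(m_ctrl),
                 labels = labels),
            class = "bc_reclass")
}

#' @export
print.bc_reclass <- function(x, ...) {
  for (grp in c("controls", "cases")) {
    cat(sprintf("%s (rows = old model, cols = new model):\n", grp))
    m <- x[[grp]]; p <- x[[paste0(grp, "_pct")]]
    disp <- matrix(sprintf("%d (%.1f)", m, p), nrow(m),
                   dimnames = dimnames(m))
    print(disp, quote = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' Categorical net reclassification index
#'
#' Net proportion of cases moved to a higher risk category minus the net
#' proportion of controls moved higher:
#' \deqn{NRI = \frac{up_{case} - down_{case}}{n_{case}} -
#'             \frac{up_{ctrl} - down_{ctrl}}{n_{ctrl}}}
#' where "up" counts members above the diagonal of the reclassification
#' table (new category higher than old) and "down" below it.
#'
#' @param table a \code{bc_reclass}.
#' @return signed proportion (positive favors the new model).
#' @export
net_reclassification_index <- function(table) {
  stopifnot(inherits(table, "bc_reclass"))
  updown <- function(m) {
    up <- sum(m[upper.tri(m)]); down <- sum(m[lower.tri(m)])
    n <- sum(m)
    if (n == 0L) bc_stop("a status group has zero members")
    (up - down) / n
  }
  updown(table$cases) - updown(table$controls)
}
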