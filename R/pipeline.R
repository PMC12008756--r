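#' Read a pipeline run configuration
#'
#' YAML file with either an \code{inputs} block (paths \code{cohort},
#' \code{coefficients}, \code{rates}, optional \code{dosages},
#' \code{weights}) or a \code{generator} block (\code{n_cases},
#' \code{n_controls}, optional \code{mode: marginal|generative},
#' \code{missingness: default|none}), plus optional \code{variants},
#' \code{thresholds} (stratification), \code{reclass_thresholds},
#' \code{age_bin_width}, \code{n_boot}, \code{seed}, \code{out_dir}.
#' Exactly one of \code{inputs}/\code{generator} must be present.
#'
#' @param path YAML config path.
#' @return a validated config list of class \code{bc_run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) bc_stop("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  defaults <- list(variants = bc_variants,
                   thresholds = c(0.03, 0.05, 0.10),
                   reclass_thresholds = c(0.03, 0.10),
                   reference_variant = "epi_only",
                   new_variant = "combined",
                   age_bin_width = 10, n_boot = 1000,
                   seed = NULL, out_dir = NULL)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$inputs) == is.null(cfg$generator))
    bc_stop("config must contain exactly one of 'inputs' or 'generator'")
  if (is.null(cfg$seed)) bc_stop("config must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  bad <- setdiff(cfg$variants, bc_variants)
  if (length(bad)) bc_stop("unknown variant(s): %s", paste(bad, collapse = ", "))
  if (!is.null(cfg$inputs)) {
    for (k in c("cohort", "coefficients", "rates")) {
      if (is.null(cfg$inputs[[k]])) bc_stop("inputs block missing '%s'", k)
      if (!file.exists(cfg$inputs[[k]]))
        bc_stop("input file not found: %s", cfg$inputs[[k]])
    }
  }
  structure(cfg, class = "bc_run_config")
}

pipeline_load <- function(cfg) {
  if (!is.null(cfg$generator)) {
    g <- cfg$generator
    coeffs <- default_coefficients()
    rates <- generate_rate_table()
    mode <- if (is.null(g$mode)) "marginal" else g$mode
    miss <- if (identical(g$missingness, "default")) default_missingness()
    cohort <- if (mode == "generative")
      generate_generative_cohort(g$n_cases, g$n_controls, seed = cfg$seed,
                                 coefficients = coeffs, rates = rates)
    else
      generate_cohort(g$n_cases, g$n_controls, seed = cfg$seed,
                      missingness = miss)
    list(cohort = cohort, coefficients = coeffs, rates = rates)
  } else {
    cohort <- read_cohort(cfg$inputs$cohort)
    coeffs <- read_coefficients(cfg$inputs$coefficients)
    if (!is.null(cfg$inputs$dosages) && !is.null(coeffs$snv_weights)) {
      dos <- utils::read.csv(cfg$inputs$dosages, row.names = 1,
                             check.names = FALSE)
      prs <- compute_prs(as.matrix(dos), coeffs)
      cohort$prs[match(rownames(dos), cohort$id)] <- prs
    }
    list(cohort = cohort, coefficients = coeffs,
         rates = read_rate_table(cfg$inputs$rates))
  }
}

#' Run the full risk-estimation analysis
#'
#' End to end: load or generate the cohort, mean-impute by status, fit a
#' \code{\link{bc_risk_model}} per requested variant (family-history
#' attenuation + baseline calibration against the cohort's controls),
#' project per-subject lifetime absolute risk, evaluate discrimination
#' (unadjusted and age-adjusted AUROC) and threshold stratification, and
#' cross-tabulate reclassification with the net reclassification index for
#' the designated reference/new variant pair. If \code{out_dir} is set,
#' writes \code{risks.csv} (per subject and variant), \code{report.json},
#' \code{report.txt} and \code{manifest.json}; identical config and seed
#' reproduce identical outputs byte for byte.
#'
#' @param config a \code{bc_run_config}, a config list, or a YAML path.
#' @return invisibly, a list with \code{models}, \code{risks},
#'   \code{evaluation}, \code{reclassification} (when both paired variants
#'   ran), and \code{manifest}.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  inputs <- pipeline_load(cfg)
  cohort <- if (is_imputed(inputs$cohort)) inputs$cohort
            else impute_missing(inputs$cohort)
  status <- cohort$status
  age <- cohort$age

  models <- list(); risks <- list(); evaluation <- list()
  for (v in cfg$variants) {
    fit <- bc_risk_model(inputs$coefficients, inputs$rates, cohort, variant = v)
    pred <- predict(fit, cohort, thresholds = cfg$thresholds)
    roc_u <- auroc(pred$lifetime_risk[status == 1],
                   pred$lifetime_risk[status == 0])
    roc_a <- age_adjusted_auroc(pred$lifetime_risk, age, status,
                                age_bin_width = cfg$age_bin_width,
                                n_boot = cfg$n_boot, seed = cfg$seed)
    models[[v]] <- fit
    risks[[v]] <- pred
    evaluation[[v]] <- list(
      auroc_unadjusted = roc_u, auroc_age_adjusted = roc_a,
      threshold_summary = threshold_summary(pred$lifetime_risk, status,
                                            cfg$thresholds),
      mean_risk = c(controls = mean(pred$lifetime_risk[status == 0]),
                    cases = mean(pred$lifetime_risk[status == 1])))
  }

  reclass <- NULL
  pair <- c(cfg$reference_variant, cfg$new_variant)
  if (all(pair %in% cfg$variants)) {
    old_cat <- categorize_risk(risks[[pair[1]]]$lifetime_risk,
                               cfg$reclass_thresholds)
    new_cat <- categorize_risk(risks[[pair[2]]]$lifetime_risk,
                               cfg$reclass_thresholds)
    tab <- reclassification_table(old_cat, new_cat, status,
                                  category_labels(cfg$reclass_thresholds))
    reclass <- list(reference = pair[1], new = pair[2], table = tab,
                    nri = net_reclassification_index(tab))
  }

  result <- list(models = models, risks = risks, evaluation = evaluation,
                 reclassification = reclass, config = cfg)
  if (!is.null(cfg$out_dir)) result$manifest <- write_outputs(result, cfg)
  invisible(result)
}

write_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  risks <- do.call(rbind, result$risks)
  risks$lp <- round(risks$lp, 10)
  risks$lifetime_risk <- round(risks$lifetime_risk, 10)
  risks$risk_pct <- round(risks$risk_pct, 8)
  utils::write.csv(risks, file.path(cfg$out_dir, "risks.csv"),
                   row.names = FALSE, quote = FALSE)

  roc_rec <- function(r) list(auroc = round(r$auroc, 10),
                              ci = round(c(r$ci_low, r$ci_high), 10))
  report <- list(
    variants = lapply(result$evaluation, function(e) list(
      auroc_unadjusted = roc_rec(e$auroc_unadjusted),
      auroc_age_adjusted = roc_rec(e$auroc_age_adjusted),
      mean_lifetime_risk_pct = round(100 * e$mean_risk, 8),
      threshold_summary = e$threshold_summary)))
  if (!is.null(result$reclassification))
    report$reclassification <- list(
      reference = result$reclassification$reference,
      new = result$reclassification$new,
      cases = result$reclassification$table$cases,
      controls = result$reclassification$table$controls,
      nri = round(result$reclassification$nri, 10))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")

  txt <- c("Breast-cancer absolute-risk estimation report", "")
  for (v in names(result$evaluation)) {
    e <- result$evaluation[[v]]
    txt <- c(txt, sprintf("== %s ==", v),
             sprintf("AUROC unadjusted:   %.3f (%.3f-%.3f)",
                     e$auroc_unadjusted$auroc, e$auroc_unadjusted$ci_low,
                     e$auroc_unadjusted$ci_high),
             sprintf("AUROC age-adjusted: %.3f (%.3f-%.3f)",
                     e$auroc_age_adjusted$auroc, e$auroc_age_adjusted$ci_low,
                     e$auroc_age_adjusted$ci_high),
             sprintf("Mean lifetime risk: controls %.1f%%, cases %.1f%%",
                     100 * e$mean_risk[["controls"]],
                     100 * e$mean_risk[["cases"]]),
             utils::capture.output(print(e$threshold_summary)), "")
  }
  if (!is.null(result$reclassification)) {
    txt <- c(txt, sprintf("== reclassification: %s -> %s ==",
                          result$reclassification$reference,
                          result$reclassification$new),
             utils::capture.output(print(result$reclassification$table)),
             sprintf("Net reclassification index: %.3f",
                     result$reclassification$nri))
  }
  writeLines(txt, file.path(cfg$out_dir, "report.txt"))

  cfg_json <- file.path(cfg$out_dir, "config.json")
  cfg_plain <- unclass(cfg)
  cfg_plain$out_dir <- NULL  # analysis config only: hash is path-independent
  jsonlite::write_json(cfg_plain, cfg_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(seed = cfg$seed,
                   config_hash = unname(tools::md5sum(cfg_json)),
                   package = "bcrisk",
                   version = as.character(utils::packageVersion("bcrisk")),
                   n_subjects = length(unique(risks$id)),
                   variants = cfg$variants)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
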