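bc_epi_terms <- c("age_menarche", "first_live_birth", "additional_live_births",
                  "breastfeeding_months", "benign_breast_disease",
                  "family_history", "height_per_10cm", "bmi_under_18.5",
                  "bmi_25_29.9", "bmi_30plus", "alcohol")

#' Construct a coefficient set
#'
#' Bundles the log odds-ratio coefficients of the relative-risk model: the
#' epidemiologic terms, the per-unit PRS coefficient, per-gene pathogenic
#' variant (PV) log-ORs with risk-allele frequencies, and optionally per-SNV
#' PRS weights with effect-allele frequencies. The family-history log-OR
#' (\code{family_history} in \code{epi}) is stored unadjusted; call
#' \code{\link{adjust_family_history}} to derive the attenuated coefficient
#' used when genetic terms are in the model.
#'
#' @param epi named numeric vector of log-ORs over the terms
#'   \code{age_menarche} (per year), \code{first_live_birth},
#'   \code{additional_live_births} (per child beyond the first),
#'   \code{breastfeeding_months} (per month), \code{benign_breast_disease},
#'   \code{family_history}, \code{height_per_10cm},
#'   \code{bmi_under_18.5}, \code{bmi_25_29.9}, \code{bmi_30plus} (versus the
#'   18.5-24.9 reference band), \code{alcohol}.
#' @param prs_coefficient log-OR per unit of the polygenic risk score.
#' @param pv data frame with columns \code{gene}, \code{beta} (log-OR for
#'   carriers), \code{freq} (risk-allele frequency in (0,1)).
#' @param snv_weights optional data frame with columns \code{variant_id},
#'   \code{effect_allele}, \code{weight} (per-allele log-OR), \code{freq}
#'   (effect-allele frequency in (0,1)).
#' @param centering named list of reference values at which continuous terms
#'   are centered so that the all-reference woman has linear predictor 0:
#'   \code{age_menarche}, \code{breastfeeding_months}, \code{height_cm}.
#' @param prs_variance population variance of the PRS, used in the
#'   family-history attenuation when the PRS enters as a precomputed score
#'   (no SNV weight table); under Hardy-Weinberg independence
#'   \eqn{\sum_k f_k(1-f_k)\beta_k^2 = \tfrac12 Var(PRS)}.
#' @return object of class \code{bc_coefficients}.
#' @export
bc_coefficients <- function(epi, prs_coefficient = 1.0, pv = NULL,
                            snv_weights = NULL,
                            centering = list(age_menarche = 15,
                                             breastfeeding_months = 0,
                                             height_cm = 160),
                            prs_variance = NULL) {
  epi <- unlist(epi)
  missing_terms <- setdiff(bc_epi_terms, names(epi))
  if (length(missing_terms))
    bc_stop("epi coefficients missing term(s): %s",
            paste(missing_terms, collapse = ", "))
  epi <- epi[bc_epi_terms]
  if (!is.null(pv)) {
    pv <- as.data.frame(pv)
    stopifnot(all(c("gene", "beta", "freq") %in% names(pv)))
    if (anyNA(pv$beta) || anyNA(pv$freq))
      bc_stop("pv entries must carry both beta and freq (missing for: %s)",
              paste(pv$gene[is.na(pv$beta) | is.na(pv$freq)], collapse = ", "))
    if (any(pv$freq <= 0 | pv$freq >= 1))
      bc_stop("pv frequencies must lie in (0,1)")
    unknown <- setdiff(pv$gene, bc_genes)
    if (length(unknown)) bc_stop("unknown gene(s): %s", paste(unknown, collapse = ", "))
  }
  if (!is.null(snv_weights)) {
    snv_weights <- as.data.frame(snv_weights)
    stopifnot(all(c("variant_id", "weight", "freq") %in% names(snv_weights)))
    if (!"effect_allele" %in% names(snv_weights)) snv_weights$effect_allele <- NA_character_
    if (anyNA(snv_weights$weight) || anyNA(snv_weights$freq))
      bc_stop("snv_weights entries must carry both weight and freq (missing for: %s)",
              paste(snv_weights$variant_id[is.na(snv_weights$weight) |
                                           is.na(snv_weights$freq)], collapse = ", "))
    if (any(snv_weights$freq <= 0 | snv_weights$freq >= 1))
      bc_stop("snv frequencies must lie in (0,1)")
  }
  structure(list(epi = epi, prs_coefficient = prs_coefficient, pv = pv,
                 snv_weights = snv_weights, centering = centering,
                 prs_variance = prs_variance,
                 family_history_adjusted = NA_real_,
                 adjusted_for = NULL),
            class = "bc_coefficients")
}

#' Default coefficient set for synthetic analyses
#'
#' Plausible log odds ratios for demonstration and simulation work with
#' synthetic cohorts. These are synthetic stand-in values chosen to be
#' epidemiologically reasonable in direction and magnitude; they are not
#' estimates from any published risk model and must not be used for clinical
#' risk assessment.
#'
#' @return a \code{bc_coefficients} object.
#' @export
default_coefficients <- function() {
  bc_coefficients(
    epi = c(age_menarche = -0.04, first_live_birth = -0.20,
            additional_live_births = -0.05, breastfeeding_months = -0.002,
            benign_breast_disease = 0.45, family_history = 0.47,
            height_per_10cm = 0.08, `bmi_under_18.5` = 0.05,
            `bmi_25_29.9` = 0.02, bmi_30plus = -0.10, alcohol = 0.25),
    prs_coefficient = 1.0,
    pv = data.frame(
      gene = bc_genes,
      beta = c(2.30, 1.70, 1.60, 0.70, 0.90, 0.70, 0.70, 0.70, 1.90),
      freq = c(0.0015, 0.0015, 0.0008, 0.0010, 0.0010,
               0.0005, 0.0003, 0.0003, 0.0002)),
    prs_variance = 0.314^2
  )
}

#' Read a coefficient set from a CSV file
#'
#' Format: an optional header block of comment lines
#' \code{# center <field> <value>} and \code{# prs_variance <value>},
#' followed by CSV columns \code{term,beta,freq}. Epidemiologic terms leave
#' \code{freq} blank; the PRS coefficient uses term \code{prs}; PV genes use
#' term \code{pv_<gene>}; SNV weights use term \code{snv_<variant_id>}.
#'
#' @param path path to the coefficient file.
#' @return a \code{bc_coefficients} object.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) bc_stop("coefficient file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  centering <- list(age_menarche = 15, breastfeeding_months = 0, height_cm = 160)
  prs_variance <- NULL
  for (h in hdr) {
    tok <- strsplit(trimws(sub("^#", "", h)), "[[:space:]]+")[[1]]
    if (length(tok) == 3 && tok[1] == "center")
      centering[[tok[2]]] <- as.numeric(tok[3])
    if (length(tok) == 2 && tok[1] == "prs_variance")
      prs_variance <- as.numeric(tok[2])
  }
  df <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                          value = TRUE), collapse = "\n"),
                        stringsAsFactors = FALSE)
  stopifnot(all(c("term", "beta") %in% names(df)))
  if (!"freq" %in% names(df)) df$freq <- NA_real_
  is_pv <- startsWith(df$term, "pv_")
  is_snv <- startsWith(df$term, "snv_")
  is_prs <- df$term == "prs"
  epi <- stats::setNames(df$beta[!is_pv & !is_snv & !is_prs],
                         df$term[!is_pv & !is_snv & !is_prs])
  pv <- if (any(is_pv)) data.frame(gene = sub("^pv_", "", df$term[is_pv]),
                                   beta = df$beta[is_pv], freq = df$freq[is_pv])
  snv <- if (any(is_snv)) data.frame(variant_id = sub("^snv_", "", df$term[is_snv]),
                                     weight = df$beta[is_snv],
                                     freq = df$freq[is_snv])
  bc_coefficients(epi = epi,
                  prs_coefficient = if (any(is_prs)) df$beta[is_prs] else 1.0,
                  pv = pv, snv_weights = snv, centering = centering,
                  prs_variance = prs_variance)
}

#' Write a coefficient set to a CSV file
#'
#' @param coeffs a \code{bc_coefficients} object.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "bc_coefficients"))
  hdr <- c(sprintf("# center %s %.10g", names(coeffs$centering),
                   unlist(coeffs$centering)),
           if (!is.null(coeffs$prs_variance))
             sprintf("# prs_variance %.10g", coeffs$prs_variance))
  rows <- data.frame(term = names(coeffs$epi), beta = unname(coeffs$epi),
                     freq = NA_real_)
  rows <- rbind(rows, data.frame(term = "prs", beta = coeffs$prs_coefficient,
                                 freq = NA_real_))
  if (!is.null(coeffs$pv))
    rows <- rbind(rows, data.frame(term = paste0("pv_", coeffs$pv$gene),
                                   beta = coeffs$pv$beta, freq = coeffs$pv$freq))
  if (!is.null(coeffs$snv_weights))
    rows <- rbind(rows, data.frame(
      term = paste0("snv_", coeffs$snv_weights$variant_id),
      beta = coeffs$snv_weights$weight, freq = coeffs$snv_weights$freq))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(rows, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @export
print.bc_coefficients <- function(x, ...) {
  cat("<bc_coefficients>\n")
  cat("  epidemiologic terms:", length(x$epi), "\n")
  cat(sprintf("  family_history log-OR: %.4f (adjusted: %s)\n",
              x$epi[["family_history"]],
              if (is.na(x$family_history_adjusted)) "not yet derived"
              else sprintf("%.4f for %s", x$family_history_adjusted,
                           x$adjusted_for)))
  cat(sprintf("  PRS coefficient: %.4f\n", x$prs_coefficient))
  cat(sprintf("  PV genes: %s\n",
              if (is.null(x$pv)) "none" else paste(x$pv$gene, collapse = ", ")))
  cat(sprintf("  SNV weights: %s\n",
              if (is.null(x$snv_weights)) "none (PRS consumed as a score)"
              else nrow(x$snv_weights)))
  invisible(x)
}
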