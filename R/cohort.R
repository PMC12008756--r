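#' High- and moderate-penetrance breast cancer genes
#'
#' Genes whose pathogenic-variant (PV) carrier status enters the risk model
#' as a binary covariate.
#'
#' @format character vector of nine gene symbols.
#' @export
bc_genes <- c("BRCA1", "BRCA2", "PALB2", "ATM", "CHEK2",
              "BARD1", "RAD51C", "RAD51D", "TP53")

# epidemiologic questionnaire fields subject to mean imputation
bc_epi_fields <- c("age_menarche", "parity", "breastfeeding_months",
                   "benign_breast_disease", "family_history",
                   "height_cm", "bmi", "alcohol")

bc_pv_cols <- function() paste0("pv_", bc_genes)

bc_cohort_cols <- function() {
  c("id", "status", "age", bc_epi_fields, "prs", bc_pv_cols())
}

#' Construct a cohort from a data frame
#'
#' Validates column names, types and ranges and returns a classed cohort.
#' Missing values are represented as \code{NA}; per-field missingness is
#' therefore carried by the \code{NA} pattern itself and survives file
#' round-trips (empty cell = missing).
#'
#' @param df data frame with columns \code{id}, \code{status} (0 = control,
#'   1 = case), \code{age}, the epidemiologic fields (\code{age_menarche},
#'   \code{parity}, \code{breastfeeding_months}, \code{benign_breast_disease},
#'   \code{family_history}, \code{height_cm}, \code{bmi}, \code{alcohol}),
#'   \code{prs}, and one \code{pv_<gene>} column per gene in
#'   \code{\link{bc_genes}}. Missing non-mandatory columns are added as all-NA.
#' @param provenance character label recorded on the cohort.
#' @param imputed logical; has mean imputation already been applied?
#' @return object of class \code{bc_cohort} (a data frame).
#' @export
as_bc_cohort <- function(df, provenance = "user", imputed = FALSE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("id", "status", "age"))
    if (!col %in% names(df)) bc_stop("mandatory column '%s' is missing", col)
  for (col in setdiff(bc_cohort_cols(), names(df))) df[[col]] <- NA_real_
  df <- df[, bc_cohort_cols()]

  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    bc_stop("duplicate id(s): %s", paste(dup, collapse = ", "))
  }
  num_cols <- setdiff(bc_cohort_cols(), "id")
  n_bad <- 0L
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    n_bad <- n_bad + sum(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    df[[col]] <- v
  }
  if (n_bad > 0L) bc_warn("%d unparseable cell(s) recorded as missing", n_bad)

  # out-of-range values become missing rather than propagating silently
  rules <- list(
    status = c(0, 1), age = c(18, 120), age_menarche = c(5, 30),
    parity = c(0, 30), breastfeeding_months = c(0, 600),
    benign_breast_disease = c(0, 1), family_history = c(0, 1),
    height_cm = c(100, 230), bmi = c(10, 80), alcohol = c(0, 1)
  )
  n_oor <- 0L
  for (col in names(rules)) {
    bad <- !is.na(df[[col]]) & (df[[col]] < rules[[col]][1] | df[[col]] > rules[[col]][2])
    n_oor <- n_oor + sum(bad)
    df[[col]][bad] <- NA_real_
  }
  for (col in bc_pv_cols()) {
    bad <- !is.na(df[[col]]) & !df[[col]] %in% c(0, 1)
    n_oor <- n_oor + sum(bad)
    df[[col]][bad] <- NA_real_
  }
  if (n_oor > 0L) bc_warn("%d out-of-range cell(s) recorded as missing", n_oor)

  if (anyNA(df$status)) bc_stop("column 'status' has missing or invalid values")
  if (anyNA(df$age)) bc_stop("column 'age' has missing or invalid values")

  structure(df, class = c("bc_cohort", "data.frame"),
            provenance = provenance, imputed = imputed)
}

#' Read a cohort from a CSV file
#'
#' File dialect: comma-separated, UTF-8, "." decimal, empty cell = missing,
#' booleans encoded 0/1. See \code{\link{as_bc_cohort}} for the schema.
#'
#' @param path path to the cohort file.
#' @return a \code{bc_cohort}.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) bc_stop("cohort file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  as_bc_cohort(df, provenance = basename(path))
}

#' Write a cohort to a CSV file
#'
#' Inverse of \code{\link{read_cohort}}: empty cells encode missing values, so
#' a write/read round trip reproduces every value and missingness flag.
#'
#' @param cohort a \code{bc_cohort}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "bc_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

is_imputed <- function(cohort) isTRUE(attr(cohort, "imputed"))

#' Mean imputation by case/control status
#'
#' Each missing epidemiologic value is replaced by the mean of the observed
#' values among participants with the same case/control status; missing
#' pathogenic-variant carrier flags are recoded to 0 (non-carrier, the far
#' more common state). Binary fields receive the status-group proportion as a
#' fractional value; the linear predictor accepts fractional binaries.
#'
#' @param cohort an unimputed \code{bc_cohort}.
#' @return a new cohort flagged imputed; the input is untouched.
#' @export
impute_missing <- function(cohort) {
  stopifnot(inherits(cohort, "bc_cohort"))
  if (is_imputed(cohort)) bc_stop("cohort is already imputed")
  out <- cohort
  for (col in bc_epi_fields) {
    v <- out[[col]]
    if (!anyNA(v)) next
    for (s in unique(out$status[is.na(v)])) {
      grp <- out$status == s
      obs <- v[grp & !is.na(v)]
      if (length(obs) == 0L)
        bc_stop("field '%s' is missing for every %s; no donor mean",
                col, if (s == 1) "case" else "control")
      v[grp & is.na(v)] <- mean(obs)
    }
    out[[col]] <- v
  }
  for (col in bc_pv_cols()) out[[col]][is.na(out[[col]])] <- 0
  attr(out, "imputed") <- TRUE
  out
}

#' Drop participants with missing values
#'
#' Complete-case filter used for sensitivity analyses.
#'
#' @param cohort a \code{bc_cohort}.
#' @param scope \code{"epidemiologic"} (questionnaire fields) or \code{"pv"}
#'   (pathogenic-variant carrier flags).
#' @return cohort restricted to complete rows in the chosen scope.
#' @export
exclude_missing <- function(cohort, scope = c("epidemiologic", "pv")) {
  stopifnot(inherits(cohort, "bc_cohort"))
  scope <- match.arg(scope)
  cols <- if (scope == "epidemiologic") bc_epi_fields else bc_pv_cols()
  keep <- !apply(is.na(as.data.frame(cohort)[, cols, drop = FALSE]), 1L, any)
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(sprintf("exclude_missing: removed %d of %d participants (%s scope)",
                    n_drop, nrow(cohort), scope))
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0L) bc_warn("all participants removed; empty cohort")
  attr(out, "provenance") <- attr(cohort, "provenance")
  attr(out, "imputed") <- attr(cohort, "imputed")
  class(out) <- class(cohort)
  out
}

#' @export
print.bc_cohort <- function(x, ...) {
  n1 <- sum(x$status == 1); n0 <- sum(x$status == 0)
  cat(sprintf("<bc_cohort> %d participants (%d cases, %d controls)\n",
              nrow(x), n1, n0))
  cat(sprintf("  provenance: %s; imputed: %s\n",
              attr(x, "provenance"), is_imputed(x)))
  nmiss <- colSums(is.na(as.data.frame(x)))
  nmiss <- nmiss[nmiss > 0]
  if (length(nmiss))
    cat("  missing:", paste(sprintf("%s=%d", names(nmiss), nmiss),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.bc_cohort <- function(object, ...) {
  df <- as.data.frame(object)
  by_status <- function(col, s) {
    v <- df[[col]][df$status == s]
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
      n_missing = sum(is.na(v)))
  }
  fields <- c("age", bc_epi_fields, "prs")
  out <- list(
    n_cases = sum(df$status == 1), n_controls = sum(df$status == 0),
    cases = t(vapply(fields, by_status, numeric(3), s = 1)),
    controls = t(vapply(fields, by_status, numeric(3), s = 0)),
    pv_carriers = colSums(df[, bc_pv_cols()] == 1, na.rm = TRUE)
  )
  class(out) <- "summary.bc_cohort"
  out
}

#' @export
print.summary.bc_cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d cases, %d controls\n", x$n_cases, x$n_controls))
  cat("Cases:\n"); print(round(x$cases, 2))
  cat("Controls:\n"); print(round(x$controls, 2))
  cat("PV carriers:\n"); print(x$pv_carriers)
  invisible(x)
}
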