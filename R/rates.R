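#' Construct an age-band rate table
#'
#' Age-specific breast-cancer incidence and competing (non-breast-cancer)
#' mortality over half-open bands [age_start, age_end) that must tile
#' [18, 80) contiguously.
#'
#' @param age_start,age_end integer band boundaries, half-open.
#' @param incidence breast-cancer incidence per person-year in each band.
#' @param mortality non-breast-cancer mortality per person-year in each band.
#' @return object of class \code{bc_rate_table} (a data frame).
#' @export
bc_rate_table <- function(age_start, age_end, incidence, mortality) {
  df <- data.frame(age_start = as.integer(age_start),
                   age_end = as.integer(age_end),
                   incidence = incidence, mortality = mortality)
  df <- df[order(df$age_start), ]
  if (df$age_start[1] > 18 || df$age_end[nrow(df)] < 80)
    bc_stop("rate bands must cover [18, 80); got [%d, %d)",
            df$age_start[1], df$age_end[nrow(df)])
  gaps <- which(df$age_end[-nrow(df)] != df$age_start[-1])
  if (length(gaps))
    bc_stop("rate bands have a gap or overlap at age(s): %s",
            paste(df$age_end[gaps], collapse = ", "))
  if (any(df$age_end <= df$age_start)) bc_stop("empty rate band")
  if (any(df$incidence < 0) || any(df$mortality < 0))
    bc_stop("rates must be non-negative")
  rownames(df) <- NULL
  structure(df, class = c("bc_rate_table", "data.frame"))
}

#' Read a rate table from a CSV file
#'
#' Columns \code{age_start,age_end,incidence_per_100k,mortality_per_100k};
#' bands are half-open [age_start, age_end). Rates are converted to
#' per-person-year internally.
#'
#' @param path path to the rate file.
#' @return a \code{bc_rate_table}.
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) bc_stop("rate file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("age_start", "age_end", "incidence_per_100k", "mortality_per_100k")
  miss <- setdiff(need, names(df))
  if (length(miss)) bc_stop("rate file missing column(s): %s",
                            paste(miss, collapse = ", "))
  bc_rate_table(df$age_start, df$age_end,
                df$incidence_per_100k / 1e5, df$mortality_per_100k / 1e5)
}

#' Write a rate table to a CSV file (per-100k scale)
#'
#' @param rates a \code{bc_rate_table}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_rate_table <- function(rates, path) {
  stopifnot(inherits(rates, "bc_rate_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# half-open age bands [age_start, age_end); rates per 100000 person-years", con)
  utils::write.csv(data.frame(age_start = rates$age_start,
                              age_end = rates$age_end,
                              incidence_per_100k = rates$incidence * 1e5,
                              mortality_per_100k = rates$mortality * 1e5),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand an age-band rate table to per-year hazards
#'
#' Each single year of age inherits its band's rate (piecewise constant).
#'
#' @param rates a \code{bc_rate_table}.
#' @return data frame with columns \code{age} (18..79), \code{incidence},
#'   \code{mortality}.
#' @export
expand_rate_table <- function(rates) {
  stopifnot(inherits(rates, "bc_rate_table"))
  ages <- 18:79
  band <- findInterval(ages, rates$age_start)
  data.frame(age = ages,
             incidence = rates$incidence[band],
             mortality = rates$mortality[band])
}
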