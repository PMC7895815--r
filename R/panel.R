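#' Country-year rate panels
#'
#' A `rate_panel` is a long-format data frame with one row per
#' (country, year, age_group) holding event counts and/or a pre-computed
#' outcome rate per 1000 women. It is the common currency of every analysis
#' in the package: the interrupted time series engine consumes one or two
#' country series from it, the synthetic control engine consumes a treated
#' unit plus a donor pool.
#'
#' Columns:
#' \describe{
#'   \item{country}{unit label (character)}
#'   \item{year}{calendar year (integer)}
#'   \item{age_group}{one of `"U16"`, `"U18"`, `"U20"`}
#'   \item{births}{birth count (includes stillbirths where the data preparer
#'     folded them in), `NA` if unavailable}
#'   \item{abortions}{abortion count, `NA` if unavailable}
#'   \item{population}{female population of the age group, `NA` if unavailable}
#'   \item{rate}{events per 1000 women; derived from the counts via
#'     [compute_rate()] when absent}
#' }
#'
#' @param country,year,age_group,births,abortions,population,rate vectors of
#'   equal length (counts and rate may be `NA`).
#' @return A validated `rate_panel` (a `data.frame` subclass).
#' @examples
#' p <- rate_panel(country = "England", year = 1998:2000, age_group = "U18",
#'                 rate = c(46.6, 44.8, 43.6))
#' p
#' @export
rate_panel <- function(country, year, age_group = "U18",
                       births = NA_real_, abortions = NA_real_,
                       population = NA_real_, rate = NA_real_) {
  df <- data.frame(country = as.character(country),
                   year = as.integer(year),
                   age_group = as.character(age_group),
                   births = as.numeric(births),
                   abortions = as.numeric(abortions),
                   population = as.numeric(population),
                   rate = as.numeric(rate),
                   stringsAsFactors = FALSE)
  validate_rate_panel(df)
}

panel_columns <- c("country", "year", "age_group",
                   "births", "abortions", "population", "rate")

age_groups <- c("U16", "U18", "U20")

#' Validate a rate panel
#'
#' Checks the structural invariants: unique (country, year, age_group) keys,
#' known age groups, non-negative counts, strictly positive populations.
#' Called by every constructor and reader; exported so externally assembled
#' data frames can be promoted to `rate_panel`.
#'
#' @param df a data frame with at least `country`, `year`, `age_group` and
#'   one of `rate` or the count columns.
#' @return `df` with class `rate_panel`, missing optional columns added as
#'   `NA`, rows ordered by (country, age_group, year).
#' @export
validate_rate_panel <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("country", "year", "age_group")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("panel schema error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!("rate" %in% names(df)) &&
      !all(c("population") %in% names(df)))
    stop("panel schema error: need either a 'rate' column or count columns ",
         "(births[, abortions], population)", call. = FALSE)
  for (col in setdiff(panel_columns, names(df)))
    df[[col]] <- rep(NA_real_, nrow(df))
  df <- df[panel_columns]

  if (anyNA(df$country) || anyNA(df$year) || anyNA(df$age_group))
    stop("panel integrity error: NA in key columns", call. = FALSE)
  if (!is.numeric(df$year) || any(df$year != as.integer(df$year)))
    stop("panel value error: year must be integer calendar years", call. = FALSE)
  df$year <- as.integer(df$year)
  bad_age <- setdiff(unique(df$age_group), age_groups)
  if (length(bad_age) > 0L)
    stop("panel value error: unknown age_group: ", paste(bad_age, collapse = ", "),
         call. = FALSE)

  key <- paste(df$country, df$year, df$age_group, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("panel integrity error: duplicate key (%s, %d, %s)",
                 d$country, d$year, d$age_group), call. = FALSE)
  }
  for (col in c("births", "abortions")) {
    x <- df[[col]]
    if (any(!is.na(x) & x < 0))
      stop("panel value error: negative ", col, call. = FALSE)
  }
  if (any(!is.na(df$population) & df$population <= 0))
    stop("panel value error: population must be > 0", call. = FALSE)
  if (any(!is.na(df$rate) & df$rate < 0))
    stop("panel value error: negative rate", call. = FALSE)

  df <- df[order(df$country, df$age_group, df$year), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("rate_panel", "data.frame")
  df
}

#' @export
print.rate_panel <- function(x, ...) {
  cat(sprintf("<rate_panel> %d rows: %d unit(s), years %d-%d, age group(s) %s\n",
              nrow(x), length(unique(x$country)),
              min(x$year), max(x$year),
              paste(unique(x$age_group), collapse = "/")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Read a rate panel from CSV
#'
#' Expects the long layout written by [write_panel()]: columns
#' `country,year,age_group,births,abortions,population,rate` (optional
#' columns may be absent; empty cells are missing values). A `schema`
#' mapping renames non-standard column headers before validation.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping standard names to
#'   the file's column names, e.g. `c(country = "nation", rate = "preg_rate")`.
#' @return A [rate_panel].
#' @export
read_panel <- function(path, schema = NULL) {
  if (!file.exists(path))
    stop("panel I/O error: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      j <- match(schema[[std]], names(df))
      if (is.na(j))
        stop("panel schema error: missing column(s): ", schema[[std]],
             call. = FALSE)
      names(df)[j] <- std
    }
  }
  for (col in intersect(c("births", "abortions", "population", "rate"),
                        names(df))) {
    x <- df[[col]]
    if (is.character(x)) x[x == ""] <- NA
    xn <- suppressWarnings(as.numeric(x))
    if (any(is.na(xn) & !is.na(x) & x != "NA"))
      stop("panel value error: non-numeric cell in column '", col, "'",
           call. = FALSE)
    df[[col]] <- xn
  }
  validate_rate_panel(df)
}

#' Write a rate panel to CSV
#'
#' Numeric cells are formatted with full precision (up to 17 significant
#' digits) so that `read_panel(write_panel(p))` reproduces `p` exactly;
#' missing values become empty cells, never the text "NA".
#'
#' @param panel a [rate_panel].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_rate_panel(panel)
  out <- as.data.frame(panel)
  for (col in c("births", "abortions", "population", "rate"))
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 17, format = "g"))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("panel I/O error: cannot write ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Outcome rate per 1000 women
#'
#' `rate = 1000 * (births + abortions) / population`. When `abortions` is
#' `NULL`/`NA` the birth-rate convention is used (events = births only),
#' matching the under-18 birth-rate measure for which abortion counts are
#' unavailable across countries.
#'
#' @param births birth count (>= 0).
#' @param abortions abortion count (>= 0), or `NULL`/`NA` for birth-rate mode.
#' @param population female population of the age group (> 0).
#' @return Rate per 1000 women (vectorised).
#' @examples
#' compute_rate(10, 5, 1000)   # 15
#' compute_rate(33, population = 2000)  # birth-rate mode: 16.5
#' @export
compute_rate <- function(births, abortions = NULL, population) {
  if (any(is.na(population)) || any(population <= 0))
    stop("rate value error: population must be > 0", call. = FALSE)
  if (any(births < 0, na.rm = TRUE))
    stop("rate value error: negative births", call. = FALSE)
  events <- births
  if (!is.null(abortions)) {
    if (any(abortions < 0, na.rm = TRUE))
      stop("rate value error: negative abortions", call. = FALSE)
    events <- events + ifelse(is.na(abortions), 0, abortions)
  }
  1000 * events / population
}

#' Percent reduction between two rates
#'
#' `round(100 * (rate_start - rate_end) / rate_start)`, the headline
#' "X% drop" figure, rounded to the nearest integer percent.
#'
#' @param rate_start rate at the start of the comparison period (> 0).
#' @param rate_end rate at the end.
#' @return Integer percent reduction (negative for an increase).
#' @examples
#' percent_reduction(46.6, 18.8)  # 60
#' @export
percent_reduction <- function(rate_start, rate_end) {
  if (any(rate_start <= 0))
    stop("rate value error: rate_start must be > 0", call. = FALSE)
  as.integer(round(100 * (rate_start - rate_end) / rate_start))
}

#' Analysis window
#'
#' Bundles the pre-period start, the intervention year (first year the
#' policy could act on the outcome; 1999 for the Teenage Pregnancy Strategy)
#' and the last post-period year.
#'
#' @param pre_start first pre-intervention year.
#' @param intervention_year first intervention year (default 1999).
#' @param post_end last analysed year.
#' @return An `analysis_window` list.
#' @export
analysis_window <- function(pre_start, intervention_year = 1999L, post_end) {
  pre_start <- as.integer(pre_start)
  intervention_year <- as.integer(intervention_year)
  post_end <- as.integer(post_end)
  if (!(pre_start < intervention_year && intervention_year <= post_end))
    stop("window error: need pre_start < intervention_year <= post_end",
         call. = FALSE)
  structure(list(pre_start = pre_start,
                 intervention_year = intervention_year,
                 post_end = post_end),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window> pre %d-%d | post %d-%d\n",
              x$pre_start, x$intervention_year - 1L,
              x$intervention_year, x$post_end))
  invisible(x)
}

pre_years  <- function(window) window$pre_start:(window$intervention_year - 1L)
post_years <- function(window) window$intervention_year:window$post_end

# Extract one unit's rate series over the window, deriving rate from counts
# where needed; gaps inside the window are an error (no imputation).
unit_series <- function(panel, unit, age_group, window) {
  sub <- panel[panel$country == unit & panel$age_group == age_group, ,
               drop = FALSE]
  if (nrow(sub) == 0L)
    stop("panel integrity error: no rows for unit '", unit, "' age_group ",
         age_group, call. = FALSE)
  yrs <- window$pre_start:window$post_end
  idx <- match(yrs, sub$year)
  if (anyNA(idx))
    stop(sprintf("panel integrity error: unit '%s' missing year(s) %s",
                 unit, paste(yrs[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  sub <- sub[idx, , drop = FALSE]
  r <- sub$rate
  derive <- is.na(r)
  if (any(derive)) {
    if (any(is.na(sub$population[derive])))
      stop("panel integrity error: unit '", unit,
           "' has years with neither rate nor counts", call. = FALSE)
    ab <- sub$abortions[derive]
    r[derive] <- 1000 * (sub$births[derive] +
                           ifelse(is.na(ab), 0, ab)) / sub$population[derive]
  }
  data.frame(year = yrs, rate = r)
}

#' Merge several countries into one aggregate unit
#'
#' Sums births, abortions and population across the named units per
#' (year, age_group) and recomputes the rate from the summed counts —
#' the preparation step for analysing an aggregate such as
#' "England and Wales" as a single treated unit. All constituent units
#' must carry complete count data: rates alone cannot be aggregated
#' without the population denominators.
#'
#' @param panel a [rate_panel].
#' @param units character vector of constituent unit labels (>= 2).
#' @param new_label label for the merged unit.
#' @return A [rate_panel] with the constituents replaced by the aggregate.
#' @export
merge_units <- function(panel, units, new_label) {
  panel <- validate_rate_panel(panel)
  if (length(units) < 2L)
    stop("panel value error: need at least 2 units to merge", call. = FALSE)
  missing_units <- setdiff(units, panel$country)
  if (length(missing_units) > 0L)
    stop("panel integrity error: unknown unit(s): ",
         paste(missing_units, collapse = ", "), call. = FALSE)
  sub <- panel[panel$country %in% units, , drop = FALSE]
  if (anyNA(sub$births) || anyNA(sub$population))
    stop("panel integrity error: merging requires complete births and ",
         "population counts for all constituent units", call. = FALSE)
  key <- interaction(sub$year, sub$age_group, drop = TRUE)
  if (any(table(key) != length(units)))
    stop("panel integrity error: constituent units cover different ",
         "(year, age_group) cells", call. = FALSE)
  agg <- do.call(rbind, lapply(split(sub, key), function(d) {
    ab <- if (all(is.na(d$abortions))) NA_real_ else
      sum(d$abortions, na.rm = TRUE)
    data.frame(country = new_label, year = d$year[1L],
               age_group = d$age_group[1L],
               births = sum(d$births), abortions = ab,
               population = sum(d$population),
               rate = compute_rate(sum(d$births),
                                   if (is.na(ab)) NULL else ab,
                                   sum(d$population)),
               stringsAsFactors = FALSE)
  }))
  validate_rate_panel(rbind(as.data.frame(panel[!panel$country %in% units, ]),
                            agg))
}
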