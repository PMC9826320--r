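#' @keywords internal
"_PACKAGE"

# Canonical column order of the comparison-record table. `season` is either an
# integer year or the literal string "pooled"; coordinates are optional.
comparison_columns <- c(
  "record_id", "study_id", "population_pair_id", "species", "trait",
  "season", "n_seasons",
  "mean_urban", "sd_urban", "n_urban",
  "mean_nonurban", "sd_nonurban", "n_nonurban",
  "lat_urban", "lon_urban", "lat_nonurban", "lon_nonurban",
  "publication_year"
)

#' Trait labels recognised by the comparison-record schema
#'
#' @return Character vector of the three life-history trait labels.
#' @export
trait_levels <- function() c("laying_date", "clutch_size", "n_fledglings")

numeric_comparison_columns <- c(
  "n_seasons", "mean_urban", "sd_urban", "n_urban",
  "mean_nonurban", "sd_nonurban", "n_nonurban",
  "lat_urban", "lon_urban", "lat_nonurban", "lon_nonurban",
  "publication_year"
)

#' Read a table of paired urban/non-urban comparisons
#'
#' Reads a CSV of per-comparison summary statistics: one row per
#' (study, population pair, trait, season) with per-arm mean, SD and sample
#' size. Column order is free; header matching is case-insensitive. Empty
#' cells, `NA` and `NaN` are read as missing values (hand-extracted
#' literature tables are rarely tidy); missing values are preserved, not
#' dropped — filtering is a separate, logged step (see
#' [apply_exclusions()]).
#'
#' @param path Path to a UTF-8, comma-separated file whose header contains
#'   the canonical columns (`record_id`, `study_id`, `population_pair_id`,
#'   `species`, `trait`, `season`, `n_seasons`, `mean_urban`, `sd_urban`,
#'   `n_urban`, `mean_nonurban`, `sd_nonurban`, `n_nonurban`, optional
#'   coordinates, `publication_year`).
#' @return A `data.frame` with one row per comparison, columns in canonical
#'   order, numeric columns parsed as numeric.
#' @seealso [write_comparisons()], [apply_exclusions()]
#' @export
read_comparisons <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("", "NA", "NaN"),
                         colClasses = "character", encoding = "UTF-8")
  names(raw) <- tolower(trimws(names(raw)))
  required <- setdiff(comparison_columns,
                      c("lat_urban", "lon_urban", "lat_nonurban", "lon_nonurban"))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(comparison_columns, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[comparison_columns]
  as_comparison_df(raw)
}

# Coerce a character-mode data.frame into the typed comparison schema,
# with row/column-addressed errors for unparseable cells.
as_comparison_df <- function(df) {
  bad_trait <- !is.na(df$trait) & !(df$trait %in% trait_levels())
  if (any(bad_trait)) {
    stop("unknown trait label in row(s) ", paste(which(bad_trait), collapse = ", "),
         ": ", paste(unique(df$trait[bad_trait]), collapse = ", "))
  }
  for (col in numeric_comparison_columns) {
    x <- df[[col]]
    parsed <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(parsed)
    if (any(bad)) {
      stop("non-numeric value in column '", col, "', row(s) ",
           paste(which(bad), collapse = ", "))
    }
    df[[col]] <- parsed
  }
  # season stays character so "pooled" and years coexist
  df$season <- as.character(df$season)
  rownames(df) <- NULL
  df
}

#' Write comparison records to CSV
#'
#' Inverse of [read_comparisons()]: numeric fields are written at full
#' precision (15 significant digits) so a write/read round trip reproduces
#' them exactly.
#'
#' @param records Comparison `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparisons <- function(records, path) {
  out <- records
  for (col in intersect(numeric_comparison_columns, names(out))) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 15, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Apply inclusion filters to comparison records
#'
#' Removes records that cannot support effect-size computation, in a fixed
#' rule order: (1) any missing per-arm sample size, (2) any missing per-arm
#' SD, (3) any per-arm n equal to one, (4) any per-arm SD of zero. A record
#' failing several rules is tallied once, under the first rule that applies,
#' so the counts reproduce a sequentially reported exclusion breakdown.
#'
#' @param records Comparison `data.frame` as returned by
#'   [read_comparisons()].
#' @return A list with elements `kept` (the filtered `data.frame`) and
#'   `log`, an exclusion log: per-rule counts (`missing_n`, `missing_sd`,
#'   `n_equals_one`, `sd_equals_zero`), total input/kept counts, and a
#'   `data.frame` of removed `record_id`s with the rule that removed each.
#' @export
apply_exclusions <- function(records) {
  n_in <- nrow(records)
  rule <- rep(NA_character_, n_in)
  miss_n  <- is.na(records$n_urban) | is.na(records$n_nonurban)
  miss_sd <- is.na(records$sd_urban) | is.na(records$sd_nonurban)
  n_one   <- (!is.na(records$n_urban) & records$n_urban == 1) |
             (!is.na(records$n_nonurban) & records$n_nonurban == 1)
  sd_zero <- (!is.na(records$sd_urban) & records$sd_urban == 0) |
             (!is.na(records$sd_nonurban) & records$sd_nonurban == 0)
  rule[is.na(rule) & miss_n]  <- "missing_n"
  rule[is.na(rule) & miss_sd] <- "missing_sd"
  rule[is.na(rule) & n_one]   <- "n_equals_one"
  rule[is.na(rule) & sd_zero] <- "sd_equals_zero"
  removed <- !is.na(rule)
  log <- list(
    input = n_in,
    kept = sum(!removed),
    counts = c(missing_n = sum(rule == "missing_n", na.rm = TRUE),
               missing_sd = sum(rule == "missing_sd", na.rm = TRUE),
               n_equals_one = sum(rule == "n_equals_one", na.rm = TRUE),
               sd_equals_zero = sum(rule == "sd_equals_zero", na.rm = TRUE)),
    removed = data.frame(record_id = records$record_id[removed],
                         rule = rule[removed],
                         stringsAsFactors = FALSE)
  )
  kept <- records[!removed, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, log = log)
}

#' Write an exclusion log as JSON
#'
#' @param log The `log` element of [apply_exclusions()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Convert a standard error to a standard deviation
#'
#' `SD = SE * sqrt(n)`, the conversion used when source papers report SE
#' rather than SD.
#'
#' @param se Standard error, positive.
#' @param n Sample size, at least 2.
#' @return The implied standard deviation.
#' @export
sd_from_se <- function(se, n) {
  stopifnot(is.numeric(se), is.numeric(n))
  if (any(se <= 0)) stop("se must be positive")
  if (any(n < 2)) stop("n must be at least 2")
  se * sqrt(n)
}

#' Estimate mean and SD from a three-number summary
#'
#' For sources reporting median and quartiles only: the mean uses the
#' quartile-weighted estimator of Luo and colleagues for the
#' (q1, median, q3) scenario, and the SD uses the Shi-style IQR estimator,
#' `(q3 - q1) / (2 * qnorm((0.75 n - 0.125) / (n + 0.25)))`.
#'
#' @param median,q1,q3 Sample median and first/third quartiles,
#'   `q1 <= median <= q3`.
#' @param n Sample size, at least 2.
#' @return A list with elements `mean` and `sd`. `sd` is 0 (degenerate, will
#'   be caught by [apply_exclusions()]) when `q1 == q3`.
#' @export
summary_from_quartiles <- function(median, q1, q3, n) {
  if (q1 > q3) stop("q1 must not exceed q3")
  if (q1 > median || median > q3) stop("median must lie between q1 and q3")
  if (n < 2) stop("n must be at least 2")
  # Luo et al. optimal weight for the three-number-summary scenario
  w <- 0.7 + 0.39 / n
  mean_est <- w * (q1 + q3) / 2 + (1 - w) * median
  # Shi et al. sample-size-adjusted normal quantile for the IQR
  eta <- (0.75 * n - 0.125) / (n + 0.25)
  sd_est <- (q3 - q1) / (2 * stats::qnorm(eta))
  list(mean = mean_est, sd = sd_est)
}

#' Standardise a laying date to a day-of-year integer
#'
#' Calendar dates are converted to days since 1 January of their year
#' (1 January = 1, leap-aware); day numbers already in `[1, 366]` pass
#' through unchanged.
#'
#' @param x A `Date`, a string parseable as `YYYY-MM-DD`, or a numeric day
#'   number.
#' @param year Ignored for `Date`/string input (the date carries its year).
#' @return Integer day-of-year.
#' @export
standardize_lay_date <- function(x, year = NULL) {
  if (inherits(x, "Date") || (is.character(x) && all(grepl("-", x)))) {
    d <- as.Date(x)
    if (any(is.na(d))) stop("unparseable date: ", paste(x[is.na(as.Date(x))], collapse = ", "))
    return(as.integer(strftime(d, "%j")))
  }
  x <- as.numeric(x)
  if (any(x < 1 | x > 366)) stop("day number outside [1, 366]")
  as.integer(x)
}
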