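#' Load an observation series
#'
#' Reads sparse year -> population observations (CSV with columns
#' `year, source, value_millions`) plus an aggregate column (CSV with columns
#' `year, value_millions`). Values are stored in millions on disk — the unit
#' in which global historical estimates are conventionally printed — and
#' converted to persons on load.
#'
#' With no arguments, loads the bundled global-population series: historical
#' estimates for 1–1950 CE from six scholarly reconstructions, UN census
#' values for 1955–2012, and the published per-year average for the 19
#' fit-target years 1750, 1800, 1850, 1875, 1900, 1920, 1930, 1940, 1950,
#' 1955–1990 (5-year), 1999, and 2012. The bundled aggregate is canonical for
#' fitting and is never silently replaced by a recomputed mean (the published
#' averaging excluded an unstated set of duplicate estimates; see
#' [recompute_average()]).
#'
#' @param path CSV of records, or `NULL` for the bundled file.
#' @param aggregate_path CSV of the aggregate column, or `NULL` for the
#'   bundled file (ignored when `path` is given without `aggregate_path`;
#'   then the aggregate is recomputed as the plain per-year mean).
#' @return `ccpop_observations`: list with `records` (data.frame
#'   `year, source, value` in persons) and `aggregate` (data.frame
#'   `year, value` in persons, ordered by year).
#' @examples
#' obs <- table1_observations()
#' obs$aggregate[obs$aggregate$year == 2012, ]
#' @export
load_observations <- function(path = NULL, aggregate_path = NULL) {
  bundled <- is.null(path)
  if (bundled) {
    path <- system.file("extdata", "table1_observations.csv", package = "ccpop")
    aggregate_path <- system.file("extdata", "table1_average.csv",
                                  package = "ccpop")
  }
  if (!file.exists(path)) data_error(sprintf("no such file: %s", path))
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "source", "value_millions")
  if (!all(need %in% names(rec))) {
    data_error(sprintf("observation CSV must have columns %s",
                       paste(need, collapse = ", ")))
  }
  if (nrow(rec) == 0) data_error("observation file contains no records")
  bad <- which(!is.finite(rec$year) | !is.finite(rec$value_millions) |
                 rec$value_millions <= 0 | rec$year < 1 | rec$year > 2012)
  if (length(bad)) {
    data_error(sprintf("malformed observation row(s): %s",
                       paste(bad, collapse = ", ")))
  }
  records <- data.frame(
    year = as.integer(rec$year),
    source = as.character(rec$source),
    value = rec$value_millions * 1e6,
    stringsAsFactors = FALSE
  )
  if (!is.null(aggregate_path)) {
    if (!file.exists(aggregate_path)) {
      data_error(sprintf("no such file: %s", aggregate_path))
    }
    agg <- read.csv(aggregate_path, stringsAsFactors = FALSE)
    if (!all(c("year", "value_millions") %in% names(agg))) {
      data_error("aggregate CSV must have columns year, value_millions")
    }
    aggregate <- data.frame(year = as.integer(agg$year),
                            value = agg$value_millions * 1e6)
  } else {
    aggregate <- recompute_average(records)
  }
  aggregate <- aggregate[order(aggregate$year), , drop = FALSE]
  rownames(aggregate) <- NULL
  structure(list(records = records, aggregate = aggregate),
            class = "ccpop_observations")
}

#' @rdname load_observations
#' @export
table1_observations <- function() load_observations()

#' @export
print.ccpop_observations <- function(x, ...) {
  cat(sprintf("<ccpop observations: %d records (%d-%d), %d aggregate years>\n",
              nrow(x$records), min(x$records$year), max(x$records$year),
              nrow(x$aggregate)))
  invisible(x)
}

#' Recompute per-year average observations
#'
#' Plain arithmetic mean per year after dropping an exclusion list of
#' (year, source) pairs. Non-normative utility: the bundled aggregate column
#' remains canonical for fitting, because the published averaging excluded
#' duplicate estimates (later studies relying on earlier ones) whose exact
#' set is not recoverable — e.g. the plain mean of the six 1800 CE estimates
#' is ~930 million versus the published 925.
#'
#' @param records data.frame `year, source, value` (persons), e.g.
#'   `obs$records`.
#' @param exclude optional data.frame with columns `year, source` naming
#'   records to drop before averaging.
#' @return data.frame `year, value` (persons); years whose every record was
#'   excluded are absent.
#' @export
recompute_average <- function(records, exclude = NULL) {
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- paste(records$year, records$source) %in%
      paste(exclude$year, exclude$source)
    records <- records[!drop, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    return(data.frame(year = integer(0), value = numeric(0)))
  }
  agg <- aggregate(value ~ year, data = records, FUN = mean)
  agg <- agg[order(agg$year), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write an observation series
#'
#' Inverse of [load_observations()]: writes `records` (and, if `aggregate_path`
#' is given, the aggregate) in the on-disk millions dialect, so that a write
#' followed by a load round-trips exactly.
#'
#' @param obs a `ccpop_observations`.
#' @param path destination CSV for records.
#' @param aggregate_path optional destination CSV for the aggregate.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path, aggregate_path = NULL) {
  rec <- data.frame(year = obs$records$year, source = obs$records$source,
                    value_millions = obs$records$value / 1e6)
  write.csv(rec, path, row.names = FALSE)
  if (!is.null(aggregate_path)) {
    agg <- data.frame(year = obs$aggregate$year,
                      value_millions = obs$aggregate$value / 1e6)
    write.csv(agg, aggregate_path, row.names = FALSE)
  }
  invisible(path)
}

# Aggregate value at a year (persons); NA if absent.
obs_at <- function(obs, year) {
  i <- match(year, obs$aggregate$year)
  if (is.na(i)) NA_real_ else obs$aggregate$value[i]
}
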