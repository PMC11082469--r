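#' Construct a yearly description series
#'
#' The two aligned per-year vectors consumed by every model: counts of species
#' described in each calendar year, and the number of unique describing
#' authors that year. Years with no descriptions carry a count of 0 and an
#' author value floored at 0.1, so that the author series stays strictly
#' positive and can enter the models as a logged exposure offset.
#'
#' @param years Consecutive integer calendar years.
#' @param counts Non-negative integer description counts, one per year.
#' @param authors Per-year unique-author tallies: positive integers, or
#'   exactly 0.1 for years with no parsed authors.
#' @return An object of class `yearly_series` with elements `years`, `counts`,
#'   `authors` and `span` (first and last year).
#' @seealso [tally_series()], [simulate_series()]
#' @export
yearly_series <- function(years, counts, authors) {
  years <- as.integer(years)
  n <- length(years)
  if (n == 0) stop("series must cover at least one year", call. = FALSE)
  if (!identical(years, years[1] + 0:(n - 1L))) {
    stop("`years` must be consecutive calendar years", call. = FALSE)
  }
  if (length(counts) != n || length(authors) != n) {
    stop("`counts` and `authors` must have one value per year", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  ok <- authors == 0.1 | (authors >= 1 & authors == round(authors))
  if (any(!ok)) {
    stop("`authors` values must be positive integers or exactly 0.1",
         call. = FALSE)
  }
  structure(
    list(years = years, counts = as.integer(counts),
         authors = as.numeric(authors),
         span = c(start = years[1], end = years[n])),
    class = "yearly_series"
  )
}

#' @export
print.yearly_series <- function(x, ...) {
  cat(sprintf("<yearly_series> %d-%d (%d years)\n",
              x$span[1], x$span[2], length(x$years)))
  cat(sprintf("  total descriptions: %d; mean %.2f/yr; max %d (%d)\n",
              sum(x$counts), mean(x$counts), max(x$counts),
              x$years[which.max(x$counts)]))
  cat(sprintf("  zero-description years: %d\n", sum(x$counts == 0)))
  invisible(x)
}

#' @export
as.data.frame.yearly_series <- function(x, ...) {
  data.frame(year = x$years, count = x$counts,
             authors_raw = authors_raw(x), authors_offset = x$authors)
}

#' Raw (pre-floor) author counts of a series
#'
#' Inverts the 0.1 floor applied to zero-author years, recovering the integer
#' author tallies (0 where no author was credited). These raw values form the
#' resampling pool for forecasting future taxonomic effort.
#'
#' @param series A [yearly_series()].
#' @return Integer vector of per-year unique-author counts.
#' @export
authors_raw <- function(series) {
  stopifnot(inherits(series, "yearly_series"))
  ifelse(series$authors == 0.1, 0L, as.integer(series$authors))
}

#' Median yearly author count over a window
#'
#' The median number of active describing authors per year over an inclusive
#' window of calendar years, computed on the raw (pre-floor) author counts so
#' that author-free years count as 0. Used as the "active taxonomists"
#' denominator when translating a forecast into a per-taxonomist workload.
#'
#' @param series A [yearly_series()].
#' @param window Length-2 integer vector `c(start, end)`, inclusive, within
#'   the series span.
#' @return The median author count (numeric scalar).
#' @export
median_authors <- function(series, window) {
  stopifnot(inherits(series, "yearly_series"), length(window) == 2)
  window <- as.integer(window)
  if (window[1] > window[2]) stop("empty window", call. = FALSE)
  if (window[1] < series$span[1] || window[2] > series$span[2]) {
    stop("`window` must lie within the series span", call. = FALSE)
  }
  keep <- series$years >= window[1] & series$years <= window[2]
  stats::median(authors_raw(series)[keep])
}

#' Write a yearly series to CSV
#'
#' @param series A [yearly_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a yearly series from CSV
#'
#' Reads a file written by [write_series_csv()] (columns `year`, `count`,
#' `authors_offset`; `authors_raw` is ignored and re-derived).
#'
#' @param path CSV file path.
#' @return A [yearly_series()].
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path)
  yearly_series(d$year, d$count, d$authors_offset)
}
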