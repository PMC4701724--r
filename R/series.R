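#' Annual ecological time series
#'
#' Constructs an `eco_series`, the basic unit of the package: one annual
#' series of biomass, landings, primary production or a derived indicator,
#' from a single source (observed or modeled).
#'
#' @param series_id Character scalar identifying the series (typically a
#'   functional-group code or an indicator code).
#' @param category One of `"biomass"`, `"landings"`, `"primary_production"`,
#'   `"indicator"`.
#' @param source One of `"observed"`, `"modeled"`.
#' @param years Integer vector of years, strictly increasing, no missing
#'   values. Years absent from the record are simply not listed (gaps are
#'   represented by absence, not by `NA` years).
#' @param values Numeric vector, same length as `years`. `NA` is allowed and
#'   marks a missing observation within the recorded span.
#' @param units Character scalar, e.g. `"t"` (metric tons) or
#'   `"dimensionless"` after standardization.
#'
#' @return An object of class `eco_series`.
#' @seealso [standardize()], [align_pair()]
#' @export
eco_series <- function(series_id, category, source, years, values,
                       units = "t") {
  stopifnot(is.character(series_id), length(series_id) == 1L)
  category <- match.arg(category, ECO_CATEGORIES)
  source <- match.arg(source, ECO_SOURCES)
  years <- as.integer(years)
  values <- as.numeric(values)
  if (anyNA(years)) stop("years may not contain missing values")
  if (length(years) != length(values))
    stop("years and values must have equal length")
  if (length(years) > 1L && any(diff(years) <= 0L))
    stop("years must be strictly increasing")
  structure(
    list(series_id = series_id, category = category, source = source,
         years = years, values = values, units = units),
    class = "eco_series"
  )
}

ECO_CATEGORIES <- c("biomass", "landings", "primary_production", "indicator")
ECO_SOURCES <- c("observed", "modeled")

#' @export
print.eco_series <- function(x, ...) {
  n_ok <- sum(!is.na(x$values))
  cat(sprintf("<eco_series> %s [%s, %s] %d years (%s-%s), %d non-missing, units: %s\n",
              x$series_id, x$category, x$source, length(x$years),
              if (length(x$years)) min(x$years) else NA,
              if (length(x$years)) max(x$years) else NA, n_ok, x$units))
  invisible(x)
}

#' @export
as.data.frame.eco_series <- function(x, ...) {
  data.frame(series_id = rep(x$series_id, length(x$years)),
             category = rep(x$category, length(x$years)),
             source = rep(x$source, length(x$years)),
             year = x$years, value = x$values,
             units = rep(x$units, length(x$years)),
             stringsAsFactors = FALSE)
}

#' Inclusive year period
#'
#' @param name Period label, e.g. `"full_hindcast"`.
#' @param start_year,end_year Integer years; both endpoints belong to the
#'   period.
#' @return An `eco_period` object.
#' @export
eco_period <- function(name, start_year, end_year) {
  start_year <- as.integer(start_year); end_year <- as.integer(end_year)
  stopifnot(length(name) == 1L, !is.na(start_year), !is.na(end_year))
  if (start_year > end_year) stop("period start must not exceed end")
  structure(list(name = as.character(name), start_year = start_year,
                 end_year = end_year),
            class = "eco_period")
}

#' @export
print.eco_period <- function(x, ...) {
  cat(sprintf("<eco_period> %s: %d-%d\n", x$name, x$start_year, x$end_year))
  invisible(x)
}

#' Standardize a series to zero mean and unit variance
#'
#' Applies a z-score transform over the full non-missing record of the
#' series: `(x - mean) / sd`, with the sample standard deviation. Biomass
#' and landings series are standardized this way before observed/modeled
#' comparison so that skill metrics are on a common dimensionless scale;
#' indicator inputs are never standardized (indicators are computed on raw
#' series).
#'
#' @param series An [eco_series()].
#' @return The standardized `eco_series` with units `"dimensionless"`.
#'   Standardization is idempotent to within numerical tolerance.
#' @export
standardize <- function(series) {
  stopifnot(inherits(series, "eco_series"))
  x <- series$values
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("degenerate series: fewer than 2 non-missing values")
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s <= 0) stop("degenerate series: zero standard deviation")
  series$values <- (x - mean(x[ok])) / s
  series$units <- "dimensionless"
  series
}

#' Pair observed and modeled series over a period
#'
#' Intersects the non-missing years of an observed and a modeled series,
#' optionally clipped to a period, producing the aligned pair on which all
#' skill metrics operate. Missing years are handled pairwise-complete:
#' years absent or `NA` in either parent are dropped.
#'
#' @param obs,mod `eco_series` objects with the same `series_id` and units.
#' @param period Optional [eco_period()]; if supplied, paired years are
#'   restricted to `[start_year, end_year]` (inclusive).
#' @param min_n Minimum number of paired points (default 3); fewer common
#'   years is an error, since rank correlation is meaningless below that.
#' @return An `eco_pair` with fields `series_id`, `category`, `years`,
#'   `obs`, `mod`, `n`.
#' @export
align_pair <- function(obs, mod, period = NULL, min_n = 3L) {
  stopifnot(inherits(obs, "eco_series"), inherits(mod, "eco_series"))
  if (obs$series_id != mod$series_id)
    stop("cannot pair series with different series_id: ",
         obs$series_id, " vs ", mod$series_id)
  if (!identical(obs$units, mod$units))
    stop("cannot pair series with different units: ",
         obs$units, " vs ", mod$units)
  yo <- obs$years[!is.na(obs$values)]
  ym <- mod$years[!is.na(mod$values)]
  common <- intersect(yo, ym)
  if (!is.null(period)) {
    stopifnot(inherits(period, "eco_period"))
    common <- common[common >= period$start_year & common <= period$end_year]
  }
  common <- sort(common)
  if (length(common) < min_n)
    stop(sprintf("insufficient overlap for '%s': %d common years (need >= %d)",
                 obs$series_id, length(common), min_n))
  structure(
    list(series_id = obs$series_id, category = obs$category,
         years = as.integer(common),
         obs = obs$values[match(common, obs$years)],
         mod = mod$values[match(common, mod$years)],
         n = length(common)),
    class = "eco_pair"
  )
}

#' @export
print.eco_pair <- function(x, ...) {
  cat(sprintf("<eco_pair> %s [%s], n = %d (%d-%d)\n", x$series_id,
              x$category, x$n, min(x$years), max(x$years)))
  invisible(x)
}

#' Plot an observed/modeled pair as overlaid time series
#'
#' @param x An `eco_pair`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.eco_pair <- function(x, ...) {
  graphics::matplot(x$years, cbind(x$obs, x$mod), type = "l", lty = c(1, 2),
                    col = c("navy", "steelblue"), xlab = "year",
                    ylab = "value", main = x$series_id, ...)
  graphics::legend("topleft", c("observed", "modeled"), lty = c(1, 2),
                   col = c("navy", "steelblue"), bty = "n")
  invisible(x)
}
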