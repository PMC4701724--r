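#' Read long-format time-series CSV
#'
#' Reads a long-format file with header
#' `series_id, category, source, year, value, units` into a collection of
#' [eco_series()] objects, one per `(series_id, source)` combination. Rows
#' with an empty `value` cell become gaps (the year is dropped from the
#' series), mirroring how survey series with late onsets are stored.
#'
#' @param path Path to a UTF-8, comma-separated file with `"."` decimal
#'   marks; empty cell = missing.
#' @return A named list of `eco_series`; names are `"<series_id>.<source>"`.
#'   A header-only file yields an empty list.
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(year = "integer"))
  need <- c("series_id", "category", "source", "year", "value", "units")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  bad_cat <- setdiff(unique(df$category), ECO_CATEGORIES)
  if (length(bad_cat))
    stop("unknown category: ", paste(bad_cat, collapse = ", "))
  bad_src <- setdiff(unique(df$source), ECO_SOURCES)
  if (length(bad_src))
    stop("unknown source: ", paste(bad_src, collapse = ", "))
  key <- paste(df$series_id, df$source, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    row <- which(duplicated(key))[1L]
    stop(sprintf("duplicate (series_id, source, year) at data row %d: (%s, %s, %d)",
                 row, df$series_id[row], df$source[row], df$year[row]))
  }
  df$value <- as.numeric(df$value)
  df <- df[!is.na(df$value), , drop = FALSE]
  groups <- split(df, paste(df$series_id, df$source, sep = "."))
  out <- lapply(groups, function(g) {
    g <- g[order(g$year), , drop = FALSE]
    eco_series(g$series_id[1L], g$category[1L], g$source[1L],
               g$year, g$value, units = g$units[1L])
  })
  out[order(names(out))]
}

#' Write a collection of series to long-format CSV
#'
#' Inverse of [read_timeseries_csv()]; finite values round-trip losslessly.
#'
#' @param series A list of [eco_series()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(series, path) {
  rows <- do.call(rbind, lapply(series, as.data.frame))
  if (is.null(rows))
    rows <- data.frame(series_id = character(0), category = character(0),
                       source = character(0), year = integer(0),
                       value = numeric(0), units = character(0))
  rows$value <- fmt_full(rows$value)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# full-precision decimal rendering so that write -> read is exact for doubles
fmt_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read a group-metadata table
#'
#' Per-group ecological attributes feeding the ecosystem indicators:
#' guild membership, commercial / threatened-endangered-protected (TEP)
#' flags, trophic level, and mean price per ton (used by the catch-value
#' indicator).
#'
#' @param path CSV with columns `group_id, name, guild, is_fish,
#'   is_commercial, is_tep, trophic_level, price_per_ton`.
#' @return A `data.frame` with logical flags and validated guilds.
#' @export
read_group_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(md)
}

ECO_GUILDS <- c("demersal_fish", "pelagic_fish", "benthos", "mammal_seal",
                "mammal_whale", "seabird", "other")

validate_metadata <- function(md) {
  need <- c("group_id", "name", "guild", "is_fish", "is_commercial",
            "is_tep", "trophic_level", "price_per_ton")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$group_id)) stop("duplicate group_id in metadata")
  bad <- setdiff(unique(md$guild), ECO_GUILDS)
  if (length(bad)) stop("unknown guild: ", paste(bad, collapse = ", "))
  for (fl in c("is_fish", "is_commercial", "is_tep"))
    md[[fl]] <- as.logical(md[[fl]])
  md$trophic_level <- as.numeric(md$trophic_level)
  md$price_per_ton <- as.numeric(md$price_per_ton)
  if (any(md$trophic_level < 1, na.rm = TRUE))
    stop("trophic_level must be >= 1")
  if (any(md$price_per_ton < 0, na.rm = TRUE))
    stop("price_per_ton must be >= 0")
  md
}

#' Write a skill table to CSV
#'
#' Serializes a [skill table][run_assessment] (one row per series x metric
#' x period) so that a subsequent [read_skill_table()] reproduces it
#' exactly, including flagged-missing (NA) cells.
#'
#' @param table A `skill_table` data.frame with columns
#'   `series_id, category, metric, period, value, n`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_skill_table <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  need <- c("series_id", "category", "metric", "period", "value", "n")
  stopifnot(all(need %in% names(table)))
  out <- table[, need]
  out$value <- fmt_full(out$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_skill_table
#' @export
read_skill_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "numeric", n = "integer"))
  class(df) <- c("skill_table", "data.frame")
  df
}
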