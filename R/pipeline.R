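#' Standard analysis periods
#'
#' The default period set for skill computation: the full 41-year hindcast,
#' a hindcast excluding the 10-year model spin-up, four decadal windows,
#' and the forecast period beyond the calibration data. The forecast is
#' fixed to 2005-2013: the last calibration year (2004) belongs to the
#' hindcast, and observations end in 2013. All boundaries are inclusive
#' and configurable.
#'
#' @param hindcast_start,hindcast_end Full hindcast bounds (1964, 2004).
#' @param spinup_years Years dropped for the no-spin-up hindcast (10).
#' @param forecast_start,forecast_end Forecast bounds (2005, 2013).
#' @return A named list of 7 [eco_period()] objects.
#' @export
define_periods <- function(hindcast_start = 1964L, hindcast_end = 2004L,
                           spinup_years = 10L,
                           forecast_start = 2005L, forecast_end = 2013L) {
  decades <- seq(hindcast_start, by = 10L,
                 length.out = 4L)
  periods <- c(
    list(eco_period("full_hindcast", hindcast_start, hindcast_end),
         eco_period("no_spinup", hindcast_start + spinup_years, hindcast_end)),
    lapply(decades, function(s) {
      eco_period(paste0("decade_", s), s, s + 9L)
    }),
    list(eco_period("forecast", forecast_start, forecast_end))
  )
  stats::setNames(periods, vapply(periods, `[[`, "", "name"))
}

# build eco_series for one group/source out of a long data.frame
long_to_series <- function(df, id, source, category) {
  g <- df[df$group_id == id & df$source == source & !is.na(df$value), ,
          drop = FALSE]
  if (nrow(g) == 0L) return(NULL)
  g <- g[order(g$year), , drop = FALSE]
  eco_series(id, category, source, g$year, g$value)
}

na_row <- function(series_id, category, period, n = NA_integer_,
                   note = NA_character_) {
  defs <- metric_definitions()
  data.frame(series_id = series_id, category = category, metric = defs$code,
             period = period, value = NA_real_, n = n, note = note,
             stringsAsFactors = FALSE)
}

score_series_pair <- function(obs, mod, periods, standardize_first = TRUE) {
  if (standardize_first) {
    obs <- tryCatch(standardize(obs), error = function(e) e)
    mod <- tryCatch(standardize(mod), error = function(e) e)
  }
  out <- lapply(periods, function(p) {
    if (inherits(obs, "error") || inherits(mod, "error")) {
      bad <- if (inherits(obs, "error")) obs else mod
      id <- if (inherits(obs, "error")) mod$series_id else obs$series_id
      cat_ <- if (inherits(obs, "error")) mod$category else obs$category
      return(na_row(id, cat_, p$name, note = conditionMessage(bad)))
    }
    pair <- tryCatch(align_pair(obs, mod, p), error = function(e) e)
    if (inherits(pair, "error"))
      return(na_row(obs$series_id, obs$category, p$name,
                    note = conditionMessage(pair)))
    m <- compute_all_metrics(pair)
    data.frame(series_id = obs$series_id, category = obs$category,
               metric = m$metric, period = p$name, value = m$value,
               n = m$n, note = m$note, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full skill assessment
#'
#' For every group's biomass and landings series: standardize observed and
#' modeled series separately over their full records (so hindcast and
#' forecast metrics share one dimensionless scale), align them
#' pairwise-complete within each period, and score all seven metrics. The
#' 22 ecosystem indicators are computed on raw series for both sources,
#' then the resulting indicator series are themselves standardized and
#' scored the same way. Cells that cannot be computed (insufficient
#' overlap, constant series, missing inputs) are flagged-missing rows with
#' the reason in `note`, never dropped.
#'
#' @param dataset An [ecosystem_dataset()].
#' @param periods A list of [eco_period()]s, default [define_periods()].
#' @param include_indicators Compute and score the indicator suite
#'   (default `TRUE`).
#' @return A `skill_table` data.frame with columns
#'   `series_id, category, metric, period, value, n, note` and no
#'   duplicate `(series_id, metric, period)` keys.
#' @export
run_assessment <- function(dataset, periods = define_periods(),
                           include_indicators = TRUE) {
  stopifnot(inherits(dataset, "ecosystem_dataset"))
  rows <- list()
  for (cat_ in c("biomass", "landings")) {
    df <- dataset[[cat_]]
    for (id in sort(unique(df$group_id))) {
      obs <- long_to_series(df, id, "observed", cat_)
      mod <- long_to_series(df, id, "modeled", cat_)
      if (is.null(obs) || is.null(mod)) next
      rows[[length(rows) + 1L]] <- score_series_pair(obs, mod, periods)
    }
  }
  if (include_indicators) {
    ind_obs <- compute_all_indicators(dataset, "observed")
    ind_mod <- compute_all_indicators(dataset, "modeled")
    for (code in names(ind_obs)) {
      o <- ind_obs[[code]]; m <- ind_mod[[code]]
      if (is_missing_indicator(o) || is_missing_indicator(m)) {
        why <- if (is_missing_indicator(o)) o$reason else m$reason
        rows[[length(rows) + 1L]] <- do.call(rbind, lapply(periods, function(p)
          na_row(code, "indicator", p$name, note = why)))
        next
      }
      rows[[length(rows) + 1L]] <- score_series_pair(o, m, periods)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  key <- paste(table$category, table$series_id, table$metric, table$period)
  stopifnot(!anyDuplicated(key))
  class(table) <- c("skill_table", "data.frame")
  table
}

# map every metric onto a "larger is better" scale so percentiles compare
# skill, not raw values: MEF and correlations as-is, AAE/RMSE negated,
# AE folded to -|AE| (only its magnitude is informative)
orient_skill <- function(metric, value) {
  out <- value
  out[metric %in% c("AAE", "RMSE")] <- -value[metric %in% c("AAE", "RMSE")]
  out[metric == "AE"] <- -abs(value[metric == "AE"])
  out
}

# midrank empirical percentile of x within reference values
percent_rank <- function(x, ref) {
  100 * (sum(ref < x) + 0.5 * sum(ref == x)) / length(ref)
}

#' Compare forecast skill against the hindcast reference distribution
#'
#' For each (series, metric) cell, the forecast skill value is placed
#' within the empirical distribution of hindcast values of the same metric
#' across all series of the same data category (orientation-corrected so
#' higher always means more skill). Cells are classed `below_40`
#' (percentile < 40), `mid_40_60` (40-60, "same" skill) or `above_60`
#' (better), and summarized as the percentage of cells per class plus the
#' percentage showing the same-or-better skill (percentile >= 40).
#'
#' @param table A `skill_table` from [run_assessment()].
#' @param hindcast,forecast Period names present in the table.
#' @param min_reference Minimum hindcast reference size (default 5).
#' @return A `skill_comparison` list with `cells` (per-cell percentiles and
#'   classes) and `summary` (per data category and overall).
#' @export
compare_hindcast_forecast <- function(table, hindcast = "full_hindcast",
                                      forecast = "forecast",
                                      min_reference = 5L) {
  stopifnot(inherits(table, "data.frame"))
  if (!all(c(hindcast, forecast) %in% table$period))
    stop("both periods must be present in the skill table")
  h <- table[table$period == hindcast & !is.na(table$value), , drop = FALSE]
  f <- table[table$period == forecast & !is.na(table$value), , drop = FALSE]
  h$skill <- orient_skill(h$metric, h$value)
  f$skill <- orient_skill(f$metric, f$value)
  cells <- f[, c("series_id", "category", "metric")]
  cells$percentile <- NA_real_
  for (i in seq_len(nrow(f))) {
    ref <- h$skill[h$metric == f$metric[i] & h$category == f$category[i]]
    if (length(ref) < min_reference)
      stop(sprintf("reference too small for metric %s in category %s (%d values, need >= %d)",
                   f$metric[i], f$category[i], length(ref), min_reference))
    cells$percentile[i] <- percent_rank(f$skill[i], ref)
  }
  cells$class <- cut(cells$percentile, c(-Inf, 40, 60, Inf),
                     labels = c("below_40", "mid_40_60", "above_60"),
                     right = FALSE)
  # percentile exactly 60 counts as "mid": [40, 60] is the same-skill band
  cells$class[cells$percentile == 60] <- "mid_40_60"
  summarize <- function(cl) {
    n <- length(cl)
    pct <- 100 * as.vector(base::table(cl)) / n
    data.frame(n_cells = n, pct_below_40 = pct[1], pct_mid_40_60 = pct[2],
               pct_above_60 = pct[3],
               pct_same_or_better = pct[2] + pct[3])
  }
  by_cat <- do.call(rbind, lapply(split(cells$class, cells$category), summarize))
  by_cat <- cbind(category = rownames(by_cat), by_cat)
  overall <- cbind(category = "all", summarize(cells$class))
  rownames(by_cat) <- rownames(overall) <- NULL
  structure(list(cells = cells, summary = rbind(by_cat, overall),
                 hindcast = hindcast, forecast = forecast),
            class = "skill_comparison")
}

#' @export
print.skill_comparison <- function(x, ...) {
  cat(sprintf("<skill_comparison> forecast '%s' vs hindcast '%s' (%d cells)\n",
              x$forecast, x$hindcast, nrow(x$cells)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Principal component analysis of skill metrics
#'
#' Builds the series x (metric, period) matrix for one data category —
#' by default 14 columns, the 7 metrics for hindcast and forecast — drops
#' rows with any missing cell and zero-variance columns (with a warning),
#' centers and scales each column to unit variance, and decomposes by
#' singular values. Metrics whose loading vectors align are redundant:
#' they rank series' skill the same way. Signs follow a deterministic
#' convention (the largest-magnitude loading of each component is
#' positive).
#'
#' @param table A `skill_table`.
#' @param category Data category to analyze (`"biomass"`, `"landings"`,
#'   `"indicator"`).
#' @param periods Character vector of period names (default full hindcast
#'   and forecast, suffixed `_h` and `_f` in column names).
#' @return An `eco_pca` list: `loadings` (columns orthonormal), `scores`,
#'   `variance_explained` (non-increasing, sums to 1), `dropped_columns`.
#' @export
pca_of_metrics <- function(table, category = "biomass",
                           periods = c(hindcast = "full_hindcast",
                                       forecast = "forecast")) {
  stopifnot(inherits(table, "data.frame"))
  sub <- table[table$category == category & table$period %in% periods, ,
               drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for category ", category)
  suffix <- if (length(periods) == 2L) c("_h", "_f")[match(sub$period, periods)]
            else paste0("_", sub$period)
  sub$column <- paste0(sub$metric, suffix)
  wide <- stats::reshape(
    sub[, c("series_id", "column", "value")], idvar = "series_id",
    timevar = "column", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rn <- wide$series_id
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- rn
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3L) stop("fewer than 3 complete rows for PCA")
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance columns: ", paste(dropped, collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = load, scores = scores, variance_explained = ve,
                 dropped_columns = dropped, category = category),
            class = "eco_pca")
}

#' @export
print.eco_pca <- function(x, ...) {
  cat(sprintf("<eco_pca> %s: %d series x %d metrics; PC1 %.1f%%, PC2 %.1f%%\n",
              x$category, nrow(x$scores), nrow(x$loadings),
              100 * x$variance_explained[1],
              100 * x$variance_explained[min(2, length(x$variance_explained))]))
  invisible(x)
}
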