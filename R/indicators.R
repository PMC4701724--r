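#' Assemble an ecosystem dataset
#'
#' Bundles the long-format inputs the indicator and assessment stages
#' consume: per-group biomass and landings for both sources, an optional
#' primary-production series, and the group metadata table.
#'
#' @param biomass data.frame `(group_id, source, year, value)` in tons.
#' @param landings data.frame `(group_id, source, year, value)` in tons.
#' @param primary_production Optional data.frame `(source, year, value)`.
#' @param metadata Group metadata as from [read_group_metadata()].
#' @return An `ecosystem_dataset` object.
#' @export
ecosystem_dataset <- function(biomass, landings, primary_production = NULL,
                              metadata) {
  metadata <- validate_metadata(metadata)
  for (nm in c("biomass", "landings")) {
    df <- get(nm)
    stopifnot(is.data.frame(df),
              all(c("group_id", "source", "year", "value") %in% names(df)))
    unknown <- setdiff(unique(df$group_id), metadata$group_id)
    if (length(unknown))
      stop(nm, " references groups absent from metadata: ",
           paste(unknown, collapse = ", "))
  }
  if (!is.null(primary_production))
    stopifnot(all(c("source", "year", "value") %in% names(primary_production)))
  structure(list(biomass = biomass, landings = landings,
                 primary_production = primary_production,
                 metadata = metadata),
            class = "ecosystem_dataset")
}

#' @export
print.ecosystem_dataset <- function(x, ...) {
  cat(sprintf("<ecosystem_dataset> %d groups; biomass rows %d; landings rows %d; PP: %s\n",
              nrow(x$metadata), nrow(x$biomass), nrow(x$landings),
              if (is.null(x$primary_production)) "absent" else "present"))
  invisible(x)
}

#' Ecosystem indicator registry
#'
#' The 22 aggregate indicators derived from biomass, landings and primary
#' production, spanning broad system totals, guild-level components,
#' top-predator state, trophic structure and economic value.
#'
#' @return data.frame with columns `code`, `description`, `needs_pp`
#'   (requires a primary-production series), `needs_landings`.
#' @export
indicator_registry <- function() {
  reg <- rbind(
    c("total_biomass", "Total biomass of all modeled groups (fish, benthos, mammals, seabirds and other invertebrates)", FALSE, FALSE),
    c("total_catch", "Total catch of commercial fish and benthos", FALSE, TRUE),
    c("catch_biomass", "Total catch as a proportion of total biomass", FALSE, TRUE),
    c("fish_biomass", "Total biomass of fish groups", FALSE, FALSE),
    c("demersal_pelagic_ratio", "Demersal fish biomass as a proportion of pelagic fish biomass", FALSE, FALSE),
    c("teps", "Total biomass of threatened, endangered and protected species", FALSE, FALSE),
    c("seal_biomass", "Total biomass of seals", FALSE, FALSE),
    c("whale_biomass", "Total biomass of whales", FALSE, FALSE),
    c("demersal_catch", "Demersal fish catch (weight)", FALSE, TRUE),
    c("pelagic_catch", "Pelagic fish catch (weight)", FALSE, TRUE),
    c("mtl_system", "Mean trophic level of all groups, biomass-weighted", FALSE, FALSE),
    c("mtl_catch", "Mean trophic level of the catch, landings-weighted", FALSE, TRUE),
    c("biomass_pp", "Total biomass as a proportion of primary production", TRUE, FALSE),
    c("demersal_biomass_pp", "Demersal fish biomass as a proportion of primary production", TRUE, FALSE),
    c("pelagic_biomass_pp", "Pelagic fish biomass as a proportion of primary production", TRUE, FALSE),
    c("catch_pp", "Fisheries catch as a proportion of primary production", TRUE, TRUE),
    c("demersal_catch_pp", "Demersal fish catch as a proportion of primary production", TRUE, TRUE),
    c("pelagic_catch_pp", "Pelagic fish catch as a proportion of primary production", TRUE, TRUE),
    c("fish_catch", "Catch of commercial fish (finfish only, no invertebrates)", FALSE, TRUE),
    c("fish_catch_fish_biomass", "Commercial fish catch as a proportion of total fish biomass", FALSE, TRUE),
    c("proportion_overfished", "Proportion of commercial groups at low biomass relative to their series maximum", FALSE, FALSE),
    c("value", "Total value of the catch (fixed per-group prices)", FALSE, TRUE)
  )
  data.frame(code = reg[, 1], description = reg[, 2],
             needs_pp = as.logical(reg[, 3]),
             needs_landings = as.logical(reg[, 4]),
             stringsAsFactors = FALSE)
}

# --- internal helpers ------------------------------------------------------

# sum of per-group series over groups `ids`, restricted to years where
# every contributing group has data; returns data.frame(year, value)
sum_over_groups <- function(df, ids, weights = NULL) {
  df <- df[df$group_id %in% ids & !is.na(df$value), , drop = FALSE]
  if (nrow(df) == 0L) return(data.frame(year = integer(0), value = numeric(0)))
  yrs <- Reduce(intersect, lapply(split(df$year, df$group_id), unique))
  if (!length(yrs)) return(data.frame(year = integer(0), value = numeric(0)))
  df <- df[df$year %in% yrs, , drop = FALSE]
  if (!is.null(weights)) df$value <- df$value * weights[df$group_id]
  agg <- stats::aggregate(value ~ year, data = df, FUN = sum)
  agg[order(agg$year), , drop = FALSE]
}

ratio_series <- function(num, den) {
  yrs <- sort(intersect(num$year, den$year))
  if (!length(yrs)) stop("ratio indicator: no overlapping years")
  d <- den$value[match(yrs, den$year)]
  if (all(d == 0)) stop("ratio indicator: all-zero denominator series")
  v <- num$value[match(yrs, num$year)] / d
  v[d == 0] <- NA_real_
  data.frame(year = yrs, value = v)
}

src_slice <- function(df, source) df[df$source == source, , drop = FALSE]

#' Compute one ecosystem indicator
#'
#' Indicators are always computed on raw (never standardized) series:
#' sums keep their original units (tons), ratios are dimensionless.
#' The annual value exists only for years where every required input does,
#' so differential data onsets (seals from 1981, whales from 1990,
#' satellite primary production from 1998) propagate into the indicator.
#'
#' @param code A registry code from [indicator_registry()].
#' @param dataset An [ecosystem_dataset()].
#' @param source `"observed"` or `"modeled"`.
#' @param overfished_threshold Relative-biomass cutoff for
#'   `proportion_overfished` (default 0.2 of the series maximum).
#' @return An [eco_series()] with category `"indicator"`.
#' @export
compute_indicator <- function(code, dataset, source = c("observed", "modeled"),
                              overfished_threshold = 0.2) {
  source <- match.arg(source)
  stopifnot(inherits(dataset, "ecosystem_dataset"))
  reg <- indicator_registry()
  if (!code %in% reg$code) stop("unknown indicator code: ", code)
  md <- dataset$metadata
  bio <- src_slice(dataset$biomass, source)
  lan <- src_slice(dataset$landings, source)
  if (reg$needs_pp[reg$code == code]) {
    if (is.null(dataset$primary_production))
      stop("indicator '", code, "' requires a primary-production series")
    pp <- src_slice(dataset$primary_production, source)
    pp <- pp[!is.na(pp$value), c("year", "value")]
    if (nrow(pp) == 0L)
      stop("indicator '", code, "' requires primary production for source ", source)
  }
  all_ids <- md$group_id
  fish_ids <- md$group_id[md$is_fish]
  dem_ids <- md$group_id[md$guild == "demersal_fish"]
  pel_ids <- md$group_id[md$guild == "pelagic_fish"]
  comm_ids <- md$group_id[md$is_commercial]
  tep_ids <- md$group_id[md$is_tep]
  seal_ids <- md$group_id[md$guild == "mammal_seal"]
  whale_ids <- md$group_id[md$guild == "mammal_whale"]
  comm_fish_ids <- md$group_id[md$is_commercial & md$is_fish]
  tl <- stats::setNames(md$trophic_level, md$group_id)
  price <- stats::setNames(md$price_per_ton, md$group_id)

  series <- switch(code,
    total_biomass = sum_over_groups(bio, all_ids),
    fish_biomass = sum_over_groups(bio, fish_ids),
    teps = sum_over_groups(bio, tep_ids),
    seal_biomass = sum_over_groups(bio, seal_ids),
    whale_biomass = sum_over_groups(bio, whale_ids),
    total_catch = sum_over_groups(lan, comm_ids),
    fish_catch = sum_over_groups(lan, comm_fish_ids),
    demersal_catch = sum_over_groups(lan, dem_ids),
    pelagic_catch = sum_over_groups(lan, pel_ids),
    value = sum_over_groups(lan, comm_ids, weights = price),
    demersal_pelagic_ratio = ratio_series(sum_over_groups(bio, dem_ids),
                                          sum_over_groups(bio, pel_ids)),
    catch_biomass = ratio_series(sum_over_groups(lan, comm_ids),
                                 sum_over_groups(bio, all_ids)),
    fish_catch_fish_biomass = ratio_series(sum_over_groups(lan, comm_fish_ids),
                                           sum_over_groups(bio, fish_ids)),
    biomass_pp = ratio_series(sum_over_groups(bio, all_ids), pp),
    demersal_biomass_pp = ratio_series(sum_over_groups(bio, dem_ids), pp),
    pelagic_biomass_pp = ratio_series(sum_over_groups(bio, pel_ids), pp),
    catch_pp = ratio_series(sum_over_groups(lan, comm_ids), pp),
    demersal_catch_pp = ratio_series(sum_over_groups(lan, dem_ids), pp),
    pelagic_catch_pp = ratio_series(sum_over_groups(lan, pel_ids), pp),
    mtl_system = mtl_series(bio, all_ids, tl),
    mtl_catch = mtl_series(lan, comm_ids, tl),
    proportion_overfished = overfished_series(bio, comm_ids,
                                              overfished_threshold)
  )
  if (nrow(series) == 0L)
    stop("indicator '", code, "': no data for source ", source)
  units <- if (code %in% c("total_biomass", "fish_biomass", "teps",
                           "seal_biomass", "whale_biomass", "total_catch",
                           "fish_catch", "demersal_catch", "pelagic_catch"))
    "t" else if (code == "value") "currency" else "dimensionless"
  eco_series(code, "indicator", source, series$year, series$value,
             units = units)
}

# biomass- or landings-weighted mean trophic level; groups lacking a
# trophic level are excluded from both numerator and denominator
mtl_series <- function(df, ids, tl) {
  ids <- ids[!is.na(tl[ids])]
  if (!length(ids)) stop("mean trophic level: no groups with trophic levels")
  num <- sum_over_groups(df, ids, weights = tl)
  den <- sum_over_groups(df, ids)
  ratio_series(num, den)
}

# yearly fraction of commercial groups whose biomass that year falls below
# `threshold` times the group's own series maximum
overfished_series <- function(bio, comm_ids, threshold) {
  if (!length(comm_ids)) stop("proportion_overfished: no commercial groups")
  bio <- bio[bio$group_id %in% comm_ids & !is.na(bio$value), , drop = FALSE]
  if (nrow(bio) == 0L) return(data.frame(year = integer(0), value = numeric(0)))
  yrs <- Reduce(intersect, lapply(split(bio$year, bio$group_id), unique))
  if (!length(yrs)) return(data.frame(year = integer(0), value = numeric(0)))
  bio <- bio[bio$year %in% yrs, , drop = FALSE]
  maxima <- tapply(bio$value, bio$group_id, max)
  rel <- bio$value / maxima[bio$group_id]
  agg <- stats::aggregate(list(value = rel < threshold),
                          by = list(year = bio$year), FUN = mean)
  agg[order(agg$year), , drop = FALSE]
}

#' Proportion of commercial groups depleted at the end of the record
#'
#' For each commercial group, mean biomass over the final `end_window`
#' years is divided by the group's series maximum; the indicator is the
#' fraction of groups below `depletion_threshold`. The reference point is
#' a depletion proxy, not a stock-assessment reference: both knobs are
#' configuration, defaulting to 20% of the series maximum over the last
#' 3 years.
#'
#' @inheritParams compute_indicator
#' @param depletion_threshold Fraction of the series maximum below which a
#'   group counts as depleted; in (0, 1).
#' @param end_window Number of final years averaged.
#' @return A single value in `[0, 1]`.
#' @export
proportion_overfished <- function(dataset, source = c("observed", "modeled"),
                                  depletion_threshold = 0.2, end_window = 3L) {
  source <- match.arg(source)
  stopifnot(depletion_threshold > 0, depletion_threshold <= 1, end_window >= 1)
  md <- dataset$metadata
  comm_ids <- md$group_id[md$is_commercial]
  if (!length(comm_ids)) stop("no commercial groups in metadata")
  bio <- src_slice(dataset$biomass, source)
  bio <- bio[bio$group_id %in% comm_ids & !is.na(bio$value), , drop = FALSE]
  if (nrow(bio) == 0L) stop("no biomass data for commercial groups")
  depleted <- vapply(split(bio, bio$group_id), function(g) {
    g <- g[order(g$year), , drop = FALSE]
    tail_vals <- utils::tail(g$value, end_window)
    mean(tail_vals) / max(g$value) < depletion_threshold
  }, logical(1))
  mean(depleted)
}

#' Compute all 22 ecosystem indicators
#'
#' Runs every registry entry for one source. Indicators whose inputs are
#' absent (for example all primary-production ratios when no
#' primary-production series is supplied) are returned as flagged-missing
#' stubs, never silently dropped, so the result always has 22 entries.
#'
#' @inheritParams compute_indicator
#' @return A named list of length 22; each element is an [eco_series()] or
#'   a flagged-missing object (test with [is_missing_indicator()], reason
#'   in `$reason`).
#' @export
compute_all_indicators <- function(dataset, source = c("observed", "modeled"),
                                   overfished_threshold = 0.2) {
  source <- match.arg(source)
  reg <- indicator_registry()
  out <- lapply(reg$code, function(code) {
    tryCatch(
      compute_indicator(code, dataset, source,
                        overfished_threshold = overfished_threshold),
      error = function(e) {
        structure(list(code = code, source = source,
                       reason = conditionMessage(e)),
                  class = "eco_indicator_missing")
      })
  })
  stats::setNames(out, reg$code)
}

#' @rdname compute_all_indicators
#' @param x Object to test.
#' @export
is_missing_indicator <- function(x) inherits(x, "eco_indicator_missing")

#' @export
print.eco_indicator_missing <- function(x, ...) {
  cat(sprintf("<missing indicator> %s [%s]: %s\n", x$code, x$source, x$reason))
  invisible(x)
}
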