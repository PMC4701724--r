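#' Stratified mean catch rate and its variance
#'
#' Combines per-stratum survey catch rates into a design-based stratified
#' mean using area weights `W_h = area_h / sum(area_h)`:
#' `mean = sum(W_h * mean_h)` and
#' `var = sum(W_h^2 * var_h / n_h)`, the textbook estimator for stratified
#' random sampling (no finite-population correction, appropriate when tows
#' sweep a negligible fraction of each stratum).
#'
#' @param strata data.frame with columns `stratum_id`, `area` (km^2),
#'   `n_tows`, `mean_catch` (kg/tow), `var_catch` (sample variance of
#'   catch per tow).
#' @return A list with `mean` (kg/tow) and `variance` (of the mean).
#' @export
stratified_mean_variance <- function(strata) {
  need <- c("stratum_id", "area", "n_tows", "mean_catch", "var_catch")
  stopifnot(is.data.frame(strata), all(need %in% names(strata)),
            nrow(strata) >= 1L)
  if (any(strata$area <= 0)) stop("stratum areas must be positive")
  if (any(strata$n_tows < 1)) stop("each stratum needs at least one tow")
  if (any(strata$var_catch < 0)) stop("variances must be non-negative")
  A <- sum(strata$area)
  if (A <= 0) stop("zero total area")
  w <- strata$area / A
  list(mean = sum(w * strata$mean_catch),
       variance = sum(w^2 * strata$var_catch / strata$n_tows))
}

#' Expand a stratified mean to a minimum swept-area biomass estimate
#'
#' Scales a stratified mean catch rate (per tow) up to a whole-area biomass
#' estimate by the factor `qA/a`, where `q` is the gear catchability, `A`
#' the total survey area and `a` the area swept by one tow. With the
#' default `q = 1` the result is a minimum biomass estimate (all fish in
#' the tow path assumed caught). The variance scales by the squared
#' constant `(qA/a)^2`, and a 95% confidence band is attached as
#' `mean +- 1.96 * sd`.
#'
#' @param mean_catch Stratified mean catch per tow.
#' @param variance Variance of the stratified mean.
#' @param q Catchability coefficient in (0, Inf); default 1.
#' @param A Total survey area (same units as `a`).
#' @param a Area swept per tow.
#' @return An object of class `swept_area_estimate`: list with
#'   `mean_biomass`, `variance`, `ci_low`, `ci_high`, `q`, `A`, `a`.
#' @export
expand_to_swept_area <- function(mean_catch, variance, q = 1, A, a) {
  stopifnot(length(mean_catch) == 1L, length(variance) == 1L)
  if (q <= 0 || A <= 0 || a <= 0)
    stop("q, A and a must all be positive")
  if (variance < 0) stop("variance must be non-negative")
  k <- q * A / a
  biomass <- mean_catch * k
  v <- variance * k^2
  hw <- 1.96 * sqrt(v)
  structure(list(mean_biomass = biomass, variance = v,
                 ci_low = biomass - hw, ci_high = biomass + hw,
                 q = q, A = A, a = a),
            class = "swept_area_estimate")
}

#' @export
print.swept_area_estimate <- function(x, ...) {
  cat(sprintf("<swept_area_estimate> %.4g [95%% CI %.4g, %.4g], q = %g\n",
              x$mean_biomass, x$ci_low, x$ci_high, x$q))
  invisible(x)
}

#' Read a strata CSV and produce a swept-area estimate
#'
#' Convenience wrapper used by the `expand` command-line subcommand.
#'
#' @param path CSV with columns `stratum_id, area, n_tows, mean_catch,
#'   var_catch`.
#' @inheritParams expand_to_swept_area
#' @return A `swept_area_estimate`.
#' @export
expand_strata_file <- function(path, q = 1, A, a) {
  strata <- utils::read.csv(path, stringsAsFactors = FALSE)
  sm <- stratified_mean_variance(strata)
  expand_to_swept_area(sm$mean, sm$variance, q = q, A = A, a = a)
}
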