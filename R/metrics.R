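#' Skill metric registry
#'
#' The seven univariate skill metrics used throughout the package, with
#' their orientation (which direction means better skill) and bounds.
#' The error convention is observed minus predicted, so a positive average
#' error means the model under-predicts. The multiplicative reliability
#' index is deliberately absent: series are standardized before comparison
#' and therefore contain negative values, for which it is undefined.
#'
#' @return A data.frame with columns `code`, `name`, `orientation`
#'   (`higher_better`, `lower_better` or `zero_best`), `lo`, `hi`.
#' @export
metric_definitions <- function() {
  data.frame(
    code = c("AE", "AAE", "RMSE", "MEF", "S", "P", "K"),
    name = c("Average Error", "Average Absolute Error",
             "Root Mean Squared Error", "Modeling Efficiency",
             "Spearman Rank Correlation", "Pearson Correlation",
             "Kendall Rank Correlation"),
    orientation = c("zero_best", "lower_better", "lower_better",
                    "higher_better", "higher_better", "higher_better",
                    "higher_better"),
    lo = c(-Inf, 0, 0, -Inf, -1, -1, -1),
    hi = c(Inf, Inf, Inf, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

check_pair <- function(pair) {
  stopifnot(inherits(pair, "eco_pair"))
  if (anyNA(pair$obs) || anyNA(pair$mod))
    stop("paired series must not contain missing values")
  if (pair$n < 3L) stop("paired series must have n >= 3")
  invisible(pair)
}

#' Average error
#'
#' Mean of the signed errors `O_i - P_i` (observed minus predicted). Large
#' positive and negative errors cancel, so a near-zero AE alone does not
#' imply good fit.
#'
#' @param pair An [align_pair()] result.
#' @return A single numeric value.
#' @export
average_error <- function(pair) {
  check_pair(pair)
  mean(pair$obs - pair$mod)
}

#' Average absolute error
#'
#' Mean of `|O_i - P_i|`; an accuracy measure insensitive to error sign.
#'
#' @inheritParams average_error
#' @return Non-negative numeric value.
#' @export
average_absolute_error <- function(pair) {
  check_pair(pair)
  mean(abs(pair$obs - pair$mod))
}

#' Root mean squared error
#'
#' `sqrt(mean((O_i - P_i)^2))`; penalizes large errors more heavily than
#' the average absolute error, so `RMSE >= AAE >= |AE|` always.
#'
#' @inheritParams average_error
#' @return Non-negative numeric value.
#' @export
rmse <- function(pair) {
  check_pair(pair)
  sqrt(mean((pair$obs - pair$mod)^2))
}

#' Modeling efficiency (Nash-Sutcliffe)
#'
#' `MEF = 1 - sum((P_i - O_i)^2) / sum((O_i - mean(O))^2)`. MEF = 1 is a
#' perfect fit; MEF = 0 means the model does exactly as well as predicting
#' the observation mean at every time point, which gives the metric its
#' objective zero threshold; MEF < 0 means the model does worse than that.
#'
#' @inheritParams average_error
#' @return Numeric value in `(-Inf, 1]`. Errors if the observations are
#'   constant (the denominator vanishes).
#' @export
modeling_efficiency <- function(pair) {
  check_pair(pair)
  denom <- sum((pair$obs - mean(pair$obs))^2)
  if (denom <= 0) stop("MEF undefined: constant observations")
  1 - sum((pair$mod - pair$obs)^2) / denom
}

#' Correlation skill metrics
#'
#' Pearson product-moment correlation (`"P"`), Spearman rank correlation
#' (`"S"`, Pearson on average ranks, ties receiving their mean rank) and
#' Kendall tau-b (`"K"`, with the standard tie correction).
#'
#' @inheritParams average_error
#' @param kind `"S"`, `"P"` or `"K"`.
#' @return Numeric value in `[-1, 1]`. Errors if either vector has zero
#'   variance.
#' @export
skill_correlation <- function(pair, kind = c("S", "P", "K")) {
  kind <- match.arg(kind)
  check_pair(pair)
  if (stats::sd(pair$obs) == 0 || stats::sd(pair$mod) == 0)
    stop("correlation undefined: zero variance")
  method <- switch(kind, S = "spearman", P = "pearson", K = "kendall")
  stats::cor(pair$obs, pair$mod, method = method)
}

#' Compute the full metric suite on one pair
#'
#' Evaluates all seven metrics of [metric_definitions()] on a pair. A
#' metric whose precondition fails (constant observations for MEF, zero
#' variance for a correlation) is reported as a flagged-missing `NA`
#' value with the reason recorded, never dropped and never coerced to 0.
#'
#' @inheritParams average_error
#' @return A data.frame with exactly 7 rows and columns
#'   `metric`, `value`, `n`, `note` (`NA` note when defined).
#' @export
compute_all_metrics <- function(pair) {
  check_pair(pair)
  defs <- metric_definitions()
  fns <- list(
    AE = function(p) average_error(p),
    AAE = function(p) average_absolute_error(p),
    RMSE = function(p) rmse(p),
    MEF = function(p) modeling_efficiency(p),
    S = function(p) skill_correlation(p, "S"),
    P = function(p) skill_correlation(p, "P"),
    K = function(p) skill_correlation(p, "K")
  )
  value <- rep(NA_real_, nrow(defs))
  note <- rep(NA_character_, nrow(defs))
  for (i in seq_len(nrow(defs))) {
    res <- tryCatch(fns[[defs$code[i]]](pair), error = function(e) e)
    if (inherits(res, "error")) note[i] <- conditionMessage(res)
    else value[i] <- res
  }
  data.frame(metric = defs$code, value = value,
             n = rep(pair$n, nrow(defs)), note = note,
             stringsAsFactors = FALSE)
}
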