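#' Packaged per-state cost anchors
#'
#' Six-year discounted mean cost per patient in each disease state, including
#' the diagnostic cascade, in EUR.
#'
#' @return named numeric vector.
#' @export
default_anchors <- function() {
  c(benign = 2182, isup1 = 10023, isup2_5 = 13073, metastatic = 271210)
}

#' Solve one calibration multiplier by bracketed root finding
#'
#' Generic one-dimensional solver used per state: finds `m` in `bounds` such
#' that `fn(m) == target`. `fn` must be continuous and strictly increasing in
#' `m` over the bracket; if the target lies outside the achievable interval a
#' "calibration out of range" error reports that interval.
#'
#' @param fn function of the multiplier returning the modelled cost.
#' @param target target cost (EUR).
#' @param bounds multiplier bracket, default `c(0.01, 100)`.
#' @param tol root tolerance on the multiplier.
#' @return the multiplier.
#' @export
calibrate_multiplier <- function(fn, target, bounds = c(0.01, 100), tol = 1e-10) {
  lo <- fn(bounds[1L]); hi <- fn(bounds[2L])
  if (target < lo - 1e-9 || target > hi + 1e-9) {
    stop(sprintf(
      "calibration out of range: target %.2f outside achievable interval [%.2f, %.2f]",
      target, lo, hi), call. = FALSE)
  }
  stats::uniroot(function(m) fn(m) - target, interval = bounds, tol = tol)$root
}

#' Calibrate a parameter set to per-state cost anchors
#'
#' Adjusts the free per-state scalars so the cohort model reproduces the
#' anchor costs to within 1 euro: the ISUP 1 surveillance-intensity
#' multiplier, the localized ADT-duration multiplier and the metastatic
#' systemic line-intensity multiplier. The states are cost-independent, so
#' each multiplier is solved by bracketed one-dimensional root finding
#' against its own anchor (anchor minus the diagnostic cascade).
#'
#' @param params a [parameter_set()].
#' @param anchors named per-state target costs including the diagnostic
#'   cascade; defaults to [default_anchors()].
#' @param bounds multiplier bracket passed to [calibrate_multiplier()].
#' @return the parameter set with calibrated `multipliers`.
#' @export
calibrate <- function(params, anchors = default_anchors(), bounds = c(0.01, 100)) {
  if (any(anchors <= 0)) stop("anchors must be positive", call. = FALSE)
  cascade <- benign_cost(params$costs)
  if ("benign" %in% names(anchors) &&
      abs(anchors[["benign"]] - cascade) > 1) {
    warning(sprintf(
      "benign anchor (%.2f) differs from the diagnostic cascade (%.2f); the benign state has no free scalar",
      anchors[["benign"]], cascade), call. = FALSE)
  }
  params$multipliers[["isup1"]] <- calibrate_multiplier(
    function(m) as_cost(params$as_sched, params$costs, params$config, m)$discounted_cost,
    anchors[["isup1"]] - cascade, bounds)
  params$multipliers[["isup2_5"]] <- calibrate_multiplier(
    function(m) localized_cost(params$loc_mix, params$costs, params$config, m)$discounted_cost,
    anchors[["isup2_5"]] - cascade, bounds)
  params$multipliers[["metastatic"]] <- calibrate_multiplier(
    function(m) metastatic_cost(params$mix, params$costs, params$config, m)$discounted_cost,
    anchors[["metastatic"]] - cascade, bounds)
  params
}
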