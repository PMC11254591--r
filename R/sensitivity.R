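#' Perturbation specification for one-way sensitivity analysis
#'
#' @param path dotted path into the parameter set (resolved with the same
#'   rules as `params[[...]]`), e.g. `"scales.cost.metastatic"`.
#' @param label human-readable parameter name for the tornado table.
#' @param low,high relative deltas (default -0.30 / +0.30) applied as
#'   `value * (1 + delta)`; or absolute bounds when `absolute = TRUE`.
#' @param absolute interpret `low`/`high` as explicit values.
#' @return a list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(path, label = path, low = -0.30, high = 0.30,
                              absolute = FALSE) {
  if (low >= high) stop("perturbation low must be < high", call. = FALSE)
  structure(list(path = path, label = label, low = low, high = high,
                 absolute = absolute),
            class = "perturbation_spec")
}

#' Scale a parameter value for sensitivity analysis
#'
#' @param value baseline value (money or fraction).
#' @param delta signed relative change (e.g. -0.30 for "30% lower").
#' @param mode `"none"` or `"truncate_euro"` (truncate the scaled value to
#'   whole euros).
#' @return the perturbed value. Probabilities (values strictly below 1)
#'   pushed above 1 are clamped with a warning; scaling knobs with baseline
#'   exactly 1 are left free.
#' @examples
#' scale_parameter(269028, -0.30, "truncate_euro")  # 188319
#' @export
scale_parameter <- function(value, delta, mode = c("none", "truncate_euro")) {
  mode <- match.arg(mode)
  out <- value * (1 + delta)
  if (value >= 0 && value < 1 && out > 1) {
    warning("perturbed probability clamped to 1", call. = FALSE)
    out <- 1
  }
  if (mode == "truncate_euro") out <- trunc_eur(out)
  out
}

#' Default one-way sensitivity specifications
#'
#' Covers the cost and case-mix parameters of the comparison: the metastatic
#' treatment component, the metastatic proportion at presentation (the net
#' stage-migration decrease), the localized and low-grade treatment
#' components, the diagnostic costs, and the ISUP 1 / ISUP 2-5 detection
#' counts. All vary 30% above and below baseline.
#'
#' @return list of [perturbation_spec()]s.
#' @export
default_dsa_specs <- function() {
  list(
    perturbation_spec("scales.cost.metastatic", "metastatic_treatment_cost"),
    perturbation_spec("scales.migration_mpc", "mpc_proportion"),
    perturbation_spec("scales.cost.isup2_5", "localized_treatment_cost"),
    perturbation_spec("scales.cost.isup1", "low_grade_treatment_cost"),
    perturbation_spec("scales.cost.diagnostic", "diagnostic_cost"),
    perturbation_spec("scales.count.isup1", "isup1_detection"),
    perturbation_spec("scales.count.isup2_5", "isup2_5_detection")
  )
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' For each specification, re-evaluates the full strategy comparison with the
#' parameter set at its low and at its high value, all other parameters at
#' baseline, and records the outcome (net saving per man, EUR). Rows are
#' ordered by descending range; ranges are rounded to cents before ordering
#' and exact ties are broken by parameter label, so the ordering does not
#' depend on the order of the specifications.
#'
#' @param params a calibrated [parameter_set()].
#' @param specs list of [perturbation_spec()]s, default [default_dsa_specs()].
#' @param baseline,comparator strategies compared.
#' @param outcome function of a `comparison_result` returning the scalar
#'   outcome; default the unrounded saving per man.
#' @return data frame of class `tornado` with columns `parameter`,
#'   `outcome_low`, `outcome_high`, `range`, plus attribute `baseline_outcome`.
#' @export
one_way_dsa <- function(params, specs = default_dsa_specs(),
                        baseline = "psa_mri", comparator = "sthlm3_reflex",
                        outcome = function(cmp) cmp$saving_per_man) {
  base_cmp <- compare_strategies(params, baseline, comparator)
  base_out <- outcome(base_cmp)
  eval_at <- function(spec, delta) {
    value <- get_path(params, spec$path)
    new_value <- if (spec$absolute) delta else scale_parameter(value, delta)
    p <- set_path(params, spec$path, new_value)
    outcome(compare_strategies(p, baseline, comparator))
  }
  rows <- lapply(specs, function(spec) {
    lo <- eval_at(spec, spec$low)
    hi <- eval_at(spec, spec$high)
    data.frame(parameter = spec$label, outcome_low = lo, outcome_high = hi,
               range = abs(hi - lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-round(out$range, 2), out$parameter)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline_outcome") <- base_out
  class(out) <- c("tornado", class(out))
  out
}

#' @export
print.tornado <- function(x, ...) {
  cat("<tornado> baseline outcome:",
      sprintf("%.2f", attr(x, "baseline_outcome")), "EUR per man\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
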