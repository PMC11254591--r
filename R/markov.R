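#' Present value of an annual cost stream
#'
#' @param stream numeric vector of annual costs, year 1 first.
#' @param rate annual discount rate (fraction); year-1 costs are undiscounted.
#' @param horizon optional maximum allowed stream length; an error is raised
#'   when the stream is longer.
#' @return discounted sum in EUR.
#' @examples
#' discount(c(0, 103), 0.03)  # 100
#' @export
discount <- function(stream, rate, horizon = NULL) {
  if (rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  if (!is.null(horizon) && length(stream) > horizon) {
    stop("cost stream longer than the model horizon", call. = FALSE)
  }
  sum(stream * discount_factors(rate, length(stream)))
}

#' @keywords internal
new_cohort_trace <- function(yearly, rate) {
  annual <- rowSums(yearly[, setdiff(names(yearly), c("year", "active", "exited")),
                           drop = FALSE])
  structure(
    list(yearly = yearly,
         annual_costs = annual,
         undiscounted_cost = sum(annual),
         discounted_cost = discount(annual, rate)),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> ", nrow(x$yearly), " years; discounted ",
      sprintf("%.2f", x$discounted_cost), " EUR (undiscounted ",
      sprintf("%.2f", x$undiscounted_cost), ")\n", sep = "")
  invisible(x)
}

#' Cost of the benign disease state
#'
#' The benign state carries the full diagnostic cascade and no treatment:
#' PSA test + Stockholm3 + MRI + biopsy unit costs.
#'
#' @param costs a [cost_table()].
#' @return EUR per patient.
#' @examples
#' benign_cost(default_costs())  # 2182
#' @export
benign_cost <- function(costs = default_costs()) {
  sum(cost_of(costs, c("psa_test", "stockholm3", "mri", "biopsy")))
}

#' Per-patient cost of active surveillance (low-grade, ISUP 1)
#'
#' Annual-cycle cohort trace: non-progressed occupants incur the surveillance
#' event schedule each year (scaled by `multiplier`, the calibrated
#' surveillance-intensity scalar); the fraction progressing in a year incurs
#' the curative-mix cost that year and leaves surveillance. All costs
#' discounted. The state total adds the diagnostic cascade ([benign_cost()])
#' to the trace's discounted treatment component.
#'
#' @param sched an [as_schedule()].
#' @param costs a [cost_table()].
#' @param config a [model_config()].
#' @param multiplier surveillance-intensity multiplier (calibration scalar).
#' @return a `cohort_trace` with attribute `total` = discounted component +
#'   diagnostic cascade.
#' @export
as_cost <- function(sched = as_schedule(), costs = default_costs(),
                    config = model_config(), multiplier = 1) {
  h <- config$horizon_years
  cum <- cum_progression_by_year(sched, h)
  d_prog <- diff(c(0, cum))
  in_as <- 1 - cum
  ev <- sched$events
  surv_unit <- ev$psa * cost_of(costs, "psa_test") +
    ev$mri * cost_of(costs, "mri") +
    ev$biopsy * cost_of(costs, "biopsy")
  surv_unit <- c(surv_unit, rep(0, h - length(surv_unit)))[seq_len(h)]
  curative_unit <- as_curative_cost(sched$curative_mix, costs)
  yearly <- data.frame(
    year = seq_len(h),
    active = in_as,
    exited = cum,
    surveillance = in_as * surv_unit * multiplier,
    curative = d_prog * curative_unit
  )
  trace <- new_cohort_trace(yearly, config$discount_rate)
  attr(trace, "total") <- trace$discounted_cost + benign_cost(costs)
  trace
}

#' Mean curative-treatment cost at progression from active surveillance
#' @keywords internal
as_curative_cost <- function(curative_mix, costs) {
  unit <- c(rp = cost_of(costs, "rp"),
            rt_short_adt = cost_of(costs, "rt") + cost_of(costs, "adt"))
  sum(curative_mix * unit[names(curative_mix)])
}

#' Discounted ADT cost for a (possibly fractional) course length
#'
#' A course of `years` contributes a full annual cost for each complete year
#' and a pro-rated cost for the final fraction, each discounted to its year.
#' @keywords internal
adt_course_cost <- function(years, annual_cost, rate, horizon) {
  frac <- pmin(pmax(years - (seq_len(horizon) - 1), 0), 1)
  discount(frac * annual_cost, rate)
}

#' Per-patient cost of intermediate/high-grade localized disease
#'
#' Year-1 curative treatment (RP, or RP + pelvic lymphadenectomy for the
#' high-grade surgical arm, or RT) plus annual ADT over the configured course
#' lengths (abbreviated for intermediate grade, extended for high grade),
#' discounted. `multiplier` scales both ADT course lengths and is the
#' calibrated free scalar of this state.
#'
#' @param mix a [localized_mix()].
#' @param costs a [cost_table()].
#' @param config a [model_config()].
#' @param multiplier ADT-duration multiplier (calibration scalar).
#' @return a `cohort_trace` with attribute `total` (component + diagnostic
#'   cascade).
#' @export
localized_cost <- function(mix = localized_mix(), costs = default_costs(),
                           config = model_config(), multiplier = 1) {
  h <- config$horizon_years
  r <- config$discount_rate
  adt <- cost_of(costs, "adt")
  w_int <- mix$intermediate_weights
  w_high <- mix$high_weights
  f_int <- mix$intermediate_fraction

  # year-1 procedure costs by arm
  proc_int <- w_int[["rp"]] * cost_of(costs, "rp") +
    w_int[["rt_adt"]] * cost_of(costs, "rt")
  proc_high <- w_high[["rp_plnd"]] * (cost_of(costs, "rp") + cost_of(costs, "plnd")) +
    w_high[["rt_adt"]] * cost_of(costs, "rt")

  # discounted ADT spend (RT arms only)
  L_int <- mix$adt_years_intermediate * multiplier
  L_high <- mix$adt_years_high * multiplier
  frac_int <- pmin(pmax(L_int - (seq_len(h) - 1), 0), 1)
  frac_high <- pmin(pmax(L_high - (seq_len(h) - 1), 0), 1)
  adt_stream <- f_int * w_int[["rt_adt"]] * frac_int * adt +
    (1 - f_int) * w_high[["rt_adt"]] * frac_high * adt

  procedure <- c(f_int * proc_int + (1 - f_int) * proc_high, rep(0, h - 1))
  yearly <- data.frame(
    year = seq_len(h),
    active = c(1, as.numeric(adt_stream[-1] > 0)),
    exited = c(0, as.numeric(adt_stream[-1] <= 0)),
    procedure = procedure,
    adt = adt_stream
  )
  trace <- new_cohort_trace(yearly, r)
  attr(trace, "total") <- trace$discounted_cost + benign_cost(costs)
  trace
}

#' Cumulative discontinuation fractions per model year
#' @keywords internal
cum_discontinuation <- function(mix, horizon) {
  cum <- mix$discontinuation_year1 +
    (seq_len(horizon) - 1) * mix$discontinuation_increment
  if (any(cum > 1)) {
    warning("discontinuation schedule exceeds 100%; clamped", call. = FALSE)
    cum <- pmin(cum, 1)
  }
  cum
}

#' Per-patient cost of metastatic disease
#'
#' Annual-cycle trace over the treatment lines of metastatic prostate cancer.
#' Active occupants (attenuated by the cumulative discontinuation schedule)
#' carry an ADT backbone, ARPI for `arpi_fraction` of patients, PARP
#' inhibition, immune therapy and osteoprotective medication at their cohort
#' fractions, one full docetaxel course in year 1 for triplet-therapy and
#' taxane-only patients, and radiopharmaceutical therapy (177Lu-PSMA or
#' radium-223) in the final two model years. These systemic-line costs are
#' scaled by `multiplier`, the calibrated line-intensity scalar that absorbs
#' unmodelled treatment intensity (sequencing of lines, relapse workup,
#' dose individualisation). PSMA-PET staging (year 1), the one-time palliative
#' (year 5) and end-of-life (year 6) totals apply to their cohort fractions
#' regardless of discontinuation and are not scaled.
#'
#' @param mix a [treatment_mix()].
#' @param costs a [cost_table()].
#' @param config a [model_config()].
#' @param multiplier systemic line-intensity multiplier (calibration scalar).
#' @return a `cohort_trace` with attribute `total` (component + diagnostic
#'   cascade).
#' @export
metastatic_cost <- function(mix = treatment_mix(), costs = default_costs(),
                            config = model_config(), multiplier = 1) {
  h <- config$horizon_years
  cum <- cum_discontinuation(mix, h)
  active <- 1 - cum
  yrs <- seq_len(h)

  adt_on <- pmin(pmax(mix$adt_years - (yrs - 1), 0), 1)
  annual_sys <- adt_on * cost_of(costs, "adt") +
    mix$arpi_fraction * cost_of(costs, "arpi") +
    mix$parp_fraction * cost_of(costs, "parp") +
    mix$immune_fraction * cost_of(costs, "immune") +
    mix$osteoprotective_fraction * cost_of(costs, "osteoprotective")

  chemo <- numeric(h)
  chemo[1] <- (mix$arpi_fraction * mix$triplet_given_arpi_fraction +
                 mix$taxane_only_fraction) * cost_of(costs, "chemo_cycle")

  radio <- numeric(h)
  radio_years <- yrs > h - 2  # final two model years
  radio_annual <- mix$radiopharm_fraction *
    (mix$radiopharm_lu_split * cost_of(costs, "lu_psma") +
       (1 - mix$radiopharm_lu_split) * cost_of(costs, "ra223"))
  radio[radio_years] <- radio_annual

  staging <- numeric(h)
  staging[1] <- cost_of(costs, "psma_pet")
  palliative <- numeric(h)
  palliative[max(1, h - 1)] <- mix$palliative_fraction * cost_of(costs, "palliative")
  eol <- numeric(h)
  eol[h] <- mix$eol_fraction * cost_of(costs, "end_of_life")

  yearly <- data.frame(
    year = yrs,
    active = active,
    exited = cum,
    systemic = active * (annual_sys + chemo + radio) * multiplier,
    staging = staging,
    palliative = palliative,
    end_of_life = eol
  )
  trace <- new_cohort_trace(yearly, config$discount_rate)
  attr(trace, "total") <- trace$discounted_cost + benign_cost(costs)
  trace
}

#' Calibrated per-state treatment components
#'
#' The discounted 6-year per-patient treatment cost of each disease state,
#' excluding the diagnostic cascade, computed from the cohort model at the
#' parameter set's calibration multipliers.
#'
#' @param params a [parameter_set()].
#' @return named numeric: `benign` (0), `isup1`, `isup2_5`, `metastatic`.
#' @export
state_components <- function(params) {
  c(benign = 0,
    isup1 = as_cost(params$as_sched, params$costs, params$config,
                    params$multipliers[["isup1"]])$discounted_cost,
    isup2_5 = localized_cost(params$loc_mix, params$costs, params$config,
                             params$multipliers[["isup2_5"]])$discounted_cost,
    metastatic = metastatic_cost(params$mix, params$costs, params$config,
                                 params$multipliers[["metastatic"]])$discounted_cost)
}

#' Per-state totals including the diagnostic cascade
#'
#' @param params a [parameter_set()].
#' @return named numeric of per-patient state costs in EUR (benign state =
#'   diagnostic cascade only).
#' @export
state_costs <- function(params) {
  state_components(params) + benign_cost(params$costs)
}
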