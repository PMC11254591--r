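#' Global model configuration
#'
#' @param horizon_years model horizon in years (default 6).
#' @param discount_rate annual discount rate as a fraction (default 0.03).
#' @param cycle_length cycle length in years (only annual cycles are
#'   supported; fixed at 1).
#' @param cohort_size reporting cohort size (default 1000 men tested).
#' @return a list of class `model_config`.
#' @export
model_config <- function(horizon_years = 6L, discount_rate = 0.03,
                         cycle_length = 1, cohort_size = 1000) {
  if (!is.finite(discount_rate) || discount_rate < 0) {
    stop("validation error at config.discount_rate: must be >= 0", call. = FALSE)
  }
  if (horizon_years < 1) {
    stop("validation error at config.horizon_years: must be >= 1", call. = FALSE)
  }
  if (cycle_length != 1) {
    stop("only annual cycles (cycle_length = 1) are supported", call. = FALSE)
  }
  structure(list(horizon_years = as.integer(horizon_years),
                 discount_rate = discount_rate,
                 cycle_length = 1,
                 cohort_size = cohort_size),
            class = "model_config")
}

#' Metastatic treatment-mix and schedule parameters
#'
#' Fractions of the metastatic cohort on each systemic line and supportive
#' component, plus the medication-discontinuation schedule (cumulative fraction
#' off systemic therapy: `discontinuation_year1` by end of year 1, increasing
#' by `discontinuation_increment` percentage points each later year).
#'
#' @param arpi_fraction fraction receiving an androgen receptor pathway
#'   inhibitor (ARPI); the complement receives taxane chemotherapy alone.
#' @param triplet_given_arpi_fraction fraction of ARPI patients also receiving
#'   docetaxel (triplet therapy).
#' @param taxane_only_fraction fraction on taxane chemotherapy without ARPI;
#'   must equal `1 - arpi_fraction`.
#' @param parp_fraction,immune_fraction,radiopharm_fraction fractions on PARP
#'   inhibition, immune therapy, radiopharmaceutical therapy.
#' @param radiopharm_lu_split fraction of radiopharmaceutical patients on
#'   177Lu-PSMA (remainder radium-223).
#' @param osteoprotective_fraction fraction receiving osteoprotective
#'   medication.
#' @param palliative_fraction,eol_fraction fractions receiving palliative and
#'   end-of-life care within the horizon.
#' @param discontinuation_year1 cumulative fraction off therapy at end of
#'   year 1.
#' @param discontinuation_increment percentage-point increase per later year.
#' @param adt_years years of ADT backbone while on therapy (default the full
#'   horizon).
#' @return a list of class `treatment_mix`.
#' @export
treatment_mix <- function(arpi_fraction = 0.80,
                          triplet_given_arpi_fraction = 0.25,
                          taxane_only_fraction = 0.20,
                          parp_fraction = 0.09,
                          immune_fraction = 0.01,
                          radiopharm_fraction = 0.30,
                          radiopharm_lu_split = 0.50,
                          osteoprotective_fraction = 0.33,
                          palliative_fraction = 0.50,
                          eol_fraction = 0.35,
                          discontinuation_year1 = 0.30,
                          discontinuation_increment = 0.10,
                          adt_years = 6) {
  mix <- list(arpi_fraction = arpi_fraction,
              triplet_given_arpi_fraction = triplet_given_arpi_fraction,
              taxane_only_fraction = taxane_only_fraction,
              parp_fraction = parp_fraction,
              immune_fraction = immune_fraction,
              radiopharm_fraction = radiopharm_fraction,
              radiopharm_lu_split = radiopharm_lu_split,
              osteoprotective_fraction = osteoprotective_fraction,
              palliative_fraction = palliative_fraction,
              eol_fraction = eol_fraction,
              discontinuation_year1 = discontinuation_year1,
              discontinuation_increment = discontinuation_increment,
              adt_years = adt_years)
  for (f in setdiff(names(mix), "adt_years")) stopifnot_fraction(mix[[f]], paste0("mix.", f))
  if (abs(arpi_fraction + taxane_only_fraction - 1) > 1e-9) {
    stop("validation error: arpi_fraction + taxane_only_fraction must equal 1",
         call. = FALSE)
  }
  if (adt_years < 0) stop("validation error at mix.adt_years: must be >= 0", call. = FALSE)
  structure(mix, class = "treatment_mix")
}

#' Active-surveillance schedule for low-grade (ISUP 1) disease
#'
#' `cum_progression` maps anchor years to cumulative fractions that have
#' progressed to curative treatment; between anchors the cumulative curve is
#' linearly interpolated, it is zero before the first anchor and flat after the
#' last. `events` gives annual surveillance test counts (PSA, MRI, biopsy);
#' frequency is highest in year 1 and decreases thereafter. On progression a
#' patient leaves surveillance and incurs the curative mix cost in that year.
#'
#' @param cum_progression named numeric vector: names are anchor years,
#'   values cumulative progression fractions (nondecreasing, in \[0,1\]).
#' @param events data frame with columns `year`, `psa`, `mri`, `biopsy`.
#' @param curative_mix named weights over `rp` and `rt_short_adt` for the
#'   curative treatment chosen at progression.
#' @param horizon_years model horizon the schedule must cover.
#' @return a list of class `as_schedule`.
#' @export
as_schedule <- function(cum_progression = c("3" = 0.25, "5" = 0.35),
                        events = NULL,
                        curative_mix = c(rp = 0.5, rt_short_adt = 0.5),
                        horizon_years = 6L) {
  if (is.null(events)) {
    events <- data.frame(
      year = 1:6,
      psa = c(3, 2, 2, 2, 2, 2),
      mri = c(1, 0, 1, 0, 1, 0),
      biopsy = c(1, 0, 1, 0, 0, 0)
    )
  }
  events <- events[events$year <= horizon_years, , drop = FALSE]
  p <- as.numeric(cum_progression)
  if (is.unsorted(p, strictly = FALSE)) {
    stop("validation error: cum_progression must be nondecreasing", call. = FALSE)
  }
  stopifnot_fraction(p, "as_schedule.cum_progression")
  if (abs(sum(curative_mix) - 1) > 1e-9) {
    stop("validation error: curative_mix weights must sum to 1", call. = FALSE)
  }
  structure(list(cum_progression = cum_progression, events = events,
                 curative_mix = curative_mix),
            class = "as_schedule")
}

#' Cumulative progression per model year from anchor points
#' @param sched an [as_schedule()].
#' @param horizon number of model years.
#' @return cumulative progression fraction for years `1:horizon`.
#' @keywords internal
cum_progression_by_year <- function(sched, horizon) {
  yrs <- as.numeric(names(sched$cum_progression))
  vals <- as.numeric(sched$cum_progression)
  out <- numeric(horizon)
  for (t in seq_len(horizon)) {
    if (t < yrs[1L]) {
      out[t] <- 0
    } else if (t >= yrs[length(yrs)]) {
      out[t] <- vals[length(vals)]
    } else {
      out[t] <- stats::approx(yrs, vals, xout = t)$y
    }
  }
  out
}

#' Treatment mix for intermediate/high-grade localized disease
#'
#' Intermediate-grade disease is treated by radical prostatectomy (RP) or
#' radiation therapy (RT) with an abbreviated ADT course; high-grade disease by
#' RP with pelvic lymphadenectomy or RT with an extended ADT course. ADT course
#' lengths may be fractional years and are the free scalars used by
#' calibration.
#'
#' @param intermediate_fraction fraction of the localized state with
#'   intermediate-grade disease.
#' @param intermediate_weights named weights over `rp`, `rt_adt`.
#' @param high_weights named weights over `rp_plnd`, `rt_adt`.
#' @param adt_years_intermediate,adt_years_high ADT course lengths in years.
#' @return a list of class `localized_mix`.
#' @export
localized_mix <- function(intermediate_fraction = 0.60,
                          intermediate_weights = c(rp = 0.5, rt_adt = 0.5),
                          high_weights = c(rp_plnd = 0.5, rt_adt = 0.5),
                          adt_years_intermediate = 1,
                          adt_years_high = 3) {
  stopifnot_fraction(intermediate_fraction, "localized_mix.intermediate_fraction")
  if (abs(sum(intermediate_weights) - 1) > 1e-9 || abs(sum(high_weights) - 1) > 1e-9) {
    stop("validation error: localized mix weights must sum to 1 per arm", call. = FALSE)
  }
  if (adt_years_intermediate < 0 || adt_years_high < 0) {
    stop("validation error: ADT course length must be >= 0", call. = FALSE)
  }
  structure(list(intermediate_fraction = intermediate_fraction,
                 intermediate_weights = intermediate_weights,
                 high_weights = high_weights,
                 adt_years_intermediate = adt_years_intermediate,
                 adt_years_high = adt_years_high),
            class = "localized_mix")
}

#' Stage-migration factors of the biomarker-enhanced pathway
#'
#' Multipliers applied to the PSA-arm per-1000 detection counts: registry data
#' comparing Stockholm3-reflex testing with conventional PSA/MRI showed a 46%
#' reduction in ISUP 1 detection, a 24% increase in ISUP 2-5 detection and a
#' 16% decrease in metastatic presentation.
#'
#' @param isup1_factor,isup2_5_factor,metastatic_factor positive multipliers.
#' @return named numeric vector of class `migration_factors`.
#' @export
migration_factors <- function(isup1_factor = 0.54, isup2_5_factor = 1.24,
                              metastatic_factor = 0.84) {
  f <- c(isup1 = isup1_factor, isup2_5 = isup2_5_factor,
         metastatic = metastatic_factor)
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("validation error: migration factors must be positive", call. = FALSE)
  }
  structure(f, class = "migration_factors")
}

#' Assemble a full model parameter set
#'
#' The container for everything the analysis needs: unit costs, model
#' configuration, per-strategy diagnostic probability tables, treatment mixes
#' and schedules, stage-migration factors, per-state calibration multipliers,
#' and the sensitivity-analysis scaling knobs.
#'
#' @param costs a [cost_table()].
#' @param config a [model_config()].
#' @param strategies named list of [diag_prob_table()]s (names `psa_mri`,
#'   `sthlm3_reflex`, optionally `swop`).
#' @param mix a [treatment_mix()].
#' @param as_sched an [as_schedule()].
#' @param loc_mix a [localized_mix()].
#' @param migration a [migration_factors()].
#' @param multipliers named calibration multipliers for the free per-state
#'   scalars (`isup1` surveillance intensity, `isup2_5` ADT durations,
#'   `metastatic` systemic line intensity); 1 = uncalibrated baseline.
#' @param scales nested list of deterministic-sensitivity scaling knobs, all 1
#'   at baseline: `cost` (diagnostic, isup1, isup2_5, metastatic), `count`
#'   (isup1, isup2_5), `migration_mpc` (scales the net metastatic decrease).
#' @return a list of class `pc_params`.
#' @export
parameter_set <- function(costs = default_costs(),
                          config = model_config(),
                          strategies = list(),
                          mix = treatment_mix(),
                          as_sched = as_schedule(),
                          loc_mix = localized_mix(),
                          migration = migration_factors(),
                          multipliers = c(isup1 = 1, isup2_5 = 1, metastatic = 1),
                          scales = NULL) {
  scales <- scales %||% list(
    cost = list(diagnostic = 1, isup1 = 1, isup2_5 = 1, metastatic = 1),
    count = list(isup1 = 1, isup2_5 = 1),
    migration_mpc = 1
  )
  params <- structure(
    list(costs = costs, config = config, strategies = strategies, mix = mix,
         as_sched = as_sched, loc_mix = loc_mix, migration = migration,
         multipliers = multipliers, scales = scales),
    class = "pc_params"
  )
  validate_parameters(params)
  params
}

#' Validate a parameter set
#'
#' Checks every probability lies in \[0,1\], every cost is nonnegative, biopsy
#' outcome distributions sum to one, PSA thresholds are nested and the horizon
#' is at least one year. Called by all constructors; exported for use after
#' manual edits.
#'
#' @param params a [parameter_set()].
#' @return `params`, invisibly; errors with the offending path otherwise.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "pc_params"))
  if (any(params$costs$unit_cost < 0)) {
    stop("validation error at costs: negative unit cost", call. = FALSE)
  }
  if (params$config$horizon_years < 1) {
    stop("validation error at config.horizon_years: must be >= 1", call. = FALSE)
  }
  if (params$config$discount_rate < 0) {
    stop("validation error at config.discount_rate: must be >= 0", call. = FALSE)
  }
  for (nm in names(params$strategies)) {
    validate_diag_prob_table(params$strategies[[nm]], where = paste0("strategies.", nm))
  }
  if (any(params$multipliers <= 0)) {
    stop("validation error at multipliers: must be positive", call. = FALSE)
  }
  invisible(params)
}

#' Load a parameter set from a config file or the packaged defaults
#'
#' `source = "defaults"` builds the packaged default set: Table-style unit
#' costs, a 6-year horizon at 3% annual discounting, diagnostic probability
#' tables generated from the packaged calibration targets
#' ([generate_diag_prob_table()]) and per-state multipliers calibrated to the
#' per-state cost anchors ([calibrate()]). A YAML/JSON path written by
#' [write_parameters()] restores a set verbatim.
#'
#' @param source `"defaults"` or a path to a YAML/JSON parameter document.
#' @return a validated [parameter_set()].
#' @export
load_parameters <- function(source = "defaults") {
  if (identical(source, "defaults")) {
    return(default_parameters())
  }
  if (!file.exists(source)) stop("no such parameter file: ", source, call. = FALSE)
  doc <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
    jsonlite::read_json(source, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(source)
  }
  params_from_list(doc)
}

#' Packaged default parameter set
#'
#' @param calibrated calibrate the per-state multipliers to the packaged cost
#'   anchors (default `TRUE`).
#' @param targets a [calibration_targets()] used to generate the diagnostic
#'   probability tables.
#' @return a validated [parameter_set()].
#' @export
default_parameters <- function(calibrated = TRUE, targets = calibration_targets()) {
  params <- parameter_set(strategies = generate_diag_prob_table(targets))
  if (calibrated) params <- calibrate(params, anchors = targets$anchors)
  params
}

#' Serialize a parameter set to YAML
#'
#' @param params a [parameter_set()].
#' @param path output file path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  doc <- list(
    costs = list(item = params$costs$item,
                 unit_cost = params$costs$unit_cost,
                 sd = params$costs$sd,
                 basis = params$costs$basis),
    config = unclass(params$config),
    strategies = lapply(params$strategies, function(s) {
      s <- unclass(s)
      s$biopsy_outcome <- as.list(s$biopsy_outcome)
      s
    }),
    mix = unclass(params$mix),
    as_sched = list(cum_progression = as.list(params$as_sched$cum_progression),
                    events = as.list(params$as_sched$events),
                    curative_mix = as.list(params$as_sched$curative_mix)),
    loc_mix = local({
      lm <- unclass(params$loc_mix)
      lm$intermediate_weights <- as.list(lm$intermediate_weights)
      lm$high_weights <- as.list(lm$high_weights)
      lm
    }),
    migration = as.list(unclass(params$migration)),
    multipliers = as.list(params$multipliers),
    scales = params$scales
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    yaml::write_yaml(doc, path, precision = 15L)
  }
  invisible(path)
}

#' @keywords internal
params_from_list <- function(doc) {
  costs <- cost_table(
    stats::setNames(as.numeric(doc$costs$unit_cost), doc$costs$item),
    stats::setNames(as.numeric(doc$costs$sd), doc$costs$item),
    stats::setNames(as.character(doc$costs$basis), doc$costs$item)
  )
  cfg <- do.call(model_config, doc$config)
  strategies <- lapply(doc$strategies, function(s) {
    s[vapply(s, is.null, logical(1))] <- NULL  # JSON nulls -> constructor defaults
    s$biopsy_outcome <- unlist(s$biopsy_outcome)
    do.call(diag_prob_table, s)
  })
  mix <- do.call(treatment_mix, doc$mix)
  sched <- as_schedule(
    cum_progression = unlist(doc$as_sched$cum_progression),
    events = as.data.frame(doc$as_sched$events),
    curative_mix = unlist(doc$as_sched$curative_mix),
    horizon_years = cfg$horizon_years
  )
  lm_args <- doc$loc_mix
  lm_args$intermediate_weights <- unlist(lm_args$intermediate_weights)
  lm_args$high_weights <- unlist(lm_args$high_weights)
  loc <- do.call(localized_mix, lm_args)
  mig <- migration_factors(doc$migration$isup1, doc$migration$isup2_5,
                           doc$migration$metastatic)
  parameter_set(costs = costs, config = cfg, strategies = strategies,
                mix = mix, as_sched = sched, loc_mix = loc, migration = mig,
                multipliers = unlist(doc$multipliers), scales = doc$scales)
}

#' @export
print.pc_params <- function(x, ...) {
  cat("<pc_params> prostate cancer cost-model parameter set\n")
  cat("  horizon:", x$config$horizon_years, "years at",
      sprintf("%.1f%%", 100 * x$config$discount_rate), "discounting\n")
  cat("  strategies:", paste(names(x$strategies), collapse = ", "), "\n")
  cat("  calibration multipliers:",
      paste(sprintf("%s=%.4g", names(x$multipliers), x$multipliers), collapse = ", "),
      "\n")
  invisible(x)
}
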