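#' Simulate individual 6-year discounted treatment components for one state
#'
#' Individual-level counterpart of the cohort model: draws each patient's
#' event schedule (progression year, treatment-arm assignment, line
#' assignment, discontinuation year) with Bernoulli/categorical probabilities
#' equal to the cohort fractions, and accumulates the same discounted annual
#' costs. By construction the expectation equals the cohort model's state
#' component, which the test suite verifies at n = 200 000.
#'
#' @param state one of `"isup1"`, `"isup2_5"`, `"metastatic"`.
#' @param n number of patients.
#' @param params a [parameter_set()].
#' @return numeric vector of per-patient discounted treatment components
#'   (EUR), excluding the diagnostic cascade.
#' @export
simulate_state_component <- function(state, n, params) {
  switch(state,
         isup1 = sim_isup1(n, params),
         isup2_5 = sim_isup2_5(n, params),
         metastatic = sim_metastatic(n, params),
         stop("unknown disease state: ", state, call. = FALSE))
}

#' @keywords internal
sim_isup1 <- function(n, params) {
  cfg <- params$config
  sched <- params$as_sched
  mult <- params$multipliers[["isup1"]]
  h <- cfg$horizon_years
  df <- discount_factors(cfg$discount_rate, h)
  cum <- cum_progression_by_year(sched, h)
  d_prog <- diff(c(0, cum))

  ev <- sched$events
  surv_unit <- ev$psa * cost_of(params$costs, "psa_test") +
    ev$mri * cost_of(params$costs, "mri") +
    ev$biopsy * cost_of(params$costs, "biopsy")
  surv_unit <- c(surv_unit, rep(0, h - length(surv_unit)))[seq_len(h)] * mult
  # discounted surveillance paid if progressing in year p (no surveillance in
  # the progression year); category h+1 = never progresses
  surv_paid <- c(cumsum(c(0, (surv_unit * df)[-h])), sum(surv_unit * df))

  prog_year <- sample.int(h + 1L, n, replace = TRUE,
                          prob = c(d_prog, 1 - cum[h]))
  unit <- c(rp = cost_of(params$costs, "rp"),
            rt_short_adt = cost_of(params$costs, "rt") + cost_of(params$costs, "adt"))
  arm <- sample(names(sched$curative_mix), n, replace = TRUE,
                prob = sched$curative_mix)
  curative <- ifelse(prog_year <= h, unit[arm] * df[pmin(prog_year, h)], 0)
  surv_paid[prog_year] + curative
}

#' @keywords internal
sim_isup2_5 <- function(n, params) {
  cfg <- params$config
  mix <- params$loc_mix
  mult <- params$multipliers[["isup2_5"]]
  h <- cfg$horizon_years
  df <- discount_factors(cfg$discount_rate, h)
  costs <- params$costs
  adt <- cost_of(costs, "adt")
  adt_disc <- function(L) {
    sum(pmin(pmax(L - (seq_len(h) - 1), 0), 1) * adt * df)
  }
  # four deterministic profiles: grade x modality
  profile_cost <- c(
    int_rp = cost_of(costs, "rp"),
    int_rt = cost_of(costs, "rt") + adt_disc(mix$adt_years_intermediate * mult),
    high_rp = cost_of(costs, "rp") + cost_of(costs, "plnd"),
    high_rt = cost_of(costs, "rt") + adt_disc(mix$adt_years_high * mult)
  )
  p <- c(mix$intermediate_fraction * mix$intermediate_weights[["rp"]],
         mix$intermediate_fraction * mix$intermediate_weights[["rt_adt"]],
         (1 - mix$intermediate_fraction) * mix$high_weights[["rp_plnd"]],
         (1 - mix$intermediate_fraction) * mix$high_weights[["rt_adt"]])
  profile <- sample.int(4L, n, replace = TRUE, prob = p)
  unname(profile_cost[profile])
}

#' @keywords internal
sim_metastatic <- function(n, params) {
  cfg <- params$config
  mix <- params$mix
  mult <- params$multipliers[["metastatic"]]
  h <- cfg$horizon_years
  df <- discount_factors(cfg$discount_rate, h)
  costs <- params$costs
  cum <- cum_discontinuation(mix, h)

  u_disc <- stats::runif(n)           # active in year t iff u > cum[t]
  on_arpi <- stats::runif(n) < mix$arpi_fraction
  triplet <- on_arpi & (stats::runif(n) < mix$triplet_given_arpi_fraction)
  chemo <- triplet | !on_arpi         # taxane-only patients all get one course
  on_parp <- stats::runif(n) < mix$parp_fraction
  on_immune <- stats::runif(n) < mix$immune_fraction
  on_radio <- stats::runif(n) < mix$radiopharm_fraction
  on_lu <- stats::runif(n) < mix$radiopharm_lu_split
  on_osteo <- stats::runif(n) < mix$osteoprotective_fraction

  adt_on <- pmin(pmax(mix$adt_years - (seq_len(h) - 1), 0), 1)
  radio_cost <- ifelse(on_lu, cost_of(costs, "lu_psma"), cost_of(costs, "ra223"))
  annual_base <- on_arpi * cost_of(costs, "arpi") +
    on_parp * cost_of(costs, "parp") +
    on_immune * cost_of(costs, "immune") +
    on_osteo * cost_of(costs, "osteoprotective")

  total <- numeric(n)
  for (t in seq_len(h)) {
    active <- u_disc > cum[t]
    sys_t <- annual_base + adt_on[t] * cost_of(costs, "adt")
    if (t == 1L) sys_t <- sys_t + chemo * cost_of(costs, "chemo_cycle")
    if (t > h - 2L) sys_t <- sys_t + on_radio * radio_cost
    total <- total + active * sys_t * mult * df[t]
  }
  total <- total + cost_of(costs, "psma_pet") * df[1L]
  total <- total + (stats::runif(n) < mix$palliative_fraction) *
    cost_of(costs, "palliative") * df[max(1, h - 1)]
  total <- total + (stats::runif(n) < mix$eol_fraction) *
    cost_of(costs, "end_of_life") * df[h]
  total
}

#' Microsimulate per-man 6-year costs under a diagnostic strategy
#'
#' Draws each man's path through the diagnostic decision tree (threshold
#' crossings as Bernoulli variables), charges the tests along the path, and,
#' for men landing in a disease state, adds an individual discounted treatment
#' component from [simulate_state_component()]. The sample mean converges to
#' the analytic cost per man of [evaluate_strategy()].
#'
#' @param params a [parameter_set()].
#' @param strategy `"psa_mri"`, `"sthlm3_reflex"` or `"swop"`.
#' @param n number of men (>= 1).
#' @param seed integer seed.
#' @return numeric vector of per-man costs (EUR) of length `n`.
#' @export
microsimulate_costs <- function(params, strategy, n, seed) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  probs <- params$strategies[[strategy]]
  if (is.null(probs)) stop("unknown strategy: ", strategy, call. = FALSE)
  costs <- params$costs
  chain <- strategy_definition(strategy, probs)
  unit <- cost_of(costs, chain$cost_key)

  reached <- matrix(FALSE, n, nrow(chain))
  reached[, 1L] <- TRUE
  for (i in seq_len(nrow(chain))[-1L]) {
    reached[, i] <- reached[, i - 1L] & (stats::runif(n) < chain$p_cond[i])
  }
  diag_cost <- drop(reached %*% unit)
  biopsied <- reached[, nrow(chain)]

  state <- rep("no_workup", n)
  k <- sum(biopsied)
  if (k > 0L) {
    state[biopsied] <- sample(names(probs$biopsy_outcome), k, replace = TRUE,
                              prob = probs$biopsy_outcome)
  }
  if (identical(strategy, "swop") && probs$fn_cs_per_1000 > 0) {
    # latent clinically significant cases missed by the risk calculator:
    # among men leaving the pathway before biopsy, assign FN status at the
    # rate implied by fn_cs_per_1000, then progress a fraction to metastatic
    p_exit <- 1 - prod(chain$p_cond)
    p_fn <- probs$fn_cs_per_1000 / (1000 * p_exit)
    stopifnot_fraction(p_fn, "swop implied per-man false-negative rate")
    exited <- !biopsied
    is_fn <- exited & (stats::runif(n) < p_fn)
    progresses <- is_fn & (stats::runif(n) < probs$fn_progress)
    state[progresses] <- "metastatic"
    state[is_fn & !progresses] <- "isup2_5"
  }

  total <- diag_cost * params$scales$cost$diagnostic
  for (s in DISEASE_STATES) {
    idx <- which(state == s)
    if (length(idx) > 0L) {
      total[idx] <- total[idx] +
        simulate_state_component(s, length(idx), params) * params$scales$cost[[s]]
    }
  }
  total
}
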