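STATE_NAMES <- c("no_workup", "benign", "isup1", "isup2_5", "metastatic")
DISEASE_STATES <- c("isup1", "isup2_5", "metastatic")

#' Diagnostic branch-probability table for one strategy
#'
#' Probabilities along the diagnostic cascade of one strategy. All strategies
#' start with a PSA test on every man; downstream tests are gated by threshold
#' crossings. Fields irrelevant to a strategy (e.g. the Stockholm3 positivity
#' for the plain PSA pathway) may be `NA`.
#'
#' @param strategy one of `"psa_mri"`, `"sthlm3_reflex"`, `"swop"`.
#' @param p_psa_ge_3 fraction of tested men with PSA >= 3 ng/ml.
#' @param p_psa_ge_1_5 fraction with PSA >= 1.5 ng/ml (must be >=
#'   `p_psa_ge_3`: nested thresholds).
#' @param p_sthlm3_pos fraction with Stockholm3 score >= 11 among men with
#'   PSA >= 1.5 (reflex strategy only).
#' @param p_high_risk fraction classified high-risk by the SWOP risk
#'   calculator among men with PSA >= 3 (SWOP strategy only).
#' @param p_pirads_pos fraction with PI-RADS >= 3 among men receiving MRI.
#' @param biopsy_outcome named distribution over
#'   `benign`, `isup1`, `isup2_5`, `metastatic` given biopsy; sums to 1.
#' @param fn_cs_per_1000 (SWOP only) clinically significant (ISUP 2-5) cases
#'   per 1000 tested men missed by the risk calculator.
#' @param fn_progress (SWOP only) fraction of those false negatives projected
#'   to progress to metastatic disease within the horizon.
#' @return a list of class `diag_prob_table`.
#' @export
diag_prob_table <- function(strategy,
                            p_psa_ge_3,
                            p_psa_ge_1_5 = NA_real_,
                            p_sthlm3_pos = NA_real_,
                            p_high_risk = NA_real_,
                            p_pirads_pos,
                            biopsy_outcome,
                            fn_cs_per_1000 = 0,
                            fn_progress = 0) {
  tab <- structure(
    list(strategy = strategy,
         p_psa_ge_3 = p_psa_ge_3,
         p_psa_ge_1_5 = p_psa_ge_1_5,
         p_sthlm3_pos = p_sthlm3_pos,
         p_high_risk = p_high_risk,
         p_pirads_pos = p_pirads_pos,
         biopsy_outcome = biopsy_outcome[c("benign", "isup1", "isup2_5", "metastatic")],
         fn_cs_per_1000 = fn_cs_per_1000,
         fn_progress = fn_progress),
    class = "diag_prob_table"
  )
  validate_diag_prob_table(tab)
  tab
}

#' @keywords internal
validate_diag_prob_table <- function(tab, where = "diag_prob_table") {
  for (f in c("p_psa_ge_3", "p_psa_ge_1_5", "p_sthlm3_pos", "p_high_risk",
              "p_pirads_pos", "fn_progress")) {
    v <- tab[[f]]
    if (!is.na(v)) stopifnot_fraction(v, paste0(where, ".", f))
  }
  bo <- tab$biopsy_outcome
  if (anyNA(bo)) {
    stop("validation error at ", where, ".biopsy_outcome: missing category",
         call. = FALSE)
  }
  stopifnot_fraction(bo, paste0(where, ".biopsy_outcome"))
  if (abs(sum(bo) - 1) > 1e-12) {
    stop("validation error at ", where,
         ".biopsy_outcome: distribution must sum to 1", call. = FALSE)
  }
  if (!is.na(tab$p_psa_ge_1_5) && tab$p_psa_ge_1_5 < tab$p_psa_ge_3 - 1e-12) {
    stop("validation error at ", where,
         ": p_psa_ge_1_5 must be >= p_psa_ge_3 (nested thresholds)",
         call. = FALSE)
  }
  invisible(tab)
}

#' Node sequence of a diagnostic strategy
#'
#' Expresses a strategy as an ordered chain of tests. Each node carries the
#' cost key charged when the node is reached and the conditional probability
#' of continuing from the previous node; men leaving the chain before biopsy
#' receive no further workup, and biopsied men are distributed over the
#' disease states by the biopsy outcome distribution.
#'
#' @param name strategy name.
#' @param probs a [diag_prob_table()] for the strategy.
#' @return data frame of class `strategy_definition` with columns `test`,
#'   `cost_key`, `p_cond` (probability of reaching the node given the previous
#'   node was reached).
#' @export
strategy_definition <- function(name, probs) {
  nodes <- switch(
    name,
    psa_mri = data.frame(
      test = c("psa", "mri", "biopsy"),
      cost_key = c("psa_test", "mri", "biopsy"),
      p_cond = c(1, probs$p_psa_ge_3, probs$p_pirads_pos)
    ),
    sthlm3_reflex = data.frame(
      test = c("psa", "sthlm3", "mri", "biopsy"),
      cost_key = c("psa_test", "stockholm3", "mri", "biopsy"),
      p_cond = c(1, probs$p_psa_ge_1_5, probs$p_sthlm3_pos, probs$p_pirads_pos)
    ),
    swop = data.frame(
      test = c("psa", "swop_trus", "mri", "biopsy"),
      cost_key = c("psa_test", "trus", "mri", "biopsy"),
      p_cond = c(1, probs$p_psa_ge_3, probs$p_high_risk, probs$p_pirads_pos)
    ),
    stop("unknown strategy: ", name, call. = FALSE)
  )
  if (anyNA(nodes$p_cond)) {
    stop("strategy '", name, "' has an undefined branch probability",
         call. = FALSE)
  }
  structure(nodes, class = c("strategy_definition", class(nodes)),
            strategy = name)
}

#' Expected diagnostic cost per man tested
#'
#' Walks the strategy chain recursively: each test contributes its unit cost
#' weighted by the probability of reaching it. Returns the per-man expectation
#' and a per-node breakdown whose contributions sum to the total.
#'
#' @param strategy a [strategy_definition()] (or a strategy name, in which
#'   case `probs` must be supplied).
#' @param probs a [diag_prob_table()] (used when `strategy` is a name).
#' @param costs a [cost_table()].
#' @return list with `total` (EUR per man) and `breakdown` (data frame with
#'   `test`, `p_reach`, `expected_cost`).
#' @export
expected_diagnostic_cost <- function(strategy, probs = NULL, costs = default_costs()) {
  if (is.character(strategy)) strategy <- strategy_definition(strategy, probs)
  unit <- cost_of(costs, strategy$cost_key)
  # recursion: expected downstream cost given arrival at node i
  downstream <- function(i) {
    if (i > nrow(strategy)) return(0)
    p_next <- if (i < nrow(strategy)) strategy$p_cond[i + 1L] else 0
    unit[i] + p_next * downstream(i + 1L)
  }
  total <- strategy$p_cond[1L] * downstream(1L)
  p_reach <- cumprod(strategy$p_cond)
  breakdown <- data.frame(test = strategy$test,
                          p_reach = p_reach,
                          expected_cost = p_reach * unit)
  stopifnot(abs(sum(breakdown$expected_cost) - total) < 1e-9)
  list(total = total, breakdown = breakdown)
}

#' Disease-state distribution per 1000 men tested
#'
#' Multiplies through the strategy chain: the fraction biopsied is the product
#' of all branch probabilities, and biopsied men are split over the four
#' states by the biopsy outcome distribution. Men leaving the chain earlier
#' are counted as `no_workup`.
#'
#' @inheritParams expected_diagnostic_cost
#' @param per number of men tested (default 1000).
#' @return a `state_distribution`: named numeric over `no_workup`, `benign`,
#'   `isup1`, `isup2_5`, `metastatic`, summing to `per`.
#' @export
state_distribution <- function(strategy, probs = NULL, per = 1000) {
  if (is.character(strategy)) {
    name <- strategy
    strategy <- strategy_definition(strategy, probs)
  } else {
    name <- attr(strategy, "strategy")
    if (is.null(probs)) stop("probs table required for biopsy outcomes", call. = FALSE)
  }
  p_biopsy <- prod(strategy$p_cond)
  counts <- c(no_workup = per * (1 - p_biopsy),
              per * p_biopsy * probs$biopsy_outcome)
  names(counts) <- STATE_NAMES
  new_state_distribution(counts)
}

#' @keywords internal
new_state_distribution <- function(counts) {
  stopifnot(identical(names(counts), STATE_NAMES))
  if (any(counts < -1e-9)) {
    stop("state distribution has a negative count", call. = FALSE)
  }
  structure(counts, class = "state_distribution")
}

#' Apply stage migration to a state distribution
#'
#' Scales the cancer-state counts by the migration factors; the net change in
#' cancer counts is absorbed by the `benign` category (a net decrease in
#' cancers returns men to the no-cancer pool), so the total is conserved
#' exactly. The absorbing category is configurable.
#'
#' @param base a `state_distribution`.
#' @param f a [migration_factors()].
#' @param absorb category absorbing the net change (`"benign"` or
#'   `"no_workup"`).
#' @return a `state_distribution` with the same total.
#' @export
apply_stage_migration <- function(base, f = migration_factors(), absorb = "benign") {
  absorb <- match.arg(absorb, c("benign", "no_workup"))
  out <- unclass(base)
  out["isup1"] <- f[["isup1"]] * base[["isup1"]]
  out["isup2_5"] <- f[["isup2_5"]] * base[["isup2_5"]]
  out["metastatic"] <- f[["metastatic"]] * base[["metastatic"]]
  delta <- sum(base[DISEASE_STATES]) - sum(out[DISEASE_STATES])
  out[absorb] <- out[absorb] + delta
  if (out[absorb] < 0) {
    stop("stage migration drives the absorbing category ('", absorb,
         "') negative", call. = FALSE)
  }
  new_state_distribution(out)
}

#' SWOP pathway state distribution and diagnostic cost
#'
#' The SWOP risk-calculator variant of the PSA pathway: men with PSA >= 3
#' undergo SWOP risk estimation (costed as a transrectal ultrasound volume
#' measurement) and only high-risk men proceed to MRI. Detected-state counts
#' come from the SWOP tree; clinically significant cases missed by the
#' calculator (`fn_cs_per_1000`) remain in the ISUP 2-5 state (delayed
#' detection) except for the fraction `fn_progress` projected to progress to
#' metastatic disease within the horizon.
#'
#' @param psa_dist `state_distribution` of the PSA pathway (used for the
#'   degenerate no-false-negative check and error reporting).
#' @param swop_probs a [diag_prob_table()] with `strategy = "swop"`.
#' @param costs a [cost_table()].
#' @param fn_progress overrides `swop_probs$fn_progress` when non-`NULL`.
#' @return list with `distribution` (a `state_distribution`) and
#'   `diagnostic_cost` (EUR per man).
#' @export
swop_distribution <- function(psa_dist, swop_probs, costs = default_costs(),
                              fn_progress = NULL) {
  fnp <- fn_progress %||% swop_probs$fn_progress
  stopifnot_fraction(fnp, "swop.fn_progress")
  fn <- swop_probs$fn_cs_per_1000
  dist <- state_distribution("swop", swop_probs)
  if (fn > dist[["no_workup"]] + 1e-9) {
    stop("SWOP false-negative count exceeds available undetected cases",
         call. = FALSE)
  }
  out <- unclass(dist)
  out["metastatic"] <- out["metastatic"] + fnp * fn
  out["isup2_5"] <- out["isup2_5"] + (1 - fnp) * fn
  out["no_workup"] <- out["no_workup"] - fn
  dc <- expected_diagnostic_cost("swop", swop_probs, costs)
  list(distribution = new_state_distribution(out), diagnostic_cost = dc$total)
}

#' @export
print.state_distribution <- function(x, ...) {
  cat("<state_distribution> per", format(sum(x)), "men tested\n")
  print(round(unclass(x), 3))
  invisible(x)
}
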