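#' Evaluate one diagnostic strategy end to end
#'
#' Combines the decision tree with the calibrated cohort model. The PSA-arm
#' state distribution comes from its tree; the biomarker arm applies the stage
#' migration factors to the (scaled) PSA-arm counts — the mechanism by which
#' the reflex pathway changes the case mix — and the SWOP variant adds its
#' false-negative progression adjustment. Per-state treatment spend is the
#' per-1000 count times the state's discounted treatment component; total
#' spend adds the diagnostic spend of all 1000 men (men leaving the pathway
#' early contribute their PSA test via the tree expectation).
#'
#' @param params a (typically calibrated) [parameter_set()].
#' @param strategy `"psa_mri"`, `"sthlm3_reflex"` or `"swop"`.
#' @return a list of class `strategy_result`: `strategy`,
#'   `diagnostic_cost_per_man`, `state_distribution`, `per_state_spend`
#'   (treatment spend by disease state), `diagnostic_spend`,
#'   `total_cost_per_1000`, `cost_per_man`.
#' @export
evaluate_strategy <- function(params, strategy) {
  if (!strategy %in% names(params$strategies)) {
    stop("unknown strategy: ", strategy, call. = FALSE)
  }
  sc <- params$scales
  comp <- state_components(params)
  comp["isup1"] <- comp["isup1"] * sc$cost$isup1
  comp["isup2_5"] <- comp["isup2_5"] * sc$cost$isup2_5
  comp["metastatic"] <- comp["metastatic"] * sc$cost$metastatic

  psa_dist <- scaled_psa_distribution(params)
  if (strategy == "psa_mri") {
    dist <- psa_dist
    diag_pm <- expected_diagnostic_cost("psa_mri", params$strategies$psa_mri,
                                        params$costs)$total
  } else if (strategy == "sthlm3_reflex") {
    dist <- apply_stage_migration(psa_dist, scaled_migration(params))
    diag_pm <- expected_diagnostic_cost("sthlm3_reflex",
                                        params$strategies$sthlm3_reflex,
                                        params$costs)$total
  } else {
    sw <- swop_distribution(psa_dist, params$strategies$swop, params$costs)
    dist <- sw$distribution
    diag_pm <- sw$diagnostic_cost
  }
  diag_pm <- diag_pm * sc$cost$diagnostic

  spend <- dist[DISEASE_STATES] * comp[DISEASE_STATES]
  diagnostic_spend <- sum(dist) * diag_pm
  total <- diagnostic_spend + sum(spend)
  structure(
    list(strategy = strategy,
         diagnostic_cost_per_man = diag_pm,
         state_distribution = dist,
         per_state_spend = spend,
         diagnostic_spend = diagnostic_spend,
         total_cost_per_1000 = total,
         cost_per_man = total / sum(dist)),
    class = "strategy_result"
  )
}

#' PSA-arm distribution with sensitivity count scaling applied
#'
#' Detection-count scaling knobs multiply the ISUP 1 and ISUP 2-5 counts; the
#' benign pool absorbs the difference so the cohort total is conserved.
#' @keywords internal
scaled_psa_distribution <- function(params) {
  dist <- state_distribution("psa_mri", params$strategies$psa_mri)
  sc <- params$scales$count
  out <- unclass(dist)
  out["isup1"] <- out["isup1"] * sc$isup1
  out["isup2_5"] <- out["isup2_5"] * sc$isup2_5
  out["benign"] <- out["benign"] + (dist[["isup1"]] - out[["isup1"]]) +
    (dist[["isup2_5"]] - out[["isup2_5"]])
  if (out["benign"] < 0) {
    stop("count scaling drives the benign pool negative", call. = FALSE)
  }
  new_state_distribution(out)
}

#' Migration factors with the mPC-proportion sensitivity knob applied
#'
#' `scales$migration_mpc` scales the net metastatic decrease:
#' factor' = 1 - (1 - factor) * scale.
#' @keywords internal
scaled_migration <- function(params) {
  f <- unclass(params$migration)
  f[["metastatic"]] <- 1 - (1 - f[["metastatic"]]) * params$scales$migration_mpc
  migration_factors(f[["isup1"]], f[["isup2_5"]], f[["metastatic"]])
}

#' Compare two diagnostic strategies
#'
#' Evaluates both strategies, computes the net saving per 1000 men and per man
#' (EUR, truncated to whole euros for reporting) and the saving percentage
#' (one decimal, half up) relative to the baseline, and optionally performs a
#' Mann-Whitney U test on microsimulated per-man 6-year cost samples.
#'
#' @param params a [parameter_set()].
#' @param baseline,comparator strategy names.
#' @param test run the Mann-Whitney comparison on microsimulated samples.
#' @param n_sim per-arm microsimulation sample size for the test.
#' @param seed seed for the microsimulation.
#' @return a list of class `comparison_result`.
#' @export
compare_strategies <- function(params, baseline = "psa_mri",
                               comparator = "sthlm3_reflex",
                               test = FALSE, n_sim = 1000, seed = 1) {
  if (identical(baseline, comparator)) {
    warning("comparing a strategy to itself", call. = FALSE)
  }
  res_b <- evaluate_strategy(params, baseline)
  res_c <- evaluate_strategy(params, comparator)
  saving <- res_b$total_cost_per_1000 - res_c$total_cost_per_1000
  saving_pm <- res_b$cost_per_man - res_c$cost_per_man
  pct <- 100 * saving / res_b$total_cost_per_1000
  out <- list(
    baseline = res_b, comparator = res_c,
    net_saving_per_1000 = saving,
    saving_per_man = saving_pm,
    saving_per_man_reported = trunc_eur(saving_pm),
    saving_percent = pct,
    saving_percent_reported = round_pct1(pct),
    u_statistic = NA_real_, p_value = NA_real_
  )
  if (test) {
    a <- microsimulate_costs(params, baseline, n_sim, seed)
    b <- microsimulate_costs(params, comparator, n_sim, seed + 1L)
    mw <- mann_whitney(a, b)
    out$u_statistic <- mw$u
    out$p_value <- mw$p_value
  }
  structure(out, class = "comparison_result")
}

#' Mann-Whitney U test for cost distributions
#'
#' U is computed by rank summation with midranks for ties. For small tie-free
#' samples (n_a * n_b <= `exact_max`) the two-sided p-value is exact, from the
#' null distribution of U ([stats::pwilcox]); otherwise (or with ties) a
#' normal approximation with tie correction and continuity correction is
#' used. When every value in both samples is identical the test is degenerate
#' and p = 1 by convention.
#'
#' @param a,b numeric samples (nonempty).
#' @param method `"auto"` (default), `"exact"` or `"approx"`.
#' @param exact_max largest n_a * n_b for which the exact branch is used.
#' @return list with `u` (U statistic of sample `a`), `p_value`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "approx"),
                         exact_max = 400) {
  method <- match.arg(method)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L

  if (stats::var(c(a, b)) == 0) {
    return(list(u = u_a, p_value = 1, method = "degenerate"))
  }
  use_exact <- switch(method,
                      auto = !ties && n_a * n_b <= exact_max,
                      exact = TRUE,
                      approx = FALSE)
  if (use_exact) {
    if (ties) stop("exact p-value unavailable with ties", call. = FALSE)
    # two-sided exact tail doubling from the null distribution of U
    if (u_a > n_a * n_b / 2) {
      p <- 2 * (1 - stats::pwilcox(u_a - 1, n_a, n_b))
    } else {
      p <- 2 * stats::pwilcox(u_a, n_a, n_b)
    }
    return(list(u = u_a, p_value = min(1, p), method = "exact"))
  }
  mu <- n_a * n_b / 2
  n <- n_a + n_b
  tie_sizes <- table(c(a, b))
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * (n + 1 - tie_term)
  z <- (u_a - mu - sign(u_a - mu) * 0.5) / sqrt(sigma2)
  list(u = u_a, p_value = 2 * stats::pnorm(-abs(z)), method = "approx")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat("<strategy_result> ", x$strategy, "\n", sep = "")
  cat(sprintf("  diagnostic cost per man: %.2f EUR\n", x$diagnostic_cost_per_man))
  cat(sprintf("  total per 1000 men:      %.0f EUR (%.0f per man)\n",
              x$total_cost_per_1000, trunc_eur(x$cost_per_man)))
  invisible(x)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$baseline$strategy, " vs ",
      x$comparator$strategy, "\n", sep = "")
  cat(sprintf("  net saving per 1000 men: %.0f EUR\n",
              trunc_eur(x$net_saving_per_1000)))
  cat(sprintf("  saving per man: %d EUR (%.1f%%)\n",
              as.integer(x$saving_per_man_reported), x$saving_percent_reported))
  if (!is.na(x$p_value)) {
    cat(sprintf("  Mann-Whitney U = %.1f, p = %.3g\n", x$u_statistic, x$p_value))
  }
  invisible(x)
}
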