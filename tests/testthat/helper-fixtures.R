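# Shared fixtures. The calibrated default set is cached per test run; it is
# deterministic, so caching cannot leak state between tests.
cached_defaults <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- default_parameters()
    p
  }
})

# cost table with chosen overrides and every other item zeroed, for toy
# single-line cohort checks
toy_costs <- function(...) {
  over <- c(...)
  keys <- default_costs()$item
  vals <- stats::setNames(rep(0, length(keys)), keys)
  vals[names(over)] <- over
  cost_table(vals)
}

# independent oracle: exhaustive enumeration of all root-to-leaf paths of a
# strategy chain (leaf = exit after node i, or biopsy outcome at the end)
enumerate_tree <- function(chain, probs, costs, per = 1000) {
  unit <- cost_of(costs, chain$cost_key)
  k <- nrow(chain)
  p_reach <- cumprod(chain$p_cond)
  expected_cost <- 0
  counts <- c(no_workup = 0, benign = 0, isup1 = 0, isup2_5 = 0, metastatic = 0)
  for (i in seq_len(k)) {
    p_exit <- p_reach[i] * (if (i < k) 1 - chain$p_cond[i + 1L] else 0)
    path_cost <- sum(unit[seq_len(i)])
    expected_cost <- expected_cost + p_exit * path_cost
    counts["no_workup"] <- counts["no_workup"] + per * p_exit
  }
  # never entered the chain at all (first node has p_cond = 1 in practice)
  p_none <- 1 - p_reach[1L]
  counts["no_workup"] <- counts["no_workup"] + per * p_none
  # biopsy leaves
  for (s in names(probs$biopsy_outcome)) {
    p_leaf <- p_reach[k] * probs$biopsy_outcome[[s]]
    expected_cost <- expected_cost + p_leaf * sum(unit)
    counts[s] <- counts[s] + per * p_leaf
  }
  list(total = expected_cost, counts = counts)
}

# a small valid diagnostic table for the plain PSA pathway
psa_table <- function(p3 = 0.5, pirads = 0.5,
                      outcome = c(benign = 0.5, isup1 = 0.2,
                                  isup2_5 = 0.25, metastatic = 0.05)) {
  diag_prob_table("psa_mri", p_psa_ge_3 = p3, p_psa_ge_1_5 = max(p3, 0.6),
                  p_pirads_pos = pirads, biopsy_outcome = outcome)
}
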