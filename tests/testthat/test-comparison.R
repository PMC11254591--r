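test_that("strategy evaluation combines tree and cohort model linearly", {
  params <- cached_defaults()
  res <- evaluate_strategy(params, "psa_mri")
  # independent assembly from the parts
  dist <- state_distribution("psa_mri", params$strategies$psa_mri)
  comp <- state_components(params)
  diag_pm <- expected_diagnostic_cost("psa_mri", params$strategies$psa_mri,
                                      params$costs)$total
  by_hand <- 1000 * diag_pm + sum(dist[c("isup1", "isup2_5", "metastatic")] *
                                    comp[c("isup1", "isup2_5", "metastatic")])
  expect_equal(res$total_cost_per_1000, by_hand, tolerance = 1e-9)
  expect_equal(res$cost_per_man, by_hand / 1000, tolerance = 1e-9)
  expect_equal(sum(res$per_state_spend) + res$diagnostic_spend,
               res$total_cost_per_1000, tolerance = 1e-9)
})

test_that("a distribution with no cancers costs diagnostics only", {
  params <- cached_defaults()
  tab <- psa_table(p3 = 0.3, pirads = 0.4,
                   outcome = c(benign = 1, isup1 = 0, isup2_5 = 0,
                               metastatic = 0))
  params$strategies$psa_mri <- tab
  res <- evaluate_strategy(params, "psa_mri")
  expect_equal(sum(res$per_state_spend), 0)
  expect_equal(res$total_cost_per_1000, 1000 * res$diagnostic_cost_per_man,
               tolerance = 1e-9)
})

test_that("evaluation is linear in state counts and in state costs", {
  params <- cached_defaults()
  res <- evaluate_strategy(params, "psa_mri")
  # doubling the metastatic component doubles the metastatic spend only
  p2 <- params
  p2$scales$cost$metastatic <- 2
  res2 <- evaluate_strategy(p2, "psa_mri")
  expect_equal(res2$per_state_spend[["metastatic"]],
               2 * res$per_state_spend[["metastatic"]], tolerance = 1e-12)
  expect_equal(res2$per_state_spend[["isup1"]], res$per_state_spend[["isup1"]])
  # halving the ISUP1 count halves its spend
  p3 <- params
  p3$scales$count$isup1 <- 0.5
  res3 <- evaluate_strategy(p3, "psa_mri")
  expect_equal(res3$per_state_spend[["isup1"]],
               0.5 * res$per_state_spend[["isup1"]], tolerance = 1e-12)
  expect_equal(sum(res3$state_distribution), 1000, tolerance = 1e-9)
})

test_that("strategy comparison reports savings under the stated rounding", {
  params <- cached_defaults()
  cmp <- compare_strategies(params, "psa_mri", "sthlm3_reflex")
  expect_equal(cmp$net_saving_per_1000,
               cmp$baseline$total_cost_per_1000 -
                 cmp$comparator$total_cost_per_1000, tolerance = 1e-9)
  expect_equal(cmp$saving_per_man_reported,
               trunc_eur(cmp$saving_per_man))
  expect_equal(cmp$saving_percent_reported,
               round_pct1(100 * cmp$net_saving_per_1000 /
                            cmp$baseline$total_cost_per_1000))
  expect_warning(self <- compare_strategies(params, "psa_mri", "psa_mri"),
                 "itself")
  expect_equal(self$saving_per_man_reported, 0)
  expect_equal(self$saving_percent_reported, 0)
  expect_error(evaluate_strategy(params, "nonsense"), "unknown strategy")
})

test_that("reported euro/percent rounding follows truncate and half-up rules", {
  expect_identical(trunc_eur(358.239), 358)
  expect_identical(trunc_eur(150.99999999), 151)
  expect_identical(trunc_eur(-2.7), -2)
  expect_identical(round_pct1(7.66), 7.7)
  expect_identical(round_pct1(7.65), 7.7)
  expect_identical(round_pct1(7.64), 7.6)
  expect_identical(round_pct1(-2.35), -2.4)
})

test_that("microsimulated per-man costs converge to the analytic mean", {
  params <- cached_defaults()
  res <- evaluate_strategy(params, "psa_mri")
  x <- microsimulate_costs(params, "psa_mri", 200000, seed = 2024)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - res$cost_per_man), 4 * se)
  # degenerate tree: every man pays exactly one PSA test
  p0 <- params
  p0$strategies$psa_mri <- psa_table(p3 = 0, pirads = 0)
  expect_equal(unique(microsimulate_costs(p0, "psa_mri", 500, seed = 1)), 29)
  expect_error(microsimulate_costs(params, "psa_mri", 0, seed = 1), ">= 1")
})

test_that("microsimulation honours the seed contract", {
  params <- cached_defaults()
  a1 <- microsimulate_costs(params, "sthlm3_reflex", 2000, seed = 5)
  a2 <- microsimulate_costs(params, "sthlm3_reflex", 2000, seed = 5)
  b <- microsimulate_costs(params, "sthlm3_reflex", 2000, seed = 6)
  expect_identical(a1, a2)
  expect_false(identical(a1, b))
  expect_lt(abs(mean(a1) - mean(b)), 6 * stats::sd(a1) / sqrt(2000) * 2)
})

test_that("Mann-Whitney matches exact enumeration and handles symmetry", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 0.1)
  expect_identical(res$method, "exact")
  # perfectly overlapping midranked samples: U = n^2/2
  res2 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res2$u, 8)
  # all values identical: degenerate convention
  expect_equal(mann_whitney(rep(2, 5), rep(2, 4))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("U statistics of the two samples always sum to n_a * n_b", {
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(sample(3:40, 1)); b <- rnorm(sample(3:40, 1))
    ua <- mann_whitney(a, b)$u
    ub <- mann_whitney(b, a)$u
    expect_equal(ua + ub, length(a) * length(b))
  }
})

test_that("exact and approximate p-values agree on 15x15 samples", {
  set.seed(99)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(15, mean = runif(1, 0, 1.5))
    pe <- mann_whitney(a, b, method = "exact")$p_value
    pa <- mann_whitney(a, b, method = "approx")$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("Mann-Whitney agrees with the reference implementation", {
  set.seed(17)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(14, mean = 0.5)
    mine <- mann_whitney(a, b, method = "exact")
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$u, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    mina <- mann_whitney(a, b, method = "approx")
    refa <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(mina$p_value, refa$p.value, tolerance = 1e-9)
  }
})
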