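test_that("generated tables hit every calibration target when re-evaluated", {
  targets <- calibration_targets()
  params <- cached_defaults()
  costs <- params$costs
  tabs <- params$strategies

  d_psa <- expected_diagnostic_cost("psa_mri", tabs$psa_mri, costs)$total
  d_s3 <- expected_diagnostic_cost("sthlm3_reflex", tabs$sthlm3_reflex, costs)$total
  expect_lt(abs((d_s3 - d_psa) - targets$diag_cost_gap_per_man), 1)

  # Stockholm3 share of biomarker-arm diagnostic spend
  brk <- expected_diagnostic_cost("sthlm3_reflex", tabs$sthlm3_reflex, costs)$breakdown
  share <- brk$expected_cost[brk$test == "sthlm3"] / d_s3
  expect_lt(abs(share - targets$sthlm3_share_of_diag), 0.005)

  # PSA-arm metastatic presentations per 1000
  dist <- state_distribution("psa_mri", tabs$psa_mri)
  expect_lt(abs(dist[["metastatic"]] - targets$psa_arm_mpc_per_1000), 0.1)

  # biomarker-arm biopsy outcomes equal the stage-migrated PSA distribution
  mig <- apply_stage_migration(dist, migration_factors())
  s3_dist <- state_distribution("sthlm3_reflex", tabs$sthlm3_reflex)
  for (s in c("isup1", "isup2_5", "metastatic")) {
    expect_equal(s3_dist[[s]], mig[[s]], tolerance = 1e-9)
  }
})

test_that("table generation round-trips across randomly drawn target sets", {
  # oracle: draw ground-truth detection counts, derive the aggregate targets
  # they imply, and require the generator to recover the counts and gaps
  costs <- default_costs()
  comp <- default_anchors()[c("isup1", "isup2_5", "metastatic")] - 2182
  f <- c(isup1 = 0.54, isup2_5 = 1.24, metastatic = 0.84)
  set.seed(2718)
  for (i in 1:10) {
    i1 <- runif(1, 15, 40); i2 <- runif(1, 40, 70); m <- runif(1, 8, 16)
    gap <- runif(1, 140, 175); share <- runif(1, 0.32, 0.38)
    d_psa <- gap / 0.42
    saving <- -1000 * gap + comp[["isup1"]] * (1 - f[["isup1"]]) * i1 -
      comp[["isup2_5"]] * (f[["isup2_5"]] - 1) * i2 +
      comp[["metastatic"]] * (1 - f[["metastatic"]]) * m
    t_psa <- 1000 * d_psa + comp[["isup1"]] * i1 + comp[["isup2_5"]] * i2 +
      comp[["metastatic"]] * m
    targets <- calibration_targets(
      diag_cost_gap_per_man = gap,
      sthlm3_share_of_diag = share,
      psa_arm_mpc_per_1000 = m,
      sthlm3_total_per_1000 = t_psa - saving,
      net_saving_per_1000 = saving
    )
    tabs <- generate_diag_prob_table(targets,
                                     strategies = c("psa_mri", "sthlm3_reflex"))
    d_psa_hat <- expected_diagnostic_cost("psa_mri", tabs$psa_mri, costs)$total
    d_s3_hat <- expected_diagnostic_cost("sthlm3_reflex", tabs$sthlm3_reflex,
                                         costs)$total
    expect_equal(d_s3_hat - d_psa_hat, gap, tolerance = 1e-6)
    dist <- state_distribution("psa_mri", tabs$psa_mri)
    expect_equal(dist[["metastatic"]], m, tolerance = 1e-6)
    expect_equal(dist[["isup1"]], i1, tolerance = 1e-6)
    expect_equal(dist[["isup2_5"]], i2, tolerance = 1e-6)
    brk <- expected_diagnostic_cost("sthlm3_reflex", tabs$sthlm3_reflex,
                                    costs)$breakdown
    expect_equal(brk$expected_cost[brk$test == "sthlm3"] / d_s3_hat, share,
                 tolerance = 1e-6)
  }
})

test_that("degenerate targets without metastatic cases zero the biopsy weight", {
  # totals consistent with zero metastatic presentations (25 ISUP 1 and
  # 50 ISUP 2-5 per 1000 men imply these aggregate targets)
  targets <- calibration_targets(psa_arm_mpc_per_1000 = 0,
                                 net_saving_per_1000 = -191520.5,
                                 sthlm3_total_per_1000 = 1291619.5)
  tabs <- generate_diag_prob_table(targets,
                                   strategies = c("psa_mri", "sthlm3_reflex"))
  expect_equal(tabs$psa_mri$biopsy_outcome[["metastatic"]], 0)
  expect_equal(tabs$sthlm3_reflex$biopsy_outcome[["metastatic"]], 0)
})

test_that("infeasible target combinations raise an informative error", {
  expect_error(
    generate_diag_prob_table(calibration_targets(sthlm3_share_of_diag = 0.99)),
    "infeasible")
})

test_that("random parameter sets always validate and evaluate cleanly", {
  for (seed in 1:100) {
    p <- random_parameter_set(seed)
    expect_silent(validate_parameters(p))
    res <- suppressWarnings(evaluate_strategy(p, "psa_mri"))
    expect_true(is.finite(res$total_cost_per_1000))
    expect_gte(res$total_cost_per_1000, 0)
  }
  expect_identical(random_parameter_set(12)$costs$unit_cost,
                   random_parameter_set(12)$costs$unit_cost)
})

test_that("synthetic cohorts are seed-reproducible and state-consistent", {
  params <- cached_defaults()
  dist <- state_distribution("psa_mri", params$strategies$psa_mri)
  c1 <- generate_cohort(dist, 5000, seed = 77, params = params)
  c2 <- generate_cohort(dist, 5000, seed = 77, params = params)
  expect_identical(c1, c2)
  expect_false(identical(c1$cost,
                         generate_cohort(dist, 5000, seed = 78,
                                         params = params)$cost))
  expect_error(generate_cohort(dist, 0, seed = 1, params = params), ">= 1")
  # a cohort concentrated on benign costs exactly the diagnostic cascade
  ben <- structure(c(no_workup = 0, benign = 1000, isup1 = 0, isup2_5 = 0,
                     metastatic = 0), class = "state_distribution")
  cb <- generate_cohort(ben, 200, seed = 3, params = params)
  expect_true(all(cb$cost == 2182))
})

test_that("cohort state frequencies pass a chi-square fit at n = 100000", {
  params <- cached_defaults()
  dist <- state_distribution("psa_mri", params$strategies$psa_mri)
  cohort <- generate_cohort(dist, 100000, seed = 424242, params = params)
  obs <- table(factor(cohort$state, levels = names(dist)))
  gof <- stats::chisq.test(obs, p = as.numeric(dist) / 1000)
  expect_gt(gof$p.value, 0.01)
})

test_that("cohort mean cost converges to the analytic per-patient expectation", {
  params <- cached_defaults()
  dist <- state_distribution("psa_mri", params$strategies$psa_mri)
  cohort <- generate_cohort(dist, 200000, seed = 515, params = params)
  comp <- state_components(params)
  cascade <- benign_cost(params$costs)
  expected <- (dist[["no_workup"]] * cost_of(params$costs, "psa_test") +
                 dist[["benign"]] * cascade +
                 sum(dist[c("isup1", "isup2_5", "metastatic")] *
                       (comp[c("isup1", "isup2_5", "metastatic")] + cascade))) / 1000
  se <- stats::sd(cohort$cost) / sqrt(nrow(cohort))
  expect_lt(abs(mean(cohort$cost) - expected), 4 * se)
})
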