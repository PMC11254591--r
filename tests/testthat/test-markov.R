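test_that("discounting matches the closed forms and a brute-force sum", {
  expect_equal(discount(c(10, 20, 30), 0), 60)
  expect_equal(discount(c(0, 103), 0.03), 100)
  set.seed(5)
  stream <- runif(6, 0, 5000)
  brute <- sum(vapply(1:6, function(t) stream[t] / 1.03^(t - 1), numeric(1)))
  expect_equal(discount(stream, 0.03), brute, tolerance = 1e-12)
  expect_error(discount(rep(1, 7), 0.03, horizon = 6), "longer")
  expect_error(discount(1, -0.1), ">= 0")
})

test_that("the benign state is the full diagnostic cascade", {
  expect_identical(benign_cost(default_costs()), 2182)
  expect_identical(benign_cost(toy_costs()), 0)
  doubled <- default_costs()
  doubled$unit_cost <- doubled$unit_cost * 2
  expect_identical(benign_cost(doubled), 4364)
})

test_that("active surveillance traces reproduce single-path hand sums", {
  cfg0 <- model_config(discount_rate = 0)
  # immediate progression, surgery only, no surveillance events
  sched <- as_schedule(cum_progression = c("1" = 1),
                       events = data.frame(year = 1:6, psa = 0, mri = 0,
                                           biopsy = 0),
                       curative_mix = c(rp = 1))
  tr <- as_cost(sched, default_costs(), cfg0)
  expect_equal(tr$discounted_cost, 10832)
  # no progression, no surveillance: nothing accrues
  sched0 <- as_schedule(cum_progression = c("6" = 0),
                        events = data.frame(year = 1:6, psa = 0, mri = 0,
                                            biopsy = 0))
  expect_equal(as_cost(sched0, default_costs(), cfg0)$discounted_cost, 0)
})

test_that("progression anchors interpolate as a piecewise-linear cumulative curve", {
  sched <- as_schedule()
  p <- cached_defaults()
  cum <- 1 - as_cost(sched, default_costs(), p$config)$yearly$active
  expect_equal(cum, c(0, 0, 0.25, 0.30, 0.35, 0.35), tolerance = 1e-12)
})

test_that("localized treatment reproduces the single-branch sums", {
  cfg0 <- model_config(discount_rate = 0)
  mix_rp <- localized_mix(intermediate_fraction = 1,
                          intermediate_weights = c(rp = 1, rt_adt = 0),
                          adt_years_intermediate = 0)
  expect_equal(localized_cost(mix_rp, default_costs(), cfg0)$discounted_cost,
               10832)
  mix_high <- localized_mix(intermediate_fraction = 0,
                            high_weights = c(rp_plnd = 1, rt_adt = 0),
                            adt_years_high = 0)
  expect_equal(localized_cost(mix_high, default_costs(), cfg0)$discounted_cost,
               12332)
  # RT with a 2-year ADT course, undiscounted: 7726 + 2*2370
  mix_rt <- localized_mix(intermediate_fraction = 1,
                          intermediate_weights = c(rp = 0, rt_adt = 1),
                          adt_years_intermediate = 2)
  expect_equal(localized_cost(mix_rt, default_costs(), cfg0)$discounted_cost,
               7726 + 2 * 2370)
})

test_that("metastatic treatment reproduces single-line hand sums", {
  cfg0 <- model_config(discount_rate = 0)
  # ADT backbone alone for one year
  mix_adt <- treatment_mix(arpi_fraction = 0, taxane_only_fraction = 1,
                           triplet_given_arpi_fraction = 0, parp_fraction = 0,
                           immune_fraction = 0, radiopharm_fraction = 0,
                           osteoprotective_fraction = 0,
                           palliative_fraction = 0, eol_fraction = 0,
                           discontinuation_year1 = 0,
                           discontinuation_increment = 0, adt_years = 1)
  costs_adt <- toy_costs(adt = 2370)
  expect_equal(metastatic_cost(mix_adt, costs_adt, cfg0)$discounted_cost, 2370)
  # radium-223 in the final two model years only
  mix_ra <- treatment_mix(arpi_fraction = 0, taxane_only_fraction = 1,
                          triplet_given_arpi_fraction = 0, parp_fraction = 0,
                          immune_fraction = 0, radiopharm_fraction = 1,
                          radiopharm_lu_split = 0,
                          osteoprotective_fraction = 0,
                          palliative_fraction = 0, eol_fraction = 0,
                          discontinuation_year1 = 0,
                          discontinuation_increment = 0, adt_years = 0)
  costs_ra <- toy_costs(ra223 = 25692)
  tr <- metastatic_cost(mix_ra, costs_ra, cfg0)
  expect_equal(tr$discounted_cost, 2 * 25692)
  expect_equal(which(tr$annual_costs > 0), c(5L, 6L))
})

test_that("a discontinuation schedule exceeding 100% is clamped with a warning", {
  mix <- treatment_mix(discontinuation_year1 = 0.8,
                       discontinuation_increment = 0.1)
  expect_warning(tr <- metastatic_cost(mix, default_costs(), model_config()),
                 "clamped")
  expect_true(all(tr$yearly$active >= 0))
})

test_that("every state component is linear in unit costs", {
  p <- cached_defaults()
  k <- 2.5
  scaled <- p$costs
  scaled$unit_cost <- scaled$unit_cost * k
  base <- c(
    as_cost(p$as_sched, p$costs, p$config, 1.3)$discounted_cost,
    localized_cost(p$loc_mix, p$costs, p$config, 0.7)$discounted_cost,
    metastatic_cost(p$mix, p$costs, p$config, 4.2)$discounted_cost
  )
  up <- c(
    as_cost(p$as_sched, scaled, p$config, 1.3)$discounted_cost,
    localized_cost(p$loc_mix, scaled, p$config, 0.7)$discounted_cost,
    metastatic_cost(p$mix, scaled, p$config, 4.2)$discounted_cost
  )
  expect_equal(up, k * base, tolerance = 1e-12)
})

test_that("discounting strictly lowers multi-year traces", {
  p <- cached_defaults()
  for (tr in list(as_cost(p$as_sched, p$costs, p$config),
                  localized_cost(p$loc_mix, p$costs, p$config),
                  metastatic_cost(p$mix, p$costs, p$config))) {
    expect_lt(tr$discounted_cost, tr$undiscounted_cost)
  }
})

test_that("cohort traces conserve mass each year", {
  p <- cached_defaults()
  for (tr in list(as_cost(p$as_sched, p$costs, p$config),
                  localized_cost(p$loc_mix, p$costs, p$config),
                  metastatic_cost(p$mix, p$costs, p$config))) {
    expect_equal(tr$yearly$active + tr$yearly$exited, rep(1, 6),
                 tolerance = 1e-12)
  }
})
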