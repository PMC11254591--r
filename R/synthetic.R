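#' Calibration targets for the synthetic diagnostic probability tables
#'
#' The published parameter supplement of the underlying cost analysis is not
#' deposited; the packaged diagnostic probability tables are therefore
#' synthesized so that the decision tree reproduces every printed aggregate.
#' Each printed aggregate pins one degree of freedom:
#' per-man diagnostic cost gap and its percentage (pin the two arms' per-man
#' diagnostic costs), the Stockholm3 share of biomarker-arm diagnostic spend
#' (pins the PSA >= 1.5 rate), the PSA-arm metastatic count (pins the biopsy
#' metastatic yield), and the biomarker-arm total and net saving per 1000 men
#' (pin the ISUP 1 and ISUP 2-5 detection counts). The SWOP pathway is pinned
#' by its printed total, its diagnostic-cost reduction versus the PSA arm and
#' the false-negative progression fraction.
#'
#' @param diag_cost_gap_per_man biomarker-arm minus PSA-arm diagnostic cost
#'   per man (EUR).
#' @param diag_gap_fraction the gap as a fraction of the PSA-arm per-man
#'   diagnostic cost.
#' @param sthlm3_share_of_diag Stockholm3 share of biomarker-arm diagnostic
#'   spend.
#' @param psa_arm_mpc_per_1000 metastatic presentations per 1000 men tested in
#'   the PSA arm.
#' @param anchors per-state cost anchors ([default_anchors()]).
#' @param sthlm3_total_per_1000 biomarker-arm total 6-year spend per 1000 men.
#' @param net_saving_per_1000 PSA-arm minus biomarker-arm total per 1000 men.
#' @param swop_total_per_1000 SWOP-pathway total spend per 1000 men.
#' @param swop_diag_reduction SWOP diagnostic-cost reduction vs the PSA arm.
#' @param swop_fn_progress fraction of SWOP false-negative clinically
#'   significant cases projected to progress to metastatic disease.
#' @return a list of class `calibration_targets`.
#' @export
calibration_targets <- function(diag_cost_gap_per_man = 151,
                                diag_gap_fraction = 0.42,
                                sthlm3_share_of_diag = 0.35,
                                psa_arm_mpc_per_1000 = 13.0,
                                anchors = default_anchors(),
                                sthlm3_total_per_1000 = 4318000,
                                net_saving_per_1000 = 358239,
                                swop_total_per_1000 = 4787048,
                                swop_diag_reduction = 0.43,
                                swop_fn_progress = 0.10) {
  t <- list(diag_cost_gap_per_man = diag_cost_gap_per_man,
            diag_gap_fraction = diag_gap_fraction,
            sthlm3_share_of_diag = sthlm3_share_of_diag,
            psa_arm_mpc_per_1000 = psa_arm_mpc_per_1000,
            anchors = anchors,
            sthlm3_total_per_1000 = sthlm3_total_per_1000,
            net_saving_per_1000 = net_saving_per_1000,
            swop_total_per_1000 = swop_total_per_1000,
            swop_diag_reduction = swop_diag_reduction,
            swop_fn_progress = swop_fn_progress)
  pos <- c("diag_cost_gap_per_man", "diag_gap_fraction", "sthlm3_share_of_diag",
           "sthlm3_total_per_1000", "swop_total_per_1000")
  for (f in pos) if (t[[f]] <= 0) stop("target ", f, " must be positive", call. = FALSE)
  if (psa_arm_mpc_per_1000 < 0) stop("target psa_arm_mpc_per_1000 must be >= 0", call. = FALSE)
  if (any(anchors <= 0)) stop("anchors must be positive", call. = FALSE)
  structure(t, class = "calibration_targets")
}

#' Generate calibrated diagnostic probability tables
#'
#' Deterministically solves the branch probabilities of the three diagnostic
#' pathways so that the decision tree reproduces the calibration targets
#' exactly (see [calibration_targets()]). Two structural rates are not pinned
#' by any printed aggregate and are fixed at field-realistic defaults: the
#' PSA >= 3 positivity among opportunistically tested men and the
#' biomarker-arm MRI referral rate; the SWOP pathway additionally fixes its
#' ISUP 1 detection fraction and benign-biopsy volume.
#'
#' @param targets a [calibration_targets()].
#' @param costs a [cost_table()].
#' @param migration a [migration_factors()].
#' @param structural structural rates: `p_psa_ge_3`, `sthlm3_mri_rate`
#'   (fraction of all tested men reaching MRI in the biomarker arm),
#'   `swop_isup1_detection`, `swop_benign_biopsies` (per 1000).
#' @param seed unused for the deterministic defaults; accepted for interface
#'   symmetry with the random generators.
#' @param strategies which pathways to solve; the SWOP solve is only feasible
#'   for target sets whose SWOP aggregates are mutually consistent.
#' @return named list of [diag_prob_table()]s: `psa_mri`, `sthlm3_reflex`,
#'   and (when requested) `swop`.
#' @export
generate_diag_prob_table <- function(targets = calibration_targets(),
                                     costs = default_costs(),
                                     migration = migration_factors(),
                                     structural = list(p_psa_ge_3 = 0.30,
                                                      sthlm3_mri_rate = 0.25,
                                                      swop_isup1_detection = 0.30,
                                                      swop_benign_biopsies = 10),
                                     seed = NULL,
                                     strategies = c("psa_mri", "sthlm3_reflex",
                                                    "swop")) {
  cascade <- benign_cost(costs)
  comp <- targets$anchors[c("isup1", "isup2_5", "metastatic")] - cascade
  if (any(comp <= 0)) {
    stop("infeasible targets: state anchors must exceed the diagnostic cascade",
         call. = FALSE)
  }
  c_psa <- cost_of(costs, "psa_test"); c_s3 <- cost_of(costs, "stockholm3")
  c_mri <- cost_of(costs, "mri"); c_bx <- cost_of(costs, "biopsy")
  c_trus <- cost_of(costs, "trus")

  gap <- targets$diag_cost_gap_per_man
  d_psa <- gap / targets$diag_gap_fraction     # PSA-arm diagnostic cost per man
  d_s3 <- d_psa + gap
  t_psa <- targets$sthlm3_total_per_1000 + targets$net_saving_per_1000
  m <- targets$psa_arm_mpc_per_1000
  f <- unclass(migration)

  # counts i1 (ISUP 1), i2 (ISUP 2-5) per 1000 in the PSA arm, solved from the
  # printed net saving and the PSA-arm total:
  #   saving = -1000*gap + C1*(1-f1)*i1 - C2*(f2-1)*i2 + C3*(1-fm)*m
  #   total  = 1000*d_psa + C1*i1 + C2*i2 + C3*m
  A <- rbind(c(comp[["isup1"]] * (1 - f[["isup1"]]),
               -comp[["isup2_5"]] * (f[["isup2_5"]] - 1)),
             c(comp[["isup1"]], comp[["isup2_5"]]))
  b <- c(targets$net_saving_per_1000 + 1000 * gap -
           comp[["metastatic"]] * (1 - f[["metastatic"]]) * m,
         t_psa - 1000 * d_psa - comp[["metastatic"]] * m)
  counts <- drop(solve(A, b))
  i1 <- counts[1L]; i2 <- counts[2L]
  if (i1 < 0 || i2 < 0) {
    stop("infeasible target combination: implied detection counts are negative (",
         sprintf("isup1 = %.2f, isup2_5 = %.2f", i1, i2), ")", call. = FALSE)
  }

  # --- PSA pathway ---------------------------------------------------------
  q3 <- structural$p_psa_ge_3
  r_psa <- (d_psa - c_psa - q3 * c_mri) / (c_bx * q3)
  check_prob(r_psa, "implied PSA-arm PI-RADS positivity")
  b_psa <- 1000 * q3 * r_psa                       # biopsies per 1000
  cancers_psa <- i1 + i2 + m
  if (cancers_psa > b_psa) {
    stop(sprintf(
      "infeasible targets: %.1f cancers per 1000 exceed %.1f biopsies in the PSA arm",
      cancers_psa, b_psa), call. = FALSE)
  }
  out_psa <- c(benign = (b_psa - cancers_psa) / b_psa,
               isup1 = i1 / b_psa, isup2_5 = i2 / b_psa, metastatic = m / b_psa)

  # --- Stockholm3 reflex pathway ------------------------------------------
  q15 <- targets$sthlm3_share_of_diag * d_s3 / c_s3   # P(PSA >= 1.5)
  check_prob(q15, "implied PSA >= 1.5 rate")
  if (q15 < q3) {
    stop("infeasible targets: implied PSA >= 1.5 rate below the PSA >= 3 rate",
         call. = FALSE)
  }
  rho <- structural$sthlm3_mri_rate                    # P(MRI) among all tested
  s3_pos <- rho / q15
  check_prob(s3_pos, "implied Stockholm3 positivity")
  r_s3 <- ((d_s3 - c_psa - q15 * c_s3) / rho - c_mri) / c_bx
  check_prob(r_s3, "implied biomarker-arm PI-RADS positivity")
  b_s3 <- 1000 * rho * r_s3
  mig_counts <- c(isup1 = f[["isup1"]] * i1, isup2_5 = f[["isup2_5"]] * i2,
                  metastatic = f[["metastatic"]] * m)
  if (sum(mig_counts) > b_s3) {
    stop("infeasible targets: migrated cancer counts exceed biomarker-arm biopsies",
         call. = FALSE)
  }
  out_s3 <- c(benign = (b_s3 - sum(mig_counts)) / b_s3, mig_counts / b_s3)
  names(out_s3) <- c("benign", "isup1", "isup2_5", "metastatic")

  out <- list(
    psa_mri = diag_prob_table("psa_mri", p_psa_ge_3 = q3, p_psa_ge_1_5 = q15,
                              p_pirads_pos = r_psa, biopsy_outcome = out_psa),
    sthlm3_reflex = diag_prob_table("sthlm3_reflex", p_psa_ge_3 = q3,
                                    p_psa_ge_1_5 = q15, p_sthlm3_pos = s3_pos,
                                    p_pirads_pos = r_s3, biopsy_outcome = out_s3)
  )
  if (!"swop" %in% strategies) {
    return(out[intersect(strategies, names(out))])
  }

  # --- SWOP risk-calculator pathway ---------------------------------------
  d_sw <- d_psa * (1 - targets$swop_diag_reduction)
  a1 <- structural$swop_isup1_detection
  b0 <- structural$swop_benign_biopsies
  fnp <- targets$swop_fn_progress
  fn <- (targets$swop_total_per_1000 - 1000 * d_sw -
           comp[["isup1"]] * a1 * i1 - comp[["isup2_5"]] * i2 -
           comp[["metastatic"]] * m) /
    (fnp * (comp[["metastatic"]] - comp[["isup2_5"]]))
  if (fn < 0 || fn > i2) {
    stop(sprintf(
      "infeasible SWOP targets: implied false-negative count %.2f outside [0, %.2f]",
      fn, i2), call. = FALSE)
  }
  i2_det <- i2 - fn
  b_sw <- m + a1 * i1 + i2_det + b0
  m_sw <- (1000 * d_sw - 1000 * c_psa - 1000 * q3 * c_trus - b_sw * c_bx) / c_mri
  if (m_sw < b_sw) {
    stop("infeasible SWOP targets: implied MRI volume below biopsy volume",
         call. = FALSE)
  }
  h_sw <- m_sw / (1000 * q3)
  check_prob(h_sw, "implied SWOP high-risk fraction")
  r_sw <- b_sw / m_sw
  out_sw <- c(benign = b0, isup1 = a1 * i1, isup2_5 = i2_det, metastatic = m) / b_sw

  out$swop <- diag_prob_table("swop", p_psa_ge_3 = q3, p_psa_ge_1_5 = q15,
                              p_high_risk = h_sw, p_pirads_pos = r_sw,
                              biopsy_outcome = out_sw,
                              fn_cs_per_1000 = fn, fn_progress = fnp)
  out[intersect(strategies, names(out))]
}

#' @keywords internal
check_prob <- function(p, what) {
  if (!is.finite(p) || p < 0 || p > 1) {
    stop("infeasible target combination: ", what,
         sprintf(" = %.4f outside [0,1]", p), call. = FALSE)
  }
  invisible(p)
}

#' Draw a random valid parameter set
#'
#' Uniformly perturbs the packaged defaults within the given relative ranges,
#' preserving all structural invariants (nested PSA thresholds, outcome
#' distributions summing to one, mix fractions in \[0,1\]). Used for
#' property-based fuzzing; every draw passes [validate_parameters()].
#'
#' @param seed integer seed.
#' @param cost_range relative unit-cost range (uniform multiplier).
#' @param prob_jitter absolute half-width of branch-probability perturbations.
#' @return a validated [parameter_set()].
#' @export
random_parameter_set <- function(seed, cost_range = c(0.5, 1.5),
                                 prob_jitter = 0.15) {
  set.seed(seed)
  base <- default_costs()
  mult <- stats::runif(nrow(base), cost_range[1L], cost_range[2L])
  costs <- cost_table(stats::setNames(base$unit_cost * mult, base$item),
                      stats::setNames(base$sd, base$item),
                      stats::setNames(base$basis, base$item))
  jit <- function(p, lo = 0, hi = 1) {
    if (is.na(p)) return(p)
    min(max(p + stats::runif(1, -prob_jitter, prob_jitter), lo), hi)
  }
  rand_outcome <- function() {
    w <- stats::rgamma(4, shape = c(6, 2, 4, 1))
    stats::setNames(w / sum(w), c("benign", "isup1", "isup2_5", "metastatic"))
  }
  q3 <- stats::runif(1, 0.10, 0.50)
  q15 <- min(q3 + stats::runif(1, 0.05, 0.35), 1)
  strategies <- list(
    psa_mri = diag_prob_table("psa_mri", p_psa_ge_3 = q3, p_psa_ge_1_5 = q15,
                              p_pirads_pos = stats::runif(1, 0.2, 0.8),
                              biopsy_outcome = rand_outcome()),
    sthlm3_reflex = diag_prob_table("sthlm3_reflex", p_psa_ge_3 = q3,
                                    p_psa_ge_1_5 = q15,
                                    p_sthlm3_pos = stats::runif(1, 0.2, 0.8),
                                    p_pirads_pos = stats::runif(1, 0.2, 0.8),
                                    biopsy_outcome = rand_outcome()),
    swop = diag_prob_table("swop", p_psa_ge_3 = q3, p_psa_ge_1_5 = q15,
                           p_high_risk = stats::runif(1, 0.2, 0.9),
                           p_pirads_pos = stats::runif(1, 0.2, 0.8),
                           biopsy_outcome = rand_outcome(),
                           fn_cs_per_1000 = stats::runif(1, 0, 20),
                           fn_progress = stats::runif(1, 0, 0.5))
  )
  arpi <- jit(0.80, 0.05, 0.95)
  mix <- treatment_mix(
    arpi_fraction = arpi, taxane_only_fraction = 1 - arpi,
    triplet_given_arpi_fraction = jit(0.25),
    parp_fraction = jit(0.09), immune_fraction = jit(0.01, 0, 0.2),
    radiopharm_fraction = jit(0.30), radiopharm_lu_split = jit(0.50),
    osteoprotective_fraction = jit(0.33),
    palliative_fraction = jit(0.50), eol_fraction = jit(0.35),
    discontinuation_year1 = jit(0.30, 0, 0.5),
    discontinuation_increment = jit(0.10, 0, 0.14)
  )
  parameter_set(costs = costs, strategies = strategies, mix = mix)
}

#' Generate an individual-level synthetic cohort
#'
#' Draws each man's disease state from a state distribution (multinomial) and
#' realizes his 6-year discounted cost from the state model's event schedules
#' (progression, line assignment, discontinuation) under the given parameter
#' set. Diagnostic spend is the full cascade for biopsied states and the PSA
#' test alone for men without workup. Bitwise reproducible under `seed`.
#'
#' @param dist a `state_distribution`.
#' @param n cohort size (>= 1).
#' @param seed integer seed.
#' @param params a [parameter_set()]; defaults to the packaged calibrated set.
#' @return a data frame of class `synthetic_cohort` with columns `id`,
#'   `state`, `cost`, and attribute `seed`.
#' @export
generate_cohort <- function(dist, n, seed, params = default_parameters()) {
  if (n < 1) stop("cohort size n must be >= 1", call. = FALSE)
  set.seed(seed)
  probs <- as.numeric(dist) / sum(dist)
  state <- sample(STATE_NAMES, n, replace = TRUE, prob = probs)
  cascade <- benign_cost(params$costs)
  cost <- numeric(n)
  cost[state == "no_workup"] <- cost_of(params$costs, "psa_test")
  cost[state == "benign"] <- cascade
  for (s in DISEASE_STATES) {
    idx <- which(state == s)
    if (length(idx) > 0L) {
      cost[idx] <- cascade + simulate_state_component(s, length(idx), params)
    }
  }
  out <- data.frame(id = seq_len(n), state = state, cost = cost,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  class(out) <- c("synthetic_cohort", class(out))
  out
}
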