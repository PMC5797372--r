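test_that("a zero-reduction arm is identical to placebo", {
  spec <- trial_spec(
    arms = list(placebo = NULL, sham = intervention("sham", 0, 0)),
    cohort = data.frame(patient_id = "P1", genotype = "APOE4+/-", x = 4, y = 4))
  res <- simulate_trial(spec, sp_cal, rp_def)
  pl <- res$trajectories[res$trajectories$arm == "placebo", ]
  sh <- res$trajectories[res$trajectories$arm == "sham", ]
  expect_identical(pl$adas, sh$adas)
  expect_identical(pl$load_x, sh$load_x)
})

test_that("the low-dose BACE-I worked case lands at effective load (4.2, 4.4)", {
  spec <- trial_spec(
    arms = list(placebo = NULL, bace_low = intervention_library()$bace_low),
    cohort = data.frame(patient_id = "P1", genotype = "APOE4+/-", x = 4, y = 4),
    eval_weeks = c(0, 13))
  rec <- simulate_patient(spec$cohort, "bace_low", spec, sp_cal, rp_def)
  expect_equal(rec$load_x[rec$week == 13], 4.2)
  expect_equal(rec$load_y[rec$week == 13], 4.4)
  # ... and its matrix sample equals the quadrature applied at the placebo
  # destination window {4, 5, 6}
  m <- build_effect_matrix(cp_final)
  s <- sample_matrix_average(m, abeta_load(4.2, 4.4), anchor_x = 5, anchor_y = 5)
  qx <- quadrature_weights(4.2, 5); qy <- quadrature_weights(4.4, 5)
  manual <- 0
  for (i in 1:3) for (j in 1:3) {
    manual <- manual + qx$weights[i] * qy$weights[j] *
      glu_conductance_factor(abeta_load(qx$support[i], qy$support[j]), cp_final)
  }
  expect_equal(s$g_ratio, manual, tolerance = 1e-12)
})

test_that("trial simulation is deterministic and needs a placebo arm", {
  spec <- trial_spec(cohort = cohort_spec(6, fixed_baseline(8, 8)), seed = 7)
  r1 <- simulate_trial(spec, sp_cal, rp_def)
  r2 <- simulate_trial(spec, sp_cal, rp_def)
  expect_identical(r1$trajectories, r2$trajectories)
  expect_identical(r1$summary, r2$summary)
  expect_error(trial_spec(arms = list(a = intervention("a", 0.5, 0.5))),
               "placebo")
})

test_that("all-placebo arms give zero contrasts", {
  spec <- trial_spec(arms = list(placebo = NULL, placebo2 = NULL),
                     cohort = cohort_spec(4, fixed_baseline(6, 6)), seed = 3)
  res <- simulate_trial(spec, sp_cal, rp_def)
  expect_true(all(abs(res$summary$benefit) < 1e-12))
})

test_that("placebo ADAS trajectories never improve with time", {
  for (g in apoe_genotypes()) for (x in c(0, 4, 9)) {
    spec <- trial_spec(arms = list(placebo = NULL),
                       cohort = data.frame(patient_id = "P1", genotype = g,
                                           x = x, y = x))
    res <- suppressWarnings(simulate_trial(spec, sp_cal, rp_def))
    expect_true(all(diff(res$trajectories$adas) >= -1e-9),
                label = paste(g, x))
  }
})

test_that("MCI region averages respect the amyloid orderings", {
  m <- mci_region_averages(cp_calib, 3, sp_cal, rp_def)
  expect_gt(m[["pos"]], m[["neg"]])
  # any parameter set with alpha* > 0 leaves Ab+ worse than Ab-
  set.seed(7)
  for (i in 1:5) {
    cpp <- coupling_params(2, runif(1, 0, 0.03), runif(1, 0, 0.0025),
                           runif(1, 1e-4, 0.0025), runif(1, 0.005, 0.035))
    m <- mci_region_averages(cpp, 3, sp_cal, rp_def)
    expect_gt(m[["pos"]], m[["neg"]])
  }
  # without the Ab40 benefit, Ab+ MCI cognition collapses (about 14 ADAS
  # points at a 2-unit cutoff)
  m <- mci_region_averages(coupling_params(2, 0, 0.0015, 0.00035, 0.025), 2,
                           sp_cal, rp_def)
  expect_gte(m[["pos"]], 13)
})

test_that("SUVR calibration is linear, anchored and invertible", {
  expect_equal(units_to_suvr(0), 1.0)
  expect_equal(units_to_suvr(3), 1.34)
  u <- seq(0, 16, by = 0.5)
  expect_equal(suvr_to_units(units_to_suvr(u)), u, tolerance = 1e-12)
  expect_error(units_to_suvr(17), "\\[0, 16\\]")
  expect_error(suvr_to_units(0.9), "intercept")
})

test_that("APOE mainly shifts the baseline, not the progression slope", {
  ap <- apoe_slope_analysis(params = sp_cal, receptor = rp_def)
  expect_lte(ap$max_rel_spread, 0.10)
  expect_gte(ap$week0_gap, 1.5)
  expect_true(all(ap$table$slope > 0))
})

test_that("matrix sampling in the engine matches brute-force re-evaluation", {
  m <- build_effect_matrix(cp_final)
  set.seed(99)
  for (i in 1:100) {
    L <- abeta_load(runif(1, 1, 15), runif(1, 1, 15))
    ax <- min(max(round(L$x) + sample(-1:1, 1), 1), 15)
    ay <- min(max(round(L$y) + sample(-1:1, 1), 1), 15)
    s <- sample_matrix_average(m, L, ax, ay)
    qx <- quadrature_weights(L$x, ax); qy <- quadrature_weights(L$y, ay)
    g <- a7 <- 0
    for (ii in 1:3) for (jj in 1:3) {
      w <- qx$weights[ii] * qy$weights[jj]
      cell <- m$grid[m$grid$x == qx$support[ii] & m$grid$y == qy$support[jj], ]
      g <- g + w * cell$g_ratio
      a7 <- a7 + w * cell$a7_factor
    }
    expect_equal(s$g_ratio, g, tolerance = 1e-12)
    expect_equal(s$a7_factor, a7, tolerance = 1e-12)
  }
})

test_that("high-baseline cohorts benefit from all interventions, in order", {
  lib <- intervention_library()
  spec <- trial_spec(arms = c(list(placebo = NULL), lib),
                     cohort = data.frame(patient_id = "P1",
                                         genotype = "APOE4+/-", x = 8, y = 8))
  res <- simulate_trial(spec, sp_cal, rp_def)
  wk78 <- res$summary[res$summary$week == 78, ]
  ben <- setNames(wk78$benefit, wk78$arm)
  expect_true(all(ben[c("bace_low", "bace_high", "gsi_low", "gsi_high",
                        "sola_low", "sola_high")] > 0))
  expect_gte(ben[["bace_high"]], ben[["gsi_high"]])
  expect_gte(ben[["gsi_high"]], ben[["sola_high"]])
  expect_gte(ben[["bace_low"]], ben[["gsi_low"]])
  expect_gte(ben[["gsi_low"]], ben[["sola_low"]])
  # effects saturate with baseline load
  spec12 <- trial_spec(arms = c(list(placebo = NULL), lib),
                       cohort = data.frame(patient_id = "P1",
                                           genotype = "APOE4+/-", x = 12, y = 12))
  res12 <- suppressWarnings(simulate_trial(spec12, sp_cal, rp_def))
  wk78_12 <- res12$summary[res12$summary$week == 78, ]
  expect_true(all(wk78_12$benefit <= 2.5))
})
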