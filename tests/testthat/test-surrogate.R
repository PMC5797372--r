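test_that("recalibration reproduces the shipped parameter file", {
  sp_refit <- calibrate_surrogate()
  for (nm in names(unclass(sp_cal))) {
    expect_equal(unlist(sp_refit[[nm]]), unlist(sp_cal[[nm]]),
                 tolerance = 1e-6, label = nm)
  }
  # and a second refit is bit-identical (deterministic optimiser)
  sp_refit2 <- calibrate_surrogate()
  expect_identical(unclass(sp_refit)[], unclass(sp_refit2)[])
})

test_that("link outputs respect the instrument ranges and monotonicity", {
  r <- seq(-500, 500, length.out = 401)
  a <- adas_from_reserve(r, sp_cal)
  expect_true(all(a >= 0 & a <= 70))
  expect_true(all(diff(a) <= 0))  # monotone decreasing in reserve
  acc <- accuracy_from_reserve(r, sp_cal)
  expect_true(all(acc >= 0 & acc <= 100))
  expect_true(all(diff(acc) >= 0))
})

test_that("healthy and MCI zero-amyloid anchors are reproduced", {
  expect_equal(adas_from_reserve(100, sp_cal), 4.5, tolerance = 1e-6)
  st <- disease_state("MCI", 0, "APOE4+/-", sp_cal)
  adas_mci0 <- adas_from_reserve(network_reserve(st, 1, 1, 0, sp_cal, rp_def),
                                 sp_cal)
  expect_equal(adas_mci0, 4.1, tolerance = 0.1)
})

test_that("increasing any deficit never improves ADAS-Cog", {
  st <- disease_state("MCI", 0, "APOE4+/-", sp_cal)
  base <- adas_from_reserve(network_reserve(st, 1, 1, 0, sp_cal, rp_def), sp_cal)
  worse_glu <- adas_from_reserve(network_reserve(st, 0.98, 1, 0, sp_cal, rp_def),
                                 sp_cal)
  worse_a7 <- adas_from_reserve(network_reserve(st, 1, 0.8, 0, sp_cal, rp_def),
                                sp_cal)
  expect_gte(worse_glu, base)
  expect_gte(worse_a7, base)
  # and along a fine ladder of alpha7 loss
  a7s <- seq(1, 0, by = -0.05)
  adas <- adas_from_reserve(network_reserve(st, 1, a7s, 0, sp_cal, rp_def),
                            sp_cal)
  expect_true(all(diff(adas) >= -1e-9))
})

test_that("accuracy sensitivity peaks at intermediate impairment", {
  d_acc <- function(res) {
    (accuracy_from_reserve(res + 0.5, sp_cal) -
       accuracy_from_reserve(res - 0.5, sp_cal))
  }
  mid <- sp_cal$Ra50
  expect_gt(d_acc(mid), d_acc(mid + 40))   # mild impairment: flatter
  expect_gt(d_acc(mid), d_acc(mid - 40))   # severe impairment: flatter
})

test_that("disease states carry the stated progressive losses", {
  st0 <- disease_state("AD", 0, "APOE4+/-", sp_cal)
  st78 <- disease_state("AD", 78, "APOE4+/-", sp_cal)
  expect_equal(100 * (st0$synapse_density - st78$synapse_density), 0.04 * 78,
               tolerance = 1e-9)
  expect_equal(100 * (st0$neuron_density - st78$neuron_density), 0.35 * 78,
               tolerance = 1e-9)
  expect_equal(st0$cholinergic_tone, 0.7)
  mci <- disease_state("MCI", 0, "APOE4+/-", sp_cal)
  expect_equal(mci$synapse_density, 0.97)
  expect_equal(mci$cholinergic_tone, 1.3)
  pp <- disease_state("AD", 0, "APOE4+/+", sp_cal)
  mm <- disease_state("AD", 0, "APOE4-/-", sp_cal)
  expect_equal(pp$synapse_density / mm$synapse_density, 0.8 / 1.2)
  expect_error(disease_state("AD", -1), "non-negative")
})

test_that("glutamate-slope anchors and their week profile are reproduced", {
  expect_equal(glu_slope(12, params = sp_cal), 0.65, tolerance = 0.1)
  expect_equal(glu_slope(26, params = sp_cal), 0.65, tolerance = 0.1)
  expect_equal(glu_slope(52, params = sp_cal), 0.40, tolerance = 0.1)
  expect_equal(glu_slope(78, params = sp_cal), 0.40, tolerance = 0.1)
  s0 <- glu_slope(0, params = sp_cal)
  expect_gt(s0, glu_slope(78, params = sp_cal))
  expect_lt(s0, glu_slope(12, params = sp_cal))
})

test_that("AD baselines sit in the 20-22 band with APOE4+/+ worst", {
  ap <- apoe_slope_analysis(params = sp_cal, receptor = rp_def)
  expect_true(all(ap$table$adas_week0 >= 19.5 & ap$table$adas_week0 <= 22.5))
  expect_equal(which.max(ap$table$adas_week0),
               which(ap$table$genotype == "APOE4+/+"))
  expect_gte(ap$week0_gap, 1.5)
})
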