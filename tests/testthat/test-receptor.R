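test_that("muscarinic competition follows the equilibrium binding law", {
  p <- rp_def
  expect_equal(muscarinic_activation(0, 5, "M1", p), 0)
  expect_equal(muscarinic_activation(p$K_ACh_M1, 0, "M1", p), 0.5)
  # scopolamine at its Ki doubles the apparent K: ach/(ach + 2K)
  expect_equal(muscarinic_activation(p$K_ACh_M1, p$Ki_M1, "M1", p), 1 / 3)
  expect_equal(muscarinic_activation(p$K_ACh_M2, p$Ki_M2, "M2", p), 1 / 3)
  expect_error(muscarinic_activation(-1, 0, "M1", p), "non-negative")
})

test_that("M2-autoreceptor feedback elevates ACh between 1 and 1 + gamma", {
  p <- rp_def
  expect_equal(ach_level_with_m2_feedback(0, 1, p), 1)
  expect_equal(ach_level_with_m2_feedback(1e9, 1, p), 1 + p$gamma,
               tolerance = 1e-6)
  p0 <- receptor_params(gamma = 0)
  expect_equal(ach_level_with_m2_feedback(7, 1, p0), 1)
  doses <- seq(0, 20, by = 0.5)
  expect_true(all(diff(ach_level_with_m2_feedback(doses, 1.3, p)) > 0))
})

test_that("nicotinic activation saturates in ACh and is gated by amyloid", {
  p <- rp_def
  n <- nicotinic_activation(1, a7_factor = 0, p)
  expect_equal(n$act_a7, 0)
  n <- nicotinic_activation(p$K_a7 / p$ach_base, a7_factor = 1, p)
  expect_equal(n$act_a7, 0.5)
  n1 <- nicotinic_activation(1, 0.7, p)
  n2 <- nicotinic_activation(2, 0.7, p)
  expect_gte(n2$act_a7, n1$act_a7)
  expect_gte(n2$act_a4b2, n1$act_a4b2)
  expect_true(all(unlist(n2) >= 0 & unlist(n2) <= 1))
  expect_error(nicotinic_activation(0, 1, p), "> 0")
})

test_that("scopolamine dose-response curves are monotone with zero-dose baselines", {
  dr <- scopolamine_dose_response(coupling = cp_final, params = sp_cal,
                                  receptor = rp_def)
  for (reg in c("neg", "pos")) {
    acc <- dr$curve$accuracy[dr$curve$region == reg]
    expect_true(all(diff(acc) <= 1e-9))
    expect_true(acc[1] > 0 && acc[1] < 100)  # finite baseline below ceiling
  }
  # the zero-dose point equals the no-drug evaluation
  dr0 <- scopolamine_dose_response(doses = 0, coupling = cp_final,
                                   params = sp_cal, receptor = rp_def)
  expect_equal(dr0$curve$accuracy,
               dr$curve$accuracy[dr$curve$dose == 0])
})

test_that("amyloid-positive MCI subjects are the more scopolamine-sensitive", {
  dr <- scopolamine_dose_response(coupling = cp_final, params = sp_cal,
                                  receptor = rp_def)
  expect_gt(abs(dr$slopes[["pos"]]), abs(dr$slopes[["neg"]]))
  # calibrated magnitudes near the published -1.08 / -1.36 %/nM pair
  expect_lt(abs(dr$slopes[["neg"]] - (-1.08)), 0.3)
  expect_lt(abs(dr$slopes[["pos"]] - (-1.36)), 0.3)
})

test_that("removing the Ab40 benefit reverses the sensitivity ordering", {
  dr <- scopolamine_dose_response(
    coupling = coupling_params(x0 = 2, delta = 0, alpha = 0.002,
                               alpha_star = 0.002, beta = 0.03),
    params = sp_cal, receptor = rp_def)
  expect_gt(abs(dr$slopes[["neg"]]), abs(dr$slopes[["pos"]]))
})

test_that("cholinergic state percent deviations vanish at the reference", {
  cs <- cholinergic_state(1, 0, rp_def)
  expect_equal(cs$m1_pct, 0)
  expect_equal(cs$gaba_pct, 0)
  expect_equal(cs$a7_ach_pct, 0)
  cs <- cholinergic_state(1.3, 0, rp_def)
  expect_gt(cs$m1_pct, 0)
  cs <- cholinergic_state(0.7, 0, rp_def)
  expect_lt(cs$m1_pct, 0)
})
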