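test_that("deposition rates follow genotype and biomarker reduction", {
  lib <- intervention_library()
  r <- deposition_rate("APOE4+/-", NULL)
  expect_equal(c(r$rate_x, r$rate_y), c(1, 1))
  r <- deposition_rate("APOE4+/-", lib$gsi_low)
  expect_equal(c(r$rate_x, r$rate_y), c(0.6, 0.8))
  r <- deposition_rate("APOE4+/+", NULL)
  expect_equal(c(r$rate_x, r$rate_y), c(1.5, 1.5))
  r <- deposition_rate("APOE4-/-", NULL)
  expect_equal(c(r$rate_x, r$rate_y), c(0.5, 0.5))
  r <- deposition_rate("APOE4+/-", lib$bace_high)
  expect_equal(c(r$rate_x, r$rate_y), c(0.1, 0.2))
  expect_error(intervention("x", 1.2, 0.5), "\\[0, 1\\]")
  expect_error(deposition_rate("APOE5"), "genotype")
})

test_that("load trajectories grow linearly and clamp at the grid ceiling", {
  tr <- load_trajectory(abeta_load(4, 4), deposition_rate("APOE4+/-"), 13)
  expect_equal(c(tr$x, tr$y), c(5, 5))
  tr <- load_trajectory(abeta_load(4, 4), deposition_rate("APOE4+/+"), 78)
  expect_equal(c(tr$x, tr$y), c(13, 13))
  zero <- deposition_rate("APOE4+/-", intervention("none", 1, 1))
  tr <- load_trajectory(abeta_load(4, 4), zero, c(0, 26, 78))
  expect_equal(tr$x, rep(4, 3))
  expect_warning(load_trajectory(abeta_load(12, 12), deposition_rate("APOE4+/-"),
                                 c(0, 78)), "clamp")
  expect_error(load_trajectory(abeta_load(4, 4), deposition_rate("APOE4+/-"),
                               c(26, 13)), "ascending")
})

test_that("quadrature weights reproduce the published worked cases", {
  q <- quadrature_weights(5)
  expect_equal(q$support, 4:6)
  expect_equal(q$weights, rep(1 / 3, 3))
  # low-dose BACE-I Ab40: effective load 4.2 against the placebo window
  q <- quadrature_weights(4.2, anchor = 5)
  expect_equal(q$support, 4:6)
  expect_equal(q$weights, c(0.7 + 1 / 30, 1 / 3, -0.2 + 2 / 15),
               tolerance = 1e-12)
  expect_equal(round(q$weights, 2), c(0.73, 0.33, -0.07))
  # Ab42 counterpart: effective load 4.4
  q <- quadrature_weights(4.4, anchor = 5)
  expect_equal(q$weights, c(0.6 + 1 / 30, 1 / 3, 1 / 30), tolerance = 1e-12)
  expect_equal(round(q$weights, 2), c(0.63, 0.33, 0.03))
  # integer load: equal thirds on the centred window
  q <- quadrature_weights(7)
  expect_equal(q$weights, rep(1 / 3, 3))
})

test_that("quadrature weights satisfy the mass constraints everywhere", {
  set.seed(42)
  loads <- runif(1000, 0, 16)
  for (L in loads) {
    q <- quadrature_weights(L)
    expect_equal(sum(q$weights), 1, tolerance = 1e-12)
    expect_equal(sum(q$weights * q$support), L, tolerance = 1e-12)
    expect_equal(q$weights[2], 1 / 3, tolerance = 1e-12)
  }
  # edge handling shifts the support inward but keeps the constraints
  for (L in c(0, 0.3, 15.8, 16)) {
    q <- quadrature_weights(L)
    expect_true(all(q$support >= 0 & q$support <= 16))
    expect_equal(sum(q$weights * q$support), L, tolerance = 1e-12)
  }
  expect_error(quadrature_weights(17), "\\[0, 16\\]")
})

test_that("matrix sampling is a weighted 3x3 block average", {
  m <- build_effect_matrix(cp_final)
  # at an integer load the sample is the plain mean of the 3x3 block
  s <- sample_matrix_average(m, abeta_load(4, 4))
  block <- m$grid[m$grid$x %in% 3:5 & m$grid$y %in% 3:5, ]
  expect_equal(s$g_ratio, mean(block$g_ratio), tolerance = 1e-12)
  expect_equal(s$a7_factor, mean(block$a7_factor), tolerance = 1e-12)
  # constant-valued function passes through unchanged
  expect_equal(sample_matrix_average(function(x, y) rep(3.7, length(x)),
                                     abeta_load(2.6, 9.1)), 3.7,
               tolerance = 1e-12)
})

test_that("matrix sampling reproduces affine functions exactly", {
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(3)
    f <- function(x, y) a[1] + a[2] * x + a[3] * y
    L <- abeta_load(runif(1, 1, 15), runif(1, 1, 15))
    expect_equal(sample_matrix_average(f, L), f(L$x, L$y), tolerance = 1e-10)
    # also with an off-centre (placebo-destination) anchor
    ax <- min(max(round(L$x) + sample(-1:1, 1), 1), 15)
    ay <- min(max(round(L$y) + sample(-1:1, 1), 1), 15)
    expect_equal(sample_matrix_average(f, L, ax, ay), f(L$x, L$y),
                 tolerance = 1e-10)
  }
})
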