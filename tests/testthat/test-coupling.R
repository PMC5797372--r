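test_that("NMDA conductance coupling reproduces hand-computed values", {
  expect_equal(glu_conductance_factor(abeta_load(0, 0), cp_final), 1.0)
  expect_equal(glu_conductance_factor(abeta_load(2, 0),
                                      coupling_params(x0 = 2, delta = 0.025)),
               1.025)
  expect_equal(glu_conductance_factor(abeta_load(4, 4), cp_final), 1.013)
  expect_equal(glu_conductance_factor(
    abeta_load(1, 16),
    coupling_params(x0 = 2, delta = 0.015, alpha_star = 0.00035)), 1.0019)
})

test_that("a peak position of zero uses the declining branch exclusively", {
  p <- coupling_params(x0 = 0, delta = 0.02, alpha = 0.002, alpha_star = 0)
  # 1 + delta + (0 - 1) * alpha, no division by x0
  expect_equal(glu_conductance_factor(abeta_load(1, 0), p), 1.018)
  expect_equal(glu_conductance_factor(abeta_load(0, 0), p), 1.02)
})

test_that("alpha7 activation factor is the floored linear law", {
  expect_equal(a7_activation_factor(abeta_load(0, 0), cp_final), 1.0)
  expect_equal(a7_activation_factor(abeta_load(16, 16),
                                    coupling_params(beta = 0.025)), 0.2)
  expect_equal(a7_activation_factor(abeta_load(16, 16),
                                    coupling_params(beta = 0.04)), 0.0)
})

test_that("out-of-bounds loads and bad parameters are rejected", {
  expect_error(abeta_load(-1, 0), "bounds")
  expect_error(abeta_load(4, 17), "bounds")
  expect_error(coupling_params(beta = -0.01), "non-negative")
  expect_error(coupling_params(x0 = 20), "\\[0, 16\\]")
})

test_that("effect matrix has 289 cells matching the point operations", {
  m <- build_effect_matrix(cp_final)
  expect_equal(nrow(m$grid), 289)
  c00 <- m$grid[m$grid$x == 0 & m$grid$y == 0, ]
  expect_equal(c00$g_ratio, 1.0)
  expect_equal(c00$a7_factor, 1.0)
  c44 <- m$grid[m$grid$x == 4 & m$grid$y == 4, ]
  expect_equal(c44$g_ratio, 1.013)
  expect_equal(c44$a7_factor, 0.76)
  m2 <- build_effect_matrix(coupling_params(x0 = 2, delta = 0.025,
                                            alpha = 0.002, alpha_star = 0.002,
                                            beta = 0.025))
  expect_equal(m2$grid$a7_factor[m2$grid$x == 4 & m2$grid$y == 4], 0.8)
})

test_that("matrix evaluation equals brute-force cell enumeration", {
  for (p in list(cp_final, cp_calib,
                 coupling_params(x0 = 4, delta = 0.01, alpha = 0.001,
                                 alpha_star = 0.0025, beta = 0.035))) {
    m <- build_effect_matrix(p)$grid
    b <- brute_effect_matrix(p)
    m <- m[order(m$y, m$x), ]
    expect_equal(m$g_ratio, b$g, tolerance = 1e-12)
    expect_equal(m$a7_factor, b$a7, tolerance = 1e-12)
  }
})

test_that("conductance is biphasic in Ab40 and monotone in Ab42", {
  m <- build_effect_matrix(cp_final)$grid
  for (yy in 0:16) {
    col <- m[m$y == yy, ]
    col <- col[order(col$x), ]
    rising <- col$g_ratio[col$x <= cp_final$x0]
    falling <- col$g_ratio[col$x >= cp_final$x0]
    expect_true(all(diff(rising) > 0))   # delta > 0
    expect_true(all(diff(falling) < 0))  # alpha > 0
  }
  for (xx in 0:16) {
    row <- m[m$x == xx, ]
    expect_true(all(diff(row$g_ratio[order(row$y)]) < 0))  # alpha* > 0
  }
  # a7 non-increasing along x + y, within [0, 1]
  expect_true(all(m$a7_factor >= 0 & m$a7_factor <= 1))
  s <- tapply(m$a7_factor, m$x + m$y, mean)
  expect_true(all(diff(s) <= 1e-12))
})

test_that("with no Ab40 benefit the conductance never exceeds baseline", {
  m <- build_effect_matrix(coupling_params(x0 = 2, delta = 0, alpha = 0.0015,
                                           alpha_star = 0.00035,
                                           beta = 0.025))$grid
  expect_equal(max(m$g_ratio), 1.0)
  expect_true(all(m$y[m$g_ratio == 1.0] == 0))
})

test_that("region partition counts and modes are exact", {
  p3 <- region_partition(3)
  expect_equal(nrow(p3$neg_cells), 9)
  expect_equal(nrow(p3$pos_cells), 196)
  p1 <- region_partition(1)
  expect_equal(p1$neg_cells, data.frame(x = 0, y = 0))
  pc <- region_partition(3, "complement")
  expect_equal(nrow(pc$pos_cells), 280)
  expect_equal(nrow(pc$pos_cells) + nrow(pc$neg_cells), 289)
  both <- merge(p3$neg_cells, p3$pos_cells)
  expect_equal(nrow(both), 0)  # disjoint
  expect_error(region_partition(0), "integer")
  expect_error(region_partition(3, "fancy"))
})

test_that("effect matrix export round-trips through the delimited table", {
  f <- tempfile(fileext = ".csv")
  m <- build_effect_matrix(cp_final)
  write_effect_matrix(m, f)
  back <- utils::read.csv(f, comment.char = "#")
  expect_equal(back$g_ratio, m$grid$g_ratio, tolerance = 1e-12)
  expect_equal(back$a7_factor, m$grid$a7_factor, tolerance = 1e-12)
  unlink(f)
})
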