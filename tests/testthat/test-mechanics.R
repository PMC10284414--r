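mp14 <- preset("CAT14")$mechanics
mp12 <- preset("CAT12")$mechanics

test_that("length-tension quadratic evaluates the reference curve", {
  expect_equal(length_tension(0, mp14), 0.6211)
  expect_equal(length_tension(5, mp14), -0.0045 * 25 + 0.0981 * 5 + 0.6211)
  expect_equal(length_tension(5, mp14), 0.9991)
  flat <- mp14; flat$g1 <- 0; flat$g2 <- 0
  expect_equal(length_tension(c(0, 4, 9), flat), rep(0.6211, 3))
  neg <- mp14; neg$g3 <- -10
  expect_warning(length_tension(0, neg), "g\\(Xm\\) <= 0")
})

test_that("series-elastic force is linear in the stretch", {
  expect_equal(series_force(0.3, 0.3, mp14), 0)
  expect_equal(series_force(0, -1, mp14), 100.3 * 0.16)
  expect_equal(series_force(0, -1, mp14), 16.048)
  expect_equal(series_force(0, -2, mp14), 2 * series_force(0, -1, mp14))
})

test_that("Hill-Mashima velocity recovers the printed operating points", {
  g1 <- unit_g_mechanics("CAT14")
  # isometric equilibrium: both branches vanish
  expect_equal(xce_rate(g1$P0_5, 5, 1, g1), 0)
  # concentric printed point: F = 57.4 N -> -74 mm/s
  expect_equal(xce_rate(57.4, 5, 1, g1),
               -g1$b0 * (g1$P0_5 - 57.4) / (57.4 + g1$a0))
  expect_equal(xce_rate(57.4, 5, 1, g1), -74.0, tolerance = 5e-3)
  # eccentric printed point: F = 127.4 N -> +71 mm/s
  expect_equal(xce_rate(127.4, 5, 1, g1), 71.0, tolerance = 5e-3)
})

test_that("Hill-Mashima branches join continuously at the isometric point", {
  set.seed(31)
  for (p in list(mp14, mp12)) {
    for (i in 1:30) {
      A <- runif(1, 0.05, 1); Xm <- runif(1, 0, 10)
      m <- p$P0_5 * length_tension(Xm, p) * A
      eps <- 1e-7 * max(1, m)
      v_lo <- xce_rate(m - eps, Xm, A, p)
      v_hi <- xce_rate(m + eps, Xm, A, p)
      expect_lt(abs(v_lo), 1e-3)
      expect_lt(abs(v_hi), 1e-3)
    }
  }
})

test_that("denominator floor guards pathological operating points", {
  g1 <- unit_g_mechanics("CAT14")
  # eccentric pole: F = (2 + c0/P0.5) * m
  A <- 1
  pole_F <- 2 * g1$P0_5 + g1$c0
  expect_error(xce_rate(pole_F, 5, A, g1, denom_floor = 1e-6), "eccentric")
})

test_that("inverse calibration reproduces the reference coefficients", {
  d14 <- calibration_data_preset("CAT14")
  hm <- hill_mashima_inverse(d14$vt[d14$vt$velocity < 0, ],
                             d14$vt[d14$vt$velocity > 0, ], d14$P0_5)
  expect_equal(hm$a0, 0.4, tolerance = 0.05 / 0.4)      # printed 0.4
  expect_equal(round(hm$b0, 1), 99.7)
  expect_equal(round(hm$c0, 1), -57.1)
  expect_equal(round(hm$d0, 1), 42.2)
  d12 <- calibration_data_preset("CAT12")
  hm12 <- hill_mashima_inverse(d12$vt[d12$vt$velocity < 0, ],
                               d12$vt[d12$vt$velocity > 0, ], d12$P0_5)
  expect_equal(round(hm12$a0, 3), -34.675)
  expect_equal(round(hm12$b0, 2), -130.31)
  expect_equal(round(hm12$c0, 2), -57.86)
  expect_equal(round(hm12$d0, 2), -202.78)
})

test_that("coefficients from the inverse equations round-trip the V-T data", {
  for (animal in c("CAT14", "CAT12")) {
    d <- calibration_data_preset(animal)
    hm <- hill_mashima_inverse(d$vt[d$vt$velocity < 0, ],
                               d$vt[d$vt$velocity > 0, ], d$P0_5)
    p <- mechanics_params(K_SE = 0.2, P0_5 = d$P0_5, g1 = 0, g2 = 0, g3 = 1,
                          a0 = hm$a0, b0 = hm$b0, c0 = hm$c0, d0 = hm$d0)
    for (i in seq_len(nrow(d$vt))) {
      v <- xce_rate(d$vt$tension[i], 5, 1, p)
      expect_lt(abs(v - d$vt$velocity[i]) / abs(d$vt$velocity[i]), 0.005)
    }
  }
})

test_that("a0 vanishes for points constructed on its null manifold", {
  # choose VS2 = 6*VS1 so VS1*TS1*(P-TS2) = VS2*TS2*(P-TS1) with
  # P = 10, TS1 = 8, TS2 = 4
  sh <- data.frame(velocity = c(-1, -6), tension = c(8, 4))
  le <- data.frame(velocity = c(1, 5), tension = c(11, 14))
  hm <- hill_mashima_inverse(sh, le, 10)
  expect_equal(hm$a0, 0, tolerance = 1e-12)
})

test_that("degenerate velocity-tension inputs are rejected", {
  sh <- data.frame(velocity = c(-2, -2), tension = c(5, 6))
  le <- data.frame(velocity = c(1, 5), tension = c(11, 14))
  expect_error(hill_mashima_inverse(sh, le, 10), "distinct")
})

test_that("length-tension fit interpolates three points exactly", {
  d14 <- calibration_data_preset("CAT14")
  g <- fit_length_tension(d14$lt, d14$P0_5)
  expect_equal(round(g$g1, 4), -0.0045)
  expect_equal(round(g$g2, 4), 0.0981)
  expect_equal(round(g$g3, 4), 0.6211)
  # interpolation property at machine precision
  for (i in 1:3) {
    pred <- g$g1 * d14$lt$Xm[i]^2 + g$g2 * d14$lt$Xm[i] + g$g3
    expect_equal(pred, d14$lt$tension[i] / d14$P0_5, tolerance = 1e-12)
  }
  d12 <- calibration_data_preset("CAT12")
  g12 <- fit_length_tension(d12$lt, d12$P0_5)
  expect_equal(g12$g2, 0.1637, tolerance = 5e-3)
  expect_equal(g12$g3, 0.4002, tolerance = 5e-3)
  # collinear points give a degenerate (linear) fit: g1 = 0
  lin <- data.frame(Xm = c(0, 5, 10), tension = c(10, 20, 30))
  expect_equal(fit_length_tension(lin, 20)$g1, 0, tolerance = 1e-12)
  dup <- data.frame(Xm = c(0, 0, 10), tension = c(10, 20, 30))
  expect_error(fit_length_tension(dup, 20), "distinct")
})

test_that("series-elastic stiffness estimate is a normalized quotient", {
  expect_equal(estimate_kse(30.6, 1.9, 100.3), 0.16, tolerance = 5e-3 / 0.16)
  expect_equal(estimate_kse(9.5, 1.55, 17.5), 0.35, tolerance = 5e-3 / 0.35)
  expect_equal(estimate_kse(100.3, 1, 100.3), 1)
  expect_error(estimate_kse(-1, 1, 10), "positive")
  expect_error(estimate_kse(1, 0, 10), "positive")
})
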