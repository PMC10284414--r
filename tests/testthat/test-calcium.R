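cap <- preset("CAT14")$calcium

test_that("release rate is causal and its kernel peaks where theory says", {
  expect_equal(release_rate(10, spike_train(), 2.5e-3, cap), 0)
  # a spike exactly at t contributes zero (rise term vanishes)
  expect_equal(release_rate(5, spike_train(5), 2.5e-3, cap), 0)
  # spikes in the future contribute nothing
  expect_equal(release_rate(5, spike_train(c(6, 10)), 2.5e-3, cap), 0)
  # single-spike kernel maximum: dense grid search (independent oracle)
  # against the closed form s* = tau1 * log((tau1 + tau2)/tau1)
  kern <- function(s) (1 - exp(-s / cap$tau1)) * exp(-s / cap$tau2)
  grid <- seq(1e-4, 50, by = 1e-4)
  s_grid <- grid[which.max(kern(grid))]
  s_closed <- cap$tau1 * log((cap$tau1 + cap$tau2) / cap$tau1)
  expect_equal(s_closed, log(14), tolerance = 1e-12)
  expect_lt(abs(s_grid - s_closed), 2e-4)
  # release_rate at the kernel peak equals CaSR * Rmax * kern(s*)
  expect_equal(release_rate(s_closed, spike_train(0), 1e-3, cap),
               1e-3 * cap$Rmax * kern(s_closed))
})

test_that("uptake saturates at Umax and matches the hand-derived point", {
  expect_equal(uptake_rate(0, cap), 0)
  expect_equal(uptake_rate(1, cap) / cap$Umax, 1, tolerance = 1e-2)
  # Ca*K = 1: ratio = 1/3, U = Umax/9
  expect_equal(uptake_rate(1 / cap$K, cap), cap$Umax / 9)
  # monotone nondecreasing over a broad sweep
  ca <- 10^seq(-9, -1, length.out = 200)
  expect_true(all(diff(uptake_rate(ca, cap)) >= 0))
  expect_true(all(uptake_rate(ca, cap) <= cap$Umax))
})

test_that("K5 length modulation is piecewise linear and continuous-ish", {
  expect_equal(k5_effective(5, cap), cap$K5i * (0.004 * 5 + 0.98))
  expect_equal(k5_effective(5, cap) / cap$K5i, 1.0)  # phi(Xm_half) = 1
  expect_equal(k5_effective(0, cap), 0.98 * cap$K5i)
  # both branch formulas agree at the intermediate length
  lower <- cap$phi1 * 5 + cap$phi2
  upper <- cap$phi3 * 5 + cap$phi4
  expect_equal(lower, 1.0)
  expect_equal(upper, 1.0)
  off <- cap; off$k5_length_dependent <- FALSE
  expect_equal(k5_effective(c(0, 3, 9), off), rep(cap$K5i, 3))
})

test_that("K6 activation modulation follows K6i/(1 + gain*A)", {
  expect_equal(k6_effective(0, cap), cap$K6i)
  expect_equal(k6_effective(1, cap), cap$K6i / 6)
  half <- cap; half$k6_activation_gain <- 2.5
  expect_equal(k6_effective(1, half), cap$K6i / 3.5)
  off <- cap; off$k6_activation_dependent <- FALSE
  zero_gain <- cap; zero_gain$k6_activation_gain <- 0
  a <- seq(0, 1, by = 0.1)
  expect_equal(k6_effective(a, off), k6_effective(a, zero_gain))
})

test_that("calcium derivatives match hand-evaluated mass action", {
  s0 <- calcium_state(CaSR = 0)
  expect_equal(unname(calcium_derivatives(s0, 0, spike_train(), 5, 0, cap)),
               rep(0, 5))
  s <- calcium_state(CaSR = 2.5e-3, CaSRCS = 0, Ca = 1e-6, CaB = 0, CaT = 0)
  d <- calcium_derivatives(s, 0, spike_train(), 5, 0, cap)
  expect_equal(d[["CaB"]], 400 * 4.3e-4 * 1e-6)   # 1.72e-7 M/ms
  expect_equal(d[["CaT"]], 4e5 * 7e-5 * 1e-6)     # 2.8e-5 M/ms
  expect_equal(d[["CaB"]], 1.72e-7)
  expect_equal(d[["CaT"]], 2.8e-5)
})

test_that("total calcium rate vanishes identically (single and two-site)", {
  set.seed(11)
  two <- cap; two$troponin_sites <- "double"
  two$K5i <- 1.37e6; two$K6i <- 0.56; two$T0 <- 1.2e-4
  for (i in 1:50) {
    s <- calcium_state(CaSR = runif(1, 0, 5e-3), CaSRCS = runif(1, 0, 0.02),
                       Ca = runif(1, 0, 1e-4), CaB = runif(1, 0, 4e-4),
                       CaT = runif(1, 0, 6e-5))
    spk <- spike_train(sort(runif(5, 0, 40)))
    t <- runif(1, 0, 60); Xm <- runif(1, 0, 10); At <- runif(1)
    d1 <- calcium_derivatives(s, t, spk, Xm, At, cap)
    expect_equal(sum(d1), 0, tolerance = 1e-18 + 1e-12 * max(abs(d1)))
    d2 <- calcium_derivatives(s, t, spk, Xm, At, two)
    w <- c(1, 1, 1, 1, 2)
    expect_equal(sum(w * d2), 0, tolerance = 1e-18 + 1e-12 * max(abs(d2)))
  }
})

test_that("saturated pools can only unload", {
  set.seed(12)
  for (i in 1:20) {
    s <- calcium_state(CaSR = runif(1, 0, 5e-3), CaSRCS = 0,
                       Ca = runif(1, 0, 1e-4), CaB = cap$B0, CaT = cap$T0)
    d <- calcium_derivatives(s, 0, spike_train(), runif(1, 0, 10),
                             runif(1), cap)
    expect_lte(d[["CaB"]], 0)
    expect_lte(d[["CaT"]], 0)
  }
})

test_that("release and uptake rates are nonnegative over random sweeps", {
  set.seed(13)
  for (i in 1:50) {
    spk <- spike_train(sort(runif(8, 0, 100)))
    expect_gte(release_rate(runif(1, 0, 120), spk, runif(1, 0, 5e-3), cap), 0)
    expect_gte(uptake_rate(runif(1, 0, 1e-2), cap), 0)
  }
})

test_that("half-activation calcium follows the two binding stoichiometries", {
  expect_equal(ca50(cap), 150 / 4e5)
  two <- preset("CAT14_twosite")$calcium
  expect_equal(ca50(two), sqrt(0.56 / 1.37e6))
})
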