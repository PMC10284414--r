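test_that("mechanics calibration is deterministic and optimizer-free", {
  d <- calibration_data_preset("CAT14")
  m1 <- calibrate_mechanics(d$lt, d$vt, d$delta_F, d$delta_X, d$P0_5)
  m2 <- calibrate_mechanics(d$lt, d$vt, d$delta_F, d$delta_X, d$P0_5)
  expect_identical(m1, m2)
  # composition equals the component operations
  expect_identical(m1$K_SE, estimate_kse(d$delta_F, d$delta_X, d$P0_5))
  g <- fit_length_tension(d$lt, d$P0_5)
  expect_identical(m1$g1, g$g1)
})

test_that("mechanics calibration reproduces both reference columns", {
  d14 <- calibration_data_preset("CAT14")
  m14 <- calibrate_mechanics(d14$lt, d14$vt, d14$delta_F, d14$delta_X,
                             d14$P0_5)
  want14 <- table1$CAT14$mechanics
  expect_equal(round(m14$K_SE, 2), want14[["K_SE"]])
  expect_equal(round(m14$g1, 4), want14[["g1"]])
  expect_equal(round(m14$g2, 4), want14[["g2"]])
  expect_equal(round(m14$g3, 4), want14[["g3"]])
  expect_equal(round(m14$a0, 1), want14[["a0"]])
  expect_equal(round(m14$b0, 1), want14[["b0"]])
  expect_equal(round(m14$c0, 1), want14[["c0"]])
  expect_equal(round(m14$d0, 1), want14[["d0"]])
  d12 <- calibration_data_preset("CAT12")
  m12 <- calibrate_mechanics(d12$lt, d12$vt, d12$delta_F, d12$delta_X,
                             d12$P0_5, Xm_min = -1, Xm_half = 3.64,
                             Xm_max = 8)
  want12 <- table1$CAT12$mechanics
  expect_equal(round(m12$K_SE, 2), want12[["K_SE"]])
  expect_equal(round(m12$a0, 3), want12[["a0"]])
  expect_equal(round(m12$b0, 2), want12[["b0"]])
})

test_that("synthetic targets are reproducible and noise-calibrated", {
  p <- preset("CAT14")
  pr <- list(short_protocol(freq = 10, duration = 400, settle = 100))
  clean <- generate_target_traces(p, pr, noise_sd = 0, seed = 7)
  sim <- simulate_muscle(p, pr[[1]], record_every = 8L, substeps = 4L)
  expect_equal(clean[[1]]$force, sim$F_N)
  n1 <- generate_target_traces(p, pr, noise_sd = 0.5, seed = 7)
  n2 <- generate_target_traces(p, pr, noise_sd = 0.5, seed = 7)
  expect_identical(n1[[1]]$force, n2[[1]]$force)
  n3 <- generate_target_traces(p, pr, noise_sd = 0.5, seed = 8)
  expect_false(identical(n1[[1]]$force, n3[[1]]$force))
  # noise SD within 5% of nominal over >= 1e4 samples
  long <- list(protocol(make_pulse_train(10, 1200), length_constant(5),
                        duration = 1200, settle = 100))
  nz <- generate_target_traces(p, long, noise_sd = 1.003, seed = 9,
                               record_every = 1L)
  base <- generate_target_traces(p, long, noise_sd = 0, seed = 9,
                                 record_every = 1L)
  resid <- nz[[1]]$force - base[[1]]$force
  expect_gte(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 1.003) / 1.003, 0.05)
})

test_that("a stage started at the optimum stays there", {
  p <- preset("CAT14")
  pr <- list(short_protocol(freq = 10, duration = 400, settle = 100))
  targets <- generate_target_traces(p, pr, noise_sd = 0, seed = 1)
  st <- calibration_stage("custom", targets, free_parameters = "tau2")
  res <- suppressWarnings(
    fit_stage(st, p, optimizer_cfg = list(maxit = 60, restarts = 0L)))
  expect_equal(unname(res$report$fitted_values[["tau2"]]),
               p$calcium$tau2, tolerance = 1e-3)
  expect_lt(res$report$trace_nrmse[1], 1e-6)
  # best-so-far objective trajectory is non-increasing
  expect_true(all(diff(res$report$objective_trajectory) <= 0))
})

test_that("a perturbed release time constant is recovered from traces", {
  p <- preset("CAT14")
  pr <- list(short_protocol(freq = 10, duration = 500, settle = 100),
             short_protocol(freq = 40, duration = 500, settle = 100))
  targets <- generate_target_traces(p, pr, noise_sd = 0, seed = 1)
  p0 <- fastmuscle:::override_parameters(
    p, list(calcium = list(tau2 = 1.3 * p$calcium$tau2)))
  st <- calibration_stage("custom", targets, free_parameters = "tau2")
  res <- suppressWarnings(
    fit_stage(st, p0, optimizer_cfg = list(maxit = 80, restarts = 1L)))
  rel_err <- abs(res$report$fitted_values[["tau2"]] - p$calcium$tau2) /
    p$calcium$tau2
  expect_lt(rel_err, 0.05)
  expect_lt(max(res$report$trace_nrmse), 1)
})

test_that("invalid stage definitions are rejected", {
  targets <- list()
  expect_error(calibration_stage("custom", targets,
                                 free_parameters = character()), "nonempty")
  expect_error(calibration_stage("custom", targets,
                                 free_parameters = "K_SE"), "unknown")
  expect_error(run_full_pipeline(preset("CAT14"), list(),
                                 stages = "shape"), "no targets")
})

test_that("troponin-rate length lines are recovered from twitch amplitudes", {
  p <- preset("CAT14")
  # targets generated at the true phi(Xm): the fit must reproduce the lines
  amp_at <- function(Xm) {
    s <- simulate_muscle(p, protocol(make_pulse_train(1, 900),
                                     length_constant(Xm), duration = 900,
                                     settle = 500),
                         record_every = 8L, substeps = 4L)
    max(s$F_N)
  }
  tt <- data.frame(Xm = c(0, 5, 10),
                   peak = c(amp_at(0), amp_at(5), amp_at(10)))
  fit <- fit_phi_lines(p, tt)
  true_phi0 <- p$calcium$phi1 * 0 + p$calcium$phi2
  true_phi10 <- p$calcium$phi3 * 10 + p$calcium$phi4
  expect_equal(unname(fit$phi_values[["0"]]), true_phi0, tolerance = 0.02)
  expect_equal(unname(fit$phi_values[["10"]]), true_phi10, tolerance = 0.02)
  expect_equal(fit$phi1 * 5 + fit$phi2, fit$phi3 * 5 + fit$phi4,
               tolerance = 0.05)
})
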