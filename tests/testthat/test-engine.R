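p14 <- preset("CAT14")

test_that("pulse trains enumerate spikes strictly inside the window", {
  expect_equal(as.numeric(make_pulse_train(20, 1000)), seq(0, 950, by = 50))
  expect_length(make_pulse_train(1, 1000), 1L)
  expect_equal(as.numeric(make_pulse_train(100, 100, start = 10)),
               seq(10, 100, by = 10))
  expect_error(make_pulse_train(0, 100))
})

test_that("length trajectories interpolate linearly and clamp outside", {
  tr <- length_constant(5)
  expect_equal(trajectory_eval(tr, c(-10, 0, 3000)), c(5, 5, 5))
  rp <- length_ramp(5, velocity = -20, t_start = 100, t_end = 600)
  expect_equal(trajectory_eval(rp, 100), 5)
  expect_equal(trajectory_eval(rp, 350), 5 - 20 * 0.25 / 1000 * 1000)
  expect_equal(trajectory_eval(rp, 600), 5 - 20 * 0.5)
  expect_equal(trajectory_eval(rp, 10000), -5)   # constant extrapolation
  st <- length_step(5, 2, at = 500, rise_ms = 1)
  expect_equal(trajectory_eval(st, c(0, 500, 501, 900)), c(5, 5, 7, 7))
})

test_that("an unstimulated muscle holds a small constant resting force", {
  s <- simulate_muscle(p14, protocol(spike_train(), length_constant(5),
                                     duration = 300), record_every = 4L)
  # the resting sigmoid leaves a ~1% baseline activation, not exactly zero
  expect_lt(max(s$F_N), 0.02 * p14$mechanics$P0_5)
  expect_lt(max(s$F_N) - min(s$F_N), 1e-6 * p14$mechanics$P0_5)
  a_rest <- a_inf(0, p14$activation$C1i, p14$activation$C2i)
  expect_equal(mean(s$A_tilde), a_rest, tolerance = 1e-3)
})

test_that("fused tetanus plateaus near the activation-scaled peak force", {
  s <- simulate_muscle(p14, isometric_protocol(100, 5, duration = 1500),
                       record_every = 8L)
  plateau <- max(s$F_N)
  expect_lt(abs(plateau - p14$mechanics$P0_5 * length_tension(5, p14$mechanics)) /
              p14$mechanics$P0_5, 0.10)
})

test_that("peak force is nondecreasing with stimulation frequency", {
  sweep <- frequency_sweep(p14, c(1, 10, 40, 100), Xm = 5, duration = 1200,
                           record_every = 8L)
  peaks <- vapply(sweep, function(s) max(s$F_N), numeric(1))
  expect_true(all(diff(peaks) > 0))
  expect_error(frequency_sweep(p14, numeric(), 5), "nonempty")
  # singleton sweep is just one simulation
  one <- frequency_sweep(p14, 40, Xm = 5, duration = 1200, record_every = 8L)
  expect_equal(one[["40"]]$F_N, sweep[["40"]]$F_N)
})

test_that("total calcium is conserved to machine precision", {
  for (nm in c("CAT14", "CAT14_twosite")) {
    s <- simulate_muscle(preset(nm), isometric_protocol(20, 5, 600),
                         record_every = 4L)
    tc <- total_calcium(s)
    expect_lt((max(tc) - min(tc)) / tc[1], 1e-9, label = nm)
  }
})

test_that("compiled and reference engines agree state-for-state", {
  pr <- short_protocol(freq = 25, duration = 150, settle = 50)
  for (sch in c("exp_midpoint", "cnexp", "rk4")) {
    a <- simulate_muscle(p14, pr, scheme = sch, engine = "cpp",
                         substeps = 2L)
    b <- simulate_muscle(p14, pr, scheme = sch, engine = "r",
                         substeps = 2L)
    for (col in c("CaSR", "Ca", "CaT", "A_tilde", "C1", "C2", "dXCE_mm",
                  "F_N"))
      expect_equal(a[[col]], b[[col]], tolerance = 1e-10,
                   label = paste(sch, col))
  }
})

test_that("integration schemes agree on converged trajectories", {
  pr <- short_protocol(freq = 20, duration = 300, settle = 100)
  mid <- simulate_muscle(p14, pr, scheme = "exp_midpoint", substeps = 8L)
  eul <- simulate_muscle(p14, pr, scheme = "cnexp", substeps = 64L)
  expect_equal(max(mid$F_N), max(eul$F_N), tolerance = 2e-3)
})

test_that("two-site troponin occupancy stays within the total pool", {
  tw <- preset("CAT14_twosite")
  s <- simulate_muscle(tw, isometric_protocol(40, 5, 500), record_every = 4L)
  expect_true(all(s$CaT >= 0 & s$CaT <= tw$calcium$T0))
  expect_true(all(s$F_N >= -1e-6))
  expect_gt(max(s$F_N), 10)  # the variant still produces tetanic force
})

test_that("isokinetic ramps modulate force in the expected directions", {
  base <- simulate_muscle(p14, isometric_protocol(100, 5, 800),
                          record_every = 8L)
  iso_end <- base$F_N[nrow(base)]
  lengthen <- protocol(make_pulse_train(100, 800),
                       length_ramp(5, 20, 400, 800), duration = 800)
  shorten <- protocol(make_pulse_train(100, 800),
                      length_ramp(5, -20, 400, 800), duration = 800)
  f_len <- simulate_muscle(p14, lengthen, record_every = 8L)$F_N
  f_sho <- simulate_muscle(p14, shorten, record_every = 8L)$F_N
  expect_gt(f_len[length(f_len)], iso_end)   # lengthening enhances force
  expect_lt(f_sho[length(f_sho)], iso_end)   # shortening depresses force
})

test_that("traces export to CSV (with sidecar) and read back", {
  s <- simulate_muscle(p14, short_protocol(duration = 100, settle = 50),
                       record_every = 8L)
  f <- file.path(tempdir(), "trace.csv")
  write_trace_csv(s, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.csv$", ".json", f)))
  back <- read_trace_csv(f)
  expect_equal(back$F_N, s$F_N)
  expect_named(back, names(as.data.frame(s)))
  side <- jsonlite::read_json(sub("\\.csv$", ".json", f),
                              simplifyVector = TRUE)
  expect_equal(side$params$mechanics$P0_5, 100.3)
  unlink(c(f, sub("\\.csv$", ".json", f)))
})

test_that("identical runs produce byte-identical trace files", {
  f1 <- file.path(tempdir(), "det1.csv")
  f2 <- file.path(tempdir(), "det2.csv")
  pr <- short_protocol(duration = 120, settle = 40)
  write_trace_csv(simulate_muscle(p14, pr, record_every = 8L), f1,
                  sidecar = FALSE)
  write_trace_csv(simulate_muscle(p14, pr, record_every = 8L), f2,
                  sidecar = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("non-finite states abort with the offending variable and time", {
  bad <- fastmuscle:::override_parameters(
    p14, list(activation = list(C3 = 1e-9)))
  # a near-zero activation time constant makes the A~ update explode in RK4
  expect_error(
    simulate_muscle(bad, short_protocol(duration = 100, settle = 10),
                    scheme = "rk4", substeps = 1L),
    "non-finite|denominator")
})

test_that("parvalbumin buffering depresses submaximal force most", {
  static <- fastmuscle:::override_parameters(
    preset("CAT14"), list(activation = list(C1n1 = 0, C2n1 = 0)))
  pv <- preset("CAT14_parvalbumin")
  red <- vapply(c(10, 100), function(f) {
    pr <- protocol(make_pulse_train(f, 1200), length_constant(5),
                   duration = 1200)
    a <- max(simulate_muscle(static, pr, record_every = 8L)$F_N)
    b <- max(simulate_muscle(pv, pr, record_every = 8L)$F_N)
    1 - b / a
  }, numeric(1))
  expect_gt(red[1], 0.2)      # strong reduction at low frequency
  expect_lt(red[2], red[1])   # fused tetanus barely affected
})
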