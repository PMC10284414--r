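# Staged parameter-estimation workflow.
#
# The mechanics module is calibrated analytically from printed
# length-tension / velocity-tension data; the calcium-activation chain is
# calibrated in ordered stages by derivative-free optimization against
# force traces:
#   shape    - tau1, tau2, C1i, C2i, C3, C4, C5, alpha on non-sagging
#              frequencies with a static calcium-force curve
#              (C1n1 = C2n1 = 0)
#   sag_c1   - C1n1..C1n4 on the strongest-sag frequency
#   slope_c2 - C2n1..C2n4 on the high-frequency tetanus
# The in-situ recordings behind the original fits are not distributed, so
# quantitative calibration testing is parameter recovery on self-generated
# synthetic traces.

#' Reference calibration measurements for the two animals
#'
#' The printed in-situ measurements used to constrain the mechanics module:
#' three length-tension points, four velocity-tension points, the
#' quick-stretch force/length differences for the series-elastic stiffness,
#' and the peak force at the intermediate length.
#'
#' @param name `"CAT14"` or `"CAT12"`.
#' @return List with `lt` (data.frame Xm/tension), `vt` (data.frame
#'   velocity/tension), `delta_F` (N), `delta_X` (mm), `P0_5` (N).
#' @export
calibration_data_preset <- function(name) {
  switch(name,
    CAT14 = list(
      lt = data.frame(Xm = c(0, 5, 10), tension = c(62.3, 100.3, 115.9)),
      vt = data.frame(velocity = c(-74, -1, 1, 71),
                      tension = c(57.4, 99.3, 101.3, 127.4)),
      delta_F = 30.6, delta_X = 1.9, P0_5 = 100.3),
    CAT12 = list(
      lt = data.frame(Xm = c(-0.55, 3.64, 7.9),
                      tension = c(5.43, 17.5, 30)),
      vt = data.frame(velocity = c(-63.81, -1.5, 1, 63.81),
                      tension = c(1.02, 17.3, 17.7, 36.03)),
      delta_F = 9.5, delta_X = 1.55, P0_5 = 17.5),
    stop("unknown calibration data preset `", name,
         "`; valid: CAT14, CAT12", call. = FALSE))
}

#' Analytic calibration of the mechanics module
#'
#' Composes [estimate_kse()], [fit_length_tension()] and
#' [hill_mashima_inverse()]; deterministic, no optimizer.
#'
#' @param lt data.frame with `Xm` (mm) and `tension` (N), three points.
#' @param vt data.frame with `velocity` (mm/s, signed) and `tension` (N),
#'   two shortening (negative velocity) and two lengthening points.
#' @param delta_F,delta_X quick-stretch force (N) and length (mm)
#'   differences for the series-elastic stiffness.
#' @param P0_5 peak force at the intermediate length (N).
#' @param Xm_min,Xm_half,Xm_max length range passed to the result.
#' @return A [mechanics_params()] object.
#' @export
calibrate_mechanics <- function(lt, vt, delta_F, delta_X, P0_5,
                                Xm_min = 0, Xm_half = 5, Xm_max = 10) {
  vt <- as.data.frame(vt)
  kse <- estimate_kse(delta_F, delta_X, P0_5)
  g <- fit_length_tension(lt, P0_5)
  hm <- hill_mashima_inverse(vt[vt$velocity < 0, ], vt[vt$velocity > 0, ],
                             P0_5)
  mechanics_params(K_SE = kse, P0_5 = P0_5, g1 = g$g1, g2 = g$g2, g3 = g$g3,
                   a0 = hm$a0, b0 = hm$b0, c0 = hm$c0, d0 = hm$d0,
                   Xm_min = Xm_min, Xm_half = Xm_half, Xm_max = Xm_max)
}

#' Generate synthetic target force traces under known parameters
#'
#' Simulates each protocol under `p` ("true" parameters) and adds i.i.d.
#' Gaussian noise; the stand-in for in-situ recordings in
#' parameter-recovery experiments.
#'
#' @param p a [model_parameters()] object (the ground truth).
#' @param protocols list of [protocol()] objects.
#' @param noise_sd noise standard deviation (N), >= 0.
#' @param seed integer RNG seed (noise reproducibility).
#' @param record_every,substeps forwarded to [simulate_muscle()].
#' @return List of class `calibration_targets`: one element per protocol
#'   with `protocol`, `time_ms`, `force`; the truth is attached as
#'   attribute `true_params`.
#' @export
generate_target_traces <- function(p, protocols, noise_sd = 0, seed = 1L,
                                   record_every = 8L, substeps = 4L) {
  stopifnot(noise_sd >= 0)
  set.seed(as.integer(seed))
  targets <- lapply(protocols, function(proto) {
    s <- simulate_muscle(p, proto, record_every = record_every,
                         substeps = substeps)
    f <- s$F_N
    if (noise_sd > 0) f <- f + rnorm(length(f), sd = noise_sd)
    list(protocol = proto, time_ms = s$time_ms, force = f,
         record_every = record_every)
  })
  attr(targets, "true_params") <- p
  attr(targets, "substeps") <- substeps
  class(targets) <- "calibration_targets"
  targets
}

# Which parameter section each optimizable name lives in.
.stage_section <- c(tau1 = "calcium", tau2 = "calcium",
                    C1i = "activation", C2i = "activation",
                    C3 = "activation", C4 = "activation",
                    C5 = "activation", alpha = "activation",
                    C1n1 = "activation", C1n2 = "activation",
                    C1n3 = "activation", C1n4 = "activation",
                    C2n1 = "activation", C2n2 = "activation",
                    C2n3 = "activation", C2n4 = "activation")

.stage_defs <- list(
  shape = list(free = c("tau1", "tau2", "C1i", "C2i", "C3", "C4", "C5",
                        "alpha"),
               fixed_overrides = list(C1n1 = 0, C2n1 = 0),
               extra_starts = list()),
  # the drift stages start from a zero drift amplitude; the extra starts
  # seed the physiologically known drift directions (midpoint drifts right
  # during sag, the inverse slope shrinks during potentiation)
  sag_c1 = list(free = c("C1n1", "C1n2", "C1n3", "C1n4"),
                fixed_overrides = list(),
                extra_starts = list(list(C1n1 = 0.02))),
  slope_c2 = list(free = c("C2n1", "C2n2", "C2n3", "C2n4"),
                  fixed_overrides = list(),
                  extra_starts = list(list(C2n1 = -0.03))))

# Physiological box constraints for the optimizable parameters: the CXn2
# thresholds and CXn3 sharpness are fractions of the total troponin pool,
# time constants are bounded by the protocol scale. Proposals outside the
# box are scored with a distance-graded penalty (no simulation).
.param_bounds <- list(
  tau1 = c(0.05, 100), tau2 = c(0.5, 200),
  C1i = c(0.01, 0.9), C2i = c(0.005, 0.9),
  C3 = c(1, 500), C4 = c(-100, 0.99), C5 = c(-50, 50),
  alpha = c(0.3, 6),
  C1n1 = c(-0.2, 0.2), C1n2 = c(0, 1), C1n3 = c(1e-4, 0.5),
  C1n4 = c(1, 3000),
  C2n1 = c(-0.2, 0.2), C2n2 = c(0, 1), C2n3 = c(1e-4, 0.5),
  C2n4 = c(1, 3000))

#' Define a calibration stage
#'
#' @param stage `"shape"`, `"sag_c1"` or `"slope_c2"` (or `"custom"` with
#'   explicit `free_parameters`).
#' @param targets a subset of [generate_target_traces()] output (the traces
#'   this stage is fitted to).
#' @param free_parameters parameter names optimized in this stage
#'   (defaulted from the stage name).
#' @param fixed_overrides named list of parameter values pinned during the
#'   fit (e.g. `list(C1n1 = 0, C2n1 = 0)` for the static-curve shape stage).
#' @return An object of class `calibration_stage`.
#' @export
calibration_stage <- function(stage, targets, free_parameters = NULL,
                              fixed_overrides = NULL) {
  extra_starts <- list()
  if (stage %in% names(.stage_defs)) {
    def <- .stage_defs[[stage]]
    if (is.null(free_parameters)) free_parameters <- def$free
    if (is.null(fixed_overrides)) fixed_overrides <- def$fixed_overrides
    extra_starts <- def$extra_starts
  }
  if (!length(free_parameters))
    stop("calibration_stage: free_parameters must be nonempty",
         call. = FALSE)
  bad <- setdiff(free_parameters, names(.stage_section))
  if (length(bad))
    stop("calibration_stage: unknown free parameter `", bad[[1L]], "`",
         call. = FALSE)
  structure(list(stage = stage, targets = targets,
                 free_parameters = free_parameters,
                 fixed_overrides = fixed_overrides %||% list(),
                 extra_starts = extra_starts),
            class = "calibration_stage")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Apply a named flat parameter vector (stage parameters) onto p.
apply_stage_values <- function(p, values) {
  ov <- list()
  for (nm in names(values)) {
    sec <- .stage_section[[nm]]
    ov[[sec]] <- c(ov[[sec]], setNames(list(unname(values[[nm]])), nm))
  }
  override_parameters(p, ov)
}

# Sum of per-trace mean squared force errors (or mean NRMSE) for parameter
# set p against targets.
stage_objective <- function(p, targets, objective = c("sse", "nrmse"),
                            substeps = 4L) {
  objective <- match.arg(objective)
  tot <- 0
  for (tg in targets) {
    s <- simulate_muscle(p, tg$protocol,
                         record_every = tg$record_every %||% 8L,
                         substeps = substeps)
    if (length(s$F_N) != length(tg$force))
      stop("stage_objective: target/simulation length mismatch",
           call. = FALSE)
    tot <- tot + if (objective == "sse") mean((tg$force - s$F_N)^2)
    else nrmse(tg$force, s$F_N)
  }
  tot
}

#' Fit one calibration stage by derivative-free local optimization
#'
#' Nelder-Mead over the stage's free parameters only; all other parameters
#' stay frozen at their values in `p0` (plus the stage's fixed overrides).
#' The objective is the sum over target traces of the mean squared force
#' error (`"sse"`, default) or of the trace NRMSE.
#'
#' @param stage a [calibration_stage()].
#' @param p0 starting [model_parameters()].
#' @param optimizer_cfg list: `maxit` (default 400), `reltol` (1e-6),
#'   `objective` ("sse" or "nrmse"), `substeps` (4).
#' @return List with `params` (fitted [model_parameters()]) and `report`
#'   (class `recovery_report`): initial/fitted values, per-parameter
#'   relative errors vs the targets' true parameters when available, the
#'   best-so-far objective trajectory, per-trace NRMSE of the fit, and a
#'   convergence flag.
#' @export
fit_stage <- function(stage, p0, optimizer_cfg = list()) {
  stopifnot(inherits(stage, "calibration_stage"),
            inherits(p0, "model_parameters"))
  cfg <- modifyList(list(maxit = 500, reltol = 1e-7, objective = "sse",
                         substeps = 4L, restarts = 1L), optimizer_cfg)
  p_base <- if (length(stage$fixed_overrides))
    apply_stage_values(p0, stage$fixed_overrides) else p0

  flat <- function(p) {
    vapply(stage$free_parameters, function(nm)
      p[[.stage_section[[nm]]]][[nm]], numeric(1))
  }
  start <- flat(p_base)
  traj <- numeric(0)
  best <- Inf
  bounds_lo <- vapply(stage$free_parameters, function(nm)
    (.param_bounds[[nm]] %||% c(-Inf, Inf))[1], numeric(1))
  bounds_hi <- vapply(stage$free_parameters, function(nm)
    (.param_bounds[[nm]] %||% c(-Inf, Inf))[2], numeric(1))
  fn <- function(x) {
    names(x) <- stage$free_parameters
    viol <- sum(pmax(bounds_lo - x, 0) + pmax(x - bounds_hi, 0))
    val <- if (viol > 0) 1e10 * (1 + viol) else tryCatch({
      pc <- apply_stage_values(p_base, as.list(x))
      stage_objective(pc, stage$targets, cfg$objective, cfg$substeps)
    }, error = function(e) 1e12)
    best <<- min(best, val)
    traj <<- c(traj, best)
    val
  }
  run_nm <- function(x0) {
    ps <- pmax(abs(x0), 0.01)
    opt <- optim(x0, fn, method = "Nelder-Mead",
                 control = list(maxit = cfg$maxit, reltol = cfg$reltol,
                                parscale = ps))
    # simplex restarts from the incumbent: a fresh simplex escapes
    # collapsed geometry, like repeated runs of a principal-axis search
    for (k in seq_len(cfg$restarts)) {
      prev <- opt$value
      opt2 <- optim(opt$par, fn, method = "Nelder-Mead",
                    control = list(maxit = cfg$maxit, reltol = cfg$reltol,
                                   parscale = pmax(abs(opt$par), 0.01)))
      if (opt2$value <= opt$value) opt <- opt2
      if (prev - opt$value < cfg$reltol * (abs(prev) + 1e-12)) break
    }
    opt
  }
  opt <- run_nm(start)
  for (es in stage$extra_starts %||% list()) {
    x0 <- start
    for (nm in names(es)) x0[[nm]] <- es[[nm]]
    opt2 <- run_nm(x0)
    if (opt2$value < opt$value) opt <- opt2
  }
  fitted <- opt$par
  names(fitted) <- stage$free_parameters
  p_fit <- apply_stage_values(p_base, as.list(fitted))

  truth <- attr(stage$targets, "true_params")
  true_vals <- if (!is.null(truth)) flat(truth) else NULL
  rel_err <- if (!is.null(true_vals))
    abs(fitted - true_vals) / pmax(abs(true_vals), 1e-12) else NULL
  trace_nrmse <- vapply(stage$targets, function(tg) {
    s <- simulate_muscle(p_fit, tg$protocol,
                         record_every = tg$record_every %||% 8L,
                         substeps = cfg$substeps)
    nrmse(tg$force, s$F_N)
  }, numeric(1))
  converged <- opt$convergence == 0
  if (!converged)
    warning("fit_stage(", stage$stage, "): optimizer did not report ",
            "convergence; returning best-so-far", call. = FALSE)
  report <- structure(
    list(stage = stage$stage, true_values = true_vals,
         initial_values = start, fitted_values = fitted,
         relative_errors = rel_err, objective_trajectory = traj,
         trace_nrmse = trace_nrmse, converged = converged,
         objective = cfg$objective),
    class = "recovery_report")
  list(params = p_fit, report = report)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> stage", x$stage,
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  tab <- data.frame(initial = x$initial_values, fitted = x$fitted_values)
  if (!is.null(x$true_values)) {
    tab$true <- x$true_values
    tab$rel_error <- x$relative_errors
  }
  print(round(tab, 5))
  cat("trace NRMSE (%):", round(x$trace_nrmse, 3), "\n")
  invisible(x)
}

#' Standard recovery protocols for the staged pipeline
#'
#' Isometric protocols at the intermediate length mirroring the staged
#' fitting design: the shape stage uses the non-sagging frequencies (the
#' strongest-sag frequency is excluded there), the C1 stage the
#' strongest-sag frequency, and the C2 stage the high-frequency tetanus.
#'
#' @param Xm muscle-tendon length (mm).
#' @param sag_freq strongest-sag frequency (Hz): 20 for CAT14, 10 for CAT12.
#' @param shape_freqs frequencies (Hz) for the shape stage.
#' @param settle settle time (ms).
#' @return Named list of protocol lists per stage.
#' @export
recovery_protocols <- function(Xm = 5, sag_freq = 20,
                               shape_freqs = c(10, 40), settle = 500) {
  list(
    shape = lapply(shape_freqs, function(f)
      protocol(make_pulse_train(f, 1200), length_constant(Xm),
               duration = 1200, settle = settle)),
    sag_c1 = list(protocol(make_pulse_train(sag_freq, 2500),
                           length_constant(Xm), duration = 2500,
                           settle = settle)),
    slope_c2 = list(protocol(make_pulse_train(40, 1500),
                             length_constant(Xm), duration = 1500,
                             settle = settle)))
}

#' Run the staged calibration pipeline
#'
#' Chains the shape, sag_c1 and slope_c2 stages (in that order) starting
#' from `p0`, each stage freeing its own parameter set and freezing the
#' rest. Stage targets are matched by name from `targets_by_stage`.
#'
#' @param p0 starting [model_parameters()] (e.g. a perturbed preset).
#' @param targets_by_stage named list (`shape`, `sag_c1`, `slope_c2`) of
#'   [generate_target_traces()] outputs.
#' @param stages character vector of stages to run, in order.
#' @param optimizer_cfg see [fit_stage()].
#' @return List with `params` (final fitted parameters) and `reports` (one
#'   `recovery_report` per stage).
#' @export
run_full_pipeline <- function(p0, targets_by_stage,
                              stages = c("shape", "sag_c1", "slope_c2"),
                              optimizer_cfg = list()) {
  p <- p0
  reports <- list()
  for (st in stages) {
    tg <- targets_by_stage[[st]]
    if (is.null(tg)) stop("run_full_pipeline: no targets for stage `", st,
                          "`", call. = FALSE)
    res <- tryCatch(
      fit_stage(calibration_stage(st, tg), p, optimizer_cfg),
      error = function(e) stop("stage `", st, "` failed: ",
                               conditionMessage(e), call. = FALSE))
    p <- res$params
    reports[[st]] <- res$report
  }
  # after the sag/slope stages the static-curve pins from the shape stage
  # are no longer in force; p carries the fitted C1n/C2n values
  list(params = p, reports = reports)
}

#' Length modulation lines for the troponin on-rate from twitch amplitudes
#'
#' Calibrates the piecewise-linear K5 length modulation phi(Xm): for each
#' extreme length the scalar phi value whose twitch peak matches the target
#' amplitude is found by root-bracketing, the intermediate length is pinned
#' at its parameterized value, and each branch line is solved through its
#' two points. Continuity at the intermediate length is checked (warning),
#' not enforced.
#'
#' @param p a [model_parameters()] object.
#' @param twitch_targets data.frame with `Xm` (three lengths: min,
#'   intermediate, max) and `peak` (N), e.g. measured twitch amplitudes.
#' @param phi_range search interval for the phi multiplier.
#' @return List with `phi1`, `phi2`, `phi3`, `phi4` and the fitted per-length
#'   multipliers `phi_values`.
#' @export
fit_phi_lines <- function(p, twitch_targets, phi_range = c(0.5, 1.5)) {
  tt <- as.data.frame(twitch_targets)
  stopifnot(nrow(tt) == 3L)
  tt <- tt[order(tt$Xm), ]
  me <- p$mechanics
  twitch_peak_at <- function(Xm, phi) {
    # pin phi(Xm) to the requested scalar by a flat line on both branches
    pp <- override_parameters(p, list(calcium = list(
      phi1 = 0, phi2 = phi, phi3 = 0, phi4 = phi)))
    s <- simulate_muscle(pp, protocol(make_pulse_train(1, 900),
                                      length_constant(Xm), duration = 900,
                                      settle = 500),
                         record_every = 8L, substeps = 4L)
    max(s$F_N)
  }
  phi_half <- p$calcium$phi3 * me$Xm_half + p$calcium$phi4
  phis <- vapply(seq_len(3L), function(i) {
    if (i == 2L) return(phi_half)
    f <- function(phi) twitch_peak_at(tt$Xm[i], phi) - tt$peak[i]
    stats::uniroot(f, phi_range, tol = 1e-4)$root
  }, numeric(1))
  # lower branch through (Xm_min, phi_min) and (Xm_half, phi_half);
  # upper branch through (Xm_half, phi_half) and (Xm_max, phi_max)
  phi1 <- (phis[2] - phis[1]) / (tt$Xm[2] - tt$Xm[1])
  phi2 <- phis[1] - phi1 * tt$Xm[1]
  phi3 <- (phis[3] - phis[2]) / (tt$Xm[3] - tt$Xm[2])
  phi4 <- phis[2] - phi3 * tt$Xm[2]
  lower_at_half <- phi1 * me$Xm_half + phi2
  upper_at_half <- phi3 * me$Xm_half + phi4
  if (abs(lower_at_half - upper_at_half) > 0.05)
    warning("fit_phi_lines: branch mismatch at the intermediate length (",
            signif(lower_at_half, 4), " vs ", signif(upper_at_half, 4), ")")
  list(phi1 = phi1, phi2 = phi2, phi3 = phi3, phi4 = phi4,
       phi_values = setNames(phis, tt$Xm))
}

#' End-to-end parameter-recovery experiment
#'
#' Generates zero-noise (or noisy) targets from a preset, perturbs the
#' shape-stage parameters by a uniform relative amount, runs the staged
#' pipeline, and evaluates the final per-trace NRMSE of every target under
#' the fitted parameters.
#'
#' @param animal `"CAT14"` or `"CAT12"` (sets the strongest-sag frequency).
#' @param perturbation relative half-width of the uniform initialization
#'   perturbation (0.2 = plus/minus 20%).
#' @param seed RNG seed for the perturbation draw (and noise, if any).
#' @param noise_sd target noise standard deviation (N).
#' @param optimizer_cfg forwarded to [fit_stage()].
#' @return List: `params` (fitted), `p0` (perturbed start), `reports`
#'   (per stage), `final_nrmse` (per-trace NRMSE, %, of the final fit on
#'   all targets), `targets_by_stage`.
#' @export
recovery_experiment <- function(animal = "CAT14", perturbation = 0.2,
                                seed = 1L, noise_sd = 0,
                                optimizer_cfg = list()) {
  true_p <- preset(animal)
  sag_freq <- if (animal == "CAT12") 10 else 20
  protos <- recovery_protocols(Xm = 5, sag_freq = sag_freq)
  # The shape stage assumes sag-free responses (it is fitted with the
  # calcium-force curve pinned static). Its synthetic targets therefore
  # come from the truth's static-curve twin -- the role the non-sagging
  # frequencies' recordings played originally -- while the sag and slope
  # stages see the full dynamic truth.
  static_truth <- override_parameters(
    true_p, list(activation = list(C1n1 = 0, C2n1 = 0)))
  targets <- list(
    shape = generate_target_traces(static_truth, protos$shape, noise_sd,
                                   seed),
    sag_c1 = generate_target_traces(true_p, protos$sag_c1, noise_sd, seed),
    slope_c2 = generate_target_traces(true_p, protos$slope_c2, noise_sd,
                                      seed))
  # the stage-frozen shape parameters of the static twin are the truth's
  attr(targets$shape, "true_params") <- true_p
  set.seed(as.integer(seed))
  ov <- list(calcium = list(), activation = list())
  for (nm in .stage_defs$shape$free) {
    sec <- .stage_section[[nm]]
    v <- true_p[[sec]][[nm]]
    ov[[sec]][[nm]] <- v * runif(1, 1 - perturbation, 1 + perturbation)
  }
  p0 <- override_parameters(true_p, ov)
  res <- run_full_pipeline(p0, targets, optimizer_cfg = optimizer_cfg)
  # endpoint: the fitted model against the full dynamic truth on every
  # protocol (shape protocols included)
  eval_targets <- c(
    generate_target_traces(true_p, protos$shape, 0, seed),
    generate_target_traces(true_p, protos$sag_c1, 0, seed),
    generate_target_traces(true_p, protos$slope_c2, 0, seed))
  final_nrmse <- vapply(eval_targets, function(tg) {
    s <- simulate_muscle(res$params, tg$protocol,
                         record_every = tg$record_every %||% 8L,
                         substeps = 4L)
    nrmse(tg$force, s$F_N)
  }, numeric(1))
  list(params = res$params, p0 = p0, reports = res$reports,
       final_nrmse = final_nrmse, targets_by_stage = targets)
}
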