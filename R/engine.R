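# Coupled fixed-step simulation engine.

#' Regular pulse train
#'
#' Spikes at `start + k * (1000/freq)` for k = 0, 1, ... while the spike time
#' is strictly inside `[start, start + duration)`.
#'
#' @param freq stimulation frequency (Hz, > 0).
#' @param duration train duration (ms, > 0).
#' @param start first spike time (ms).
#' @return A [spike_train()].
#' @export
make_pulse_train <- function(freq, duration, start = 0) {
  stopifnot(freq > 0, duration > 0, start >= 0)
  isi <- 1000 / freq
  n <- ceiling(duration / isi)
  times <- start + (seq_len(n) - 1) * isi
  spike_train(times[times < start + duration])
}

#' Stimulation/length protocol
#'
#' @param spikes a [spike_train()].
#' @param length a `length_trajectory` (see [length_constant()]).
#' @param duration simulated time after stimulation onset (ms, > 0).
#' @param settle unstimulated pre-run (ms) at the initial length, letting
#'   the binding pools and the resting activation equilibrate before t = 0.
#' @return An object of class `protocol`.
#' @export
protocol <- function(spikes, length, duration, settle = 2000) {
  stopifnot(inherits(spikes, "spike_train"),
            inherits(length, "length_trajectory"),
            duration > 0, settle >= 0)
  structure(list(spikes = spikes, length = length,
                 duration = duration, settle = settle),
            class = "protocol")
}

# Isometric constant-frequency protocol helper.
isometric_protocol <- function(freq, Xm, duration = 3000, settle = 2000,
                               train_duration = duration) {
  protocol(make_pulse_train(freq, train_duration), length_constant(Xm),
           duration = duration, settle = settle)
}

#' Simulate the coupled muscle-tendon model
#'
#' Integrates calcium kinetics, activation dynamics (with the drifting C1/C2
#' sigmoid) and Hill-Mashima mechanics as one joint state vector at a fixed
#' step `p$dt`. The settle phase runs before t = 0 with no stimulation at the
#' protocol's initial length; length changes are measured relative to the
#' length at stimulation onset, so isometric runs have dXm = 0. Force is
#' recomputed algebraically from the series-elastic stretch at every step.
#'
#' @param p a [model_parameters()] object.
#' @param proto a [protocol()].
#' @param scheme integration scheme: `"exp_midpoint"` (second-order
#'   exponential midpoint on the per-variable linearization, default),
#'   `"cnexp"` (first-order exponential Euler) or `"rk4"`. The exponential
#'   schemes are robust to the stiff saturable-uptake term at the default
#'   step, where explicit RK4 is unstable; the midpoint variant removes the
#'   first-order truncation bias visible in twitch amplitudes.
#' @param record_every record every n-th step (1 = every step).
#' @param include_settle include the settle phase (t < 0) in the output.
#' @param engine `"cpp"` (compiled core) or `"r"` (reference R stepper,
#'   slow; used for cross-checking).
#' @param denom_floor Hill-Mashima denominator floor (N); see [xce_rate()].
#' @param clamp_negative_force clamp series force at zero when the series
#'   element goes slack (default off: the equations dictate the sign).
#' @param substeps internal integration substeps per recorded step `dt`.
#'   The calcium release/uptake boundary layer after each spike is much
#'   faster than `dt`; the default (8) resolves it so that simulated
#'   amplitudes are step-size-converged (see the methods vignette).
#' @param conserve_mass enforce the total-calcium invariant exactly at each
#'   substep by assigning the integrator's closure residual to the free SR
#'   pool (default TRUE).
#' @return A data.frame of class `muscle_sim` with columns `time_ms`,
#'   `CaSR`, `CaSRCS`, `Ca`, `CaB`, `CaT`, `A_tilde`, `C1`, `C2`, `A`,
#'   `Xm_mm`, `dXCE_mm`, `F_N`, plus metadata attributes (`params`,
#'   `protocol`, `dt_ms`, `settle_ms`, `scheme`).
#' @export
simulate_muscle <- function(p, proto, scheme = c("exp_midpoint", "cnexp",
                                                 "rk4"),
                            record_every = 1L, include_settle = FALSE,
                            engine = c("cpp", "r"), denom_floor = 1e-9,
                            clamp_negative_force = FALSE, substeps = 8L,
                            conserve_mass = TRUE) {
  stopifnot(inherits(p, "model_parameters"), inherits(proto, "protocol"))
  scheme <- match.arg(scheme)
  engine <- match.arg(engine)
  record_every <- max(1L, as.integer(record_every))
  substeps <- max(1L, as.integer(substeps))
  prm <- params_to_list(p)
  if (engine == "cpp") {
    m <- .sim_core(prm, as.numeric(proto$spikes),
                   proto$length$times, proto$length$values,
                   p$dt, proto$settle, proto$duration,
                   record_every, include_settle, scheme, denom_floor,
                   clamp_negative_force, substeps, conserve_mass)
  } else {
    m <- sim_core_r(prm, as.numeric(proto$spikes),
                    proto$length$times, proto$length$values,
                    p$dt, proto$settle, proto$duration,
                    record_every, include_settle, scheme, denom_floor,
                    clamp_negative_force, substeps, conserve_mass)
  }
  neg <- attr(m, "neg_force_steps")
  if (!is.null(neg) && neg > 0 && !clamp_negative_force)
    warning("series-elastic force went negative (slack) on ", neg,
            " recorded steps", call. = FALSE)
  df <- as.data.frame(m)
  names(df) <- c("time_ms", "CaSR", "CaSRCS", "Ca", "CaB", "CaT",
                 "A_tilde", "C1", "C2", "dXCE_mm", "A", "Xm_mm", "F_N")
  df <- df[, c("time_ms", "CaSR", "CaSRCS", "Ca", "CaB", "CaT",
               "A_tilde", "C1", "C2", "A", "Xm_mm", "dXCE_mm", "F_N")]
  attr(df, "params") <- p
  attr(df, "protocol") <- proto
  attr(df, "dt_ms") <- p$dt
  attr(df, "settle_ms") <- proto$settle
  attr(df, "scheme") <- scheme
  class(df) <- c("muscle_sim", "data.frame")
  df
}

#' @export
print.muscle_sim <- function(x, ...) {
  cat("<muscle_sim>", nrow(x), "samples,",
      format(min(x$time_ms)), "to", format(max(x$time_ms)), "ms\n")
  cat("  peak force:", format(max(x$F_N), digits = 5), "N | scheme:",
      attr(x, "scheme"), "| dt:", attr(x, "dt_ms"), "ms\n")
  invisible(x)
}

#' Isometric frequency sweep
#'
#' One isometric run per stimulation frequency at a fixed length.
#'
#' @param p a [model_parameters()] object.
#' @param freqs stimulation frequencies (Hz), nonempty.
#' @param Xm muscle-tendon length (mm).
#' @param duration simulated/stimulated duration (ms).
#' @param ... passed on to [simulate_muscle()].
#' @return A named list of `muscle_sim` objects (names = frequencies).
#' @export
frequency_sweep <- function(p, freqs, Xm, duration = 3000, ...) {
  if (!length(freqs)) stop("frequency_sweep: `freqs` must be nonempty",
                           call. = FALSE)
  out <- lapply(freqs, function(f)
    simulate_muscle(p, isometric_protocol(f, Xm, duration), ...))
  names(out) <- as.character(freqs)
  out
}

#' Total calcium inventory of a simulation
#'
#' CaSR + CaSRCS + Ca + CaB + m*CaT with stoichiometric weight m = 2 for the
#' two-site troponin variant. Conserved by the model equations; the relative
#' drift over a run measures integrator error.
#'
#' @param sim a `muscle_sim`.
#' @return Numeric vector (M), one value per sample.
#' @export
total_calcium <- function(sim) {
  p <- attr(sim, "params")
  m <- if (p$calcium$troponin_sites == "double") 2 else 1
  sim$CaSR + sim$CaSRCS + sim$Ca + sim$CaB + m * sim$CaT
}

#' Write a simulation trace to CSV (with JSON sidecar)
#'
#' @param sim a `muscle_sim`.
#' @param path output CSV path; a `.json` sidecar with the parameters and
#'   protocol is written next to it.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(sim, path, sidecar = TRUE) {
  write.csv(as.data.frame(sim), path, row.names = FALSE)
  if (sidecar) {
    p <- attr(sim, "params")
    proto <- attr(sim, "protocol")
    meta <- list(
      params = params_to_list(p),
      protocol = list(spike_times_ms = as.numeric(proto$spikes),
                      length_breakpoints_ms = proto$length$times,
                      length_values_mm = proto$length$values,
                      duration_ms = proto$duration,
                      settle_ms = proto$settle),
      dt_ms = attr(sim, "dt_ms"), scheme = attr(sim, "scheme"))
    jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a simulation trace written by [write_trace_csv()]
#'
#' @param path CSV path.
#' @return A data.frame with the trace columns (metadata attributes are not
#'   restored).
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  need <- c("time_ms", "F_N")
  if (!all(need %in% names(df)))
    stop("read_trace_csv: `", path, "` lacks required columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df
}
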