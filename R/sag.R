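# Sag quantification and classification from simulated force traces.
#
# Sag types (unfused isometric tetanus, envelope of per-interstimulus force
# peaks after the initial peak):
#   none - no decline beyond tolerance
#   I    - simple progressive decline
#   II   - decline with multiple recoveries (multiple force peaks)
#   III  - decline, one bounded recovery, second decline (ends below peak)
#   IV   - decline followed by amplification above the initial peak

#' Per-interstimulus force-peak envelope
#'
#' The maximum of the force trace within each interstimulus window
#' [t_i, t_{i+1}) (the last window extends to the end of the trace). Windows
#' before the first spike are excluded.
#'
#' @param trace a `muscle_sim` (or data.frame with `time_ms` and `F_N`).
#' @param freq stimulation frequency (Hz) of the constant-frequency
#'   protocol that produced the trace; defaults to the spike train stored
#'   with the trace.
#' @return A list of class `ripple_envelope` with `peak_times` (ms) and
#'   `peak_values` (N).
#' @export
ripple_envelope <- function(trace, freq = NULL) {
  spikes <- if (!is.null(freq)) {
    as.numeric(make_pulse_train(freq, max(trace$time_ms)))
  } else {
    proto <- attr(trace, "protocol")
    if (is.null(proto)) stop("ripple_envelope: supply `freq` for traces ",
                             "without an attached protocol", call. = FALSE)
    as.numeric(proto$spikes)
  }
  spikes <- spikes[spikes <= max(trace$time_ms)]
  if (length(spikes) < 3L)
    stop("ripple_envelope: need at least 3 spikes to form an envelope",
         call. = FALSE)
  edges <- c(spikes, max(trace$time_ms) + .Machine$double.eps)
  idx <- findInterval(trace$time_ms, edges)
  keep <- idx >= 1L & idx <= length(spikes)
  pv <- tapply(trace$F_N[keep], idx[keep], max)
  win <- as.integer(names(pv))
  tt <- vapply(seq_along(win), function(j) {
    w <- idx == win[j] & keep
    trace$time_ms[w][which.max(trace$F_N[w])]
  }, numeric(1))
  structure(list(peak_times = tt, peak_values = as.numeric(pv)),
            class = "ripple_envelope")
}

#' Classify sag behaviour from a force-peak envelope
#'
#' Locates the initial peak (first envelope point not exceeded within the
#' next two interstimulus intervals) and decomposes the envelope after it
#' into cumulative swings: a new phase is recorded whenever the envelope
#' retraces more than `rel_tol` times the initial peak from its running
#' extreme, so slow drifts spread over many interstimulus intervals still
#' register. The swing-sign pattern maps to: no significant declines ->
#' `none`; a single decline (`-`) -> `I`; decline then recovery (`-+`)
#' ending above the initial peak -> `IV`, otherwise (the recovery forms a
#' second, lower force peak) -> `II`, as do two or more recoveries;
#' decline, bounded recovery, second decline (`-+-`) -> `III`. A pattern
#' matching none of the rules is reported as `none` with the observed sign
#' pattern (never silently guessed).
#'
#' @param env a [ripple_envelope()] (or a bare numeric vector of envelope
#'   values, for which unit-spaced times are assumed).
#' @param rel_tol relative tolerance (fraction of the initial peak) below
#'   which an envelope difference counts as flat.
#' @return A list of class `sag_classification` with `sag_type` (factor:
#'   none/I/II/III/IV), `initial_peak`, `final_level`,
#'   `sag_magnitude` ((initial - final)/initial), and `sign_pattern`.
#' @export
classify_sag <- function(env, rel_tol = 0.01) {
  v <- if (inherits(env, "ripple_envelope")) env$peak_values else
    as.numeric(env)
  if (length(v) < 3L)
    stop("classify_sag: need at least 3 envelope points", call. = FALSE)
  n <- length(v)
  ip <- NA_integer_
  for (i in seq_len(n - 1L)) {
    ahead <- v[seq(i + 1L, min(n, i + 2L))]
    if (all(v[i] >= ahead)) { ip <- i; break }
  }
  if (is.na(ip)) ip <- which.max(v)  # envelope still rising at the end
  peak <- v[ip]
  final <- mean(v[seq(max(ip, n - max(1L, ceiling(0.1 * n)) + 1L), n)])
  mag <- (peak - final) / peak
  # cumulative swing (zigzag) decomposition: a phase reversal is recorded
  # when the envelope retraces more than rel_tol * peak from its running
  # extreme, so slow drifts spread over many intervals still register
  runs <- integer(0)
  dir <- 0L
  ext <- peak
  tol <- rel_tol * peak
  for (x in v[(ip + 1L):n]) {
    if (dir == 0L) {
      if (x >= ext + tol) { dir <- 1L; runs <- c(runs, 1L); ext <- x }
      else if (x <= ext - tol) { dir <- -1L; runs <- c(runs, -1L); ext <- x }
    } else if (dir == 1L) {
      if (x > ext) ext <- x
      else if (x <= ext - tol) { dir <- -1L; runs <- c(runs, -1L); ext <- x }
    } else {
      if (x < ext) ext <- x
      else if (x >= ext + tol) { dir <- 1L; runs <- c(runs, 1L); ext <- x }
    }
  }
  pattern <- paste(c("-1" = "-", "1" = "+")[as.character(runs)],
                   collapse = "")
  type <- if (!length(runs) || all(runs == 1L)) {
    "none"
  } else if (identical(runs, -1L)) {
    "I"
  } else if (identical(runs, c(-1L, 1L))) {
    if (v[n] > peak * (1 + rel_tol)) "IV" else "II"
  } else if (identical(runs, c(-1L, 1L, -1L))) {
    "III"
  } else if (length(runs) >= 4L && runs[1] == -1L &&
             sum(runs == 1L) >= 2L) {
    "II"
  } else {
    "none"
  }
  structure(list(sag_type = factor(type,
                                   levels = c("none", "I", "II", "III", "IV")),
                 initial_peak = peak, final_level = final,
                 sag_magnitude = mag, sign_pattern = pattern),
            class = "sag_classification")
}

#' @export
print.sag_classification <- function(x, ...) {
  cat("<sag_classification> type", as.character(x$sag_type),
      "| initial peak", format(x$initial_peak, digits = 5),
      "N | final", format(x$final_level, digits = 5),
      "N | magnitude", format(x$sag_magnitude, digits = 4),
      "| pattern", x$sign_pattern, "\n")
  invisible(x)
}

# Simulate one isometric run and classify its envelope.
simulate_and_classify <- function(p, freq, Xm, duration = 3000,
                                  rel_tol = 0.01, record_every = 4L, ...) {
  s <- simulate_muscle(p, isometric_protocol(freq, Xm, duration),
                       record_every = record_every, ...)
  cl <- classify_sag(ripple_envelope(s, freq), rel_tol = rel_tol)
  cl$freq <- freq
  cl$Xm <- Xm
  cl
}

#' Map of sag types over the C2 threshold/time-constant plane
#'
#' Runs one isometric simulation per (C2n2, C2n4) grid cell, all other
#' parameters fixed, and classifies the resulting envelope.
#'
#' @param p a [model_parameters()] object.
#' @param C2n2_grid values of the C2-drift threshold.
#' @param tauC2_grid values of the C2-drift time constant (ms).
#' @param freq stimulation frequency (Hz).
#' @param Xm muscle-tendon length (mm).
#' @param duration stimulated duration (ms).
#' @param rel_tol classification tolerance, see [classify_sag()].
#' @return A data.frame (class `sag_type_map`) with columns `C2n2`,
#'   `tau_C2`, `type`, `sag_magnitude`, `error` (NA unless the cell's
#'   simulation failed, in which case the message is recorded).
#' @export
sag_type_map <- function(p, C2n2_grid, tauC2_grid, freq = 20, Xm = 5,
                         duration = 3000, rel_tol = 0.01) {
  stopifnot(length(C2n2_grid) >= 1L, length(tauC2_grid) >= 1L)
  grid <- expand.grid(C2n2 = C2n2_grid, tau_C2 = tauC2_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pi <- override_parameters(p, list(activation = list(
      C2n2 = grid$C2n2[i], C2n4 = grid$tau_C2[i])))
    tryCatch({
      cl <- simulate_and_classify(pi, freq, Xm, duration, rel_tol)
      list(type = as.character(cl$sag_type), mag = cl$sag_magnitude,
           err = NA_character_)
    }, error = function(e)
      list(type = NA_character_, mag = NA_real_, err = conditionMessage(e)))
  })
  grid$type <- vapply(res, `[[`, character(1), "type")
  grid$sag_magnitude <- vapply(res, `[[`, numeric(1), "mag")
  grid$error <- vapply(res, `[[`, character(1), "err")
  class(grid) <- c("sag_type_map", "data.frame")
  grid
}

#' Length dependence of sag
#'
#' Isometric tetani at several muscle-tendon lengths, optionally with
#' per-length overrides of the C2-drift parameters (emulating the
#' length-dependent cooperativity reported from skinned fibres: stronger
#' slope potentiation when shortened, weaker or reversed when lengthened).
#'
#' @param p a [model_parameters()] object.
#' @param lengths muscle-tendon lengths (mm).
#' @param freq stimulation frequency (Hz).
#' @param c2_overrides_per_length optional list, same length as `lengths`,
#'   of activation-parameter override lists (e.g.
#'   `list(C2n1 = -0.06, C2n2 = 0.2)`), or NULL entries for no override.
#' @param duration stimulated duration (ms).
#' @param rel_tol classification tolerance.
#' @return A data.frame with `Xm`, `type`, `sag_magnitude`, `initial_peak`,
#'   `final_level`.
#' @export
length_dependence_experiment <- function(p, lengths, freq = 20,
                                         c2_overrides_per_length = NULL,
                                         duration = 3000, rel_tol = 0.01) {
  stopifnot(length(lengths) >= 1L)
  if (!is.null(c2_overrides_per_length))
    stopifnot(length(c2_overrides_per_length) == length(lengths))
  rows <- lapply(seq_along(lengths), function(i) {
    pi <- p
    ov <- c2_overrides_per_length[[i]]
    if (!is.null(ov)) pi <- override_parameters(p, list(activation = ov))
    cl <- simulate_and_classify(pi, freq, lengths[i], duration, rel_tol)
    data.frame(Xm = lengths[i], type = as.character(cl$sag_type),
               sag_magnitude = cl$sag_magnitude,
               initial_peak = cl$initial_peak, final_level = cl$final_level)
  })
  do.call(rbind, rows)
}

#' Normalized root-mean-square error between two force traces
#'
#' 100 * sqrt(mean((Fm - Fs)^2)) / |max(Fm) - min(Fm)|, in percent,
#' normalized by the measured trace's range.
#'
#' @param measured reference force series (N).
#' @param simulated comparison force series (N), same length.
#' @return NRMSE in percent.
#' @export
nrmse <- function(measured, simulated) {
  if (length(measured) != length(simulated) || length(measured) < 2L)
    stop("nrmse: series must have equal length >= 2", call. = FALSE)
  rng <- max(measured) - min(measured)
  if (rng == 0)
    stop("nrmse: measured series has zero range", call. = FALSE)
  100 * sqrt(mean((measured - simulated)^2)) / abs(rng)
}
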