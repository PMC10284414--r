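# Muscle-tendon length trajectories: piecewise-linear breakpoints with
# constant extrapolation outside the defined range.

new_length_trajectory <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 1L,
            all(is.finite(times)), all(is.finite(values)))
  if (is.unsorted(times, strictly = length(times) > 1L))
    stop("length_trajectory: breakpoint times must be strictly increasing",
         call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "length_trajectory")
}

#' Constant-length (isometric) trajectory
#'
#' @param Xm muscle-tendon length (mm).
#' @return A `length_trajectory`.
#' @export
length_constant <- function(Xm) new_length_trajectory(0, Xm)

#' Constant-velocity ramp trajectory
#'
#' Holds `Xm0` until `t_start`, changes at `velocity` until `t_end`, then
#' holds the final length.
#'
#' @param Xm0 initial length (mm).
#' @param velocity ramp velocity (mm/s; lengthening positive).
#' @param t_start,t_end ramp start and end times (ms), `t_end > t_start >= 0`.
#' @return A `length_trajectory`.
#' @export
length_ramp <- function(Xm0, velocity, t_start, t_end) {
  stopifnot(t_end > t_start, t_start >= 0)
  x1 <- Xm0 + velocity * (t_end - t_start) / 1000
  if (t_start > 0) new_length_trajectory(c(0, t_start, t_end), c(Xm0, Xm0, x1))
  else new_length_trajectory(c(0, t_end), c(Xm0, x1))
}

#' Step-length trajectory
#'
#' A rapid length step of amplitude `step` at time `at`, realized as a steep
#' linear ramp of duration `rise_ms` (a true discontinuity is not
#' representable with finite series-elastic force).
#'
#' @param Xm0 initial length (mm).
#' @param step step amplitude (mm; lengthening positive).
#' @param at step onset (ms, > 0).
#' @param rise_ms rise time of the step (ms).
#' @return A `length_trajectory`.
#' @export
length_step <- function(Xm0, step, at, rise_ms = 1) {
  stopifnot(at > 0, rise_ms > 0)
  new_length_trajectory(c(0, at, at + rise_ms), c(Xm0, Xm0, Xm0 + step))
}

#' Evaluate a length trajectory
#'
#' @param traj a `length_trajectory`.
#' @param t times (ms); vectorized.
#' @return Xm(t) in mm, with constant extrapolation beyond the breakpoints.
#' @export
trajectory_eval <- function(traj, t) {
  stopifnot(inherits(traj, "length_trajectory"))
  if (length(traj$times) == 1L) return(rep(traj$values, length(t)))
  stats::approx(traj$times, traj$values, xout = t, rule = 2)$y
}
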