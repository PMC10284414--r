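# Module 1: SR/sarcoplasm calcium kinetics.
#
# State (all M): CaSR (free SR calcium), CaSRCS (calsequestrin-bound SR
# calcium), Ca (free sarcoplasmic calcium), CaB (buffer-bound), CaT
# (troponin-bound; stores [Ca2T] in the two-site variant).

#' Construct a calcium state
#'
#' @param CaSR,CaSRCS,Ca,CaB,CaT species concentrations (M); `CaT` holds
#'   the doubly-occupied troponin concentration in the two-site variant.
#' @return A named numeric vector of class `calcium_state`.
#' @export
calcium_state <- function(CaSR, CaSRCS = 0, Ca = 0, CaB = 0, CaT = 0) {
  s <- c(CaSR = CaSR, CaSRCS = CaSRCS, Ca = Ca, CaB = CaB, CaT = CaT)
  if (any(!is.finite(s)) || any(s < 0))
    stop("calcium_state: all concentrations must be finite and >= 0",
         call. = FALSE)
  class(s) <- "calcium_state"
  s
}

#' Construct a spike train
#'
#' @param times stimulus times (ms), strictly increasing, all >= 0; may be
#'   empty.
#' @return A numeric vector of class `spike_train`.
#' @export
spike_train <- function(times = numeric()) {
  times <- as.numeric(times)
  if (length(times)) {
    if (any(!is.finite(times)) || any(times < 0))
      stop("spike_train: times must be finite and >= 0", call. = FALSE)
    if (any(diff(times) <= 0))
      stop("spike_train: times must be strictly increasing", call. = FALSE)
  }
  structure(times, class = "spike_train")
}

#' SR calcium release rate
#'
#' Spike-triggered release: each past spike contributes a kernel
#' (1 - exp(-(t - t_i)/tau1)) * exp(-(t - t_i)/tau2); the sum is scaled by
#' the instantaneous free SR calcium and `Rmax`. Spikes with t_i > t
#' contribute zero (a spike cannot act before it occurs).
#'
#' @param t time (ms).
#' @param spikes a [spike_train()].
#' @param CaSR free SR calcium (M).
#' @param p a [calcium_params()] object.
#' @return Release rate (M/ms), >= 0.
#' @export
release_rate <- function(t, spikes, CaSR, p) {
  stopifnot(t >= 0, CaSR >= 0)
  CaSR * p$Rmax * release_kernel_sum(t, as.numeric(spikes), p$tau1, p$tau2)
}

# Sum of per-spike release kernels at time t (dimensionless).
release_kernel_sum <- function(t, times, tau1, tau2) {
  s <- t - times[times <= t]
  if (!length(s)) return(0)
  sum((1 - exp(-s / tau1)) * exp(-s / tau2))
}

#' SR calcium uptake rate
#'
#' Saturable pump uptake
#' U = Umax * (Ca^2 K^2 / (1 + Ca K + Ca^2 K^2))^2, monotone in Ca and
#' bounded by `Umax`.
#'
#' @param Ca free sarcoplasmic calcium (M), >= 0.
#' @param p a [calcium_params()] object.
#' @return Uptake rate (M/ms) in [0, Umax].
#' @export
uptake_rate <- function(Ca, p) {
  stopifnot(all(Ca >= 0))
  ck <- Ca * p$K
  q <- ck^2 / (1 + ck + ck^2)
  p$Umax * q^2
}

#' Length-modulated troponin on-rate
#'
#' K5 = K5i * phi(Xm), with phi piecewise linear in the muscle-tendon length:
#' phi1*Xm + phi2 below the intermediate length, phi3*Xm + phi4 at or above
#' it. With `k5_length_dependent = FALSE` the default `K5i` is returned for
#' any length.
#'
#' @param Xm muscle-tendon length (mm); values outside `[Xm_min, Xm_max]`
#'   are allowed but unusual.
#' @param p a [calcium_params()] object.
#' @param Xm_half intermediate length (mm) splitting the two branches.
#' @return Effective K5 (same units as `K5i`).
#' @export
k5_effective <- function(Xm, p, Xm_half = 5) {
  if (!p$k5_length_dependent) return(rep(p$K5i, length(Xm)))
  phi <- ifelse(Xm < Xm_half, p$phi1 * Xm + p$phi2, p$phi3 * Xm + p$phi4)
  p$K5i * phi
}

#' Activation-modulated troponin off-rate
#'
#' K6 = K6i / (1 + gain * A~), reflecting the increased troponin affinity for
#' calcium with crossbridge attachment. With
#' `k6_activation_dependent = FALSE` the default `K6i` is returned; the gain
#' (default 5) halves to 2.5 for the "half dependence" variant.
#'
#' @param A_tilde scaled activation in [0, 1].
#' @param p a [calcium_params()] object.
#' @return Effective K6 (1/ms).
#' @export
k6_effective <- function(A_tilde, p) {
  stopifnot(all(A_tilde >= 0), all(A_tilde <= 1))
  if (!p$k6_activation_dependent) return(rep(p$K6i, length(A_tilde)))
  p$K6i / (1 + p$k6_activation_gain * A_tilde)
}

#' Time derivatives of the calcium state
#'
#' Mass-action kinetics of the five calcium pools. For single-site troponin
#' the troponin terms are first order in Ca; the two-site variant
#' (`troponin_sites = "double"`) replaces them with the 2Ca + T = Ca2T
#' scheme (second order in Ca, stoichiometric weight 2 on Ca2T). The
#' weighted total calcium CaSR + CaSRCS + Ca + CaB + m*CaT (m = 1 or 2) is
#' conserved exactly.
#'
#' @param s a [calcium_state()].
#' @param t time (ms).
#' @param spikes a [spike_train()].
#' @param Xm muscle-tendon length (mm).
#' @param A_tilde scaled activation in [0, 1].
#' @param p a [calcium_params()] object.
#' @param Xm_half intermediate length (mm) for the K5 modulation.
#' @return Named numeric vector of rates (M/ms) for the five pools.
#' @export
calcium_derivatives <- function(s, t, spikes, Xm, A_tilde, p, Xm_half = 5) {
  K5 <- k5_effective(Xm, p, Xm_half)
  K6 <- k6_effective(A_tilde, p)
  R <- release_rate(t, spikes, s[["CaSR"]], p)
  U <- uptake_rate(s[["Ca"]], p)
  CaSR <- s[["CaSR"]]; CaSRCS <- s[["CaSRCS"]]
  Ca <- s[["Ca"]]; CaB <- s[["CaB"]]; CaT <- s[["CaT"]]
  dCaSR <- -p$K1 * p$CS0 * CaSR + (p$K1 * CaSR + p$K2) * CaSRCS - R + U
  dCaSRCS <- p$K1 * p$CS0 * CaSR - (p$K1 * CaSR + p$K2) * CaSRCS
  dCaB <- p$K3 * p$B0 * Ca - (p$K3 * Ca + p$K4) * CaB
  if (p$troponin_sites == "single") {
    dCa <- -(p$K3 * p$B0 + K5 * p$T0) * Ca +
      (p$K3 * Ca + p$K4) * CaB + (K5 * Ca + K6) * CaT + R - U
    dCaT <- K5 * p$T0 * Ca - (K5 * Ca + K6) * CaT
  } else {
    dCa <- -(p$K3 * p$B0 + 2 * K5 * p$T0 * Ca) * Ca +
      (p$K3 * Ca + p$K4) * CaB + (2 * K5 * Ca^2 + 2 * K6) * CaT + R - U
    dCaT <- K5 * p$T0 * Ca^2 - (K5 * Ca^2 + K6) * CaT
  }
  c(CaSR = dCaSR, CaSRCS = dCaSRCS, Ca = dCa, CaB = dCaB, CaT = dCaT)
}

#' Half-activation calcium concentration of the troponin reaction
#'
#' The free-calcium level at which half the troponin is bound at
#' steady state: K6i/K5i for single-site binding and sqrt(K6i/K5i) for the
#' two-site scheme.
#'
#' @param p a [calcium_params()] object.
#' @return Ca50 (M).
#' @export
ca50 <- function(p) {
  if (p$troponin_sites == "single") p$K6i / p$K5i else sqrt(p$K6i / p$K5i)
}
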