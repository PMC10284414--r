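# Module 2: dynamically drifting sigmoid calcium-activation relationship.

#' Steady-state activation sigmoid
#'
#' A~inf = 0.5 * (1 + tanh((r - C1)/C2)): strictly increasing in the
#' bound-troponin fraction r, midpoint C1, analytic slope 1/(2*C2) at r = C1.
#'
#' @param r bound-troponin fraction CaT/T0.
#' @param C1 sigmoid midpoint.
#' @param C2 inverse-slope parameter (> 0).
#' @return Steady-state scaled activation in (0, 1).
#' @export
a_inf <- function(r, C1, C2) {
  stopifnot(C2 > 0)
  0.5 * (1 + tanh((r - C1) / C2))
}

#' Activation time constant
#'
#' tau = C3 / cosh((r - C4) / (2 * C5)); maximal (= C3) at r = C4 and
#' symmetric about it.
#'
#' @param r bound-troponin fraction.
#' @param C3 maximal time constant (ms, > 0).
#' @param C4 centre of the cosh dependence.
#' @param C5 width parameter (nonzero).
#' @return Time constant (ms) in (0, C3].
#' @export
tau_a <- function(r, C3, C4, C5) {
  stopifnot(C3 > 0, C5 != 0)
  C3 / cosh((r - C4) / (2 * C5))
}

#' Steady-state target of the drifting C1/C2 parameters
#'
#' CXinf = CXn1 * (1 + tanh((r - CXn2)/CXn3)) + CXi. With `CXn1 = 0` the
#' target is the constant `CXi` (static calcium-force relationship).
#'
#' @param r bound-troponin fraction.
#' @param CXn1 saturation amplitude (half the full swing).
#' @param CXn2 threshold (fraction of T0).
#' @param CXn3 threshold sharpness (nonzero).
#' @param CXi resting value.
#' @return The steady-state target value.
#' @export
cx_inf <- function(r, CXn1, CXn2, CXn3, CXi) {
  stopifnot(CXn3 != 0)
  CXn1 * (1 + tanh((r - CXn2) / CXn3)) + CXi
}

#' Construct an activation state
#'
#' @param A_tilde scaled activation in [0, 1].
#' @param C1,C2 current (drifting) midpoint and inverse slope; C2 > 0.
#' @return Named numeric vector of class `activation_state`.
#' @export
activation_state <- function(A_tilde = 0, C1, C2) {
  if (A_tilde < 0 || A_tilde > 1)
    stop("activation_state: A_tilde must be in [0, 1]", call. = FALSE)
  if (C2 <= 0) stop("activation_state: C2 must be > 0", call. = FALSE)
  structure(c(A_tilde = A_tilde, C1 = C1, C2 = C2),
            class = "activation_state")
}

# Floor applied to the drifting C2 before it enters the sigmoid; guards the
# tanh argument if a parameter sweep drives C2inf <= 0 (possible: C2n1 < 0).
.C2_FLOOR <- 1e-6

#' Time derivatives of the activation state
#'
#' First-order relaxation of A~ toward [a_inf()] evaluated with the *current*
#' drifting C1 and C2, and of C1/C2 toward their [cx_inf()] targets with time
#' constants C1n4 and C2n4.
#'
#' @param s an [activation_state()].
#' @param r bound-troponin fraction CaT/T0.
#' @param p an [activation_params()] object.
#' @return Named numeric vector of rates (1/ms) for `A_tilde`, `C1`, `C2`.
#' @export
activation_derivatives <- function(s, r, p) {
  C2 <- max(s[["C2"]], .C2_FLOOR)
  dA <- (a_inf(r, s[["C1"]], C2) - s[["A_tilde"]]) / tau_a(r, p$C3, p$C4, p$C5)
  dC1 <- (cx_inf(r, p$C1n1, p$C1n2, p$C1n3, p$C1i) - s[["C1"]]) / p$C1n4
  dC2 <- (cx_inf(r, p$C2n1, p$C2n2, p$C2n3, p$C2i) - s[["C2"]]) / p$C2n4
  c(A_tilde = dA, C1 = dC1, C2 = dC2)
}

#' Crossbridge activation from scaled activation
#'
#' A = A~^alpha; with alpha >= 1 this de-emphasizes submaximal A~.
#'
#' @param A_tilde scaled activation in [0, 1].
#' @param alpha activation exponent (> 0).
#' @return Activation A in [0, 1].
#' @export
activation_output <- function(A_tilde, alpha) {
  stopifnot(alpha > 0, all(A_tilde >= 0), all(A_tilde <= 1))
  A_tilde^alpha
}
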