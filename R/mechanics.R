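# Module 3: series-elastic force, modified Hill-Mashima contractile-element
# velocity, length-tension scaling, and analytic calibration from printed
# length-tension / velocity-tension data points.

#' Length-tension scaling factor
#'
#' g(Xm) = g1*Xm^2 + g2*Xm + g3, the dimensionless scaling of the peak force
#' P0.5 with muscle-tendon length.
#'
#' @param Xm muscle-tendon length (mm); vectorized.
#' @param p a [mechanics_params()] object.
#' @return g(Xm), dimensionless.
#' @export
length_tension <- function(Xm, p) {
  g <- p$g1 * Xm^2 + p$g2 * Xm + p$g3
  if (any(g <= 0))
    warning("length_tension: g(Xm) <= 0 at some requested lengths")
  g
}

#' Series-elastic force
#'
#' F = P0.5 * K_SE * (dXm - dXCE): the series element transmits force in
#' proportion to its stretch, the difference between whole-unit and
#' contractile-element length changes.
#'
#' @param dXm muscle-tendon length change from the reference (mm).
#' @param dXCE contractile-element length change (mm, shortening negative).
#' @param p a [mechanics_params()] object.
#' @return Force (N).
#' @export
series_force <- function(dXm, dXCE, p) {
  p$P0_5 * p$K_SE * (dXm - dXCE)
}

#' Contractile-element velocity (modified Hill-Mashima)
#'
#' Signed CE velocity given the transmitted force, length and activation.
#' Concentric branch (F <= P0.5*g*A):
#' v = -b0*(P0.5*g*A - F)/(F + a0*g*A); eccentric branch (F > P0.5*g*A):
#' v = -d0*(P0.5*g*A - F)/(2*P0.5*g*A - F + c0*g*A). Both branches vanish at
#' the isometric point F = P0.5*g*A, so the rate is continuous there.
#' Shortening is negative.
#'
#' @param F transmitted force (N).
#' @param Xm muscle-tendon length (mm).
#' @param A crossbridge activation in [0, 1].
#' @param p a [mechanics_params()] object.
#' @param denom_floor smallest admissible branch-denominator magnitude (N);
#'   smaller values signal an operating point outside the calibrated regime.
#' @return CE velocity (mm/s).
#' @export
xce_rate <- function(F, Xm, A, p, denom_floor = 1e-9) {
  stopifnot(A >= -1e-12, A <= 1 + 1e-12)
  gA <- length_tension(Xm, p) * A
  m <- p$P0_5 * gA
  if (abs(m - F) < .Machine$double.eps * max(1, abs(F)))
    return(0)  # isometric equilibrium, both branches have zero numerator
  if (abs(m) < 1e-6 * p$P0_5 && abs(F) < 1e-6 * p$P0_5)
    return(0)  # fully relaxed and slack: branch formulas approach 0/0
  if (F <= m) {
    den <- F + p$a0 * gA
    if (abs(den) < denom_floor)
      stop("xce_rate: concentric-branch denominator below floor (F = ",
           signif(F, 6), " N)", call. = FALSE)
    -p$b0 * (m - F) / den
  } else {
    den <- 2 * m - F + p$c0 * gA
    if (abs(den) < denom_floor)
      stop("xce_rate: eccentric-branch denominator below floor (F = ",
           signif(F, 6), " N)", call. = FALSE)
    -p$d0 * (m - F) / den
  }
}

#' Analytic Hill-Mashima coefficients from four velocity-tension points
#'
#' Given two shortening points (velocity < 0) and two lengthening points
#' (velocity > 0) on the velocity-tension curve at full excitation, returns
#' the coefficients (a0, b0, c0, d0) that make the Hill-Mashima rate pass
#' through all four points. Within each pair the smaller-magnitude velocity
#' plays the role of the first point. The eccentric offset c0 uses the
#' denominator V_L1*(P0.5 - T_L2) - V_L2*(P0.5 - T_L1); this (rather than a
#' variant grouping sometimes seen in print, which is dimensionally
#' inconsistent) reproduces the reference coefficient tables.
#'
#' @param shortening data.frame/list with `velocity` (mm/s, negative) and
#'   `tension` (N), two rows.
#' @param lengthening same, with positive velocities, two rows.
#' @param P0_5 peak isometric force at the intermediate length (N).
#' @return Named list with `a0`, `c0` (N) and `b0`, `d0` (mm/s).
#' @export
hill_mashima_inverse <- function(shortening, lengthening, P0_5) {
  sh <- as.data.frame(shortening); le <- as.data.frame(lengthening)
  stopifnot(nrow(sh) == 2L, nrow(le) == 2L, P0_5 > 0,
            all(sh$velocity < 0), all(le$velocity > 0),
            all(sh$tension >= 0), all(le$tension >= 0))
  sh <- sh[order(abs(sh$velocity)), ]  # V_S1 = smaller magnitude
  le <- le[order(abs(le$velocity)), ]
  vs1 <- sh$velocity[1]; ts1 <- sh$tension[1]
  vs2 <- sh$velocity[2]; ts2 <- sh$tension[2]
  vl1 <- le$velocity[1]; tl1 <- le$tension[1]
  vl2 <- le$velocity[2]; tl2 <- le$tension[2]
  if (vs1 == vs2 || vl1 == vl2)
    stop("hill_mashima_inverse: velocities within a pair must be distinct",
         call. = FALSE)
  den_a <- vs2 * (P0_5 - ts1) - vs1 * (P0_5 - ts2)
  den_b <- vs1 * (P0_5 - ts2) - vs2 * (P0_5 - ts1)
  den_c <- vl1 * (P0_5 - tl2) - vl2 * (P0_5 - tl1)
  den_d <- vl2 * (P0_5 - tl1) - vl1 * (P0_5 - tl2)
  if (any(abs(c(den_a, den_c)) < 1e-12))
    stop("hill_mashima_inverse: degenerate point configuration ",
         "(zero denominator)", call. = FALSE)
  a0 <- (vs1 * ts1 * (P0_5 - ts2) - vs2 * ts2 * (P0_5 - ts1)) / den_a
  b0 <- vs2 * vs1 * (ts1 - ts2) / den_b
  c0 <- ((2 * vl2 * P0_5 - vl2 * tl2) * (P0_5 - tl1) +
           (vl1 * tl1 - 2 * vl1 * P0_5) * (P0_5 - tl2)) / den_c
  d0 <- vl1 * vl2 * (tl1 - tl2) / den_d
  list(a0 = a0, b0 = b0, c0 = c0, d0 = d0)
}

#' Fit the length-tension quadratic through three points
#'
#' Least-squares quadratic of tension/P0.5 against Xm; with exactly three
#' distinct lengths this is exact interpolation.
#'
#' @param points data.frame/list with `Xm` (mm) and `tension` (N); three
#'   rows (more are accepted and fitted by least squares).
#' @param P0_5 normalizing peak force (N).
#' @return Named list with `g1`, `g2`, `g3`.
#' @export
fit_length_tension <- function(points, P0_5) {
  pts <- as.data.frame(points)
  stopifnot(nrow(pts) >= 3L, P0_5 > 0, all(pts$tension >= 0))
  if (anyDuplicated(pts$Xm))
    stop("fit_length_tension: Xm values must be distinct", call. = FALSE)
  y <- pts$tension / P0_5
  fit <- lm(y ~ poly(Xm, 2, raw = TRUE), data = pts)
  cf <- unname(coef(fit))
  list(g1 = cf[3], g2 = cf[2], g3 = cf[1])
}

#' Series-elastic stiffness from a quick-stretch measurement
#'
#' K_SE = (delta_F / delta_X) / P0.5: force change per length change,
#' normalized by the peak force.
#'
#' @param delta_F force difference (N, > 0).
#' @param delta_X length difference (mm, > 0).
#' @param P0_5 peak force (N, > 0).
#' @return Normalized stiffness (1/mm).
#' @export
estimate_kse <- function(delta_F, delta_X, P0_5) {
  if (!(delta_F > 0 && delta_X > 0 && P0_5 > 0))
    stop("estimate_kse: all inputs must be positive", call. = FALSE)
  (delta_F / delta_X) / P0_5
}
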