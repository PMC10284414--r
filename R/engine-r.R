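# Reference R implementation of the fixed-step core. Mirrors the compiled
# stepper state-for-state; used to cross-check the compiled engine on short
# runs (it is orders of magnitude slower).

sim_core_r <- function(prm, spikes, traj_t, traj_x, dt, settle, duration,
                       record_every, include_settle, scheme, denom_floor,
                       clamp_negative_force, substeps = 1L,
                       conserve_mass = TRUE) {
  ca <- prm$calcium; ac <- prm$activation; me <- prm$mechanics
  two_site <- ca$troponin_sites == "double"
  n_settle <- round(settle / dt)
  n_main <- round(duration / dt)

  traj <- function(t) {
    if (length(traj_t) == 1L) return(traj_x)
    stats::approx(traj_t, traj_x, xout = t, rule = 2)$y
  }
  xm_ref <- traj(0)

  uptake <- function(Ca) {
    u <- Ca * ca$K
    q <- u^2 / (1 + u + u^2)
    ca$Umax * q^2
  }
  duptake <- function(Ca) {
    u <- Ca * ca$K
    D <- 1 + u + u^2
    q <- u^2 / D
    ca$Umax * 2 * q * ca$K * (2 * u + u^2) / D^2
  }

  deriv <- function(t, y, settling) {
    CaSR <- y[1]; CaSRCS <- y[2]; Ca <- y[3]; CaB <- y[4]; CaT <- y[5]
    At <- y[6]; C1 <- y[7]; C2 <- y[8]; x <- y[9]
    Xm <- if (settling) traj(0) else traj(t)
    dXm <- if (settling) 0 else Xm - xm_ref
    S <- if (settling) 0 else
      release_kernel_sum(t, spikes, ca$tau1, ca$tau2)
    R <- CaSR * ca$Rmax * S
    U <- uptake(Ca); dU <- duptake(Ca)
    Atc <- min(1, max(0, At))
    K5 <- if (ca$k5_length_dependent) {
      phi <- if (Xm < me$Xm_half) ca$phi1 * Xm + ca$phi2
             else ca$phi3 * Xm + ca$phi4
      ca$K5i * phi
    } else ca$K5i
    K6 <- if (ca$k6_activation_dependent)
      ca$K6i / (1 + ca$k6_activation_gain * Atc) else ca$K6i

    f <- b <- numeric(9)
    f[1] <- -ca$K1 * ca$CS0 * CaSR + (ca$K1 * CaSR + ca$K2) * CaSRCS - R + U
    b[1] <- ca$K1 * ca$CS0 - ca$K1 * CaSRCS + ca$Rmax * S
    f[2] <- ca$K1 * ca$CS0 * CaSR - (ca$K1 * CaSR + ca$K2) * CaSRCS
    b[2] <- ca$K1 * CaSR + ca$K2
    f[4] <- ca$K3 * ca$B0 * Ca - (ca$K3 * Ca + ca$K4) * CaB
    b[4] <- ca$K3 * Ca + ca$K4
    if (!two_site) {
      f[3] <- -(ca$K3 * ca$B0 + K5 * ca$T0) * Ca +
        (ca$K3 * Ca + ca$K4) * CaB + (K5 * Ca + K6) * CaT + R - U
      b[3] <- (ca$K3 * ca$B0 + K5 * ca$T0) - ca$K3 * CaB - K5 * CaT + dU
      f[5] <- K5 * ca$T0 * Ca - (K5 * Ca + K6) * CaT
      b[5] <- K5 * Ca + K6
    } else {
      f[3] <- -(ca$K3 * ca$B0 + 2 * K5 * ca$T0 * Ca) * Ca +
        (ca$K3 * Ca + ca$K4) * CaB + (2 * K5 * Ca^2 + 2 * K6) * CaT + R - U
      b[3] <- ca$K3 * ca$B0 + 4 * K5 * ca$T0 * Ca - ca$K3 * CaB -
        4 * K5 * Ca * CaT + dU
      f[5] <- K5 * ca$T0 * Ca^2 - (K5 * Ca^2 + K6) * CaT
      b[5] <- K5 * Ca^2 + K6
    }
    r <- CaT / ca$T0
    C2c <- max(C2, 1e-6)
    ainf <- 0.5 * (1 + tanh((r - C1) / C2c))
    tau <- ac$C3 / cosh((r - ac$C4) / (2 * ac$C5))
    f[6] <- (ainf - At) / tau; b[6] <- 1 / tau
    f[7] <- (cx_inf(r, ac$C1n1, ac$C1n2, ac$C1n3, ac$C1i) - C1) / ac$C1n4
    b[7] <- 1 / ac$C1n4
    f[8] <- (cx_inf(r, ac$C2n1, ac$C2n2, ac$C2n3, ac$C2i) - C2) / ac$C2n4
    b[8] <- 1 / ac$C2n4
    FF <- me$P0_5 * me$K_SE * (dXm - x)
    A <- Atc^ac$alpha
    g <- me$g1 * Xm^2 + me$g2 * Xm + me$g3
    gA <- g * A; m <- me$P0_5 * gA
    if (abs(m - FF) < 1e-14 * max(1, abs(FF)) ||
        (abs(m) < 1e-6 * me$P0_5 && abs(FF) < 1e-6 * me$P0_5)) {
      v <- 0; dvdF <- 0
    } else if (FF <= m) {
      den <- FF + me$a0 * gA
      if (abs(den) < denom_floor)
        stop("concentric-branch denominator below floor at t = ", t,
             call. = FALSE)
      v <- -me$b0 * (m - FF) / den
      dvdF <- me$b0 * (m + me$a0 * gA) / den^2
    } else {
      den <- 2 * m - FF + me$c0 * gA
      if (abs(den) < denom_floor)
        stop("eccentric-branch denominator below floor at t = ", t,
             call. = FALSE)
      v <- -me$d0 * (m - FF) / den
      dvdF <- me$d0 * (m + me$c0 * gA) / den^2
    }
    f[9] <- v / 1000
    b[9] <- dvdF * me$P0_5 * me$K_SE / 1000
    list(f = f, b = b)
  }

  y <- c(ca$CaSR_init, 0, 0, 0, 0, 0, ac$C1i, ac$C2i, 0)
  h <- dt / substeps
  mass_w <- if (two_site) 2 else 1
  total0 <- ca$CaSR_init
  first_rec <- if (include_settle) -n_settle else 0
  ks <- seq(first_rec, n_main, by = record_every)
  if (ks[length(ks)] != n_main) ks <- c(ks, n_main)
  out <- matrix(NA_real_, nrow = length(ks), ncol = 13)
  row <- 1L

  for (k in seq(-n_settle, n_main)) {
    settling <- k < 0
    t <- k * dt
    if (any(!is.finite(y)))
      stop("non-finite state at t = ", t, call. = FALSE)
    if (k %in% ks) {
      Xm <- if (settling) traj(0) else traj(t)
      dXm <- if (settling) 0 else Xm - xm_ref
      FF <- me$P0_5 * me$K_SE * (dXm - y[9])
      if (FF < 0 && clamp_negative_force) FF <- 0
      Atc <- min(1, max(0, y[6]))
      out[row, ] <- c(t, y, Atc^ac$alpha, Xm, FF)
      row <- row + 1L
    }
    if (k == n_main) break
    exp_update <- function(y, f, b, hh) {
      ifelse(abs(b) * hh > 1e-12,
             (y + f / b) + (-f / b) * exp(-b * hh),
             y + f * hh)
    }
    for (ss in seq_len(substeps)) {
      ts <- t + (ss - 1) * h
      if (scheme == "exp_midpoint") {
        d1 <- deriv(ts, y, settling)
        yh <- exp_update(y, d1$f, d1$b, h / 2)
        d2 <- deriv(ts + h / 2, yh, settling)
        f_eff <- d2$f + d2$b * (yh - y)
        y <- exp_update(y, f_eff, d2$b, h)
      } else if (scheme == "cnexp") {
        d <- deriv(ts, y, settling)
        y <- exp_update(y, d$f, d$b, h)
      } else {
        d1 <- deriv(ts, y, settling)$f
        d2 <- deriv(ts + h / 2, y + h / 2 * d1, settling)$f
        d3 <- deriv(ts + h / 2, y + h / 2 * d2, settling)$f
        d4 <- deriv(ts + h, y + h * d3, settling)$f
        y <- y + h / 6 * (d1 + 2 * d2 + 2 * d3 + d4)
      }
      if (conserve_mass)
        y[1] <- total0 - (y[2] + y[3] + y[4] + mass_w * y[5])
      y[6] <- min(1, max(0, y[6]))
    }
  }
  out
}
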