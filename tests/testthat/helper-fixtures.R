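# Frozen reference parameter table (printed values) used across tests.
table1 <- list(
  CAT14 = list(
    calcium = c(K1 = 3000, K2 = 3, K3 = 400, K4 = 1, K5i = 4e5, K6i = 150,
                K = 850, Rmax = 10, Umax = 2000, tau1 = 1, tau2 = 13,
                phi1 = 0.004, phi2 = 0.98, phi3 = 0.0002, phi4 = 0.999,
                CS0 = 0.03, B0 = 4.3e-4, T0 = 7e-5, CaSR_init = 2.5e-3),
    activation = c(C1i = 0.154, C1n1 = 0.01, C1n2 = 0.15, C1n3 = 0.01,
                   C1n4 = 85, C2i = 0.11, C2n1 = -0.0315, C2n2 = 0.27,
                   C2n3 = 0.015, C2n4 = 70, C3 = 54.717, C4 = -18.847,
                   C5 = 3.905, alpha = 1.65),
    mechanics = c(K_SE = 0.16, P0_5 = 100.3, g1 = -0.0045, g2 = 0.0981,
                  g3 = 0.6211, a0 = 0.4, b0 = 99.7, c0 = -57.1, d0 = 42.2)),
  CAT12 = list(
    calcium = c(K1 = 3000, K2 = 3, K3 = 400, K4 = 1, K5i = 4e5, K6i = 150,
                K = 850, Rmax = 10, Umax = 2000, tau1 = 12, tau2 = 19.9,
                phi1 = 0.0716, phi2 = 0.7394, phi3 = 0.0305, phi4 = 0.8889,
                CS0 = 0.03, B0 = 4.3e-4, T0 = 7e-5, CaSR_init = 2.5e-3),
    activation = c(C1i = 0.159, C1n1 = 0.0032, C1n2 = 0.0094,
                   C1n3 = 0.0083, C1n4 = 600, C2i = 0.109, C2n1 = -0.0435,
                   C2n2 = 0.315, C2n3 = 0.024, C2n4 = 80, C3 = 54.717,
                   C4 = -18.847, C5 = 3.095, alpha = 1.5),
    mechanics = c(K_SE = 0.35, P0_5 = 17.5, g1 = 0.0003, g2 = 0.1637,
                  g3 = 0.4002, a0 = -34.675, b0 = -130.31, c0 = -57.86,
                  d0 = -202.78)))

# Mechanics parameter set with a flat unit length-tension curve (g = 1
# at every length), used to evaluate the force-velocity branch formulas at
# the printed operating points.
unit_g_mechanics <- function(animal = "CAT14") {
  m <- table1[[animal]]$mechanics
  mechanics_params(K_SE = m[["K_SE"]], P0_5 = m[["P0_5"]],
                   g1 = 0, g2 = 0, g3 = 1,
                   a0 = m[["a0"]], b0 = m[["b0"]],
                   c0 = m[["c0"]], d0 = m[["d0"]])
}

# Short isometric protocol used by engine tests.
short_protocol <- function(freq = 20, Xm = 5, duration = 400, settle = 200) {
  protocol(make_pulse_train(freq, duration), length_constant(Xm),
           duration = duration, settle = settle)
}

sim_classify <- function(p, freq, Xm = 5, duration = 3000, ...) {
  s <- simulate_muscle(p, protocol(make_pulse_train(freq, duration),
                                   length_constant(Xm), duration = duration),
                       record_every = 4L, ...)
  classify_sag(ripple_envelope(s, freq))
}
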