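#' @useDynLib fastmuscle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm lm coef setNames
#' @importFrom utils write.csv read.csv modifyList packageVersion
NULL

# ---- constructors -----------------------------------------------------------

#' Calcium-kinetics parameters (Module 1)
#'
#' Rate constants and pool sizes for sarcoplasmic-reticulum (SR) calcium
#' handling: calsequestrin buffering inside the SR, spike-triggered release,
#' saturable pump uptake, cytosolic buffering by soluble proteins, and
#' calcium-troponin binding modulated by muscle-tendon length and activation.
#'
#' Units follow the source data: concentrations in M, time in ms, length in
#' mm. Second-order rate constants are 1/(M*ms) for single-site troponin and
#' 1/(M^2*ms) for the two-site (`troponin_sites = "double"`) variant.
#'
#' @param K1,K2 forward (1/(M*ms)) and backward (1/ms) rates of the
#'   CaSR + CS reaction inside the SR.
#' @param K3,K4 forward/backward rates of cytosolic buffering (Ca + B).
#' @param K5i,K6i default forward/backward rates of the calcium-troponin
#'   reaction; `K5i` is modulated by length (see [k5_effective()]) and `K6i`
#'   by activation (see [k6_effective()]).
#' @param K association constant (1/M) of calcium binding to the uptake pump.
#' @param Rmax maximal release rate scale (1/ms).
#' @param Umax maximal uptake rate (M/ms).
#' @param tau1,tau2 rise/decay time constants (ms) of the release kernel.
#' @param phi1,phi2,phi3,phi4 piecewise-linear length modulation of K5:
#'   slope (1/mm) and intercept below and at/above the intermediate length.
#' @param CS0,B0,T0 total calsequestrin, buffer and troponin pools (M).
#' @param CaSR_init initial free SR calcium (M).
#' @param troponin_sites `"single"` (Ca + T = CaT) or `"double"`
#'   (2Ca + T = Ca2T).
#' @param k5_length_dependent,k6_activation_dependent logical toggles for the
#'   K5(Xm) and K6(A~) modulations.
#' @param k6_activation_gain gain of the activation dependence of K6
#'   (K6 = K6i / (1 + gain * A~)); 5 by default, 2.5 for "half dependence".
#' @return An object of class `calcium_params`.
#' @export
calcium_params <- function(K1, K2, K3, K4, K5i, K6i, K, Rmax, Umax,
                           tau1, tau2, phi1, phi2, phi3, phi4,
                           CS0, B0, T0, CaSR_init,
                           troponin_sites = c("single", "double"),
                           k5_length_dependent = TRUE,
                           k6_activation_dependent = TRUE,
                           k6_activation_gain = 5) {
  troponin_sites <- match.arg(troponin_sites)
  p <- list(K1 = K1, K2 = K2, K3 = K3, K4 = K4, K5i = K5i, K6i = K6i,
            K = K, Rmax = Rmax, Umax = Umax, tau1 = tau1, tau2 = tau2,
            phi1 = phi1, phi2 = phi2, phi3 = phi3, phi4 = phi4,
            CS0 = CS0, B0 = B0, T0 = T0, CaSR_init = CaSR_init,
            troponin_sites = troponin_sites,
            k5_length_dependent = isTRUE(k5_length_dependent),
            k6_activation_dependent = isTRUE(k6_activation_dependent),
            k6_activation_gain = k6_activation_gain)
  class(p) <- "calcium_params"
  validate_calcium_params(p)
}

validate_calcium_params <- function(p) {
  pos <- c("K1", "K2", "K3", "K4", "K5i", "K6i", "K", "Rmax", "Umax",
           "tau1", "tau2", "CS0", "B0", "T0", "CaSR_init")
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("calcium_params: `", f, "` must be a single positive finite number",
           call. = FALSE)
  }
  for (f in c("phi1", "phi2", "phi3", "phi4", "k6_activation_gain")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("calcium_params: `", f, "` must be a single finite number",
           call. = FALSE)
  }
  if (p$k6_activation_gain < 0)
    stop("calcium_params: `k6_activation_gain` must be >= 0", call. = FALSE)
  p
}

#' Activation-dynamics parameters (Module 2)
#'
#' Parameters of the dynamically drifting sigmoid that maps the bound-troponin
#' fraction r = CaT/T0 to the scaled activation A~, and of the first-order
#' drift of its midpoint C1 (calcium sensitivity) and inverse slope C2
#' (calcium cooperativity). `C1n1`/`C2n1` bound the drift amplitude,
#' `C1n2`/`C2n2` its CaT/T0 threshold, `C1n3`/`C2n3` the threshold sharpness
#' and `C1n4`/`C2n4` the drift time constants (ms). `alpha` is the exponent
#' that maps A~ to the crossbridge activation A = A~^alpha.
#'
#' @param C1i,C2i initial (resting) midpoint and inverse slope.
#' @param C1n1,C1n2,C1n3,C1n4 drift parameters of C1 (C1n4 in ms).
#' @param C2n1,C2n2,C2n3,C2n4 drift parameters of C2 (C2n4 in ms).
#' @param C3 maximal activation time constant (ms).
#' @param C4,C5 centre and width of the cosh-shaped dependence of the
#'   activation time constant on r.
#' @param alpha activation exponent (dimensionless, > 0).
#' @return An object of class `activation_params`.
#' @export
activation_params <- function(C1i, C1n1, C1n2, C1n3, C1n4,
                              C2i, C2n1, C2n2, C2n3, C2n4,
                              C3, C4, C5, alpha) {
  p <- list(C1i = C1i, C1n1 = C1n1, C1n2 = C1n2, C1n3 = C1n3, C1n4 = C1n4,
            C2i = C2i, C2n1 = C2n1, C2n2 = C2n2, C2n3 = C2n3, C2n4 = C2n4,
            C3 = C3, C4 = C4, C5 = C5, alpha = alpha)
  class(p) <- "activation_params"
  validate_activation_params(p)
}

validate_activation_params <- function(p) {
  for (f in names(p)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("activation_params: `", f, "` must be a single finite number",
           call. = FALSE)
  }
  if (p$C1n4 <= 0) stop("activation_params: C1n4 must be > 0", call. = FALSE)
  if (p$C2n4 <= 0) stop("activation_params: C2n4 must be > 0", call. = FALSE)
  if (p$C3 <= 0) stop("activation_params: C3 must be > 0", call. = FALSE)
  if (p$C5 == 0) stop("activation_params: C5 must be nonzero", call. = FALSE)
  if (p$alpha <= 0) stop("activation_params: alpha must be > 0", call. = FALSE)
  if (p$C2i <= 0) stop("activation_params: C2i must be > 0", call. = FALSE)
  p
}

#' Mechanics parameters (Module 3)
#'
#' Series-elastic stiffness, peak force, quadratic length-tension scaling
#' g(Xm) = g1*Xm^2 + g2*Xm + g3, and the four modified Hill-Mashima
#' force-velocity coefficients (a0, b0 concentric; c0, d0 eccentric).
#'
#' @param K_SE series-elastic stiffness normalized by `P0_5` (1/mm).
#' @param P0_5 peak isometric force at the intermediate length (N).
#' @param g1,g2,g3 length-tension quadratic coefficients; `g1` multiplies
#'   Xm^2 with Xm in mm.
#' @param a0,c0 Hill-Mashima force offsets (N) for the concentric and
#'   eccentric branch.
#' @param b0,d0 Hill-Mashima velocity scales (mm/s).
#' @param Xm_min,Xm_half,Xm_max physiological minimum, intermediate and
#'   maximum muscle-tendon lengths (mm).
#' @return An object of class `mechanics_params`.
#' @export
mechanics_params <- function(K_SE, P0_5, g1, g2, g3, a0, b0, c0, d0,
                             Xm_min = 0, Xm_half = 5, Xm_max = 10) {
  p <- list(K_SE = K_SE, P0_5 = P0_5, g1 = g1, g2 = g2, g3 = g3,
            a0 = a0, b0 = b0, c0 = c0, d0 = d0,
            Xm_min = Xm_min, Xm_half = Xm_half, Xm_max = Xm_max)
  class(p) <- "mechanics_params"
  validate_mechanics_params(p)
}

validate_mechanics_params <- function(p) {
  for (f in names(p)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("mechanics_params: `", f, "` must be a single finite number",
           call. = FALSE)
  }
  if (p$P0_5 <= 0) stop("mechanics_params: P0_5 must be > 0", call. = FALSE)
  if (p$K_SE <= 0) stop("mechanics_params: K_SE must be > 0", call. = FALSE)
  if (!(p$Xm_min < p$Xm_half && p$Xm_half < p$Xm_max))
    stop("mechanics_params: need Xm_min < Xm_half < Xm_max", call. = FALSE)
  gs <- length_tension(seq(p$Xm_min, p$Xm_max, length.out = 101), p)
  if (any(gs <= 0))
    stop("mechanics_params: g(Xm) must be positive over [Xm_min, Xm_max]",
         call. = FALSE)
  p
}

#' Full model parameter set
#'
#' @param calcium a [calcium_params()] object.
#' @param activation an [activation_params()] object.
#' @param mechanics a [mechanics_params()] object.
#' @param dt integration step (ms); 0.025 by default.
#' @param label free-text label for the parameter set.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(calcium, activation, mechanics,
                             dt = 0.025, label = "custom") {
  stopifnot(inherits(calcium, "calcium_params"),
            inherits(activation, "activation_params"),
            inherits(mechanics, "mechanics_params"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("model_parameters: dt must be a single positive number", call. = FALSE)
  structure(list(calcium = calcium, activation = activation,
                 mechanics = mechanics, dt = dt, label = as.character(label)),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>", x$label, "\n")
  cat("  dt:", x$dt, "ms | troponin:", x$calcium$troponin_sites, "\n")
  cat("  P0.5:", x$mechanics$P0_5, "N | K_SE:", x$mechanics$K_SE, "1/mm\n")
  cat("  C1i:", x$activation$C1i, "| C2i:", x$activation$C2i,
      "| alpha:", x$activation$alpha, "\n")
  invisible(x)
}

# ---- presets ----------------------------------------------------------------

.preset_names <- c("CAT14", "CAT12", "CAT14_twosite", "CAT14_parvalbumin")

#' Built-in animal parameter presets
#'
#' `CAT14` (model development) and `CAT12` (model validation) are the two cat
#' medial gastrocnemius parameter sets. `CAT14_twosite` is the fast-fibre
#' variant with two troponin regulatory sites (2Ca + T = Ca2T) plus the
#' accompanying release/kinetic overrides, and `CAT14_parvalbumin` the
#' variant with parvalbumin-like cytosolic buffering (both with their stated
#' overrides applied on top of CAT14).
#'
#' @param name one of `"CAT14"`, `"CAT12"`, `"CAT14_twosite"`,
#'   `"CAT14_parvalbumin"`.
#' @return A [model_parameters()] object.
#' @examples
#' p <- preset("CAT14")
#' p$mechanics$a0   # 0.4 N
#' @export
preset <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% .preset_names))
    stop("unknown preset `", paste(name, collapse = ","),
         "`; valid presets: ", paste(.preset_names, collapse = ", "),
         call. = FALSE)
  base <- switch(
    name,
    CAT14 = , CAT14_twosite = , CAT14_parvalbumin = list(
      calcium = list(K1 = 3000, K2 = 3, K3 = 400, K4 = 1,
                     K5i = 4e5, K6i = 150, K = 850, Rmax = 10, Umax = 2000,
                     tau1 = 1, tau2 = 13,
                     phi1 = 0.004, phi2 = 0.98, phi3 = 0.0002, phi4 = 0.999,
                     CS0 = 0.03, B0 = 4.3e-4, T0 = 7e-5, CaSR_init = 2.5e-3),
      activation = list(C1i = 0.154, C1n1 = 0.01, C1n2 = 0.15, C1n3 = 0.01,
                        C1n4 = 85, C2i = 0.11, C2n1 = -0.0315, C2n2 = 0.27,
                        C2n3 = 0.015, C2n4 = 70,
                        C3 = 54.717, C4 = -18.847, C5 = 3.905, alpha = 1.65),
      mechanics = list(K_SE = 0.16, P0_5 = 100.3,
                       g1 = -0.0045, g2 = 0.0981, g3 = 0.6211,
                       a0 = 0.4, b0 = 99.7, c0 = -57.1, d0 = 42.2)),
    CAT12 = list(
      calcium = list(K1 = 3000, K2 = 3, K3 = 400, K4 = 1,
                     K5i = 4e5, K6i = 150, K = 850, Rmax = 10, Umax = 2000,
                     tau1 = 12, tau2 = 19.9,
                     phi1 = 0.0716, phi2 = 0.7394, phi3 = 0.0305,
                     phi4 = 0.8889,
                     CS0 = 0.03, B0 = 4.3e-4, T0 = 7e-5, CaSR_init = 2.5e-3),
      activation = list(C1i = 0.159, C1n1 = 0.0032, C1n2 = 0.0094,
                        C1n3 = 0.0083, C1n4 = 600, C2i = 0.109,
                        C2n1 = -0.0435, C2n2 = 0.315, C2n3 = 0.024,
                        C2n4 = 80,
                        C3 = 54.717, C4 = -18.847, C5 = 3.095, alpha = 1.5),
      mechanics = list(K_SE = 0.35, P0_5 = 17.5,
                       g1 = 0.0003, g2 = 0.1637, g3 = 0.4002,
                       a0 = -34.675, b0 = -130.31, c0 = -57.86, d0 = -202.78))
  )
  if (name == "CAT14_twosite") {
    base$calcium[c("T0", "K5i", "K6i", "CaSR_init", "Rmax", "tau2")] <-
      list(1.2e-4, 1.37e6, 0.56, 0.04, 139, 14.5)
    base$calcium$troponin_sites <- "double"
    base$activation[c("C1i", "C2i", "C2n1", "C2n4")] <-
      list(0.162, 0.134, -0.0095, 200)
  }
  if (name == "CAT14_parvalbumin") {
    base$calcium[c("K3", "K4", "B0")] <- list(4.17e7, 0.5, 7.5e-4)
    # the parvalbumin variant was examined with a static calcium-force curve
    base$activation[c("C1n1", "C2n1")] <- list(0, 0)
  }
  model_parameters(
    calcium = do.call(calcium_params, base$calcium),
    activation = do.call(activation_params, base$activation),
    mechanics = do.call(mechanics_params, base$mechanics),
    dt = 0.025, label = name)
}

# ---- config I/O -------------------------------------------------------------

params_to_list <- function(p) {
  stopifnot(inherits(p, "model_parameters"))
  list(calcium = unclass(p$calcium), activation = unclass(p$activation),
       mechanics = unclass(p$mechanics), dt = p$dt, label = p$label)
}

#' Serialize a parameter set to a YAML or JSON config file
#'
#' @param p a [model_parameters()] object.
#' @param path output path; format chosen from the extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return `path`, invisibly.
#' @export
save_parameters <- function(p, path) {
  x <- params_to_list(p)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 15L)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else stop("save_parameters: unsupported extension in `", path, "`",
              call. = FALSE)
  invisible(path)
}

.known_fields <- list(
  calcium = c("K1", "K2", "K3", "K4", "K5i", "K6i", "K", "Rmax", "Umax",
              "tau1", "tau2", "phi1", "phi2", "phi3", "phi4", "CS0", "B0",
              "T0", "CaSR_init", "troponin_sites", "k5_length_dependent",
              "k6_activation_dependent", "k6_activation_gain"),
  activation = c("C1i", "C1n1", "C1n2", "C1n3", "C1n4",
                 "C2i", "C2n1", "C2n2", "C2n3", "C2n4",
                 "C3", "C4", "C5", "alpha"),
  mechanics = c("K_SE", "P0_5", "g1", "g2", "g3", "a0", "b0", "c0", "d0",
                "Xm_min", "Xm_half", "Xm_max"))

#' Load a parameter set from a config file
#'
#' The config is YAML or JSON with an optional top-level `base:` naming a
#' preset; any of the `calcium`, `activation`, `mechanics` sections (or the
#' scalars `dt`, `label`) then override individual fields of that base. All
#' invariants are re-validated after merging.
#'
#' @param config_path path to a `.yaml`/`.yml` or `.json` config file.
#' @param base default base preset if the file does not name one.
#' @return A [model_parameters()] object.
#' @export
load_parameters <- function(config_path, base = "CAT14") {
  if (!file.exists(config_path))
    stop("config file not found: ", config_path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", config_path, ignore.case = TRUE)) {
    yaml::read_yaml(config_path)
  } else if (grepl("\\.json$", config_path, ignore.case = TRUE)) {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  } else stop("load_parameters: unsupported extension in `", config_path, "`",
              call. = FALSE)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg))
    stop("config must be a mapping of sections to fields", call. = FALSE)
  if (!is.null(cfg$base)) base <- cfg$base
  p <- params_to_list(preset(base))
  for (sec in c("calcium", "activation", "mechanics")) {
    if (is.null(cfg[[sec]])) next
    if (!is.list(cfg[[sec]]))
      stop("config section `", sec, "` must be a mapping", call. = FALSE)
    bad <- setdiff(names(cfg[[sec]]), .known_fields[[sec]])
    if (length(bad))
      stop("unknown field `", bad[[1L]], "` in config section `", sec, "`",
           call. = FALSE)
    p[[sec]] <- modifyList(p[[sec]], cfg[[sec]])
  }
  bad_top <- setdiff(names(cfg),
                     c("base", "calcium", "activation", "mechanics",
                       "dt", "label"))
  if (length(bad_top))
    stop("unknown top-level config key `", bad_top[[1L]], "`", call. = FALSE)
  if (!is.null(cfg$dt)) p$dt <- cfg$dt
  if (!is.null(cfg$label)) p$label <- cfg$label
  model_parameters(
    calcium = do.call(calcium_params, p$calcium),
    activation = do.call(activation_params, p$activation),
    mechanics = do.call(mechanics_params, p$mechanics),
    dt = p$dt, label = p$label)
}

# Apply named overrides like list(activation = list(C2n4 = 100)) to a
# model_parameters object, re-validating the result.
override_parameters <- function(p, overrides) {
  if (is.null(overrides) || !length(overrides)) return(p)
  x <- params_to_list(p)
  for (sec in names(overrides)) {
    if (!sec %in% c("calcium", "activation", "mechanics", "dt", "label"))
      stop("override_parameters: unknown section `", sec, "`", call. = FALSE)
    if (sec %in% c("dt", "label")) { x[[sec]] <- overrides[[sec]]; next }
    bad <- setdiff(names(overrides[[sec]]), .known_fields[[sec]])
    if (length(bad))
      stop("override_parameters: unknown field `", bad[[1L]], "` in `",
           sec, "`", call. = FALSE)
    x[[sec]] <- modifyList(x[[sec]], overrides[[sec]])
  }
  model_parameters(
    calcium = do.call(calcium_params, x$calcium),
    activation = do.call(activation_params, x$activation),
    mechanics = do.call(mechanics_params, x$mechanics),
    dt = x$dt, label = x$label)
}
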