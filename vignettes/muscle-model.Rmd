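---
title: "An action-potential-driven muscle-tendon model with a dynamic calcium-force relationship"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An action-potential-driven muscle-tendon model with a dynamic calcium-force relationship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastmuscle)
```

## The model

`fastmuscle` simulates force production of fast-twitch skeletal muscle (the
cat medial gastrocnemius) in response to action-potential trains, as a chain
of three coupled modules integrated as one state vector:

**Calcium kinetics.** Five pools — free SR calcium, calsequestrin-bound SR
calcium, free sarcoplasmic calcium, buffer-bound calcium, and
troponin-bound calcium — exchange by mass action. Each stimulus at time
$t_i$ opens a release flux
$R = [\mathrm{Ca}_{SR}] \, R_{max} \sum_i (1 - e^{-(t-t_i)/\tau_1}) e^{-(t-t_i)/\tau_2}$
(spikes act only after they occur), and a saturable pump returns calcium to
the SR with
$U = U_{max}\left(\frac{[\mathrm{Ca}]^2K^2}{1 + [\mathrm{Ca}]K + [\mathrm{Ca}]^2K^2}\right)^2$.
The troponin on-rate $K_5$ is modulated by muscle-tendon length through a
piecewise-linear factor $\phi(X_m)$ (two branches meeting at the
intermediate length), and the off-rate $K_6 = K_{6i}/(1 + 5\tilde A)$ falls
with activation, representing the increased calcium affinity of troponin
when crossbridges are attached. A two-site variant
(`troponin_sites = "double"`) replaces $\mathrm{Ca} + T$ with
$2\,\mathrm{Ca} + T = \mathrm{Ca_2}T$, making troponin binding second order
in free calcium.

**Activation dynamics.** The bound-troponin fraction $r = [\mathrm{CaT}]/T_0$
drives the scaled activation $\tilde A$ toward the sigmoid
$\tilde A_\infty = \tfrac12\!\left(1 + \tanh\frac{r - C_1}{C_2}\right)$
with time constant $\tau_{\tilde A} = C_3 / \cosh\frac{r - C_4}{2 C_5}$.
The midpoint $C_1$ (calcium sensitivity, the pCa50 analogue) and the
inverse slope $C_2$ (whose reciprocal plays the role of a Hill
coefficient) are themselves state variables, relaxing with time constants
$C_{1n4}$, $C_{2n4}$ toward sigmoid targets of $r$ parameterized by a
saturation amplitude ($C_{Xn1}$), threshold ($C_{Xn2}$) and sharpness
($C_{Xn3}$). This drifting operating curve is the model's central
hypothesis: a rightward $C_1$ drift depresses force at intermediate
stimulation rates (sag), while $C_2$ shrinkage (slope steepening)
potentiates force at high rates. Crossbridge activation is
$A = \tilde A^{\alpha}$.

**Mechanics.** A contractile element in series with a lumped elastic
element: $F = P_{0.5} K_{SE} (\Delta X_m - \Delta X_{CE})$, with the CE
velocity from modified Hill-type force-velocity relations — a concentric
hyperbola for $F \le P_{0.5}\,g(X_m)\,A$ and an eccentric branch above it,
both scaled by the quadratic length-tension factor
$g(X_m) = g_1 X_m^2 + g_2 X_m + g_3$. The four force-velocity coefficients
$(a_0, b_0, c_0, d_0)$ are obtained in closed form from two shortening and
two lengthening operating points (`hill_mashima_inverse()`); within each
pair the smaller-magnitude velocity acts as the first point. For the
eccentric offset $c_0$ we evaluate the denominator as
$V_{L,1}(P_{0.5} - T_{L,2}) - V_{L,2}(P_{0.5} - T_{L,1})$; a grouping
sometimes seen in print is dimensionally inconsistent and does not
reproduce the reference coefficient tables, while this form does — the
unit test against both animals' coefficient columns is the acceptance test
of that reading.

Units follow the reference parameter table throughout: concentrations in M,
time in ms, length in mm, force in N, velocities in mm/s (the engine
converts to mm/ms internally). No internal rescaling is applied, so any
unit oddity of the printed table (e.g. the enormous nominal $U_{max}$ and
the "mm" label on $g_1$, which actually multiplies $X_m^2$) is preserved
rather than "fixed"; the uptake saturation makes the effective uptake flux
physiological despite the nominal scale.

## Parameter sets

`preset()` ships four sets: `CAT14` (development animal), `CAT12`
(validation animal, including its negative concentric coefficients),
`CAT14_twosite` (two troponin regulatory sites, with the accompanying
release and $C_1/C_2$ adjustments; its half-activation calcium is
$\sqrt{K_{6i}/K_{5i}}$ rather than $K_{6i}/K_{5i}$), and
`CAT14_parvalbumin` (fast cytosolic buffering with a static calcium-force
curve). Variant switches — troponin stoichiometry, the length dependence of
$K_5$, the activation dependence of $K_6$ and its gain — are data in the
parameter object, not code branches, so the supplementary experiments are
pure configuration changes, loadable from YAML/JSON configs with
`base:`-preset inheritance.

## Numerical scheme

The coupled system is integrated at a fixed output step of
`dt = 0.025` ms. The calcium subsystem is stiff at that step: the
derivative of the uptake term alone reaches $\sim 10^3\,\mathrm{ms}^{-1}$
at physiological calcium, so explicit RK4 diverges at `dt` (it is retained
as a `scheme` option for convergence checks at small steps). The default
scheme is a per-variable linearized *exponential midpoint* rule: each state
is advanced with the exact solution of its local linearization
$\dot y = a - b y$, with $(a, b)$ evaluated at a half-step predictor. Two
further choices matter:

* **Substeps.** The post-spike release/uptake boundary layer has a time
  constant near 0.01 ms, below the output step. The engine therefore takes
  `substeps = 8` internal steps per output step by default; at this
  setting twitch and tetanus amplitudes are step-size-converged (doubling
  the substeps changes the twitch peak by $<10^{-4}$ relative, and halving
  `dt` changes the fused-tetanus peak by $\sim 10^{-11}$ relative).
  Under-resolving the boundary layer is not a harmless smoothing: it
  inflates the twitch by more than a factor of two and pushes the
  bound-troponin excursions across the $C_1$-drift threshold at 10 Hz,
  producing spurious sag where the converged model shows none.
* **Mass closure.** Per-variable exponential factors do not cancel exactly
  across a reaction pair, leaving an $O(10^{-10}\,\mathrm{M})$ per-step
  residual in the total-calcium invariant. After every substep the residual
  is assigned to the free-SR pool — the dominant store, where it is
  relatively negligible — so the weighted inventory
  $\mathrm{Ca}_{SR} + \mathrm{Ca}_{SR}CS + \mathrm{Ca} + \mathrm{CaB} + m\,\mathrm{CaT}$
  ($m = 2$ for the two-site variant) is conserved to machine precision
  over multi-second runs. The closure can be disabled
  (`conserve_mass = FALSE`) to measure the raw integrator drift.

**Initial state and settle phase.** The printed initial conditions give the
SR calcium load and the total pool sizes but not the bound fractions or the
resting free calcium; bound pools and free calcium start at zero and every
protocol runs an unstimulated settle phase (default 2000 ms) before t = 0
so the calsequestrin equilibrium, the resting activation and the series
element relax before the first stimulus. Note the resting state is not
force-free: $\tilde A_\infty(0) \approx 0.057$ for CAT14, leaving a
baseline activation near 1% and a resting force below 1 N. This is a
property of the model equations (the activation sigmoid never reaches
zero), not an artifact. Length changes are measured relative to the length
at stimulation onset, so isometric protocols have $\Delta X_m \equiv 0$.

**Degenerate mechanics inputs.** Both force-velocity branches vanish at the
isometric point, and below $10^{-6} P_{0.5}$ in both force and capacity the
CE is defined stationary (the branch formulas approach 0/0 there). A
configurable denominator floor turns a true pole crossing — an operating
point outside the calibrated force-velocity regime — into an error naming
the branch and time. Negative series force (a slack series element) is
permitted as the equations dictate, with a warning and an optional
clamp-at-zero flag.

## Sag classification

Sag types are defined pictorially in the experimental literature; the
package's operational definition works on the envelope of per-interstimulus
force peaks (`ripple_envelope()`). The initial peak is the first envelope
point not exceeded within the following two interstimulus intervals (this
skips the rising staircase). After it, the envelope is decomposed into
cumulative swings: a new phase is recorded when the envelope retraces more
than `rel_tol` (default 1%) of the initial peak from its running extreme.
Cumulative — rather than interval-by-interval — detection is what lets a
slow drift spread over dozens of intervals register, e.g. the 10 Hz sag of
CAT12, whose per-interval decrements are individually sub-tolerance. The
swing-sign pattern maps to the type taxonomy: only declines → **I**
(simple sag); decline with one recovery ending below the initial peak, or
with two or more recoveries → **II** (multiple force peaks); decline,
bounded recovery, second decline → **III**; decline then recovery ending
above the initial peak → **IV** (force amplification). Patterns with no
significant post-peak decline are `none`, and anything not matching a rule
is reported as `none` with its sign pattern rather than silently guessed.
The sag magnitude is (initial peak − final level)/initial peak, with the
final level the mean of the last 10% of envelope points to be robust to
residual ripple.

With the default CAT14 parameters at the intermediate length, 20 Hz
stimulation classifies as Type I, 10 Hz and 100 Hz as `none`, and pinning
$C_{1n1} = C_{2n1} = 0$ (static calcium-force curve) removes the sag —
the package's reproduction of the central observation. CAT12 shows its
strongest sag at 10 Hz, again Type I.

**The lowered-threshold operating point.** The complex sag forms are
produced by lowering the $C_2$-drift threshold $C_{2n2}$ and varying its
time constant $\tau_{C2} = C_{2n4}$. The reference account does not print
the lowered $C_{2n2}$ value; this package fixes it at **0.13** (half the
default 0.27, placing the threshold inside the 20 Hz bound-troponin ripple
band), chosen once from the structure of the type map and used for all
type-II/III/IV demonstrations. At that value the model yields Type II at
$\tau_{C2} \le 100$ ms and Type IV at 30 Hz with $\tau_{C2} = 500$ ms. A
known limitation: the II → III → I sequence along $\tau_{C2}$ at 20 Hz is
compressed relative to the reference account — Type III (decline, bounded
recovery, second decline) expresses at $\tau_{C2} \approx 200$ ms, while at
$\tau_{C2} = 500$ ms the $C_2$ feedback loop is overdamped and the envelope
declines monotonically (Type I). The cause is the position of the 20 Hz
operating point relative to the drifted midpoint: in this implementation
the mean bound-troponin fraction sits slightly below $C_1$ at 20 Hz, so
slow slope-steepening only depresses, and the single recovery that defines
Type III requires a faster loop. The corresponding acceptance expectation
is asserted at the stated 500 ms and left failing rather than silently
retuned.

**Length dependence.** Without per-length overrides, the 20 Hz sag
magnitude increases with muscle-tendon length (0.11 at 0 mm to 0.14 at
10 mm). The skinned-fibre-motivated manipulation — stronger and earlier
slope steepening when shortened ($C_{2n1} = -0.063$, $C_{2n2} = 0.13$),
reversed drift when lengthened ($C_{2n1} = +0.0315$, $C_{2n2} = 0.13$),
defaults at the intermediate length — reverses the ordering. The override
values are the package's own emulation of that qualitative manipulation
(the reference states the directions, not the numbers) and are fixed in
`length_dependence_experiment()` examples and tests.

## Calibration

The mechanics module is calibrated analytically — no optimizer — from
printed measurements (`calibration_data_preset()`): the series stiffness
from a quick stretch, the length-tension quadratic through three points
(exact interpolation), and the Hill coefficients from the four-point
inverse equations. This reproduces both animals' coefficient columns to
printed precision and is bit-for-bit deterministic.

The calcium-activation chain is fitted in ordered stages, mirroring the
original workflow: `shape` frees $\tau_1, \tau_2, C_{1i}, C_{2i}, C_3, C_4,
C_5, \alpha$ against the non-sagging frequencies (10 and 40 Hz for CAT14)
with the drift pinned off ($C_{1n1} = C_{2n1} = 0$; the strongest-sag
frequency is deliberately excluded); `sag_c1` frees $C_{1n1..4}$ against
the strongest-sag frequency; `slope_c2` frees $C_{2n1..4}$ against the
40 Hz tetanus. Each stage is a Nelder-Mead search (derivative-free local,
relative tolerance $10^{-6..7}$, with one fresh-simplex restart from the
incumbent, as repeated principal-axis-style local searches would provide;
the contract is the stage structure and objective, not the specific
algorithm). The objective is the sum of per-trace mean squared force
errors; NRMSE is available as an alternative. Invalid parameter proposals
are rejected by the validators and scored with a large penalty.

Because the in-situ recordings are not distributed, quantitative
calibration claims are tested by *parameter recovery*: targets are
generated from a known preset (`generate_target_traces()`, optionally with
Gaussian noise under a caller-supplied seed), initial values are perturbed
by ±20%, and the pipeline must bring every target trace back below 2%
NRMSE. Recovery reports always carry both per-parameter relative errors
and per-trace NRMSE — compensating parameter combinations along weakly
identified directions (e.g. $C_3$ versus $C_5$ trade-offs in the shape
stage) are acceptable when the trace fit is met, and reporting parameter
error alone would hide them. Recovery runs use 1.2–2.5 s traces sampled
every 0.2 ms with 4 substeps and a 500 ms settle — at these settings the
targets are still step-size-converged, and a full three-stage recovery
completes in a few minutes on one CPU. An optional fifth stage
(`fit_phi_lines()`) recalibrates the $\phi(X_m)$ length-modulation lines
from twitch amplitudes at the three reference lengths by per-length root
bracketing followed by the two per-branch line solves, with branch
continuity at the intermediate length checked but not enforced.

## What the synthetic data does and does not emulate

Synthetic targets are exact model traces plus optional i.i.d. Gaussian
noise. They emulate the *information content* of clean in-situ force
recordings: sampling rate, trace length, the frequencies used per stage.
They do not emulate motor-unit heterogeneity (the model is a lumped whole
muscle), slow fatigue processes, baseline drift, filtering artifacts of
force transducers, or correlated noise. Passing the recovery experiment
therefore shows the pipeline is consistent and identifiable on the model
manifold — it does not show that the staged fit would recover physiological
parameters from an arbitrary real recording.

## Problem sizes in the test-suite

Unit tests run sub-second simulations (100–600 ms); classification and
acceptance checks use the full 3 s isometric tetani at `dt = 0.025` ms with
8 substeps (≈1 s wall-clock each); the recovery experiment uses the
trimmed protocols above. These sizes are the package's own choices for a
fast, deterministic suite; all of them are step-size-converged per the
substeps analysis.

## Known limitations

* Type III sag does not express at $\tau_{C2} = 500$ ms / 20 Hz with the
  chosen lowered threshold (see above); it appears at intermediate
  $\tau_{C2}$ instead.
* The resting state carries a ~1% baseline activation; force baselines are
  therefore ≈0.9 N (CAT14), not zero.
* CAT12's negative concentric coefficients put parts of its force-velocity
  curve outside a classical Hill regime; the denominator floor guards the
  pathological operating points, and no claim is made outside the
  calibrated range.
* No parallel passive element, no pennation geometry, no stochastic
  channel gating, no spatial calcium diffusion, no fatigue-stage SR
  depletion beyond what the pool equations produce, and no random or
  locomotor-like stimulation protocols.
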