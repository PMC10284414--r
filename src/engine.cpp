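// Fixed-step integration core for the coupled muscle-tendon model.
//
// State vector (9): CaSR, CaSRCS, Ca, CaB, CaT, A_tilde, C1, C2, dXCE.
// Schemes: per-variable linearized exponential midpoint (default;
// second-order, robust to the stiff uptake/release boundary layers),
// first-order exponential Euler ("cnexp"), and classical RK4 (stable only
// at small substeps; kept for convergence checks).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  // calcium
  double K1, K2, K3, K4, K5i, K6i, K, Rmax, Umax, tau1, tau2;
  double phi1, phi2, phi3, phi4, CS0, B0, T0, CaSR_init;
  bool two_site, k5_len, k6_act;
  double k6_gain;
  // activation
  double C1i, C1n1, C1n2, C1n3, C1n4, C2i, C2n1, C2n2, C2n3, C2n4;
  double C3, C4, C5, alpha;
  // mechanics
  double K_SE, P0_5, g1, g2, g3, a0, b0, c0, d0, Xm_half;
};

const double C2_FLOOR = 1e-6;

Params read_params(const List& prm) {
  List ca = prm["calcium"], ac = prm["activation"], me = prm["mechanics"];
  Params p;
  p.K1 = ca["K1"]; p.K2 = ca["K2"]; p.K3 = ca["K3"]; p.K4 = ca["K4"];
  p.K5i = ca["K5i"]; p.K6i = ca["K6i"]; p.K = ca["K"];
  p.Rmax = ca["Rmax"]; p.Umax = ca["Umax"];
  p.tau1 = ca["tau1"]; p.tau2 = ca["tau2"];
  p.phi1 = ca["phi1"]; p.phi2 = ca["phi2"];
  p.phi3 = ca["phi3"]; p.phi4 = ca["phi4"];
  p.CS0 = ca["CS0"]; p.B0 = ca["B0"]; p.T0 = ca["T0"];
  p.CaSR_init = ca["CaSR_init"];
  p.two_site = as<std::string>(ca["troponin_sites"]) == "double";
  p.k5_len = as<bool>(ca["k5_length_dependent"]);
  p.k6_act = as<bool>(ca["k6_activation_dependent"]);
  p.k6_gain = ca["k6_activation_gain"];
  p.C1i = ac["C1i"]; p.C1n1 = ac["C1n1"]; p.C1n2 = ac["C1n2"];
  p.C1n3 = ac["C1n3"]; p.C1n4 = ac["C1n4"];
  p.C2i = ac["C2i"]; p.C2n1 = ac["C2n1"]; p.C2n2 = ac["C2n2"];
  p.C2n3 = ac["C2n3"]; p.C2n4 = ac["C2n4"];
  p.C3 = ac["C3"]; p.C4 = ac["C4"]; p.C5 = ac["C5"];
  p.alpha = ac["alpha"];
  p.K_SE = me["K_SE"]; p.P0_5 = me["P0_5"];
  p.g1 = me["g1"]; p.g2 = me["g2"]; p.g3 = me["g3"];
  p.a0 = me["a0"]; p.b0 = me["b0"]; p.c0 = me["c0"]; p.d0 = me["d0"];
  p.Xm_half = me["Xm_half"];
  return p;
}

// Sum of release kernels over spikes with t_i <= t. `lo` is advanced past
// spikes older than the cutoff (kernel < 1e-11 there); both indices are
// monotone in t over a forward sweep.
double kernel_sum(double t, const NumericVector& spikes, int& lo,
                  double tau1, double tau2) {
  double cutoff = 25.0 * tau2;
  int n = spikes.size();
  while (lo < n && t - spikes[lo] > cutoff) ++lo;
  double s = 0.0;
  for (int i = lo; i < n; ++i) {
    double d = t - spikes[i];
    if (d < 0) break;
    s += (1.0 - std::exp(-d / tau1)) * std::exp(-d / tau2);
  }
  return s;
}

// Piecewise-linear trajectory lookup with constant extrapolation.
double traj_eval(double t, const NumericVector& tt, const NumericVector& tv) {
  int n = tt.size();
  if (t <= tt[0]) return tv[0];
  if (t >= tt[n - 1]) return tv[n - 1];
  int i = 1;
  while (tt[i] < t) ++i;  // n is small (a handful of breakpoints)
  double w = (t - tt[i - 1]) / (tt[i] - tt[i - 1]);
  return tv[i - 1] + w * (tv[i] - tv[i - 1]);
}

double uptake(double Ca, const Params& p, double* dU = nullptr) {
  double u = Ca * p.K;
  double D = 1.0 + u + u * u;
  double q = u * u / D;
  if (dU) *dU = p.Umax * 2.0 * q * p.K * (2.0 * u + u * u) / (D * D);
  return p.Umax * q * q;
}

double k5_eff(double Xm, const Params& p) {
  if (!p.k5_len) return p.K5i;
  double phi = (Xm < p.Xm_half) ? p.phi1 * Xm + p.phi2
                                : p.phi3 * Xm + p.phi4;
  return p.K5i * phi;
}

double k6_eff(double At, const Params& p) {
  if (!p.k6_act) return p.K6i;
  return p.K6i / (1.0 + p.k6_gain * At);
}

// Hill-Mashima CE velocity (mm/s) and its derivative w.r.t. force.
double ce_velocity(double F, double g, double A, const Params& p,
                   double denom_floor, double t_now, double* dvdF) {
  double gA = g * A;
  double m = p.P0_5 * gA;
  if (std::fabs(m - F) < 1e-14 * std::max(1.0, std::fabs(F))) {
    if (dvdF) *dvdF = 0.0;
    return 0.0;
  }
  // fully relaxed and slack: below ~micro-P0.5 force/capacity the branch
  // formulas approach 0/0; the CE is defined stationary there
  double zg = 1e-6 * p.P0_5;
  if (std::fabs(m) < zg && std::fabs(F) < zg) {
    if (dvdF) *dvdF = 0.0;
    return 0.0;
  }
  if (F <= m) {
    double den = F + p.a0 * gA;
    if (std::fabs(den) < denom_floor)
      stop("concentric-branch denominator below floor at t = %f ms", t_now);
    if (dvdF) *dvdF = p.b0 * (m + p.a0 * gA) / (den * den);
    return -p.b0 * (m - F) / den;
  }
  double den = 2.0 * m - F + p.c0 * gA;
  if (std::fabs(den) < denom_floor)
    stop("eccentric-branch denominator below floor at t = %f ms", t_now);
  if (dvdF) *dvdF = p.d0 * (m + p.c0 * gA) / (den * den);
  return -p.d0 * (m - F) / den;
}

struct Deriv {
  double f[9];      // raw derivatives
  double b[9];      // per-variable linear decay coefficient (-df_i/dy_i)
};

// Full derivative evaluation at (t, y); also returns the per-variable
// linearization used by the exponential-Euler update.
void derivs(double t, const double y[9], const Params& p,
            const NumericVector& spikes, int& spike_lo,
            const NumericVector& tt, const NumericVector& tv,
            double xm_ref, bool settling, double denom_floor, Deriv& d) {
  double CaSR = y[0], CaSRCS = y[1], Ca = y[2], CaB = y[3], CaT = y[4];
  double At = y[5], C1 = y[6], C2 = y[7], x = y[8];

  double Xm = settling ? traj_eval(0.0, tt, tv) : traj_eval(t, tt, tv);
  double dXm = settling ? 0.0 : Xm - xm_ref;

  double S = settling ? 0.0 : kernel_sum(t, spikes, spike_lo, p.tau1, p.tau2);
  double R = CaSR * p.Rmax * S;
  double dU;
  double U = uptake(Ca, p, &dU);
  double Atc = std::min(1.0, std::max(0.0, At));
  double K5 = k5_eff(Xm, p);
  double K6 = k6_eff(Atc, p);

  // CaSR / CaSRCS
  d.f[0] = -p.K1 * p.CS0 * CaSR + (p.K1 * CaSR + p.K2) * CaSRCS - R + U;
  d.b[0] = p.K1 * p.CS0 - p.K1 * CaSRCS + p.Rmax * S;
  d.f[1] = p.K1 * p.CS0 * CaSR - (p.K1 * CaSR + p.K2) * CaSRCS;
  d.b[1] = p.K1 * CaSR + p.K2;
  // Ca, CaB, CaT
  d.f[3] = p.K3 * p.B0 * Ca - (p.K3 * Ca + p.K4) * CaB;
  d.b[3] = p.K3 * Ca + p.K4;
  if (!p.two_site) {
    d.f[2] = -(p.K3 * p.B0 + K5 * p.T0) * Ca +
      (p.K3 * Ca + p.K4) * CaB + (K5 * Ca + K6) * CaT + R - U;
    d.b[2] = (p.K3 * p.B0 + K5 * p.T0) - p.K3 * CaB - K5 * CaT + dU;
    d.f[4] = K5 * p.T0 * Ca - (K5 * Ca + K6) * CaT;
    d.b[4] = K5 * Ca + K6;
  } else {
    double Ca2 = Ca * Ca;
    d.f[2] = -(p.K3 * p.B0 + 2.0 * K5 * p.T0 * Ca) * Ca +
      (p.K3 * Ca + p.K4) * CaB + (2.0 * K5 * Ca2 + 2.0 * K6) * CaT + R - U;
    d.b[2] = p.K3 * p.B0 + 4.0 * K5 * p.T0 * Ca - p.K3 * CaB -
      4.0 * K5 * Ca * CaT + dU;
    d.f[4] = K5 * p.T0 * Ca2 - (K5 * Ca2 + K6) * CaT;
    d.b[4] = K5 * Ca2 + K6;
  }
  // activation
  double r = CaT / p.T0;
  double C2c = std::max(C2, C2_FLOOR);
  double ainf = 0.5 * (1.0 + std::tanh((r - C1) / C2c));
  double tau = p.C3 / std::cosh((r - p.C4) / (2.0 * p.C5));
  d.f[5] = (ainf - At) / tau;
  d.b[5] = 1.0 / tau;
  double c1inf = p.C1n1 * (1.0 + std::tanh((r - p.C1n2) / p.C1n3)) + p.C1i;
  double c2inf = p.C2n1 * (1.0 + std::tanh((r - p.C2n2) / p.C2n3)) + p.C2i;
  d.f[6] = (c1inf - C1) / p.C1n4;
  d.b[6] = 1.0 / p.C1n4;
  d.f[7] = (c2inf - C2) / p.C2n4;
  d.b[7] = 1.0 / p.C2n4;
  // mechanics: F from the series element, CE velocity in mm/s -> mm/ms
  double F = p.P0_5 * p.K_SE * (dXm - x);
  double A = std::pow(Atc, p.alpha);
  double g = p.g1 * Xm * Xm + p.g2 * Xm + p.g3;
  double dvdF;
  double v = ce_velocity(F, g, A, p, denom_floor, t, &dvdF);
  d.f[8] = v / 1000.0;
  d.b[8] = dvdF * p.P0_5 * p.K_SE / 1000.0;
}

void check_finite(const double y[9], double t) {
  static const char* nm[9] = {"CaSR", "CaSRCS", "Ca", "CaB", "CaT",
                              "A_tilde", "C1", "C2", "dXCE"};
  for (int i = 0; i < 9; ++i)
    if (!std::isfinite(y[i]))
      stop("non-finite state `%s` at t = %f ms", nm[i], t);
}

}  // namespace

// One linearized exponential-Euler update of the full state over `h`,
// using derivative/linearization `d` (evaluated elsewhere).
void exp_update(double y[9], const Deriv& d, double h) {
  for (int i = 0; i < 9; ++i) {
    double b = d.b[i];
    if (std::fabs(b) * h > 1e-12) {
      double yinf = y[i] + d.f[i] / b;  // a/b with a = f + b*y
      y[i] = yinf + (y[i] - yinf) * std::exp(-b * h);
    } else {
      y[i] += d.f[i] * h;
    }
  }
}

// [[Rcpp::export(name = ".sim_core")]]
NumericMatrix sim_core(List prm, NumericVector spikes,
                       NumericVector traj_t, NumericVector traj_x,
                       double dt, double settle, double duration,
                       int record_every, bool include_settle,
                       std::string scheme, double denom_floor,
                       bool clamp_negative_force, int substeps,
                       bool conserve_mass) {
  Params p = read_params(prm);
  bool rk4 = (scheme == "rk4");
  bool midpoint = (scheme == "exp_midpoint");
  if (substeps < 1) substeps = 1;
  double h = dt / substeps;
  double mass_w = p.two_site ? 2.0 : 1.0;
  double total0 = p.CaSR_init;  // bound pools and free Ca start empty
  long n_settle = (long)std::lround(settle / dt);
  long n_main = (long)std::lround(duration / dt);

  double y[9] = {p.CaSR_init, 0.0, 0.0, 0.0, 0.0,
                 0.0, p.C1i, p.C2i, 0.0};
  double xm_ref = traj_eval(0.0, traj_t, traj_x);

  // count recorded rows
  long first_rec = include_settle ? -n_settle : 0;
  long n_rec = 0;
  for (long k = first_rec; k <= n_main; k += record_every) ++n_rec;
  if ((n_main - first_rec) % record_every != 0) ++n_rec;  // force last row
  NumericMatrix out(n_rec, 13);

  int spike_lo = 0, spike_lo_sub = 0;
  long row = 0;
  long neg_force = 0;

  for (long k = -n_settle; k <= n_main; ++k) {
    bool settling = k < 0;
    double t = k * dt;
    check_finite(y, t);

    bool rec = (k >= first_rec) &&
      (((k - first_rec) % record_every == 0) || k == n_main);
    if (rec) {
      double Xm = settling ? traj_eval(0.0, traj_t, traj_x)
                           : traj_eval(t, traj_t, traj_x);
      double dXm = settling ? 0.0 : Xm - xm_ref;
      double F = p.P0_5 * p.K_SE * (dXm - y[8]);
      if (F < 0) {
        ++neg_force;
        if (clamp_negative_force) F = 0.0;
      }
      double Atc = std::min(1.0, std::max(0.0, y[5]));
      out(row, 0) = t;
      for (int i = 0; i < 9; ++i) out(row, 1 + i) = y[i];
      out(row, 10) = std::pow(Atc, p.alpha);
      out(row, 11) = Xm;
      out(row, 12) = F;
      ++row;
    }
    if (k == n_main) break;

    for (int ss = 0; ss < substeps; ++ss) {
      double ts = t + ss * h;
      if (midpoint) {
        // exponential midpoint: half-step predictor, then a full step using
        // the linearization at the midpoint state (second-order, retains
        // the stability of the exponential update on the stiff terms)
        Deriv d1, d2;
        derivs(ts, y, p, spikes, spike_lo, traj_t, traj_x, xm_ref, settling,
               denom_floor, d1);
        double yh[9];
        for (int i = 0; i < 9; ++i) yh[i] = y[i];
        exp_update(yh, d1, 0.5 * h);
        spike_lo_sub = spike_lo;
        derivs(ts + 0.5 * h, yh, p, spikes, spike_lo_sub, traj_t, traj_x,
               xm_ref, settling, denom_floor, d2);
        // re-anchor the midpoint linearization at the start-of-step state:
        // a2 = f2 + b2*y_half, update uses f_eff = a2 - b2*y
        for (int i = 0; i < 9; ++i)
          d2.f[i] = d2.f[i] + d2.b[i] * (yh[i] - y[i]);
        exp_update(y, d2, h);
      } else if (!rk4) {
        Deriv d;
        derivs(ts, y, p, spikes, spike_lo, traj_t, traj_x, xm_ref, settling,
               denom_floor, d);
        exp_update(y, d, h);
      } else {
        Deriv d1, d2, d3, d4;
        double y2[9], y3[9], y4[9];
        // settle flag held constant within the step taken from its start
        derivs(ts, y, p, spikes, spike_lo, traj_t, traj_x, xm_ref, settling,
               denom_floor, d1);
        for (int i = 0; i < 9; ++i) y2[i] = y[i] + 0.5 * h * d1.f[i];
        spike_lo_sub = spike_lo;
        derivs(ts + 0.5 * h, y2, p, spikes, spike_lo_sub, traj_t, traj_x,
               xm_ref, settling, denom_floor, d2);
        for (int i = 0; i < 9; ++i) y3[i] = y[i] + 0.5 * h * d2.f[i];
        spike_lo_sub = spike_lo;
        derivs(ts + 0.5 * h, y3, p, spikes, spike_lo_sub, traj_t, traj_x,
               xm_ref, settling, denom_floor, d3);
        for (int i = 0; i < 9; ++i) y4[i] = y[i] + h * d3.f[i];
        spike_lo_sub = spike_lo;
        derivs(ts + h, y4, p, spikes, spike_lo_sub, traj_t, traj_x,
               xm_ref, settling, denom_floor, d4);
        for (int i = 0; i < 9; ++i)
          y[i] += h / 6.0 * (d1.f[i] + 2.0 * d2.f[i] + 2.0 * d3.f[i] +
                             d4.f[i]);
      }
      if (conserve_mass) {
        // mass closure: the per-variable exponential factors do not cancel
        // exactly across a reaction pair, leaving a tiny (O(1e-10)/step)
        // residual in the total-calcium invariant; assign it to the large
        // SR free pool so the inventory is exact
        y[0] = total0 - (y[1] + y[2] + y[3] + mass_w * y[4]);
      }
      // keep A_tilde in [0,1]; tiny numerical excursions only
      if (y[5] < 0.0) y[5] = 0.0;
      if (y[5] > 1.0) y[5] = 1.0;
    }
  }
  out.attr("neg_force_steps") = (double)neg_force;
  return out;
}
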