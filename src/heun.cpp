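#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stochastic Heun integrator for delay-coupled Epileptor networks.
//
// Full model (6 variables per node): x1, y1, z, x2, y2, g with
//   x1' = y1 - f1(x1, x2, z) - z + I1
//   y1' = (1 - 5 x1^2 - y1) / tau1
//   z'  = (4 (x1 - x0) - z - w * sum_j W_ij [x1_j(t - tau_ij) - x1_i]) / tau0
//   x2' = -y2 + x2 - x2^3 + I2 + 0.002 g - 0.3 (z - 3.5)   [+ noise]
//   y2' = (-y2 + f2(x2)) / tau2                             [+ noise]
//   g'  = x1 - gamma * g
// with piecewise nonlinearities
//   f1 = x1^3 - 3 x1^2                      if x1 < 0
//        (x2 - 0.6 (z - 4)^2) x1            if x1 >= 0
//   f2 = 0                                  if x2 < -0.25
//        6 (x2 + 0.25)                      if x2 >= -0.25
//
// Reduced model (2 variables per node): x, z with
//   x' = -x^3 - 2 x^2 + 1 - z + I1          [+ noise]
//   z' = (4 (x - x0) - z - w * sum_j W_ij [x_j(t - tau_ij) - x_i]) / tau0
//
// Noise is additive, injected into x2' and y2' (full) or x' (reduced), with
// increments N(0, sigma^2 * dt) drawn from R's RNG so that set.seed() on the
// R side gives bit-identical realizations.
//
// Protocol events handled in-loop:
//   * at step == activation_step the active EZ node's x0 switches to x0_ez;
//   * once the detection variable (g for the full model, x for the reduced)
//     crosses thr_on upward after activation, the node is marked recruited;
//   * when it later falls below thr_off the node's seizure has terminated:
//     the node is uncoupled from the network for the rest of the run and, if
//     it is the active EZ, its x0 reverts to the surround value.

static inline double f1_full(double x1, double x2, double z) {
  if (x1 < 0.0)
    return x1 * x1 * x1 - 3.0 * x1 * x1;
  double d = z - 4.0;
  return (x2 - 0.6 * d * d) * x1;
}

static inline double f2_full(double x2) {
  if (x2 < -0.25) return 0.0;
  return 6.0 * (x2 + 0.25);
}

struct Params {
  double I1, I2, gamma, tau0, tau1, tau2, w;
};

// [[Rcpp::export(name = ".heun_sim")]]
List heun_sim(NumericMatrix state0,      // n x nv initial state (nv = 6 or 2)
              int model,                 // 1 = full, 2 = reduced
              int n_steps,               // steps to integrate
              double dt,
              NumericVector x0,          // per-node excitability (surround values)
              double w,
              NumericMatrix W,           // n x n coupling weights
              IntegerMatrix delay_steps, // n x n integer delays in steps
              double sigma,
              List pars,                 // I1, I2, gamma, tau0, tau1, tau2
              int activation_step,       // -1: never activate
              int active_ez,             // 0-based; -1: none
              double x0_ez,
              double thr_on,             // NA: no detection / no uncoupling
              double thr_off,
              int record_mode,           // 0 none, 1 detection var only, 2 full
              int record_stride,
              double blowup_bound) {
  const int n = state0.nrow();
  const int nv = (model == 1) ? 6 : 2;
  if (state0.ncol() != nv) stop("state0 has %d columns; expected %d", state0.ncol(), nv);
  Params p;
  p.I1 = as<double>(pars["I1"]);   p.I2 = as<double>(pars["I2"]);
  p.gamma = as<double>(pars["gamma"]);
  p.tau0 = as<double>(pars["tau0"]); p.tau1 = as<double>(pars["tau1"]);
  p.tau2 = as<double>(pars["tau2"]);
  p.w = w;

  const bool detect = R_finite(thr_on);
  const double sd_inc = sigma * std::sqrt(dt);
  const bool noisy = sigma > 0.0;

  // state arrays
  std::vector<double> s(n * nv), sp(n * nv), k1(n * nv), k2(n * nv);
  for (int i = 0; i < n; ++i)
    for (int v = 0; v < nv; ++v) s[v * n + i] = state0(i, v);

  std::vector<double> x0v(x0.begin(), x0.end());
  std::vector<int> coupled(n, 1);

  // delay ring buffer over the coupling variable (x1 resp. x)
  int maxd = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (delay_steps(i, j) > maxd) maxd = delay_steps(i, j);
  const int L = maxd + 1;
  std::vector<double> buf((size_t)L * n);
  for (int l = 0; l < L; ++l)
    for (int j = 0; j < n; ++j) buf[(size_t)l * n + j] = s[j]; // x1 is block 0

  // sparse adjacency for the coupling sums
  std::vector<std::vector<int>> nbr(n);
  std::vector<std::vector<double>> wij(n);
  std::vector<std::vector<int>> dij(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && W(i, j) != 0.0) {
        nbr[i].push_back(j);
        wij[i].push_back(W(i, j));
        dij[i].push_back(delay_steps(i, j));
      }

  // recording
  int n_rec = 0;
  if (record_mode > 0) n_rec = n_steps / record_stride + 1; // includes step 0
  NumericMatrix rec_states;
  NumericMatrix rec_det;
  NumericVector rec_times(record_mode > 0 ? n_rec : 0);
  if (record_mode == 2) rec_states = NumericMatrix(n_rec, n * nv);
  if (record_mode >= 1) rec_det = NumericMatrix(n_rec, n);
  const int det_block = (model == 1) ? 5 : 0; // g resp. x
  int irec = 0;
  auto record = [&](int step) {
    if (record_mode == 0) return;
    if (step % record_stride != 0) return;
    rec_times[irec] = step * dt;
    for (int i = 0; i < n; ++i) rec_det(irec, i) = s[det_block * n + i];
    if (record_mode == 2)
      for (int v = 0; v < nv; ++v)
        for (int i = 0; i < n; ++i) rec_states(irec, v * n + i) = s[v * n + i];
    ++irec;
  };

  IntegerVector onset_step(n, NA_INTEGER), offset_step(n, NA_INTEGER);

  std::vector<double> cpl(n), dWx(noisy ? n : 0), dWy(noisy ? n : 0);

  // coupling sums; x_now = coupling variable at evaluation time t_eval,
  // delayed values for d >= 1 served from the ring buffer
  auto coupling = [&](const double* x_now, int t_eval) {
    const int base = t_eval % L; // ring position; d < L so one wrap suffices
    for (int i = 0; i < n; ++i) {
      double c = 0.0;
      if (coupled[i]) {
        const double xi = x_now[i];
        const std::vector<int>& nb = nbr[i];
        for (size_t k = 0; k < nb.size(); ++k) {
          const int j = nb[k];
          if (!coupled[j]) continue;
          const int d = dij[i][k];
          int slot = base - d;
          if (slot < 0) slot += L;
          const double xj = (d == 0) ? x_now[j] : buf[(size_t)slot * n + j];
          c += wij[i][k] * (xj - xi);
        }
      }
      cpl[i] = c;
    }
  };

  auto drift = [&](const std::vector<double>& st, int t_eval, std::vector<double>& out) {
    const double* x1 = &st[0];
    coupling(x1, t_eval);
    if (model == 1) {
      const double* y1 = &st[n];     const double* z = &st[2 * n];
      const double* x2 = &st[3 * n]; const double* y2 = &st[4 * n];
      const double* g = &st[5 * n];
      for (int i = 0; i < n; ++i) {
        out[i]         = y1[i] - f1_full(x1[i], x2[i], z[i]) - z[i] + p.I1;
        out[n + i]     = (1.0 - 5.0 * x1[i] * x1[i] - y1[i]) / p.tau1;
        out[2 * n + i] = (4.0 * (x1[i] - x0v[i]) - z[i] - p.w * cpl[i]) / p.tau0;
        out[3 * n + i] = -y2[i] + x2[i] - x2[i] * x2[i] * x2[i] + p.I2
                         + 0.002 * g[i] - 0.3 * (z[i] - 3.5);
        out[4 * n + i] = (-y2[i] + f2_full(x2[i])) / p.tau2;
        out[5 * n + i] = x1[i] - p.gamma * g[i];
      }
    } else {
      const double* z = &st[n];
      for (int i = 0; i < n; ++i) {
        out[i]     = -x1[i] * x1[i] * x1[i] - 2.0 * x1[i] * x1[i] + 1.0 - z[i] + p.I1;
        out[n + i] = (4.0 * (x1[i] - x0v[i]) - z[i] - p.w * cpl[i]) / p.tau0;
      }
    }
  };

  record(0);

  for (int step = 0; step < n_steps; ++step) {
    if (step == activation_step && active_ez >= 0) x0v[active_ez] = x0_ez;

    drift(s, step, k1);

    if (noisy) {
      for (int i = 0; i < n; ++i) dWx[i] = R::norm_rand() * sd_inc;
      if (model == 1)
        for (int i = 0; i < n; ++i) dWy[i] = R::norm_rand() * sd_inc;
    }

    // predictor
    for (int q = 0; q < n * nv; ++q) sp[q] = s[q] + dt * k1[q];
    if (noisy) {
      if (model == 1) {
        for (int i = 0; i < n; ++i) { sp[3 * n + i] += dWx[i]; sp[4 * n + i] += dWy[i]; }
      } else {
        for (int i = 0; i < n; ++i) sp[i] += dWx[i];
      }
    }

    drift(sp, step + 1, k2);

    // corrector
    for (int q = 0; q < n * nv; ++q) s[q] += 0.5 * dt * (k1[q] + k2[q]);
    if (noisy) {
      if (model == 1) {
        for (int i = 0; i < n; ++i) { s[3 * n + i] += dWx[i]; s[4 * n + i] += dWy[i]; }
      } else {
        for (int i = 0; i < n; ++i) s[i] += dWx[i];
      }
    }

    const int s1 = step + 1;
    for (int j = 0; j < n; ++j) buf[(size_t)(s1 % L) * n + j] = s[j];

    // blow-up guard
    double a0 = s[0];
    if (!R_finite(a0) || std::fabs(a0) > blowup_bound) {
      bool bad = false;
      for (int q = 0; q < n * nv; ++q)
        if (!R_finite(s[q]) || std::fabs(s[q]) > blowup_bound) { bad = true; break; }
      if (bad)
        stop("integration diverged at step %d (|state| > %g or non-finite)", s1, blowup_bound);
    }

    // seizure detection + postictal uncoupling
    if (detect && activation_step >= 0 && s1 > activation_step) {
      const double* dv = &s[det_block * n];
      for (int i = 0; i < n; ++i) {
        if (onset_step[i] == NA_INTEGER) {
          if (dv[i] >= thr_on) onset_step[i] = s1;
        } else if (offset_step[i] == NA_INTEGER) {
          if (dv[i] <= thr_off) {
            offset_step[i] = s1;
            coupled[i] = 0;
            if (i == active_ez) x0v[i] = x0[i]; // revert to surround value
          }
        }
      }
    }

    record(s1);

    if ((step & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix final_state(n, nv);
  for (int i = 0; i < n; ++i)
    for (int v = 0; v < nv; ++v) final_state(i, v) = s[v * n + i];

  return List::create(
    _["final_state"] = final_state,
    _["times"] = rec_times,
    _["det"] = rec_det,
    _["states"] = rec_states,
    _["onset_step"] = onset_step,
    _["offset_step"] = offset_step,
    _["coupled"] = IntegerVector(coupled.begin(), coupled.end()),
    _["x0_final"] = NumericVector(x0v.begin(), x0v.end()));
}
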