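#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Threshold-linear rate dynamics with projection at the rate floor:
//   tau * dr = -r + W r - theta + drive,  and if r_i == 0 with a negative
// raw derivative, the decrease is not enacted (dr_i = 0).
// W is stored row-major in a flat buffer for speed.
static inline void deriv(const double* W, const double* theta, int n,
                         const double* r, const double* drive,
                         double inv_tau, double* out) {
  for (int i = 0; i < n; ++i) {
    double acc = -r[i] - theta[i] + drive[i];
    const double* wrow = W + (size_t)i * n;
    for (int j = 0; j < n; ++j) acc += wrow[j] * r[j];
    acc *= inv_tau;
    if (r[i] <= 0.0 && acc < 0.0) acc = 0.0;
    out[i] = acc;
  }
}

// Total applied current per unit at time t: sum over rectangular pulses,
// onset-inclusive, offset-exclusive (H(0) = 1).
static inline void drive_at(double t, int n, int nstim, const double* amp,
                            const double* onset, const double* dur,
                            const double* w /* n x nstim, col-major */,
                            double* out) {
  for (int i = 0; i < n; ++i) out[i] = 0.0;
  for (int a = 0; a < nstim; ++a) {
    if (t >= onset[a] && t < onset[a] + dur[a]) {
      const double* wcol = w + (size_t)a * n;
      for (int i = 0; i < n; ++i) out[i] += amp[a] * wcol[i];
    }
  }
}

static inline void clamp0(double* v, int n) {
  for (int i = 0; i < n; ++i) if (v[i] < 0.0) v[i] = 0.0;
}

struct Work {
  std::vector<double> k1, k2, k3, k4, tmp, dr;
  explicit Work(int n) : k1(n), k2(n), k3(n), k4(n), tmp(n), dr(n) {}
};

// One clamped RK4 step from time t; overwrites r.
static void rk4_step(const double* W, const double* theta, int n, double* r,
                     double t, double dt, double inv_tau, int nstim,
                     const double* amp, const double* onset,
                     const double* dur, const double* sw, bool clamp_stages,
                     Work& wk) {
  double* k1 = wk.k1.data(); double* k2 = wk.k2.data();
  double* k3 = wk.k3.data(); double* k4 = wk.k4.data();
  double* tmp = wk.tmp.data(); double* dr = wk.dr.data();
  drive_at(t, n, nstim, amp, onset, dur, sw, dr);
  deriv(W, theta, n, r, dr, inv_tau, k1);
  for (int i = 0; i < n; ++i) tmp[i] = r[i] + 0.5 * dt * k1[i];
  if (clamp_stages) clamp0(tmp, n);
  drive_at(t + 0.5 * dt, n, nstim, amp, onset, dur, sw, dr);
  deriv(W, theta, n, tmp, dr, inv_tau, k2);
  for (int i = 0; i < n; ++i) tmp[i] = r[i] + 0.5 * dt * k2[i];
  if (clamp_stages) clamp0(tmp, n);
  deriv(W, theta, n, tmp, dr, inv_tau, k3);
  for (int i = 0; i < n; ++i) tmp[i] = r[i] + dt * k3[i];
  if (clamp_stages) clamp0(tmp, n);
  drive_at(t + dt, n, nstim, amp, onset, dur, sw, dr);
  deriv(W, theta, n, tmp, dr, inv_tau, k4);
  for (int i = 0; i < n; ++i) {
    r[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (r[i] < 0.0) r[i] = 0.0;
  }
}

static void check_finite(const double* r, int n, double t) {
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(r[i]) || std::fabs(r[i]) > 1e9) {
      stop("integration diverged at t = %f s (unit %d)", t, i + 1);
    }
  }
}

static std::vector<double> row_major(const NumericMatrix& W) {
  const int n = W.nrow();
  std::vector<double> out((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out[(size_t)i * n + j] = W(i, j);
  return out;
}

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix W, NumericVector theta, NumericVector r0,
                  double tau, double dt, double t_end,
                  NumericVector stim_amp, NumericVector stim_onset,
                  NumericVector stim_dur, NumericMatrix stim_w,
                  int sample_every, bool clamp_stages) {
  const int n = r0.size();
  const int nstim = stim_amp.size();
  const long nsteps = (long)std::llround(t_end / dt);
  std::vector<double> Wf = row_major(W);
  std::vector<double> r(r0.begin(), r0.end());
  std::vector<double> sw(stim_w.begin(), stim_w.end());
  Work wk(n);
  const double inv_tau = 1.0 / tau;
  const long nsamp = nsteps / sample_every + 2;
  NumericMatrix rates(nsamp, n);
  NumericVector times(nsamp);
  long s = 0;
  times[s] = 0.0;
  for (int i = 0; i < n; ++i) rates(s, i) = r[i];
  ++s;
  for (long k = 0; k < nsteps; ++k) {
    rk4_step(Wf.data(), &theta[0], n, r.data(), k * dt, dt, inv_tau, nstim,
             nstim ? &stim_amp[0] : NULL, nstim ? &stim_onset[0] : NULL,
             nstim ? &stim_dur[0] : NULL, sw.data(), clamp_stages, wk);
    if ((k & 1023) == 0) check_finite(r.data(), n, (k + 1) * dt);
    if ((k + 1) % sample_every == 0 || k + 1 == nsteps) {
      times[s] = (k + 1) * dt;
      for (int i = 0; i < n; ++i) rates(s, i) = r[i];
      ++s;
    }
  }
  check_finite(r.data(), n, nsteps * dt);
  return List::create(_["times"] = times[Range(0, s - 1)],
                      _["rates"] = rates(Range(0, s - 1), _),
                      _["final"] = NumericVector(r.begin(), r.end()));
}

// Autonomous relaxation with early exit: the run stops as soon as every unit
// has stayed within `tol` (Hz) of the current state for a full `window`
// seconds (the proximity convergence criterion, checked on a sliding
// window). Samples are recorded every `sample_dt` for envelope analysis of
// non-converged runs.
// [[Rcpp::export]]
List cpp_settle(NumericMatrix W, NumericVector theta, NumericVector r0,
                double tau, double dt, double max_time,
                double sample_dt, double window, double tol,
                bool clamp_stages) {
  const int n = r0.size();
  const long nsteps = (long)std::llround(max_time / dt);
  const int sample_every = std::max(1, (int)std::llround(sample_dt / dt));
  const int win_samples = std::max(2, (int)std::llround(window / sample_dt));
  const int check_every = std::max(1, win_samples / 5);
  std::vector<double> Wf = row_major(W);
  std::vector<double> r(r0.begin(), r0.end());
  Work wk(n);
  const double inv_tau = 1.0 / tau;
  const long max_samp = nsteps / sample_every + 2;
  std::vector<double> samp((size_t)max_samp * n);
  std::vector<double> stimes(max_samp);
  long s = 0;
  stimes[s] = 0.0;
  for (int i = 0; i < n; ++i) samp[(size_t)s * n + i] = r[i];
  ++s;
  bool prox = false;
  long k = 0;
  for (; k < nsteps; ++k) {
    rk4_step(Wf.data(), &theta[0], n, r.data(), k * dt, dt, inv_tau, 0,
             NULL, NULL, NULL, NULL, clamp_stages, wk);
    if ((k & 2047) == 0) check_finite(r.data(), n, (k + 1) * dt);
    if ((k + 1) % sample_every == 0) {
      stimes[s] = (k + 1) * dt;
      for (int i = 0; i < n; ++i) samp[(size_t)s * n + i] = r[i];
      ++s;
      if (s > win_samples && ((s - 1) % check_every == 0)) {
        bool ok = true;
        for (long q = s - 1 - win_samples; q < s && ok; ++q) {
          const double* sq = samp.data() + (size_t)q * n;
          for (int i = 0; i < n; ++i) {
            if (std::fabs(sq[i] - r[i]) >= tol) { ok = false; break; }
          }
        }
        if (ok) { prox = true; ++k; break; }
      }
    }
  }
  check_finite(r.data(), n, k * dt);
  NumericMatrix rates(s, n);
  NumericVector times(s);
  for (long q = 0; q < s; ++q) {
    times[q] = stimes[q];
    for (int i = 0; i < n; ++i) rates(q, i) = samp[(size_t)q * n + i];
  }
  return List::create(_["times"] = times, _["rates"] = rates,
                      _["final"] = NumericVector(r.begin(), r.end()),
                      _["proximity"] = prox,
                      _["t_elapsed"] = (double)k * dt);
}
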