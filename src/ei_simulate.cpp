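#include <Rcpp.h>
using namespace Rcpp;

// Euler integration of the two-population rate network.
//
// Divisive mode:
//   a dr_exc_j/dt = s_j - (w0 + sum_k W[j,k] r_inh_k) * r_exc_j
//   b dr_inh_i/dt = sum_j W[j,i] (r_exc_j - 1)
// both populations clamped at zero.
//
// Subtractive mode (constant leak, additive inhibition):
//   a dr_exc_j/dt = s_j - w0 * r_exc_j - sum_k W[j,k] r_inh_k
//   b dr_inh_i/dt = sum_j W[j,i] (r_exc_j - 1)
// inhibitory rates clamped at zero; excitatory error units are signed.
//
// Input is piecewise constant: S (m x K) with segment start times breaks
// (K, breaks[0] == 0). Recording every rec_steps steps; optional early
// stop when the largest instantaneous rate of change falls below
// steady_tol (checked every 100 steps, only meaningful for constant
// input).
// [[Rcpp::export]]
List ei_simulate_cpp(NumericMatrix W, double w0, double a, double b,
                     double dt, NumericMatrix S, NumericVector breaks,
                     double duration, int rec_steps, bool subtractive,
                     NumericVector exc0, NumericVector inh0,
                     bool stop_when_steady, double steady_tol) {
  const int m = W.nrow(), n = W.ncol(), K = S.ncol();
  const int nsteps = (int)std::ceil(duration / dt - 1e-9);
  const int max_rec = nsteps / rec_steps + 2;

  std::vector<double> exc(exc0.begin(), exc0.end());
  std::vector<double> inh(inh0.begin(), inh0.end());
  std::vector<double> pred(m), dexc(m), dinh(n);

  NumericMatrix rec_exc(max_rec, m), rec_inh(max_rec, n);
  NumericVector rec_t(max_rec);
  int nrec = 0;
  auto record = [&](double t) {
    for (int j = 0; j < m; ++j) rec_exc(nrec, j) = exc[j];
    for (int i = 0; i < n; ++i) rec_inh(nrec, i) = inh[i];
    rec_t[nrec] = t;
    ++nrec;
  };
  record(0.0);

  int seg = 0;
  bool steady = false;
  int step = 0;
  for (step = 1; step <= nsteps; ++step) {
    double t = (step - 1) * dt;
    while (seg + 1 < K && t >= breaks[seg + 1]) ++seg;

    // prediction / inhibitory drive per excitatory unit
    for (int j = 0; j < m; ++j) {
      double p = w0;
      for (int k = 0; k < n; ++k) p += W(j, k) * inh[k];
      pred[j] = p;
    }
    double maxrate = 0.0;
    if (subtractive) {
      double leak = dt * w0 / a;
      if (leak > 1.0)
        stop("unstable integration: w0*dt/a > 1; reduce dt");
      for (int j = 0; j < m; ++j) {
        dexc[j] = (S(j, seg) - w0 * exc[j] - (pred[j] - w0)) / a;
      }
    } else {
      for (int j = 0; j < m; ++j) {
        if (dt * pred[j] / a > 1.0)
          stop("unstable integration: leak*dt/a > 1; reduce dt");
        dexc[j] = (S(j, seg) - pred[j] * exc[j]) / a;
      }
    }
    for (int i = 0; i < n; ++i) {
      double g = 0.0;
      for (int j = 0; j < m; ++j) g += W(j, i) * (exc[j] - 1.0);
      dinh[i] = g / b;
    }
    for (int j = 0; j < m; ++j) {
      exc[j] += dt * dexc[j];
      if (!subtractive && exc[j] < 0.0) exc[j] = 0.0;
      if (!R_finite(exc[j]))
        stop("non-finite excitatory rate: dt too large for stability");
      if (std::fabs(dexc[j]) > maxrate) maxrate = std::fabs(dexc[j]);
    }
    for (int i = 0; i < n; ++i) {
      inh[i] += dt * dinh[i];
      if (inh[i] < 0.0) inh[i] = 0.0;
      if (!R_finite(inh[i]))
        stop("non-finite inhibitory rate: dt too large for stability");
      if (std::fabs(dinh[i]) > maxrate) maxrate = std::fabs(dinh[i]);
    }
    if (step % rec_steps == 0) record(step * dt);
    if (stop_when_steady && (step % 100 == 0) && maxrate < steady_tol) {
      steady = true;
      if (step % rec_steps != 0) record(step * dt);
      break;
    }
  }

  return List::create(_["times"] = rec_t[Range(0, nrec - 1)],
                      _["r_exc"] = rec_exc(Range(0, nrec - 1), _),
                      _["r_inh"] = rec_inh(Range(0, nrec - 1), _),
                      _["steady"] = steady,
                      _["steps"] = std::min(step, nsteps));
}
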