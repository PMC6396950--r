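#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stochastic mass-action propensity: rate * prod_s choose(x_s, r_s).
static inline double propensity(const double rate, const int *r,
                                const double *x, const int nsp) {
  double a = rate;
  for (int s = 0; s < nsp; ++s) {
    int rs = r[s];
    if (rs == 0) continue;
    double xs = x[s];
    if (xs < rs) return 0.0;
    if (rs == 1) {
      a *= xs;
    } else {
      double c = 1.0;
      for (int k = 0; k < rs; ++k) c *= (xs - k) / (k + 1.0);
      a *= c;
    }
  }
  return a;
}

// Gillespie direct method over a mass-action network. States are sampled on
// the regular grid 0, dt, 2dt, ... (piecewise-constant interpolation of the
// exact path). Uses R's RNG, so set.seed() in R gives reproducible paths.
// [[Rcpp::export]]
List ssa_core(const IntegerMatrix reactants, const IntegerMatrix net_change,
              const NumericVector rate, const IntegerVector init,
              const double t_max, const double sample_dt,
              const double max_events) {
  const int nsp = init.size();
  const int nr = rate.size();
  const int ns = (int)std::floor(t_max / sample_dt + 1e-9) + 1;
  std::vector<double> x(nsp);
  for (int s = 0; s < nsp; ++s) x[s] = init[s];
  std::vector<int> R(nsp * nr), N(nsp * nr);
  for (int j = 0; j < nr; ++j)
    for (int s = 0; s < nsp; ++s) {
      R[j * nsp + s] = reactants(s, j);
      N[j * nsp + s] = net_change(s, j);
    }
  NumericMatrix out(ns, nsp);
  std::vector<double> a(nr);
  double t = 0.0, events = 0.0;
  int isamp = 0;
  bool exhausted = false;
  while (t < t_max) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) {
      a[j] = propensity(rate[j], &R[j * nsp], x.data(), nsp);
      a0 += a[j];
    }
    if (a0 <= 0.0) break;  // absorbed: state constant for the rest
    double tau = exp_rand() / a0;
    double t_new = t + tau;
    while (isamp < ns && isamp * sample_dt < t_new) {
      if (isamp * sample_dt > t_max + 1e-12) break;
      for (int s = 0; s < nsp; ++s) out(isamp, s) = x[s];
      ++isamp;
    }
    if (t_new >= t_max) { t = t_max; break; }
    double u = unif_rand() * a0, acc = 0.0;
    int j = nr - 1;
    for (int jj = 0; jj < nr; ++jj) {
      acc += a[jj];
      if (u <= acc) { j = jj; break; }
    }
    for (int s = 0; s < nsp; ++s) x[s] += N[j * nsp + s];
    t = t_new;
    events += 1.0;
    if (events >= max_events) { exhausted = true; break; }
  }
  while (isamp < ns) {
    for (int s = 0; s < nsp; ++s) out(isamp, s) = x[s];
    ++isamp;
  }
  return List::create(_["states"] = out, _["events"] = events,
                      _["t_end"] = t, _["exhausted"] = exhausted);
}
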