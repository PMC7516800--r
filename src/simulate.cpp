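#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis dynamics on a weighted network, pair-once Hamiltonian
// H = -sum_{i<j} J_ij s_i s_j. One iteration is one time step: a
// simultaneous update of all spins (synchronous mode) or n random
// single-site attempts (sequential mode, the standard Monte-Carlo
// step-per-site convention); observables are recorded once per time step.
// Uses R's RNG so traces are reproducible under set.seed(); draw order
// matches the R-level step functions exactly: initialization draws n
// variates (one per spin, node order), then each synchronous step draws n
// variates in node order, and each sequential step draws (site, acceptance)
// n times.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix J, double temperature,
                  int n_thermalization, int n_iterations,
                  bool synchronous) {
  const int n = J.nrow();
  std::vector<double> s(n);
  for (int i = 0; i < n; ++i) s[i] = (unif_rand() < 0.5) ? -1.0 : 1.0;

  // local field h_i = sum_j J_ij s_j, maintained incrementally
  std::vector<double> h(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) h[i] += J(i, j) * s[j];

  double energy = 0.0;
  for (int i = 0; i < n; ++i) energy += s[i] * h[i];
  energy *= -0.5;

  IntegerVector state_code(n_iterations);
  NumericVector magnetization(n_iterations), energy_out(n_iterations);
  std::vector<double> u(n), dE(n);

  const int total = n_thermalization + n_iterations;
  for (int t = 0; t < total; ++t) {
    if (synchronous) {
      for (int i = 0; i < n; ++i) dE[i] = 2.0 * s[i] * h[i];
      for (int i = 0; i < n; ++i) u[i] = unif_rand();
      bool any_flip = false;
      for (int i = 0; i < n; ++i) {
        double p = (dE[i] > 0) ? std::exp(-dE[i] / temperature) : 1.0;
        if (u[i] < p) { s[i] = -s[i]; any_flip = true; }
      }
      if (any_flip) {
        for (int i = 0; i < n; ++i) {
          h[i] = 0.0;
          for (int j = 0; j < n; ++j) h[i] += J(i, j) * s[j];
        }
        energy = 0.0;
        for (int i = 0; i < n; ++i) energy += s[i] * h[i];
        energy *= -0.5;
      }
    } else {
      for (int k = 0; k < n; ++k) {
        int i = (int)(unif_rand() * n);
        if (i >= n) i = n - 1;
        double de = 2.0 * s[i] * h[i];
        double p = (de > 0) ? std::exp(-de / temperature) : 1.0;
        double uu = unif_rand();
        if (uu < p) {
          s[i] = -s[i];
          energy += de;
          for (int j = 0; j < n; ++j) h[j] += 2.0 * J(j, i) * s[i];
        }
      }
    }
    if (t >= n_thermalization) {
      int k = t - n_thermalization;
      int code = 0;
      double m = 0.0;
      for (int i = 0; i < n; ++i) {
        if (s[i] > 0) code |= (1 << i);
        m += s[i];
      }
      state_code[k] = code;
      magnetization[k] = std::fabs(m) / n;
      energy_out[k] = energy;
    }
  }
  return List::create(_["state_code"] = state_code,
                      _["magnetization"] = magnetization,
                      _["energy"] = energy_out);
}
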