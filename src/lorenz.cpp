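// Fixed-step RK4 integration of the Lorenz system, returning the x
// component sampled every `substeps` steps. Fixed-step + fixed parameters
// make the trace bit-reproducible across platforms with IEEE doubles.
#include <Rcpp.h>
using namespace Rcpp;

static inline void lorenz_deriv(const double s[3], double d[3],
                                double sigma, double rho, double beta) {
  d[0] = sigma * (s[1] - s[0]);
  d[1] = s[0] * (rho - s[2]) - s[1];
  d[2] = s[0] * s[1] - beta * s[2];
}

// [[Rcpp::export(name = ".lorenz_x_cpp")]]
NumericVector lorenz_x_cpp(int n_samples, double dt, int substeps,
                           double x0, double y0, double z0, int skip,
                           double sigma = 10.0, double rho = 28.0,
                           double beta = 8.0 / 3.0) {
  NumericVector out(n_samples);
  double s[3] = {x0, y0, z0};
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  long total = (long)skip + (long)n_samples * substeps;
  long rec = 0;
  for (long step = 0; step < total; ++step) {
    lorenz_deriv(s, k1, sigma, rho, beta);
    for (int i = 0; i < 3; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
    lorenz_deriv(tmp, k2, sigma, rho, beta);
    for (int i = 0; i < 3; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
    lorenz_deriv(tmp, k3, sigma, rho, beta);
    for (int i = 0; i < 3; ++i) tmp[i] = s[i] + dt * k3[i];
    lorenz_deriv(tmp, k4, sigma, rho, beta);
    for (int i = 0; i < 3; ++i)
      s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    long after = step + 1 - skip;
    if (after > 0 && after % substeps == 0 && rec < n_samples)
      out[rec++] = s[0];
  }
  return out;
}
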