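#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Euler-Maruyama integrator for a single particle dragged by a
// harmonic guide across a sum-of-Gaussians potential.
//
//   x_{t+dt} = x_t + (dt/gamma) * ( -U'(x_t) + k (lambda_t - x_t) )
//              + sqrt(2 kT dt / gamma) * xi
//
// External work follows the stiff-spring convention,
// dW = k (lambda - x) dlambda, accumulated with the pre-update state so
// that W(0) = 0 exactly. The noise vector is drawn in R so that seeding
// stays under R's RNG.
// [[Rcpp::export]]
List sim_pull_impl(double x0, double lambda0, double sgn, double velocity,
                   double dt, int n_steps, double spring, double friction,
                   double kT, NumericVector g_height, NumericVector g_center,
                   NumericVector g_width, NumericVector noise) {
  if (noise.size() < n_steps)
    stop("noise vector shorter than the number of steps");
  NumericVector x(n_steps + 1), lambda(n_steps + 1), work(n_steps + 1),
      tt(n_steps + 1);
  const double mob = dt / friction;
  const double sig = std::sqrt(2.0 * kT * dt / friction);
  const double dlam = sgn * velocity * dt;
  const int ng = g_height.size();
  double xc = x0, lc = lambda0, wc = 0.0;
  x[0] = xc;
  lambda[0] = lc;
  work[0] = 0.0;
  tt[0] = 0.0;
  for (int i = 0; i < n_steps; ++i) {
    double grad = 0.0;  // U'(x)
    for (int j = 0; j < ng; ++j) {
      const double d = (xc - g_center[j]) / g_width[j];
      grad += -g_height[j] * d / g_width[j] * std::exp(-0.5 * d * d);
    }
    const double fguide = spring * (lc - xc);
    wc += fguide * dlam;
    xc += mob * (-grad + fguide) + sig * noise[i];
    lc += dlam;
    x[i + 1] = xc;
    lambda[i + 1] = lc;
    work[i + 1] = wc;
    tt[i + 1] = (i + 1) * dt;
  }
  return List::create(_["time"] = tt, _["lambda"] = lambda,
                      _["position"] = x, _["work"] = work);
}
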