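#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin (Brownian dynamics) integrator on
//   U_total(z, b) = U_pmf(z, b) + U_bias(z) + U_restraint(z, b)
// with U_pmf a sum of Gaussians in z plus an optional radial harmonic term,
// U_bias = 0.5 * k * (z - z0)^2 and flat-bottom harmonic walls.
//
// Update rule per step (Euler-Maruyama):
//   x <- x + (D / kBT) * F(x) * dt + sqrt(2 * D * dt) * xi
// b additionally receives the entropic Jacobian drift (D / b) * dt when
// `radial_jacobian` is true (b is a distance-from-axis coordinate, so the
// unbiased radial density is proportional to b), with the drift denominator
// floored at `b_floor` and a reflecting boundary at b = 0.
//
// Uses R's RNG (norm_rand) so results are reproducible under set.seed().

static inline double pmf_dUdz(double z, const NumericVector& gh,
                              const NumericVector& gc, const NumericVector& gw) {
  double d = 0.0;
  for (int i = 0; i < gh.size(); ++i) {
    double u = (z - gc[i]) / gw[i];
    d += gh[i] * std::exp(-0.5 * u * u) * (-(z - gc[i]) / (gw[i] * gw[i]));
  }
  return d;
}

// [[Rcpp::export(name = ".bd_chain")]]
NumericMatrix bd_chain(double z_init, double b_init,
                       int n_steps, int stride,
                       double dt, double D, double kBT,
                       NumericVector gh, NumericVector gc, NumericVector gw,
                       double radial_k,
                       bool has_bias, double bias_k, double bias_z0,
                       double z_min, double z_max, double b_max, double wall_k,
                       bool radial_jacobian, double b_floor) {
  if (n_steps < stride)
    stop("n_steps must be at least sample_stride");
  const int n_keep = n_steps / stride;
  NumericMatrix out(n_keep, 2);
  double z = z_init, b = b_init;
  const double mob = D / kBT * dt;        // mobility * dt
  const double sig = std::sqrt(2.0 * D * dt);
  int kept = 0;
  for (int s = 1; s <= n_steps; ++s) {
    // forces F = -dU/dx
    double Fz = -pmf_dUdz(z, gh, gc, gw);
    double Fb = -radial_k * b;
    if (has_bias) Fz += -bias_k * (z - bias_z0);
    if (z > z_max) Fz += -wall_k * (z - z_max);
    if (z < z_min) Fz += -wall_k * (z - z_min);
    if (b > b_max) Fb += -wall_k * (b - b_max);
    double dz = mob * Fz + sig * norm_rand();
    double db = mob * Fb + sig * norm_rand();
    if (radial_jacobian) db += D / std::max(b, b_floor) * dt;
    if (std::fabs(dz) > 5.0 || std::fabs(db) > 5.0)
      stop("divergent step (displacement > 5 A at step %d); reduce dt or D", s);
    z += dz;
    b = std::fabs(b + db);                 // reflecting boundary at b = 0
    if (s % stride == 0) {
      out(kept, 0) = z;
      out(kept, 1) = b;
      ++kept;
    }
  }
  return out;
}
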