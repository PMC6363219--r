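#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Potential U(z,c) = sum_g A_g exp(-(z-zg)^2/(2 szg^2) - (c-cg)^2/(2 scg^2))
//                  + 0.5 * kappa_c * c^2
// wells: matrix with columns amp, z0, sz, c0, sc.
static inline void grad_u(const NumericMatrix& wells, double kappa_c,
                          double z, double c, double* gz, double* gc) {
  double dz = 0.0, dc = 0.0;
  const int G = wells.nrow();
  for (int g = 0; g < G; ++g) {
    const double a  = wells(g, 0);
    const double uz = (z - wells(g, 1)) / wells(g, 2);
    const double uc = (c - wells(g, 3)) / wells(g, 4);
    const double e  = a * std::exp(-0.5 * (uz * uz + uc * uc));
    dz += -e * uz / wells(g, 2);
    dc += -e * uc / wells(g, 4);
  }
  dc += kappa_c * c;
  *gz = dz;
  *gc = dc;
}

// Overdamped Euler-Maruyama on (z, c); harmonic umbrella bias on z optional
// (kbias <= 0 means unbiased). Reflecting walls at [zmin, zmax].
// Frames recorded every `stride` steps, including the initial state.
// [[Rcpp::export]]
List bd_simulate_cpp(NumericMatrix wells, double kappa_c, double kBT,
                     double Dz, double Dc, double zmin, double zmax,
                     double zbias, double kbias,
                     double z_init, double c_init,
                     int n_steps, double dt, int stride, int seed,
                     int n_burn) {
  if (n_steps < 0) stop("n_steps must be non-negative");
  if (dt <= 0) stop("dt must be positive");
  if (stride < 1) stop("stride must be >= 1");

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> norm(0.0, 1.0);

  const int n_frames = n_steps / stride + 1;
  NumericVector zs(n_frames), cs(n_frames);

  const double sz = std::sqrt(2.0 * Dz * dt);
  const double sc = std::sqrt(2.0 * Dc * dt);
  double z = z_init, c = c_init, gz, gc;

  // unrecorded equilibration steps
  for (int s = 0; s < n_burn; ++s) {
    grad_u(wells, kappa_c, z, c, &gz, &gc);
    if (kbias > 0) gz += kbias * (z - zbias);
    z += -(Dz / kBT) * gz * dt + sz * norm(rng);
    c += -(Dc / kBT) * gc * dt + sc * norm(rng);
    while (z < zmin || z > zmax) {
      if (z < zmin) z = 2.0 * zmin - z;
      if (z > zmax) z = 2.0 * zmax - z;
    }
  }

  zs[0] = z; cs[0] = c;
  int out = 1;
  for (int s = 1; s <= n_steps; ++s) {
    grad_u(wells, kappa_c, z, c, &gz, &gc);
    if (kbias > 0) gz += kbias * (z - zbias);
    z += -(Dz / kBT) * gz * dt + sz * norm(rng);
    c += -(Dc / kBT) * gc * dt + sc * norm(rng);
    // reflecting walls in z
    while (z < zmin || z > zmax) {
      if (z < zmin) z = 2.0 * zmin - z;
      if (z > zmax) z = 2.0 * zmax - z;
    }
    if (s % stride == 0) { zs[out] = z; cs[out] = c; ++out; }
  }
  return List::create(_["z"] = zs, _["c"] = cs);
}

// Maximum |gradient| of U over a coarse (z, c) grid; used for the step-size
// stability criterion dt * max|grad U| * D / kBT << dz_scale.
// [[Rcpp::export]]
double max_abs_grad_cpp(NumericMatrix wells, double kappa_c,
                        double zmin, double zmax, double cmin, double cmax,
                        int nz, int nc) {
  double m = 0.0, gz, gc;
  for (int i = 0; i < nz; ++i) {
    const double z = zmin + (zmax - zmin) * i / (nz - 1.0);
    for (int j = 0; j < nc; ++j) {
      const double c = cmin + (cmax - cmin) * j / (nc - 1.0);
      grad_u(wells, kappa_c, z, c, &gz, &gc);
      const double g = std::sqrt(gz * gz + gc * gc);
      if (g > m) m = g;
    }
  }
  return m;
}

// [[Rcpp::export]]
NumericVector potential_cpp(NumericMatrix wells, double kappa_c,
                            NumericVector z, NumericVector c) {
  const int n = z.size();
  NumericVector u(n);
  const int G = wells.nrow();
  for (int i = 0; i < n; ++i) {
    double v = 0.5 * kappa_c * c[i] * c[i];
    for (int g = 0; g < G; ++g) {
      const double uz = (z[i] - wells(g, 1)) / wells(g, 2);
      const double uc = (c[i] - wells(g, 3)) / wells(g, 4);
      v += wells(g, 0) * std::exp(-0.5 * (uz * uz + uc * uc));
    }
    u[i] = v;
  }
  return u;
}
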