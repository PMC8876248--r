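#include <Rcpp.h>
using namespace Rcpp;

// Analytic gradients of the canonical surfaces. Codes:
// 0 flat, 1 harmonic (par[0]=k_surface), 2 square_well (gradient 0),
// 3 membrane_double_well (par = D, B, z_min, z_wall).
static inline double surf_grad(int code, const double *par, double z) {
  switch (code) {
  case 0: return 0.0;
  case 1: return par[0] * z;
  case 2: return 0.0;
  case 3: {
    double D = par[0], B = par[1], zmin = par[2], zwall = par[3];
    double az = std::fabs(z), s = (z < 0.0) ? -1.0 : 1.0;
    double y0, y1, x0, x1;
    if (az <= zmin)      { x0 = 0.0;  x1 = zmin;  y0 = -(D - B); y1 = -D; }
    else if (az < zwall) { x0 = zmin; x1 = zwall; y0 = -D;       y1 = 0.0; }
    else return 0.0;
    double t = (az - x0) / (x1 - x0);
    return s * (y1 - y0) * (6.0 * t - 6.0 * t * t) / (x1 - x0);
  }
  }
  return 0.0;
}

// Overdamped (Brownian) Euler-Maruyama on U(z) = G(z) + k/2 (z - zref)^2:
//   z <- z - D/RT * U'(z) * dt + sqrt(2 D dt) * xi.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".brownian_path")]]
NumericVector brownian_path(int surf_code, NumericVector surf_par,
                            double z_ref, double k_bias,
                            int n_steps, double dt, double diffusion,
                            double rt, double z0) {
  NumericVector out(n_steps);
  const double mob = diffusion * dt / rt;      // mobility * dt
  const double noise = std::sqrt(2.0 * diffusion * dt);
  const double *par = surf_par.begin();
  double z = z0;
  GetRNGstate();
  for (int i = 0; i < n_steps; ++i) {
    double g = surf_grad(surf_code, par, z) + k_bias * (z - z_ref);
    if (!R_FINITE(g)) {
      PutRNGstate();
      stop("non-finite surface gradient at z = %f (step %d)", z, i + 1);
    }
    z += -mob * g + noise * norm_rand();
    out[i] = z;
  }
  PutRNGstate();
  return out;
}
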