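#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double wrap0L(double z, double L) {
  z = std::fmod(z, L);
  if (z < 0.0) z += L;
  return z;
}

static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// Overdamped (Brownian) Euler-Maruyama integrator for independent walkers
// on a shared 1-D potential.  The deterministic force is the sum of an
// interpolated potential force (uniform grid; periodic grids must include
// both endpoints with equal force values), a constant field force, an
// optional per-walker harmonic bias (minimum-image displacement when
// periodic) and an optional step restraint that pushes walkers away from a
// boundary plane inside a narrow transition region.
//
// Update: z' = z + beta*D*F(z)*dt + sqrt(2*D*dt)*eta, eta ~ N(0,1).
// Noise is drawn from R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix bd_simulate_cpp(NumericVector z0, int n_steps, double dt,
                              double D, double kT,
                              NumericVector grid_x, NumericVector grid_f,
                              double periodic_L,
                              NumericVector bias_center, double bias_k,
                              double field_force,
                              double restraint_boundary,
                              double restraint_halfwidth,
                              double restraint_force,
                              bool has_restraint,
                              int sample_every) {
  const int nw = z0.size();
  const bool periodic = periodic_L > 0.0;
  const bool has_bias = bias_center.size() == nw && bias_k > 0.0;
  const int ng = grid_x.size();
  const double gx0 = ng > 0 ? grid_x[0] : 0.0;
  const double gh  = ng > 1 ? grid_x[1] - grid_x[0] : 1.0;
  const int n_samp = n_steps / sample_every;

  NumericMatrix out(n_samp, nw);
  std::vector<double> z(z0.begin(), z0.end());
  const double beta = 1.0 / kT;
  const double sig = std::sqrt(2.0 * D * dt);
  const double mob = beta * D * dt;

  int row = 0;
  for (int s = 1; s <= n_steps; ++s) {
    for (int w = 0; w < nw; ++w) {
      double zz = z[w];
      double F = field_force;
      if (ng > 1) {
        double u;
        if (periodic) {
          u = wrap0L(zz - gx0, periodic_L) / gh;
          if (u > ng - 1) u = ng - 1;  // guard rounding at the seam
        } else {
          u = (zz - gx0) / gh;
          if (u < 0.0) u = 0.0;
          if (u > ng - 1) u = ng - 1;
        }
        int i = (int)std::floor(u);
        if (i >= ng - 1) i = ng - 2;
        double frac = u - i;
        F += grid_f[i] * (1.0 - frac) + grid_f[i + 1] * frac;
      }
      if (has_bias) {
        double d = zz - bias_center[w];
        if (periodic) d = min_image(d, periodic_L);
        F -= bias_k * d;
      }
      if (has_restraint) {
        double u = zz - restraint_boundary;
        if (periodic) u = min_image(u, periodic_L);
        if (u >= 0.0 && u < restraint_halfwidth) F += restraint_force;
        else if (u < 0.0 && u > -restraint_halfwidth) F -= restraint_force;
      }
      double dz = mob * F + sig * norm_rand();
      if (periodic && std::fabs(dz) > 0.5 * periodic_L)
        stop("divergent step at t = %g ns: |dz| = %g nm exceeds half the box"
             " (L = %g nm); reduce the time step",
             s * dt, std::fabs(dz), periodic_L);
      zz += dz;
      if (periodic) zz = wrap0L(zz, periodic_L);
      z[w] = zz;
    }
    if (s % sample_every == 0) {
      for (int w = 0; w < nw; ++w) out(row, w) = z[w];
      ++row;
    }
  }
  return out;
}

// WHAM self-consistency iteration.
//   p(b)   = sum_i n_i(b) / sum_i N_i f_i c_i(b),   c_i(b) = exp(-beta w_i(b))
//   f_i^-1 = sum_b p(b) c_i(b)
// iterated until max_i |kT * d(ln f_i)| < tol.  p is normalised to unit
// total mass each sweep.  counts: n_windows x n_bins; cmat likewise.
// [[Rcpp::export]]
List wham_solve_cpp(NumericMatrix counts, NumericVector N_i,
                    NumericMatrix cmat, NumericVector f_init,
                    double kT, double tol, int max_iter) {
  const int nwin = counts.nrow();
  const int nb = counts.ncol();
  std::vector<double> ntot(nb, 0.0);
  for (int b = 0; b < nb; ++b)
    for (int i = 0; i < nwin; ++i) ntot[b] += counts(i, b);

  std::vector<double> f(f_init.begin(), f_init.end());
  std::vector<double> p(nb, 0.0);
  double resid = R_PosInf;
  int it = 0;
  bool converged = false;

  while (it < max_iter) {
    ++it;
    double psum = 0.0;
    for (int b = 0; b < nb; ++b) {
      double den = 0.0;
      for (int i = 0; i < nwin; ++i) den += N_i[i] * f[i] * cmat(i, b);
      p[b] = den > 0.0 ? ntot[b] / den : 0.0;
      psum += p[b];
    }
    for (int b = 0; b < nb; ++b) p[b] /= psum;

    resid = 0.0;
    for (int i = 0; i < nwin; ++i) {
      double s = 0.0;
      for (int b = 0; b < nb; ++b) s += p[b] * cmat(i, b);
      double fn = 1.0 / s;
      double ch = std::fabs(kT * (std::log(fn) - std::log(f[i])));
      if (ch > resid) resid = ch;
      f[i] = fn;
    }
    if (resid < tol) { converged = true; break; }
  }

  return List::create(_["p"] = NumericVector(p.begin(), p.end()),
                      _["f"] = NumericVector(f.begin(), f.end()),
                      _["iterations"] = it,
                      _["residual"] = resid,
                      _["converged"] = converged);
}
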