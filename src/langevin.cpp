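// Overdamped Langevin (Brownian) integrator for ions in a 1D channel
// potential with radial confinement.  Euler-Maruyama update
//   dr = F * (D/kT) * dt + sqrt(2 D dt) * xi
// Axial forces: Gaussian wells/barriers, linear field on an interval,
// screened-Coulomb pair repulsion (projected on the axis), optional
// per-ion harmonic bias (umbrella restraints).  z-boundaries: reflecting
// wall at the top, re-injection (teleport by +Lz, logged) below the
// bottom wall.  Uses R's RNG so a set.seed() in R fixes the trajectory.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix init,        // n_ions x 3 (x, y, z)
                  NumericVector charges,     // e
                  int n_steps, double dt, double D, double kT,
                  int stride,
                  double zlo, double zhi,
                  double pore_lo, double pore_hi,
                  double r_pore, double r_out, double k_rad,
                  NumericVector well_c, NumericVector well_d, NumericVector well_w,
                  NumericVector bar_c, NumericVector bar_h, NumericVector bar_w,
                  double field, double field_lo, double field_hi,
                  double rep_A, double rep_lambda, double rep_core,
                  NumericVector bias_k, NumericVector bias_c,
                  double mobility, double max_step, int reflect_bottom)
{
  const int n = init.nrow();
  const double Lz = zhi - zlo;
  const double noise = (kT > 0.0) ? std::sqrt(2.0 * D * dt) : 0.0;
  const int n_frames = n_steps / stride + 1;

  std::vector<double> x(n), y(n), z(n), wrap_off(n, 0.0);
  for (int i = 0; i < n; ++i) {
    x[i] = init(i, 0); y[i] = init(i, 1); z[i] = init(i, 2);
  }

  NumericVector coords(static_cast<R_xlen_t>(n_frames) * n * 3);
  NumericMatrix zunwrap(n_frames, n);
  std::vector<double> exit_step;
  std::vector<int> exit_ion, exit_dir;

  RNGScope rng;

  auto save_frame = [&](int f) {
    for (int i = 0; i < n; ++i) {
      coords[f + n_frames * (R_xlen_t)(i)]             = x[i];
      coords[f + n_frames * (R_xlen_t)(i + n)]         = y[i];
      coords[f + n_frames * (R_xlen_t)(i + 2 * n)]     = z[i];
      zunwrap(f, i) = z[i] - wrap_off[i];
    }
  };
  save_frame(0);

  const int nw = well_c.size(), nb = bar_c.size();
  int frame = 1;

  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      double fz = 0.0;
      // wells / barriers
      for (int k = 0; k < nw; ++k) {
        double d = z[i] - well_c[k], w2 = well_w[k] * well_w[k];
        fz += -well_d[k] * d / w2 * std::exp(-d * d / (2.0 * w2));
      }
      for (int k = 0; k < nb; ++k) {
        double d = z[i] - bar_c[k], w2 = bar_w[k] * bar_w[k];
        fz += bar_h[k] * d / w2 * std::exp(-d * d / (2.0 * w2));
      }
      // field (force on charge q is q*field inside the interval)
      if (field != 0.0 && z[i] >= field_lo && z[i] <= field_hi)
        fz += charges[i] * field;
      // pair repulsion along the axis, soft-core regularized at short
      // range (r -> sqrt(dz^2 + rc^2)); negligible beyond ~2*rc
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dz = z[i] - z[j];
        double r = std::sqrt(dz * dz + rep_core * rep_core);
        double u = rep_A * charges[i] * charges[j] / r * std::exp(-r / rep_lambda);
        double fmag = u * (1.0 / r + 1.0 / rep_lambda); // -dU/dr
        fz += fmag * dz / r;
      }
      // umbrella bias
      if (bias_k[i] > 0.0) fz += -bias_k[i] * (z[i] - bias_c[i]);

      // radial flat-bottom confinement
      double fx = 0.0, fy = 0.0;
      double R = (z[i] >= pore_lo && z[i] <= pore_hi) ? r_pore : r_out;
      double r2 = x[i] * x[i] + y[i] * y[i];
      if (r2 > R * R) {
        double r = std::sqrt(r2);
        double f = -k_rad * (r - R) / r;
        fx = f * x[i]; fy = f * y[i];
      }

      double dxs = fx * mobility * dt + (noise > 0 ? noise * norm_rand() : 0.0);
      double dys = fy * mobility * dt + (noise > 0 ? noise * norm_rand() : 0.0);
      double dzs = fz * mobility * dt + (noise > 0 ? noise * norm_rand() : 0.0);
      if (std::fabs(dzs) > max_step || std::fabs(dxs) > max_step ||
          std::fabs(dys) > max_step)
        stop("step displacement exceeded %g A at step %d; reduce the timestep",
             max_step, s);
      x[i] += dxs; y[i] += dys; z[i] += dzs;

      // top wall: reflect
      if (z[i] > zhi) z[i] = 2.0 * zhi - z[i];
      if (z[i] > zhi) z[i] = zhi;   // double overshoot guard
      if (reflect_bottom && z[i] < zlo) {
        z[i] = 2.0 * zlo - z[i];
        if (z[i] < zlo) z[i] = zlo;
      }
      // bottom: re-injection at the extracellular reservoir (teleport +Lz,
      // raw exit logged; the unwrapped record excludes the teleport)
      if (z[i] < zlo) {
        exit_step.push_back(s * dt);
        exit_ion.push_back(i + 1);
        exit_dir.push_back(-1);
        z[i] += Lz;
        wrap_off[i] += Lz;
      }
    }
    if (s % stride == 0) save_frame(frame++);
  }

  coords.attr("dim") = IntegerVector::create(n_frames, n, 3);
  return List::create(
    _["coords"] = coords,
    _["z_unwrapped"] = zunwrap,
    _["exit_time_ps"] = NumericVector(exit_step.begin(), exit_step.end()),
    _["exit_ion"] = IntegerVector(exit_ion.begin(), exit_ion.end()),
    _["exit_dir"] = IntegerVector(exit_dir.begin(), exit_dir.end()));
}
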