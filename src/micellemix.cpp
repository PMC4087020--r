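#include <Rcpp.h>
using namespace Rcpp;

static inline double min_image(double d, double box) {
  return d - box * std::round(d / box);
}

// Closest-bead minimum-image distance matrix between molecules.
// pos: n_beads x 3 (Angstrom), mol: 0-based molecule index per bead,
// n_mol: number of molecules, box: cubic edge (Angstrom).
// [[Rcpp::export]]
NumericMatrix cpp_closest_bead_matrix(NumericMatrix pos, IntegerVector mol,
                                      int n_mol, double box) {
  int n = pos.nrow();
  NumericMatrix out(n_mol, n_mol);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int m = 0; m < n_mol; ++m) out(m, m) = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int mi = mol[i], mj = mol[j];
      if (mi == mj) continue;
      double dx = min_image(pos(i, 0) - pos(j, 0), box);
      double dy = min_image(pos(i, 1) - pos(j, 1), box);
      double dz = min_image(pos(i, 2) - pos(j, 2), box);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < out(mi, mj)) { out(mi, mj) = d; out(mj, mi) = d; }
    }
  }
  return out;
}

// Overdamped Langevin dynamics for coarse-grained bead chains in a cubic
// periodic box. Forces: harmonic bonds along each chain, Lennard-Jones
// attraction/repulsion with a per-bead-type-pair well depth, and a screened
// Coulomb (Yukawa) term between charged beads. Friction coefficient is 1 in
// reduced units, so dx = dt * F + sqrt(2 T dt) * eta.
//
// pos0: n x 3 start coordinates (Angstrom, wrapped); type: 0-based bead
// type; bonds: m x 2 matrix of 0-based bead indices; eps: n_type x n_type
// LJ well depths; charge: per-bead charge.
// Returns a list of n_snapshots coordinate matrices (wrapped), including
// the initial state.
// [[Rcpp::export]]
List cpp_toy_langevin(NumericMatrix pos0, IntegerVector type,
                      IntegerMatrix bonds, NumericVector charge,
                      NumericMatrix eps, double sigma, double rcut,
                      double k_bond, double b0, double coul_strength,
                      double screening_length, double box, double dt,
                      double temperature, int n_steps, int stride,
                      double fmax) {
  int n = pos0.nrow();
  int nb = bonds.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
  }
  int n_snap = n_steps / stride + 1;
  List snaps(n_snap);
  NumericVector times(n_snap);
  {
    NumericMatrix s0(n, 3);
    for (int i = 0; i < n; ++i) { s0(i,0)=x[i]; s0(i,1)=y[i]; s0(i,2)=z[i]; }
    snaps[0] = s0;
  }
  double rcut2 = rcut * rcut;
  double noise = std::sqrt(2.0 * temperature * dt);
  int snap_idx = 1;
  for (int step = 1; step <= n_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    // non-bonded pairs
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = min_image(x[i] - x[j], box);
        if (dx >= rcut || dx <= -rcut) continue;
        double dy = min_image(y[i] - y[j], box);
        if (dy >= rcut || dy <= -rcut) continue;
        double dz = min_image(z[i] - z[j], box);
        if (dz >= rcut || dz <= -rcut) continue;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rcut2 || r2 < 1e-12) continue;
        double r = std::sqrt(r2);
        double fmag = 0.0; // force along +rij acting on i (repulsive > 0)
        double e = eps(type[i], type[j]);
        if (e > 0.0) {
          double sr = sigma / r;
          double sr6 = sr * sr * sr; sr6 = sr6 * sr6;
          double sr12 = sr6 * sr6;
          // dU/dr of 4e(sr12 - sr6); force = -dU/dr
          fmag += 24.0 * e * (2.0 * sr12 - sr6) / r;
        }
        double qq = charge[i] * charge[j];
        if (qq != 0.0 && coul_strength != 0.0) {
          double ex = std::exp(-r / screening_length);
          // U = A q_i q_j exp(-r/l)/r; F = A q_i q_j (1/r^2 + 1/(l r)) exp(-r/l)
          fmag += coul_strength * qq * ex * (1.0 / r2 + 1.0 / (screening_length * r));
        }
        if (fmag > fmax) fmag = fmax;
        if (fmag < -fmax) fmag = -fmax;
        double fxp = fmag * dx / r, fyp = fmag * dy / r, fzp = fmag * dz / r;
        fx[i] += fxp; fy[i] += fyp; fz[i] += fzp;
        fx[j] -= fxp; fy[j] -= fyp; fz[j] -= fzp;
      }
    }
    // bonds
    for (int b = 0; b < nb; ++b) {
      int i = bonds(b, 0), j = bonds(b, 1);
      double dx = min_image(x[i] - x[j], box);
      double dy = min_image(y[i] - y[j], box);
      double dz = min_image(z[i] - z[j], box);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-9) continue;
      double fmag = -k_bond * (r - b0);
      double fxp = fmag * dx / r, fyp = fmag * dy / r, fzp = fmag * dz / r;
      fx[i] += fxp; fy[i] += fyp; fz[i] += fzp;
      fx[j] -= fxp; fy[j] -= fyp; fz[j] -= fzp;
    }
    // integrate
    for (int i = 0; i < n; ++i) {
      double nx = x[i] + dt * fx[i] + noise * norm_rand();
      double ny = y[i] + dt * fy[i] + noise * norm_rand();
      double nz = z[i] + dt * fz[i] + noise * norm_rand();
      if (!std::isfinite(nx) || !std::isfinite(ny) || !std::isfinite(nz)) {
        stop("Toy dynamics became unstable at step %d (non-finite coordinate); reduce the step size.", step);
      }
      x[i] = nx - box * std::floor(nx / box);
      y[i] = ny - box * std::floor(ny / box);
      z[i] = nz - box * std::floor(nz / box);
    }
    if (step % stride == 0 && snap_idx < n_snap) {
      NumericMatrix s(n, 3);
      for (int i = 0; i < n; ++i) { s(i,0)=x[i]; s(i,1)=y[i]; s(i,2)=z[i]; }
      snaps[snap_idx++] = s;
    }
    if (step % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return snaps;
}
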