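// Source-function evaluation: for reference points r, accumulate
//   SF(r, Omega) = -(1/4pi) sum_voxels w(voxel, Omega) * lap(voxel) * V / |r - r_voxel|
// over every voxel of the grid (no cutoff). Near-field treatment: the voxel
// containing r and its 26 neighbours are re-integrated on a q^3 subdivision
// (the kernel varies strongly across a voxel there), and the subcell holding
// r itself gets the equal-volume-sphere rule
//   -lap * R^2 / 2,  R = (3 V_sub / 4 pi)^(1/3),
// the standard integrable-singularity correction. Far voxels use the plain
// midpoint rule. Long-double accumulators keep the heavy source/sink
// cancellation below the symmetry tolerances exercised in the tests.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NSUB = 6;  // near-field subdivision per axis

// [[Rcpp::export(name = ".sf_eval_cpp")]]
NumericMatrix sf_eval_cpp(NumericMatrix points, IntegerVector self_voxel,
                          NumericVector lap, IntegerVector dim,
                          NumericVector origin, NumericMatrix axes,
                          double voxel_volume, IntegerVector label,
                          IntegerVector frac_index, NumericMatrix frac_w,
                          bool periodic) {
  const int np = points.nrow();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  const int M = frac_w.ncol() > 0 ? frac_w.ncol() : 1;
  const double inv4pi = 1.0 / (4.0 * M_PI);
  const double Rself = std::cbrt(3.0 * voxel_volume / (4.0 * M_PI));
  const double vsub = voxel_volume / (NSUB * NSUB * NSUB);
  const double Rsub = std::cbrt(3.0 * vsub / (4.0 * M_PI));

  // inverse cell matrix for fractional coordinates of the reference point
  double A[3][3], B[3][3];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) A[r][c] = axes(r, c);
  {
    double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
                 A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
                 A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
    B[0][0] = (A[1][1] * A[2][2] - A[1][2] * A[2][1]) / det;
    B[1][0] = -(A[1][0] * A[2][2] - A[1][2] * A[2][0]) / det;
    B[2][0] = (A[1][0] * A[2][1] - A[1][1] * A[2][0]) / det;
    B[0][1] = -(A[0][1] * A[2][2] - A[0][2] * A[2][1]) / det;
    B[1][1] = (A[0][0] * A[2][2] - A[0][2] * A[2][0]) / det;
    B[2][1] = -(A[0][0] * A[2][1] - A[0][1] * A[2][0]) / det;
    B[0][2] = (A[0][1] * A[1][2] - A[0][2] * A[1][1]) / det;
    B[1][2] = -(A[0][0] * A[1][2] - A[0][2] * A[1][0]) / det;
    B[2][2] = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) / det;
  }

  std::vector<long> fslot(n, -1);
  for (int s = 0; s < frac_index.size(); ++s) fslot[frac_index[s]] = s;

  NumericMatrix out(np, M);
  std::vector<long double> acc(M);

  for (int p = 0; p < np; ++p) {
    const double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    const long self = self_voxel[p];  // zero-based flat index
    const int si = self % nx, sj = (self / nx) % ny,
              sk = self / ((long)nx * ny);
    std::fill(acc.begin(), acc.end(), (long double)0.0);

    // ---- far field: plain midpoint rule over every voxel ----------------
    long v = 0;
    for (int k = 0; k < nz; ++k) {
      const double bx = origin[0] + k * axes(2, 0);
      const double by = origin[1] + k * axes(2, 1);
      const double bz = origin[2] + k * axes(2, 2);
      for (int j = 0; j < ny; ++j) {
        double cx = bx + j * axes(1, 0);
        double cy = by + j * axes(1, 1);
        double cz = bz + j * axes(1, 2);
        for (int i = 0; i < nx; ++i, ++v) {
          double contrib;
          if (v == self) {
            contrib = -lap[v] * Rself * Rself / 2.0;
          } else {
            double dx = px - cx, dy = py - cy, dz = pz - cz;
            double d = std::sqrt(dx * dx + dy * dy + dz * dz);
            contrib = -inv4pi * lap[v] * voxel_volume / d;
          }
          int L = label[v];
          if (L > 0) {
            acc[L - 1] += contrib;
          } else {
            long s = fslot[v];
            for (int m = 0; m < M; ++m) acc[m] += contrib * frac_w(s, m);
          }
          cx += axes(0, 0); cy += axes(0, 1); cz += axes(0, 2);
        }
      }
    }

    // ---- near field: replace the 27 voxels around r by a subdivision ----
    // fractional coordinates of r and its containing subcell
    double fx = B[0][0] * (px - origin[0]) + B[1][0] * (py - origin[1]) +
                B[2][0] * (pz - origin[2]);
    double fy = B[0][1] * (px - origin[0]) + B[1][1] * (py - origin[1]) +
                B[2][1] * (pz - origin[2]);
    // (row-vector convention: u = (x - o) %*% solve(A))
    double fz = B[0][2] * (px - origin[0]) + B[1][2] * (py - origin[1]) +
                B[2][2] * (pz - origin[2]);

    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int ii = si + di, jj = sj + dj, kk = sk + dk;
          if (periodic) {
            ii = (ii + nx) % nx; jj = (jj + ny) % ny; kk = (kk + nz) % nz;
          } else if (ii < 0 || ii >= nx || jj < 0 || jj >= ny ||
                     kk < 0 || kk >= nz) {
            continue;
          }
          long w = ii + (long)nx * (jj + (long)ny * kk);
          // remove the plain contribution added in the main loop
          // (recomputed identically, so the subtraction is exact)
          double cx = origin[0] + ii * axes(0, 0) + jj * axes(1, 0) +
                      kk * axes(2, 0);
          double cy = origin[1] + ii * axes(0, 1) + jj * axes(1, 1) +
                      kk * axes(2, 1);
          double cz = origin[2] + ii * axes(0, 2) + jj * axes(1, 2) +
                      kk * axes(2, 2);
          double plain;
          if (w == self) {
            plain = -lap[w] * Rself * Rself / 2.0;
          } else {
            double dx = px - cx, dy = py - cy, dz = pz - cz;
            plain = -inv4pi * lap[w] * voxel_volume /
                    std::sqrt(dx * dx + dy * dy + dz * dz);
          }
          // subdivided re-integration; note near-field geometry uses the
          // unwrapped lattice offsets so periodic images sit where they are
          long double fine = 0.0;
          // subcell of this voxel containing r (if any)
          double ux = fx - (si + di - 0.5), uy = fy - (sj + dj - 0.5),
                 uz = fz - (sk + dk - 0.5);
          int rsx = (int)std::floor(ux * NSUB);
          int rsy = (int)std::floor(uy * NSUB);
          int rsz = (int)std::floor(uz * NSUB);
          for (int sc = 0; sc < NSUB; ++sc)
            for (int sb = 0; sb < NSUB; ++sb)
              for (int sa = 0; sa < NSUB; ++sa) {
                double oa = (sa + 0.5) / NSUB - 0.5;
                double ob = (sb + 0.5) / NSUB - 0.5;
                double oc = (sc + 0.5) / NSUB - 0.5;
                double qx = cx + oa * A[0][0] + ob * A[1][0] + oc * A[2][0];
                double qy = cy + oa * A[0][1] + ob * A[1][1] + oc * A[2][1];
                double qz = cz + oa * A[0][2] + ob * A[1][2] + oc * A[2][2];
                if (sa == rsx && sb == rsy && sc == rsz) {
                  fine += -lap[w] * Rsub * Rsub / 2.0;
                } else {
                  double dx = px - qx, dy = py - qy, dz = pz - qz;
                  double d = std::sqrt(dx * dx + dy * dy + dz * dz);
                  fine += -inv4pi * lap[w] * vsub / d;
                }
              }
          double delta = (double)(fine - (long double)plain);
          int L = label[w];
          if (L > 0) {
            acc[L - 1] += delta;
          } else {
            long s = fslot[w];
            for (int m = 0; m < M; ++m) acc[m] += delta * frac_w(s, m);
          }
        }

    for (int m = 0; m < M; ++m) out(p, m) = (double)acc[m];
  }
  return out;
}
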