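// Grid-based Bader partitioning: 26-neighbourhood density maxima and the
// Yu-Trinkle fractional-weight scheme. Voxels are visited in order of
// descending density; uphill flux through the Voronoi facets of the voxel
// (the 6 face neighbours on an orthogonal lattice) distributes basin weights,
// so zero-flux surfaces are realised as fractional boundary weights.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct GridIdx {
  int nx, ny, nz;
  bool periodic;
  inline long flat(int i, int j, int k) const {
    return i + (long)nx * (j + (long)ny * k);
  }
  // neighbour of v displaced by (di,dj,dk); returns -1 if outside a
  // non-periodic grid (reflecting boundary: no outward flux)
  inline long shift(long v, int di, int dj, int dk) const {
    int i = v % nx, j = (v / nx) % ny, k = v / ((long)nx * ny);
    i += di; j += dj; k += dk;
    if (periodic) {
      i = (i + nx) % nx; j = (j + ny) % ny; k = (k + nz) % nz;
    } else if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) {
      return -1;
    }
    return flat(i, j, k);
  }
};

} // namespace

// A maximum exceeds all 26 neighbours; exact density ties are broken by flat
// voxel index (matching the YT descending sort) so a plateau peak spanning
// several voxels yields exactly one maximum.
// [[Rcpp::export(name = ".find_maxima_cpp")]]
IntegerVector find_maxima_cpp(NumericVector rho, IntegerVector dim,
                              bool periodic) {
  GridIdx g{dim[0], dim[1], dim[2], periodic};
  const long n = (long)g.nx * g.ny * g.nz;
  std::vector<int> out;
  for (long v = 0; v < n; ++v) {
    bool is_max = true;
    for (int dk = -1; dk <= 1 && is_max; ++dk)
      for (int dj = -1; dj <= 1 && is_max; ++dj)
        for (int di = -1; di <= 1 && is_max; ++di) {
          if (!di && !dj && !dk) continue;
          long w = g.shift(v, di, dj, dk);
          if (w >= 0 &&
              (rho[w] > rho[v] || (rho[w] == rho[v] && w < v))) is_max = false;
        }
    if (is_max) out.push_back(v);  // zero-based flat index
  }
  return wrap(out);
}

// Returns list(label, frac_index, frac_w):
//   label: per-voxel 1-based basin for pure voxels, 0 for fractional ones
//   frac_index: zero-based flat indices of fractional voxels
//   frac_w: (nfrac x M) weight rows matching frac_index
// maxima: zero-based flat indices (basin m is maxima[m]); spacing: the three
// axis step lengths; low_thresh: voxels below it inherit their steepest-
// ascent neighbour's assignment without new flux work.
// Degenerate situations (exact ties in the steepest slope, equidistant
// maxima) average over the tied alternatives, so exact mirror symmetry of
// the density yields exactly mirror-symmetric weights.
// [[Rcpp::export(name = ".yt_weights_cpp")]]
List yt_weights_cpp(NumericVector rho, IntegerVector dim, bool periodic,
                    IntegerVector maxima, NumericVector spacing,
                    double voxel_volume, double low_thresh) {
  GridIdx g{dim[0], dim[1], dim[2], periodic};
  const long n = (long)g.nx * g.ny * g.nz;
  const int M = maxima.size();
  if (M < 1) stop("no density maxima supplied");

  std::vector<int> basin_of_max(n, -1);
  for (int m = 0; m < M; ++m) basin_of_max[maxima[m]] = m;

  // Voronoi facet flux coefficients area/distance for the 6 face neighbours
  double a1 = spacing[0], a2 = spacing[1], a3 = spacing[2];
  const int fo[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  double fc[6];
  fc[0] = fc[1] = (voxel_volume / a1) / a1;
  fc[2] = fc[3] = (voxel_volume / a2) / a2;
  fc[4] = fc[5] = (voxel_volume / a3) / a3;

  // 26-neighbour offsets with distances (steepest-ascent fallback)
  std::vector<std::array<int,3>> noff;
  std::vector<double> ndist;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj && !dk) continue;
        noff.push_back({di, dj, dk});
        ndist.push_back(std::sqrt(di*di*a1*a1 + dj*dj*a2*a2 + dk*dk*a3*a3));
      }

  // descending density, exact ties broken by flat index (determinism)
  std::vector<long> order(n);
  for (long v = 0; v < n; ++v) order[v] = v;
  std::sort(order.begin(), order.end(), [&](long a, long b) {
    if (rho[a] != rho[b]) return rho[a] > rho[b];
    return a < b;
  });

  std::vector<int> lab(n, -1);          // >=0 pure basin, -2 fractional
  std::vector<long> fslot(n, -1);
  std::vector<std::vector<double>> fw;  // weights of fractional voxels
  std::vector<long> fidx;

  // add coef * (weight row of assigned voxel w) into wacc
  auto add_row = [&](long w, double coef, std::vector<double>& wacc) {
    if (lab[w] >= 0) {
      wacc[lab[w]] += coef;
    } else {
      const std::vector<double>& nw = fw[fslot[w]];
      for (int m = 0; m < M; ++m) wacc[m] += coef * nw[m];
    }
  };
  // commit the accumulated row for voxel v: pure if one basin holds all
  // weight, else a new fractional entry
  auto commit = [&](long v, const std::vector<double>& wacc) {
    int nz = 0, last = -1;
    for (int m = 0; m < M; ++m) {
      if (wacc[m] != 0.0) { ++nz; last = m; }
    }
    if (nz == 1) {
      lab[v] = last;
    } else {
      lab[v] = -2;
      fslot[v] = fidx.size();
      fidx.push_back(v);
      fw.push_back(wacc);
    }
  };
  // basin one-hot (or tie-average) of the nearest maxima; last-resort only
  auto nearest_max_row = [&](long v, std::vector<double>& wacc) {
    int i = v % g.nx, j = (v / g.nx) % g.ny, k = v / ((long)g.nx * g.ny);
    double best = -1;
    std::vector<int> tied;
    for (int m = 0; m < M; ++m) {
      long u = maxima[m];
      int ui = u % g.nx, uj = (u / g.nx) % g.ny, uk = u / ((long)g.nx * g.ny);
      double dx = (i - ui) * a1, dy = (j - uj) * a2, dz = (k - uk) * a3;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (best < 0 || d2 < best) { best = d2; tied.clear(); tied.push_back(m); }
      else if (d2 == best) tied.push_back(m);
    }
    for (int m : tied) wacc[m] += 1.0 / tied.size();
  };
  // steepest already-assigned uphill 26-neighbour(s); exact slope ties are
  // averaged. Returns false if no uphill neighbour exists.
  auto steepest_row = [&](long v, std::vector<double>& wacc) {
    double rv = rho[v], best = 0;
    std::vector<long> tied;
    for (size_t q = 0; q < noff.size(); ++q) {
      long w = g.shift(v, noff[q][0], noff[q][1], noff[q][2]);
      if (w < 0 || lab[w] == -1 || rho[w] <= rv) continue;
      double sl = (rho[w] - rv) / ndist[q];
      if (tied.empty() || sl > best) { best = sl; tied.clear(); tied.push_back(w); }
      else if (sl == best) tied.push_back(w);
    }
    if (tied.empty()) return false;
    for (long w : tied) add_row(w, 1.0 / tied.size(), wacc);
    return true;
  };

  std::vector<double> wtmp(M);
  for (long t = 0; t < n; ++t) {
    long v = order[t];
    if (basin_of_max[v] >= 0) { lab[v] = basin_of_max[v]; continue; }
    double rv = rho[v];
    std::fill(wtmp.begin(), wtmp.end(), 0.0);

    if (rv < low_thresh) {
      // negligible population: inherit the steepest-ascent assignment
      if (!steepest_row(v, wtmp)) nearest_max_row(v, wtmp);
      commit(v, wtmp);
      continue;
    }

    // uphill flux through the 6 Voronoi facets
    double flux[6];
    long nb[6];
    double tot = 0;
    for (int q = 0; q < 6; ++q) {
      nb[q] = g.shift(v, fo[q][0], fo[q][1], fo[q][2]);
      flux[q] = 0;
      if (nb[q] >= 0 && rho[nb[q]] > rv && lab[nb[q]] != -1) {
        flux[q] = fc[q] * (rho[nb[q]] - rv);
        tot += flux[q];
      }
    }

    if (tot <= 0) {
      // ridge voxel (a 6-neighbour maximum that is not a 26-neighbourhood
      // maximum): hand it to its steepest uphill 26-neighbour; failing
      // that, adopt an already-assigned equal-density plateau neighbour,
      // or as a last resort the nearest maximum
      if (!steepest_row(v, wtmp)) {
        long eq = -1;
        for (size_t q = 0; q < noff.size() && eq < 0; ++q) {
          long w = g.shift(v, noff[q][0], noff[q][1], noff[q][2]);
          if (w >= 0 && lab[w] != -1 && rho[w] == rv) eq = w;
        }
        if (eq >= 0) add_row(eq, 1.0, wtmp);
        else nearest_max_row(v, wtmp);
      }
      commit(v, wtmp);
      continue;
    }

    for (int q = 0; q < 6; ++q) {
      if (flux[q] > 0) add_row(nb[q], flux[q] / tot, wtmp);
    }
    commit(v, wtmp);
  }

  for (long v = 0; v < n; ++v) {
    if (lab[v] == -1) stop("internal error: unassigned voxel in YT sweep");
  }

  IntegerVector label(n);
  for (long v = 0; v < n; ++v) label[v] = lab[v] >= 0 ? lab[v] + 1 : 0;
  IntegerVector frac_index(fidx.size());
  NumericMatrix frac_w(fidx.size(), M);
  for (size_t s = 0; s < fidx.size(); ++s) {
    frac_index[s] = fidx[s];
    for (int m = 0; m < M; ++m) frac_w(s, m) = fw[s][m];
  }
  return List::create(_["label"] = label, _["frac_index"] = frac_index,
                      _["frac_w"] = frac_w);
}
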