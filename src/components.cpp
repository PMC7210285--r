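#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 26-connected component labelling of a 3-D boolean mask, flat index with the
// first lattice index fastest. Periodic grids wrap across faces. Labels are
// renumbered by descending component size (1 = largest); non-mask voxels get 0.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   bool periodic) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  std::vector<int> lab(n, 0);
  std::vector<long> stack;
  int nlab = 0;
  std::vector<long> sizes;

  for (long seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    ++nlab;
    sizes.push_back(0);
    stack.push_back(seed);
    lab[seed] = nlab;
    while (!stack.empty()) {
      long v = stack.back();
      stack.pop_back();
      ++sizes[nlab - 1];
      int i = v % nx, j = (v / nx) % ny, k = v / ((long)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (periodic) {
              ii = (ii + nx) % nx; jj = (jj + ny) % ny; kk = (kk + nz) % nz;
            } else if (ii < 0 || ii >= nx || jj < 0 || jj >= ny ||
                       kk < 0 || kk >= nz) {
              continue;
            }
            long w = ii + (long)nx * (jj + (long)ny * kk);
            if (mask[w] && !lab[w]) {
              lab[w] = nlab;
              stack.push_back(w);
            }
          }
    }
  }

  // renumber by descending size, ties by original label order
  std::vector<int> order(nlab);
  for (int i = 0; i < nlab; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> newlab(nlab + 1, 0);
  for (int r = 0; r < nlab; ++r) newlab[order[r] + 1] = r + 1;

  IntegerVector out(n);
  for (long v = 0; v < n; ++v) out[v] = newlab[lab[v]];
  return out;
}
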