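// 26-connected component labeling of a 3D binary array (iterative BFS).
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector labels(n);
  const int *m = LOGICAL(mask);
  int *lab = INTEGER(labels);
  int next = 0;
  std::vector<size_t> queue;
  for (size_t start = 0; start < n; ++start) {
    if (!m[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      size_t idx = queue.back();
      queue.pop_back();
      const int z = (int)(idx / ((size_t)nx * ny));
      const int rem = (int)(idx % ((size_t)nx * ny));
      const int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            const size_t j = (size_t)xx + (size_t)nx * yy + (size_t)nx * ny * zz;
            if (m[j] && !lab[j]) { lab[j] = next; queue.push_back(j); }
          }
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// local maxima over the 26-neighborhood (ties count as maxima)
// [[Rcpp::export]]
LogicalVector cpp_local_max3d(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  LogicalVector out(n);
  const double *v = REAL(vol);
  for (size_t idx = 0; idx < n; ++idx) {
    if (v[idx] <= 0) continue;
    const int z = (int)(idx / ((size_t)nx * ny));
    const int rem = (int)(idx % ((size_t)nx * ny));
    const int y = rem / nx, x = rem % nx;
    bool ismax = true;
    for (int dz = -1; dz <= 1 && ismax; ++dz) {
      const int zz = z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = -1; dy <= 1 && ismax; ++dy) {
        const int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          const int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          if (v[(size_t)xx + (size_t)nx * yy + (size_t)nx * ny * zz] > v[idx]) {
            ismax = false;
            break;
          }
        }
      }
    }
    out[idx] = ismax;
  }
  out.attr("dim") = dim;
  return out;
}
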