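#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// 3D connected-component labelling, 6- or 26-connectivity, BFS.
// mask: logical vector in column-major order for dims (nx, ny, nz).
// Returns integer labels (0 = background), labels start at 1 in discovery order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");

  IntegerVector labels(n, 0);
  int next_label = 0;
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    labels[s] = ++next_label;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < dxs.size(); ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          q.push(w);
        }
      }
    }
  }
  return labels;
}

// Trilinear sampling of a 3D volume at arbitrary continuous coordinates.
// coords: N x 3 matrix of 0-based voxel coordinates. Points outside the grid
// (beyond the outermost voxel centres) return `outside`.
// [[Rcpp::export]]
NumericVector sample_trilinear_cpp(NumericVector vol, IntegerVector dims,
                                   NumericMatrix coords, double outside) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t np = coords.nrow();
  NumericVector out(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[i] = outside;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    int x1 = std::min(x0 + 1, nx - 1);
    int y1 = std::min(y0 + 1, ny - 1);
    int z1 = std::min(z0 + 1, nz - 1);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    #define V(a, b, c) vol[(a) + (R_xlen_t)nx * ((b) + (R_xlen_t)ny * (c))]
    double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
    double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
    double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
    double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
    #undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling; same conventions as sample_trilinear_cpp.
// [[Rcpp::export]]
NumericVector sample_nearest_cpp(NumericVector vol, IntegerVector dims,
                                 NumericMatrix coords, double outside) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t np = coords.nrow();
  NumericVector out(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x >= nx - 0.5 || y >= ny - 0.5 || z >= nz - 0.5) {
      out[i] = outside;
      continue;
    }
    int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
    xi = std::max(0, std::min(xi, nx - 1));
    yi = std::max(0, std::min(yi, ny - 1));
    zi = std::max(0, std::min(zi, nz - 1));
    out[i] = vol[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
  }
  return out;
}

// Per-row stable descending top-T column indices (1-based).
// NA entries are "undefined" and never selected. Rows with fewer than T
// defined entries are padded with 0. Ties keep column order (stable).
// [[Rcpp::export]]
IntegerMatrix row_top_indices_cpp(NumericMatrix V, int T) {
  const int nr = V.nrow(), nc = V.ncol();
  if (T < 1) stop("T must be >= 1");
  IntegerMatrix out(nr, T);
  std::vector<int> idx;
  idx.reserve(nc);
  for (int i = 0; i < nr; ++i) {
    idx.clear();
    for (int j = 0; j < nc; ++j)
      if (!NumericVector::is_na(V(i, j))) idx.push_back(j);
    int k = std::min<int>(T, idx.size());
    // stable partial selection: stable_sort is cheap at these widths
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
      return V(i, a) > V(i, b);
    });
    for (int t = 0; t < T; ++t)
      out(i, t) = (t < k) ? idx[t] + 1 : 0;
  }
  return out;
}

// Per-row stable descending 0-based ranks (best = 0). NA stays NA.
// [[Rcpp::export]]
IntegerMatrix row_ranks_desc_cpp(NumericMatrix V) {
  const int nr = V.nrow(), nc = V.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<int> idx;
  idx.reserve(nc);
  for (int i = 0; i < nr; ++i) {
    idx.clear();
    for (int j = 0; j < nc; ++j) {
      out(i, j) = NA_INTEGER;
      if (!NumericVector::is_na(V(i, j))) idx.push_back(j);
    }
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
      return V(i, a) > V(i, b);
    });
    for (size_t r = 0; r < idx.size(); ++r)
      out(i, idx[r]) = (int)r;
  }
  return out;
}
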