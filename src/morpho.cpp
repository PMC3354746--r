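#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Neighbour offsets for a given connectivity on a (nr, nc, ns) grid.
// conn 4/8 act within a slice; 6/18/26 act in 3D.
static std::vector<std::array<int, 3>> neighbour_offsets(int conn) {
  std::vector<std::array<int, 3>> off;
  if (conn == 4 || conn == 8) {
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        if (conn == 4 && dr != 0 && dc != 0) continue;
        off.push_back({dr, dc, 0});
      }
  } else if (conn == 6 || conn == 18 || conn == 26) {
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc)
        for (int ds = -1; ds <= 1; ++ds) {
          int nz = (dr != 0) + (dc != 0) + (ds != 0);
          if (nz == 0) continue;
          if (conn == 6 && nz > 1) continue;
          if (conn == 18 && nz > 2) continue;
          off.push_back({dr, dc, ds});
        }
  } else {
    stop("unsupported connectivity: %d", conn);
  }
  return off;
}

// Connected-component labelling of a logical mask (2D matrix or 3D array).
// Returns an integer array of the same shape; 0 outside the mask, components
// numbered 1..n in order of their smallest linear index (so the component
// containing the first TRUE voxel in column-major order is component 1).
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nr = dims[0], nc = dims[1], ns = dims.size() > 2 ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nr * nc * ns;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<std::array<int, 3>> off = neighbour_offsets(connectivity);

  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] != TRUE || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int s = (int)(v / ((R_xlen_t)nr * nc));
      int rem = (int)(v % ((R_xlen_t)nr * nc));
      int c = rem / nr;
      int r = rem % nr;
      for (size_t k = 0; k < off.size(); ++k) {
        int r2 = r + off[k][0], c2 = c + off[k][1], s2 = s + off[k][2];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc || s2 < 0 || s2 >= ns) continue;
        R_xlen_t w = (R_xlen_t)s2 * nr * nc + (R_xlen_t)c2 * nr + r2;
        if (mask[w] == TRUE && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = next;
  return lab;
}

static const double DT_INF = std::numeric_limits<double>::max() / 4.0;

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher) with
// anisotropic step weight w (so distances accrue as (w * index gap)^2).
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  double w2 = w * w;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] >= DT_INF && f[v[k]] >= DT_INF) { // both empty: keep single parabola
      v[k] = q;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) / (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double gap = w * (q - v[k]);
    d[q] = gap * gap + f[v[k]];
    if (d[q] > DT_INF) d[q] = DT_INF;
  }
}

// Euclidean distance (in physical units) from every voxel to the nearest
// voxel centre OUTSIDE the mask. Background voxels get 0. `spacing` holds the
// physical step per axis (row, col, slice). Works for 2D (dims length 2) and
// 3D inputs.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  int nr = dims[0], nc = dims[1], ns = dims.size() > 2 ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nr * nc * ns;
  if (mask.size() != n) stop("mask length does not match dims");
  if ((int)spacing.size() < (ns > 1 ? 3 : 2)) stop("spacing too short for dims");

  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = (mask[i] == TRUE) ? DT_INF : 0.0;

  int maxdim = std::max(nr, std::max(nc, ns));
  std::vector<double> line(maxdim), out(maxdim);

  // pass along rows (axis 1)
  for (int s = 0; s < ns; ++s)
    for (int c = 0; c < nc; ++c) {
      R_xlen_t base = (R_xlen_t)s * nr * nc + (R_xlen_t)c * nr;
      for (int r = 0; r < nr; ++r) line[r] = d[base + r];
      dt1d(line, out, nr, spacing[0]);
      for (int r = 0; r < nr; ++r) d[base + r] = out[r];
    }
  // pass along columns (axis 2)
  for (int s = 0; s < ns; ++s)
    for (int r = 0; r < nr; ++r) {
      R_xlen_t base = (R_xlen_t)s * nr * nc + r;
      for (int c = 0; c < nc; ++c) line[c] = d[base + (R_xlen_t)c * nr];
      dt1d(line, out, nc, spacing[1]);
      for (int c = 0; c < nc; ++c) d[base + (R_xlen_t)c * nr] = out[c];
    }
  // pass along slices (axis 3)
  if (ns > 1) {
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        R_xlen_t base = (R_xlen_t)c * nr + r;
        for (int s = 0; s < ns; ++s) line[s] = d[base + (R_xlen_t)s * nr * nc];
        dt1d(line, out, ns, spacing[2]);
        for (int s = 0; s < ns; ++s) d[base + (R_xlen_t)s * nr * nc] = out[s];
      }
  }

  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i)
    res[i] = d[i] >= DT_INF ? R_PosInf : std::sqrt(d[i]);
  res.attr("dim") = dims;
  return res;
}
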