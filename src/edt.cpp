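#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

// 1-D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher)
// f: input squared distances sampled at positions step*0, step*1, ...
// d: output; v, z: work buffers of length n and n+1.
static void dt1d(const double* f, double* d, int n, double step,
                 int* v, double* z) {
  const double inf = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -inf;
  z[1] = inf;
  for (int q = 1; q < n; ++q) {
    double xq = q * step, s = 0;
    while (k >= 0) {
      double xv = v[k] * step;
      if (f[q] == inf) {
        s = inf;                       // new parabola never undercuts
      } else if (f[v[k]] == inf) {
        s = -inf;                      // stack parabola is everywhere above
      } else {
        s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      }
      if (s <= z[k]) { --k; } else break;
    }
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -inf;
      z[1] = inf;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = inf;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * step;
    double diff = xq - xv;
    d[q] = (f[v[k]] == std::numeric_limits<double>::infinity())
             ? std::numeric_limits<double>::infinity()
             : diff * diff + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest seed
// voxel centre, on an anisotropic grid. seeds: logical array; dims length 3.
// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector seeds, IntegerVector dims,
                              NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(ntot);
  const double inf = std::numeric_limits<double>::infinity();
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = seeds[i] ? 0.0 : inf;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along axis 1 (fastest-varying, stride 1)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      double* col = &out[(R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1];
      for (int i = 0; i < n1; ++i) f[i] = col[i];
      dt1d(f.data(), d.data(), n1, spacing[0], v.data(), z.data());
      for (int i = 0; i < n1; ++i) col[i] = d[i];
    }
  // axis 2 (stride n1)
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      double* base = &out[(R_xlen_t)k * n1 * n2 + i];
      for (int j = 0; j < n2; ++j) f[j] = base[(R_xlen_t)j * n1];
      dt1d(f.data(), d.data(), n2, spacing[1], v.data(), z.data());
      for (int j = 0; j < n2; ++j) base[(R_xlen_t)j * n1] = d[j];
    }
  // axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      double* base = &out[(R_xlen_t)j * n1 + i];
      for (int k = 0; k < n3; ++k) f[k] = base[k * s3];
      dt1d(f.data(), d.data(), n3, spacing[2], v.data(), z.data());
      for (int k = 0; k < n3; ++k) base[k * s3] = d[k];
    }
  return out;
}

// 6-connected component labelling of a 3D logical array.
// Returns integer array: 0 background, 1..n component ids (BFS order).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(ntot, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  for (R_xlen_t start = 0; start < ntot; ++start) {
    if (!mask[start] || lab[start]) continue;
    lab[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t p = q.front(); q.pop();
      int i = (int)(p % n1), j = (int)((p / n1) % n2), k = (int)(p / s3);
      R_xlen_t nb[6];
      int nn = 0;
      if (i > 0)      nb[nn++] = p - 1;
      if (i < n1 - 1) nb[nn++] = p + 1;
      if (j > 0)      nb[nn++] = p - s2;
      if (j < n2 - 1) nb[nn++] = p + s2;
      if (k > 0)      nb[nn++] = p - s3;
      if (k < n3 - 1) nb[nn++] = p + s3;
      for (int t = 0; t < nn; ++t) {
        R_xlen_t pp = nb[t];
        if (mask[pp] && !lab[pp]) { lab[pp] = next; q.push(pp); }
      }
    }
  }
  return lab;
}

// Surface voxels under 6-connectivity: foreground with a face-adjacent
// background neighbour or a grid boundary face.
// [[Rcpp::export]]
LogicalVector surface_mask_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(ntot, false);
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t p = (R_xlen_t)k * s3 + (R_xlen_t)j * s2 + i;
        if (!mask[p]) continue;
        bool border =
          i == 0 || i == n1 - 1 || j == 0 || j == n2 - 1 ||
          k == 0 || k == n3 - 1 ||
          !mask[p - 1] || !mask[p + 1] || !mask[p - s2] || !mask[p + s2] ||
          !mask[p - s3] || !mask[p + s3];
        out[p] = border;
      }
  return out;
}
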