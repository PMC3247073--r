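#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher 1D squared distance transform along a line of
// samples at physical pitch w (mm). f holds squared distances on input.
static void dt1d(std::vector<double> &f, double w) {
  const int n = (int)f.size();
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  const double INF = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  int k = -1;  // envelope built from finite parabolas only
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = -INF;
    while (k >= 0) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) return;  // all-infinite line: nothing to propagate
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
  f.swap(d);
}

// Anisotropic squared Euclidean distance transform of a 3D seed mask.
// mask: logical, column-major with dim (d1, d2, d3); spacing: mm per step
// along each dimension. Returns squared distance (mm^2) from every voxel to
// the nearest TRUE voxel (Inf if the mask is empty).
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("edt_sq: mask length does not match dim");
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> line;
  // pass along dim 1 (fastest-varying)
  line.resize(d1);
  for (int k3 = 0; k3 < d3; ++k3)
    for (int k2 = 0; k2 < d2; ++k2) {
      R_xlen_t base = (R_xlen_t)d1 * (k2 + (R_xlen_t)d2 * k3);
      bool finite = false;
      for (int i = 0; i < d1; ++i) { line[i] = out[base + i]; if (line[i] < INF) finite = true; }
      if (!finite) continue;
      dt1d(line, spacing[0]);
      for (int i = 0; i < d1; ++i) out[base + i] = line[i];
    }
  // pass along dim 2
  line.resize(d2);
  for (int k3 = 0; k3 < d3; ++k3)
    for (int k1 = 0; k1 < d1; ++k1) {
      R_xlen_t base = k1 + (R_xlen_t)d1 * d2 * k3;
      bool finite = false;
      for (int i = 0; i < d2; ++i) { line[i] = out[base + (R_xlen_t)d1 * i]; if (line[i] < INF) finite = true; }
      if (!finite) continue;
      dt1d(line, spacing[1]);
      for (int i = 0; i < d2; ++i) out[base + (R_xlen_t)d1 * i] = line[i];
    }
  // pass along dim 3
  line.resize(d3);
  const R_xlen_t stride3 = (R_xlen_t)d1 * d2;
  for (int k2 = 0; k2 < d2; ++k2)
    for (int k1 = 0; k1 < d1; ++k1) {
      R_xlen_t base = k1 + (R_xlen_t)d1 * k2;
      bool finite = false;
      for (int i = 0; i < d3; ++i) { line[i] = out[base + stride3 * i]; if (line[i] < INF) finite = true; }
      if (!finite) continue;
      dt1d(line, spacing[2]);
      for (int i = 0; i < d3; ++i) out[base + stride3 * i] = line[i];
    }
  return out;
}
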