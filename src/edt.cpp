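#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Felzenszwalb & Huttenlocher 1-D squared distance transform with sample
// spacing s (samples at x_i = i*s). Samples with f == INF carry no parabola.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q0 = 0;
  while (q0 < n && f[q0] == INF) q0++;
  if (q0 == n) {
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; q++) {
    if (f[q] == INF) continue;
    double xq = q * s;
    double sint;
    while (true) {
      double xv = v[k] * s;
      sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (sint <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * s;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

//' @noRd
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);

  // x pass
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, nx, spacing[0]);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny, spacing[1]);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; k++) f[k] = out[base + stride * k];
      dt1d(f, d, nz, spacing[2]);
      for (int k = 0; k < nz; k++) out[base + stride * k] = d[k];
    }

  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (out[i] == INF) ? R_PosInf : std::sqrt(out[i]);
  return out;
}
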