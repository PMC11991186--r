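#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Outward skin normals from the gradient of a Gaussian-smoothed body mask.
// The derivative-of-Gaussian kernel (sigma in voxels, truncated at 3*sigma)
// is applied to the binary body mask at the voxel nearest each query point;
// the mask gradient points into the body, so the outward normal is its
// negation. Rows with (near-)zero gradient are returned as zero vectors and
// handled by the caller's fallback.
// [[Rcpp::export(name = ".skin_normals_cpp")]]
NumericMatrix skin_normals_cpp(LogicalVector body, IntegerVector dim,
                               NumericVector spacing, NumericVector origin,
                               NumericMatrix pts, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int np = pts.nrow();
  const int rad = (int)std::ceil(3.0 * sigma) + 1;
  NumericMatrix out(np, 3);
  const int w = 2 * rad + 1;
  std::vector<double> g[3], dg[3];
  for (int a = 0; a < 3; a++) { g[a].resize(w); dg[a].resize(w); }

  for (int p = 0; p < np; p++) {
    int c[3];
    double fc[3];  // continuous voxel coordinate of the query point
    bool ok = true;
    for (int a = 0; a < 3; a++) {
      fc[a] = (pts(p, a) - origin[a]) / spacing[a];
      c[a] = (int)std::llround(fc[a]);
      if (c[a] < 0 || c[a] >= dim[a]) ok = false;
    }
    if (!ok) {
      out(p, 0) = out(p, 1) = out(p, 2) = 0.0;
      continue;
    }
    // kernel evaluated at the exact (fractional) offsets from the point
    for (int a = 0; a < 3; a++)
      for (int o = -rad; o <= rad; o++) {
        double t = (c[a] + o) - fc[a];
        double gv = std::exp(-0.5 * t * t / (sigma * sigma));
        g[a][o + rad] = gv;
        dg[a][o + rad] = -(t / (sigma * sigma)) * gv;
      }
    double grad[3] = {0.0, 0.0, 0.0};
    for (int oz = -rad; oz <= rad; oz++) {
      int z = c[2] + oz;
      if (z < 0 || z >= nz) continue;
      for (int oy = -rad; oy <= rad; oy++) {
        int y = c[1] + oy;
        if (y < 0 || y >= ny) continue;
        R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int ox = -rad; ox <= rad; ox++) {
          int x = c[0] + ox;
          if (x < 0 || x >= nx) continue;
          if (!body[base + x]) continue;
          grad[0] += dg[0][ox + rad] * g[1][oy + rad] * g[2][oz + rad];
          grad[1] += g[0][ox + rad] * dg[1][oy + rad] * g[2][oz + rad];
          grad[2] += g[0][ox + rad] * g[1][oy + rad] * dg[2][oz + rad];
        }
      }
    }
    // grad here is sum_o body(c+o) * dG(o) = -d/dx [G * body]; the
    // smoothed mask decreases outward, so this is the outward normal
    out(p, 0) = grad[0];
    out(p, 1) = grad[1];
    out(p, 2) = grad[2];
  }
  return out;
}
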