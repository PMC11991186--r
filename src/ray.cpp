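#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double DINF = std::numeric_limits<double>::infinity();

// Reason codes for per-direction feasibility:
//   0 ok; 1 no skin crossing within reach; 2 skin crossing outside the
//   parent-image bounds; 3 skin re-entry / multi-crossing; 4 blocked by an
//   opaque voxel (all later outputs frozen at the stopping point).
enum Reason { OK = 0, NO_SKIN = 1, OUTSIDE_IMAGE = 2, MULTI_CROSS = 3,
              BLOCKED = 4 };

// Exact voxel traversal (Amanatides & Woo) of a piecewise-constant field:
// per-voxel chord lengths give the exact Beer-Lambert line integral
// A = sum k_i * l_i per absorption class. Voxel i covers the half-open
// world interval [origin + (i-1/2)*sp, origin + (i+1/2)*sp) per axis
// (0-based indices, voxel-centre convention). Rays start at `target` and
// march outward to radius Rmm.
//
// All per-ray outputs are defined "up to the stopping point": once an
// opaque voxel is hit (respect_opaque = true) nothing further is
// accumulated or recorded, so early termination (breaking the march
// there) changes no output. Empty-space skipping clips the march to the
// bounding box of absorbing/opaque/skin voxels; the parent-image exit
// time is computed analytically, so skipped voxels contribute nothing.
//
// cls: 0 = none, 1 = soft tissue (Atra class), 2 = vessel (Avas class).
// img_lo/img_hi: world bounds (outer voxel faces) of the parent image; a
// skin crossing beyond these bounds fails the visible-region condition.
// [[Rcpp::export(name = ".cast_rays_cpp")]]
List cast_rays_cpp(NumericVector k, IntegerVector cls, LogicalVector opaque,
                   LogicalVector skin, IntegerVector dim,
                   NumericVector spacing, NumericVector origin,
                   NumericVector target, NumericMatrix dirs, double Rmm,
                   NumericVector img_lo, NumericVector img_hi,
                   bool early_terminate, bool skip_empty,
                   bool respect_opaque) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ndir = dirs.nrow();
  const double eps = 1e-9;

  IntegerVector iobs(ndir), reason(ndir), skin_ok(ndir);
  NumericVector a_tra(ndir), a_vas(ndir), t_skin(ndir);

  // bounding box (voxel indices) of "interesting" voxels
  int blo[3] = {0, 0, 0}, bhi[3] = {nx - 1, ny - 1, nz - 1};
  bool any_interesting = true;
  if (skip_empty) {
    int lo[3] = {nx, ny, nz}, hi[3] = {-1, -1, -1};
    R_xlen_t idx = 0;
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++, idx++) {
          if (k[idx] > 0 || opaque[idx] || skin[idx]) {
            if (x < lo[0]) lo[0] = x;
            if (y < lo[1]) lo[1] = y;
            if (z < lo[2]) lo[2] = z;
            if (x > hi[0]) hi[0] = x;
            if (y > hi[1]) hi[1] = y;
            if (z > hi[2]) hi[2] = z;
          }
        }
    if (hi[0] < 0) {
      any_interesting = false;
    } else {
      for (int a = 0; a < 3; a++) { blo[a] = lo[a]; bhi[a] = hi[a]; }
    }
  }

  for (int r = 0; r < ndir; r++) {
    double d[3] = {dirs(r, 0), dirs(r, 1), dirs(r, 2)};
    double A[3] = {0.0, 0.0, 0.0};  // index 1 = soft, 2 = vessel
    double ts = NA_REAL;            // skin entry time (mm)
    bool has_skin = false, blocked = false, multi = false;
    int state = 0;  // 0 before skin, 1 inside skin run, 2 after skin

    // exit time of the parent-image world box (target lies inside it)
    double t_img = DINF;
    for (int a = 0; a < 3; a++) {
      if (d[a] > eps)
        t_img = std::min(t_img, (img_hi[a] - target[a]) / d[a]);
      else if (d[a] < -eps)
        t_img = std::min(t_img, (img_lo[a] - target[a]) / d[a]);
    }

    // march interval: clip to interesting bbox if skipping empty space
    double t0 = 0.0, t1 = Rmm;
    if (skip_empty) {
      if (!any_interesting) {
        t1 = -1.0;
      } else {
        double tb0 = -DINF, tb1 = DINF;
        for (int a = 0; a < 3; a++) {
          double lo_w = origin[a] + (blo[a] - 0.5) * spacing[a];
          double hi_w = origin[a] + (bhi[a] + 0.5) * spacing[a];
          if (std::fabs(d[a]) > eps) {
            double ta = (lo_w - target[a]) / d[a];
            double tb = (hi_w - target[a]) / d[a];
            if (ta > tb) std::swap(ta, tb);
            tb0 = std::max(tb0, ta);
            tb1 = std::min(tb1, tb);
          } else if (target[a] < lo_w || target[a] > hi_w) {
            tb1 = -DINF;  // ray never enters the box
          }
        }
        t0 = std::max(0.0, tb0);
        t1 = std::min(Rmm, tb1);
      }
    }

    if (t1 > t0) {
      int iv[3], step[3];
      double tmax[3], tdelta[3];
      for (int a = 0; a < 3; a++) {
        double p = target[a] + t0 * d[a];
        double ci = (p - origin[a]) / spacing[a];
        iv[a] = (int)std::llround(ci);
        if (d[a] > eps) {
          step[a] = 1;
          tmax[a] = ((origin[a] + (iv[a] + 0.5) * spacing[a]) - target[a]) / d[a];
          tdelta[a] = spacing[a] / d[a];
        } else if (d[a] < -eps) {
          step[a] = -1;
          tmax[a] = ((origin[a] + (iv[a] - 0.5) * spacing[a]) - target[a]) / d[a];
          tdelta[a] = spacing[a] / (-d[a]);
        } else {
          step[a] = 0;
          tmax[a] = DINF;
          tdelta[a] = DINF;
        }
      }

      double t_cur = t0;
      while (t_cur < t1 - eps) {
        int ax = 0;
        if (tmax[1] < tmax[ax]) ax = 1;
        if (tmax[2] < tmax[ax]) ax = 2;
        double t_next = std::min(tmax[ax], t1);
        double chord = t_next - t_cur;

        bool ingrid = iv[0] >= 0 && iv[0] < nx && iv[1] >= 0 && iv[1] < ny &&
                      iv[2] >= 0 && iv[2] < nz;
        if (ingrid && chord > 0 && !blocked) {
          R_xlen_t li = iv[0] + (R_xlen_t)nx * (iv[1] + (R_xlen_t)ny * iv[2]);
          bool sk = skin[li];
          bool op = respect_opaque && opaque[li];
          double kk = k[li];
          int cl = cls[li];

          if (state == 2) {
            // beyond the skin: any labelled matter means re-entry
            if (sk || op || kk > 0) {
              multi = true;
              if (early_terminate) break;
            }
          } else {
            if (state == 0 && sk) {
              state = 1;
              ts = t_cur;
              has_skin = true;
            } else if (state == 1 && !sk) {
              state = 2;
            }
            if (state < 2) {
              if (op) {
                blocked = true;  // outputs frozen from here on
                if (early_terminate) break;
              } else if (kk > 0 && cl >= 1 && cl <= 2) {
                A[cl] += kk * chord;
              }
            } else if (op || kk > 0) {
              // first post-skin voxel is labelled matter: re-entry
              multi = true;
              if (early_terminate) break;
            }
          }
        }
        t_cur = t_next;
        if (tmax[ax] <= t1) {
          iv[ax] += step[ax];
          tmax[ax] += tdelta[ax];
        }
      }
    }

    bool skin_in_img = has_skin && ts <= t_img + eps;
    bool sok = has_skin && skin_in_img && !multi && !blocked;
    int rsn;
    if (blocked)
      rsn = BLOCKED;
    else if (multi)
      rsn = MULTI_CROSS;
    else if (!has_skin)
      rsn = NO_SKIN;
    else if (!skin_in_img)
      rsn = OUTSIDE_IMAGE;
    else
      rsn = OK;

    iobs[r] = blocked ? 0 : 1;
    skin_ok[r] = sok ? 1 : 0;
    reason[r] = rsn;
    a_tra[r] = A[1];
    a_vas[r] = A[2];
    t_skin[r] = has_skin ? ts : NA_REAL;
  }

  return List::create(_["iobs"] = iobs, _["skin_ok"] = skin_ok,
                      _["reason"] = reason, _["a_tra"] = a_tra,
                      _["a_vas"] = a_vas, _["t_skin"] = t_skin);
}
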