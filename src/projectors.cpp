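// Ray-driven forward projection and voxel-driven (optionally deformed)
// backprojection for a circular cone-beam trajectory.
//
// Conventions (shared with the R level, which converts to 0-based here):
//   world frame: right-handed, rotation axis = z, isocenter at the origin;
//   source at angle theta: S = sid * (cos t, sin t, 0);
//   detector u axis e_u = (-sin t, cos t, 0), v axis = +z;
//   volume origin = world position of the centre of voxel (0,0,0).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double trilinear(const double *vol, int nx, int ny, int nz,
                               double gx, double gy, double gz) {
  if (gx < -0.5 || gx > nx - 0.5 || gy < -0.5 || gy > ny - 0.5 ||
      gz < -0.5 || gz > nz - 0.5)
    return 0.0;
  if (gx < 0) gx = 0; if (gx > nx - 1) gx = nx - 1;
  if (gy < 0) gy = 0; if (gy > ny - 1) gy = ny - 1;
  if (gz < 0) gz = 0; if (gz > nz - 1) gz = nz - 1;
  int i0 = (int)std::floor(gx); if (i0 > nx - 2) i0 = nx - 2; if (nx == 1) i0 = 0;
  int j0 = (int)std::floor(gy); if (j0 > ny - 2) j0 = ny - 2; if (ny == 1) j0 = 0;
  int k0 = (int)std::floor(gz); if (k0 > nz - 2) k0 = nz - 2; if (nz == 1) k0 = 0;
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  int i1 = (nx == 1) ? i0 : i0 + 1;
  int j1 = (ny == 1) ? j0 : j0 + 1;
  int k1 = (nz == 1) ? k0 : k0 + 1;
  if (nx == 1) fx = 0; if (ny == 1) fy = 0; if (nz == 1) fz = 0;
  const size_t sxy = (size_t)nx * ny;
  #define V(i,j,k) vol[(size_t)(i) + (size_t)nx*(j) + sxy*(k)]
  double c00 = V(i0,j0,k0)*(1-fx) + V(i1,j0,k0)*fx;
  double c10 = V(i0,j1,k0)*(1-fx) + V(i1,j1,k0)*fx;
  double c01 = V(i0,j0,k1)*(1-fx) + V(i1,j0,k1)*fx;
  double c11 = V(i0,j1,k1)*(1-fx) + V(i1,j1,k1)*fx;
  #undef V
  double c0 = c00*(1-fy) + c10*fy;
  double c1 = c01*(1-fy) + c11*fy;
  return c0*(1-fz) + c1*fz;
}

static inline double bilinear(const double *img, int nr, int nc,
                              double gr, double gc) {
  if (gr < -0.5 || gr > nr - 0.5 || gc < -0.5 || gc > nc - 0.5)
    return 0.0;
  if (gr < 0) gr = 0; if (gr > nr - 1) gr = nr - 1;
  if (gc < 0) gc = 0; if (gc > nc - 1) gc = nc - 1;
  int r0 = (int)std::floor(gr); if (r0 > nr - 2) r0 = nr - 2; if (nr == 1) r0 = 0;
  int c0 = (int)std::floor(gc); if (c0 > nc - 2) c0 = nc - 2; if (nc == 1) c0 = 0;
  double fr = gr - r0, fc = gc - c0;
  int r1 = (nr == 1) ? r0 : r0 + 1;
  int c1 = (nc == 1) ? c0 : c0 + 1;
  if (nr == 1) fr = 0; if (nc == 1) fc = 0;
  double a = img[r0 + (size_t)nr*c0]*(1-fr) + img[r1 + (size_t)nr*c0]*fr;
  double b = img[r0 + (size_t)nr*c1]*(1-fr) + img[r1 + (size_t)nr*c1]*fr;
  return a*(1-fc) + b*fc;
}

// intersect ray o + t*d with axis-aligned box [lo, hi]; returns false if missed
static inline bool ray_box(const double o[3], const double d[3],
                           const double lo[3], const double hi[3],
                           double &t0, double &t1) {
  t0 = 0.0; t1 = 1e30;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (o[a] < lo[a] || o[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - o[a]) / d[a];
      double tb = (hi[a] - o[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t1 > t0;
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector vdim,
                                  NumericVector vspacing, NumericVector vorigin,
                                  NumericVector angles, double sid, double sdd,
                                  int nr, int nc, double ps,
                                  double off_u, double off_v, double step) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const int nv = angles.size();
  const double *vp = REAL(vol);
  NumericVector out((size_t)nr * nc * nv);
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = vorigin[a] - 0.5 * vspacing[a];
    hi[a] = vorigin[a] + (vdim[a] - 0.5) * vspacing[a];
  }
  const double cu = 0.5 * (nc - 1), cv = 0.5 * (nr - 1);
  for (int k = 0; k < nv; ++k) {
    const double ct = std::cos(angles[k]), st = std::sin(angles[k]);
    const double S[3]  = { sid * ct, sid * st, 0.0 };
    const double eu[3] = { -st, ct, 0.0 };
    const double D0[3] = { -(sdd - sid) * ct, -(sdd - sid) * st, 0.0 };
    double *page = REAL(out) + (size_t)k * nr * nc;
    for (int c = 0; c < nc; ++c) {
      const double u = (c - cu) * ps + off_u;
      for (int r = 0; r < nr; ++r) {
        const double v = (r - cv) * ps + off_v;
        double X[3] = { D0[0] + u * eu[0], D0[1] + u * eu[1], v };
        double d[3] = { X[0] - S[0], X[1] - S[1], X[2] - S[2] };
        double nrm = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
        double t0, t1;
        if (!ray_box(S, d, lo, hi, t0, t1)) continue;
        int nstep = (int)std::ceil((t1 - t0) / step);
        if (nstep < 1) nstep = 1;
        double dt = (t1 - t0) / nstep, acc = 0.0;
        for (int m = 0; m < nstep; ++m) {
          double t = t0 + (m + 0.5) * dt;
          double gx = (S[0] + t*d[0] - vorigin[0]) / vspacing[0];
          double gy = (S[1] + t*d[1] - vorigin[1]) / vspacing[1];
          double gz = (S[2] + t*d[2] - vorigin[2]) / vspacing[2];
          acc += trilinear(vp, nx, ny, nz, gx, gy, gz);
        }
        page[r + (size_t)nr * c] = acc * dt;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nr, nc, nv);
  return out;
}

// weight_mode: 0 = FDK ((sid/s)^2 per view, times dbeta), 1 = plain mean
// defcoords: optional N x 3 matrix of deformed world coordinates (voxel order)
// [[Rcpp::export]]
NumericVector cpp_back_project(NumericVector stack, IntegerVector sdim,
                               NumericVector angles, double sid, double sdd,
                               double ps, double off_u, double off_v,
                               IntegerVector vdim, NumericVector vspacing,
                               NumericVector vorigin,
                               Nullable<NumericMatrix> defcoords,
                               int weight_mode, double dbeta) {
  const int nr = sdim[0], nc = sdim[1], nv = sdim[2];
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox);
  const double cu = 0.5 * (nc - 1), cv = 0.5 * (nr - 1);
  const bool deformed = defcoords.isNotNull();
  NumericMatrix dc;
  if (deformed) dc = NumericMatrix(defcoords);
  for (int k = 0; k < nv; ++k) {
    const double ct = std::cos(angles[k]), st = std::sin(angles[k]);
    const double *page = REAL(stack) + (size_t)k * nr * nc;
    size_t idx = 0;
    for (int kz = 0; kz < nz; ++kz) {
      const double wz0 = vorigin[2] + kz * vspacing[2];
      for (int jy = 0; jy < ny; ++jy) {
        const double wy0 = vorigin[1] + jy * vspacing[1];
        for (int ix = 0; ix < nx; ++ix, ++idx) {
          double wx = vorigin[0] + ix * vspacing[0], wy = wy0, wz = wz0;
          if (deformed) { wx = dc(idx, 0); wy = dc(idx, 1); wz = dc(idx, 2); }
          const double s = sid - (wx * ct + wy * st);
          if (s < 1e-6) continue;
          const double pu = sdd * (-wx * st + wy * ct) / s;
          const double pv = sdd * wz / s;
          const double gc = (pu - off_u) / ps + cu;
          const double gr = (pv - off_v) / ps + cv;
          double val = bilinear(page, nr, nc, gr, gc);
          if (weight_mode == 0) {
            const double w = sid / s;
            val *= w * w;
          }
          out[idx] += val;
        }
      }
    }
  }
  const double scale = (weight_mode == 0) ? dbeta : 1.0 / nv;
  for (size_t i = 0; i < nvox; ++i) out[i] *= scale;
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}
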