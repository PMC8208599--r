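// Analytic polychromatic projection simulator for phantoms built from
// convex quadric primitives (ellipsoids and capped cylinders).
//
// Per detector pixel the ray (or a supersampled bundle of sub-rays) is
// intersected with every primitive analytically; overlapping primitives are
// resolved by priority (innermost material wins) in a 1D interval sweep,
// giving exact per-material path lengths L_m.  The detected intensity is
// I = sum_E w(E) * exp(-sum_m mu_m(E) * L_m).
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Hit { double t0, t1; int prim; };

// intersection of ray o + t d with primitive row `p` of the table
static inline bool prim_intersect(const double *p, const double o[3],
                                  const double d[3], double &t0, double &t1) {
  const int type = (int)p[0];
  // local frame: x_l = R^T (x - c); R stored row-major at p[7..15]
  double oc[3] = { o[0] - p[1], o[1] - p[2], o[2] - p[3] };
  double ol[3], dl[3];
  // R^T v : component i = sum_j R[j][i] * v[j]
  for (int i = 0; i < 3; ++i) {
    ol[i] = p[7 + 0*3 + i] * oc[0] + p[7 + 1*3 + i] * oc[1] + p[7 + 2*3 + i] * oc[2];
    dl[i] = p[7 + 0*3 + i] * d[0]  + p[7 + 1*3 + i] * d[1]  + p[7 + 2*3 + i] * d[2];
  }
  if (type == 0) { // ellipsoid, semi-axes a,b,c
    double os[3] = { ol[0] / p[4], ol[1] / p[5], ol[2] / p[6] };
    double ds[3] = { dl[0] / p[4], dl[1] / p[5], dl[2] / p[6] };
    double A = ds[0]*ds[0] + ds[1]*ds[1] + ds[2]*ds[2];
    double B = 2.0 * (os[0]*ds[0] + os[1]*ds[1] + os[2]*ds[2]);
    double C = os[0]*os[0] + os[1]*os[1] + os[2]*os[2] - 1.0;
    double disc = B*B - 4*A*C;
    if (disc <= 0 || A == 0) return false;
    double sq = std::sqrt(disc);
    t0 = (-B - sq) / (2*A); t1 = (-B + sq) / (2*A);
    return true;
  } else { // capped elliptic cylinder: radii a (x), c (y), half-length b
    const double rx = p[4], hl = p[5];
    const double ry = (p[6] > 0.0) ? p[6] : p[4];
    const double o0 = ol[0] / rx, o1 = ol[1] / ry;
    const double e0 = dl[0] / rx, e1 = dl[1] / ry;
    double A = e0*e0 + e1*e1;
    double ta, tb;
    if (A < 1e-14) { // ray parallel to axis
      if (o0*o0 + o1*o1 > 1.0) return false;
      ta = -1e30; tb = 1e30;
    } else {
      double B = 2.0 * (o0*e0 + o1*e1);
      double C = o0*o0 + o1*o1 - 1.0;
      double disc = B*B - 4*A*C;
      if (disc <= 0) return false;
      double sq = std::sqrt(disc);
      ta = (-B - sq) / (2*A); tb = (-B + sq) / (2*A);
    }
    // axial clip |z| <= hl
    double tz0, tz1;
    if (std::fabs(dl[2]) < 1e-14) {
      if (std::fabs(ol[2]) > hl) return false;
      tz0 = -1e30; tz1 = 1e30;
    } else {
      tz0 = (-hl - ol[2]) / dl[2];
      tz1 = ( hl - ol[2]) / dl[2];
      if (tz0 > tz1) std::swap(tz0, tz1);
    }
    t0 = std::max(ta, tz0); t1 = std::min(tb, tz1);
    return t1 > t0;
  }
}

// row-major copy of the primitive table for contiguous per-ray access
static std::vector<double> pack_prims(const NumericMatrix &prims) {
  const int np = prims.nrow();
  std::vector<double> tab((size_t)np * 16);
  for (int p = 0; p < np; ++p)
    for (int c = 0; c < 16; ++c) tab[(size_t)p * 16 + c] = prims(p, c);
  return tab;
}

// trace one ray; accumulates per-material path lengths into L (size nmat)
static void trace_lengths(const std::vector<double> &ptab, const int *mat,
                          const int *prio, int nmat,
                          const double o[3], const double d[3], double *L) {
  const int np = (int)(ptab.size() / 16);
  std::vector<Hit> hits;
  hits.reserve(8);
  for (int p = 0; p < np; ++p) {
    double t0, t1;
    if (prim_intersect(&ptab[(size_t)p * 16], o, d, t0, t1)) {
      Hit h; h.t0 = t0; h.t1 = t1; h.prim = p;
      hits.push_back(h);
    }
  }
  if (hits.empty()) return;
  std::vector<double> ev;
  ev.reserve(hits.size() * 2);
  for (size_t i = 0; i < hits.size(); ++i) { ev.push_back(hits[i].t0); ev.push_back(hits[i].t1); }
  std::sort(ev.begin(), ev.end());
  for (size_t s = 0; s + 1 < ev.size(); ++s) {
    double ta = ev[s], tb = ev[s + 1];
    if (tb - ta <= 1e-12) continue;
    double tm = 0.5 * (ta + tb);
    int best = -1, bestprio = -2147483647;
    for (size_t i = 0; i < hits.size(); ++i) {
      if (hits[i].t0 <= tm && tm <= hits[i].t1) {
        int pr = prio[hits[i].prim];
        if (pr > bestprio) { bestprio = pr; best = hits[i].prim; }
      }
    }
    if (best >= 0) L[mat[best]] += tb - ta;
  }
}

// [[Rcpp::export]]
NumericVector cpp_trace_ray(NumericMatrix prims, IntegerVector mat,
                            IntegerVector prio, int nmat,
                            NumericVector origin, NumericVector direction) {
  NumericVector L(nmat);
  double o[3] = { origin[0], origin[1], origin[2] };
  double d[3] = { direction[0], direction[1], direction[2] };
  double nrm = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
  std::vector<double> ptab = pack_prims(prims);
  trace_lengths(ptab, INTEGER(mat), INTEGER(prio), nmat, o, d, REAL(L));
  return L;
}

// mu: nE x nmat matrix of linear attenuation coefficients (1/mm)
// wE: nE spectral weights; returned stack holds raw detected intensities
// [[Rcpp::export]]
NumericVector cpp_simulate_stack(NumericMatrix prims, IntegerVector mat,
                                 IntegerVector prio, int nmat,
                                 NumericMatrix mu, NumericVector wE,
                                 NumericVector angles, double sid, double sdd,
                                 int nr, int nc, double ps,
                                 double off_u, double off_v, int supersample) {
  const int nv = angles.size(), nE = wE.size();
  NumericVector out((size_t)nr * nc * nv);
  const double cu = 0.5 * (nc - 1), cv = 0.5 * (nr - 1);
  const int ss = supersample < 1 ? 1 : supersample;
  std::vector<double> L(nmat);
  const std::vector<double> ptab = pack_prims(prims);
  const int *matp = INTEGER(mat), *priop = INTEGER(prio);
  for (int k = 0; k < nv; ++k) {
    const double ct = std::cos(angles[k]), st = std::sin(angles[k]);
    const double S[3]  = { sid * ct, sid * st, 0.0 };
    const double eu[3] = { -st, ct, 0.0 };
    const double D0x = -(sdd - sid) * ct, D0y = -(sdd - sid) * st;
    double *page = REAL(out) + (size_t)k * nr * nc;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        double acc = 0.0;
        for (int si = 0; si < ss; ++si) {
          const double duu = ((si + 0.5) / ss - 0.5);
          const double u = (c + duu - cu) * ps + off_u;
          for (int sj = 0; sj < ss; ++sj) {
            const double dvv = ((sj + 0.5) / ss - 0.5);
            const double v = (r + dvv - cv) * ps + off_v;
            double X[3] = { D0x + u * eu[0], D0y + u * eu[1], v };
            double d[3] = { X[0] - S[0], X[1] - S[1], X[2] - S[2] };
            double nrm = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
            d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
            std::fill(L.begin(), L.end(), 0.0);
            trace_lengths(ptab, matp, priop, nmat, S, d, L.data());
            double I = 0.0;
            for (int e = 0; e < nE; ++e) {
              double a = 0.0;
              for (int m = 0; m < nmat; ++m)
                if (L[m] > 0.0) a += mu(e, m) * L[m];
              I += wE[e] * std::exp(-a);
            }
            acc += I;
          }
        }
        page[r + (size_t)nr * c] = acc / (ss * ss);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nr, nc, nv);
  return out;
}
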