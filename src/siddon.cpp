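#include <Rcpp.h>
#include "cb_geom.h"
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact ray/grid intersection lengths (Siddon-style parametric plane
// traversal).  The ray is the segment p0 -> p1; emit(idx, len) is called
// once per traversed voxel in order along the ray, idx being the 0-based
// linear index ix + nx*(iy + ny*iz), len the chord through that voxel in
// mm.  Zero-length crossings below len_eps are dropped.
template <class F>
static inline void traverse_ray(const double p0[3], const double p1[3],
                                const CbGrid& g, F&& emit,
                                double len_eps = 1e-12) {
  const double D[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  const double L = std::sqrt(D[0] * D[0] + D[1] * D[1] + D[2] * D[2]);
  if (L <= 0.0) return;

  const double bmin[3] = {g.xmin(), g.ymin(), g.zmin()};
  const double bmax[3] = {g.xmax(), g.ymax(), g.zmax()};
  const double sp[3] = {g.dx, g.dy, g.dz};
  const int n[3] = {g.nx, g.ny, g.nz};

  // slab clipping of t in [0, 1]
  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (D[a] != 0.0) {
      double ta = (bmin[a] - p0[a]) / D[a];
      double tb = (bmax[a] - p0[a]) / D[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    } else if (p0[a] < bmin[a] || p0[a] > bmax[a]) {
      return;  // parallel to slab and outside it
    }
  }
  if (t0 >= t1) return;

  // entry voxel
  int idx[3];
  for (int a = 0; a < 3; ++a) {
    double q = p0[a] + t0 * D[a];
    int i = (int)std::floor((q - bmin[a]) / sp[a]);
    if (i < 0) i = 0;
    if (i >= n[a]) i = n[a] - 1;
    idx[a] = i;
  }

  // per-axis next-crossing parameter and increment
  double tmax[3], tdel[3];
  int step[3];
  const double INF = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    if (D[a] > 0.0) {
      step[a] = 1;
      tmax[a] = (bmin[a] + (idx[a] + 1) * sp[a] - p0[a]) / D[a];
      tdel[a] = sp[a] / D[a];
    } else if (D[a] < 0.0) {
      step[a] = -1;
      tmax[a] = (bmin[a] + idx[a] * sp[a] - p0[a]) / D[a];
      tdel[a] = -sp[a] / D[a];
    } else {
      step[a] = 0;
      tmax[a] = INF;
      tdel[a] = INF;
    }
  }

  double tcur = t0;
  while (tcur < t1) {
    double tnext = t1;
    if (tmax[0] < tnext) tnext = tmax[0];
    if (tmax[1] < tnext) tnext = tmax[1];
    if (tmax[2] < tnext) tnext = tmax[2];
    double len = (tnext - tcur) * L;
    if (len > len_eps)
      emit(idx[0] + n[0] * (idx[1] + n[1] * idx[2]), len);
    if (tnext >= t1) break;
    for (int a = 0; a < 3; ++a) {
      if (tmax[a] == tnext) {  // exact: tnext was copied from tmax[a]
        idx[a] += step[a];
        tmax[a] += tdel[a];
        if (idx[a] < 0 || idx[a] >= n[a]) return;
      }
    }
    tcur = tnext;
  }
}

static CbGrid as_grid(IntegerVector dims, NumericVector spacing,
                      NumericVector origin) {
  CbGrid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.dx = spacing[0]; g.dy = spacing[1]; g.dz = spacing[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  return g;
}

static CbGeom as_geom(double sad, double sdd, int nu, int nv,
                      double du, double dv, double off_u, double off_v) {
  CbGeom G;
  G.sad = sad; G.sdd = sdd; G.nu = nu; G.nv = nv;
  G.du = du; G.dv = dv; G.off_u = off_u; G.off_v = off_v;
  return G;
}

// [[Rcpp::export]]
List cpp_trace_ray(NumericVector p0, NumericVector p1, IntegerVector dims,
                   NumericVector spacing, NumericVector origin) {
  if (p0.size() != 3 || p1.size() != 3)
    stop("ray endpoints must be length-3");
  for (int a = 0; a < 3; ++a)
    if (!R_finite(p0[a]) || !R_finite(p1[a]))
      stop("non-finite ray endpoint");
  CbGrid g = as_grid(dims, spacing, origin);
  std::vector<int> js;
  std::vector<double> ls;
  double q0[3] = {p0[0], p0[1], p0[2]};
  double q1[3] = {p1[0], p1[1], p1[2]};
  traverse_ray(q0, q1, g, [&](int j, double l) {
    js.push_back(j + 1);  // 1-based for R
    ls.push_back(l);
  });
  return List::create(_["index"] = wrap(js), _["length"] = wrap(ls));
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  double sad, double sdd, int nu, int nv,
                                  double du, double dv, double off_u,
                                  double off_v, NumericVector angles) {
  CbGrid g = as_grid(dims, spacing, origin);
  CbGeom G = as_geom(sad, sdd, nu, nv, du, dv, off_u, off_v);
  const int nview = angles.size();
  NumericVector out((R_xlen_t)nu * nv * nview);
  const double* mu = vol.begin();
  double* o = out.begin();
  for (int k = 0; k < nview; ++k) {
    double s[3];
    G.source(angles[k], s);
    for (int iv = 0; iv < nv; ++iv) {
      for (int iu = 0; iu < nu; ++iu) {
        double p[3];
        G.pixel(angles[k], iu, iv, p);
        double acc = 0.0;
        traverse_ray(s, p, g, [&](int j, double l) { acc += l * mu[j]; });
        o[(R_xlen_t)k * nu * nv + (R_xlen_t)iv * nu + iu] = acc;
      }
    }
  }
  return out;
}

// Ray-driven backprojection: accumulate num_j = sum_k l_jk * P_k and
// den_j = sum_k l_jk over all views and detector pixels.  Accumulation
// order is fixed: views outer, detector rows (v), then columns (u).
// [[Rcpp::export]]
List cpp_backproject_rdb(NumericVector proj, IntegerVector dims,
                         NumericVector spacing, NumericVector origin,
                         double sad, double sdd, int nu, int nv,
                         double du, double dv, double off_u, double off_v,
                         NumericVector angles) {
  CbGrid g = as_grid(dims, spacing, origin);
  CbGeom G = as_geom(sad, sdd, nu, nv, du, dv, off_u, off_v);
  const int nview = angles.size();
  const R_xlen_t nvox = (R_xlen_t)g.nx * g.ny * g.nz;
  NumericVector num(nvox), den(nvox);
  double* numv = num.begin();
  double* denv = den.begin();
  const double* P = proj.begin();
  for (int k = 0; k < nview; ++k) {
    double s[3];
    G.source(angles[k], s);
    for (int iv = 0; iv < nv; ++iv) {
      for (int iu = 0; iu < nu; ++iu) {
        double p[3];
        G.pixel(angles[k], iu, iv, p);
        const double Pk = P[(R_xlen_t)k * nu * nv + (R_xlen_t)iv * nu + iu];
        traverse_ray(p, s, g, [&](int j, double l) {
          numv[j] += l * Pk;
          denv[j] += l;
        });
      }
    }
  }
  return List::create(_["num"] = num, _["den"] = den);
}
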