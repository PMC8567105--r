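#include <Rcpp.h>
#include "cb_geom.h"
#include <cmath>

using namespace Rcpp;

// Pixel-driven FDK backprojection: perspective-project each voxel centre
// onto the detector, bilinearly interpolate the filtered projection, and
// accumulate with the FDK distance weight (sad/U)^2, U being the voxel's
// distance from the source along the central-ray direction.  view_scale
// carries the per-view angular weight (dbeta, short/full-scan factor and
// filter-scale normalisation), applied uniformly.
// [[Rcpp::export]]
NumericVector cpp_backproject_pdb(NumericVector proj, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  double sad, double sdd, int nu, int nv,
                                  double du, double dv, double off_u,
                                  double off_v, NumericVector angles,
                                  NumericVector view_scale) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int nview = angles.size();
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* o = out.begin();
  const double* P = proj.begin();

  for (int k = 0; k < nview; ++k) {
    const double b = angles[k] * M_PI / 180.0;
    const double sb = std::sin(b), cb = std::cos(b);
    // source, central-ray unit vector (source -> isocenter), detector u axis
    const double sx = sad * sb, sy = -sad * cb;
    const double ex = -sb, ey = cb;           // central ray direction
    const double ux = cb, uy = sb;            // detector u direction
    const double scale = view_scale[k];
    const double* Pk = P + (R_xlen_t)k * nu * nv;
    R_xlen_t j = 0;
    for (int iz = 0; iz < nz; ++iz) {
      const double z = oz + iz * dz;
      for (int iy = 0; iy < ny; ++iy) {
        const double y = oy + iy * dy;
        for (int ix = 0; ix < nx; ++ix, ++j) {
          const double x = ox + ix * dx;
          const double rx = x - sx, ry = y - sy;  // rz = z
          const double U = rx * ex + ry * ey;     // distance along central ray
          if (U <= 1e-9) continue;
          const double mag = sdd / U;
          // hit point on detector plane, in detector coordinates
          const double ucoord = mag * (rx * ux + ry * uy) - off_u;
          const double vcoord = mag * z - off_v;
          const double fu = ucoord / du + (nu - 1) / 2.0;
          const double fv = vcoord / dv + (nv - 1) / 2.0;
          if (fu < 0.0 || fu > nu - 1 || fv < 0.0 || fv > nv - 1) continue;
          int i0 = (int)std::floor(fu);
          int v0 = (int)std::floor(fv);
          if (i0 >= nu - 1) i0 = nu - 2;
          if (v0 >= nv - 1) v0 = nv - 2;
          if (i0 < 0) i0 = 0;
          if (v0 < 0) v0 = 0;
          const double au = fu - i0, av = fv - v0;
          double interp;
          if (nu == 1) {
            interp = (nv == 1) ? Pk[0]
                               : (1 - av) * Pk[v0 * nu] + av * Pk[(v0 + 1) * nu];
          } else if (nv == 1) {
            interp = (1 - au) * Pk[i0] + au * Pk[i0 + 1];
          } else {
            interp = (1 - au) * (1 - av) * Pk[v0 * nu + i0] +
                     au * (1 - av) * Pk[v0 * nu + i0 + 1] +
                     (1 - au) * av * Pk[(v0 + 1) * nu + i0] +
                     au * av * Pk[(v0 + 1) * nu + i0 + 1];
          }
          const double w = (sad / U) * (sad / U);
          o[j] += scale * w * interp;
        }
      }
    }
  }
  return out;
}
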