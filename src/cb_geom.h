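#ifndef CB_GEOM_H
#define CB_GEOM_H

#include <cmath>

// Circular cone-beam geometry. Convention: rotation axis +z; at gantry
// angle 0 the source is at (0, -sad, 0) and the detector centre at
// (0, sdd - sad, 0); detector u rotates with the gantry (u == +x at angle
// 0), v is +z. Angles in degrees, counter-clockwise seen from +z.
struct CbGeom {
  double sad, sdd;
  int nu, nv;
  double du, dv;
  double off_u, off_v;

  void source(double beta_deg, double s[3]) const {
    double b = beta_deg * M_PI / 180.0;
    s[0] = sad * std::sin(b);
    s[1] = -sad * std::cos(b);
    s[2] = 0.0;
  }
  // centre of detector pixel (iu, iv), 0-based
  void pixel(double beta_deg, int iu, int iv, double p[3]) const {
    double b = beta_deg * M_PI / 180.0;
    double ux = std::cos(b), uy = std::sin(b);
    double cx = -(sdd - sad) * std::sin(b) + off_u * ux;
    double cy = (sdd - sad) * std::cos(b) + off_u * uy;
    double u = (iu - (nu - 1) / 2.0) * du;
    double v = (iv - (nv - 1) / 2.0) * dv + off_v;
    p[0] = cx + u * ux;
    p[1] = cy + u * uy;
    p[2] = v;
  }
};

// Axis-aligned voxel grid; origin = physical centre of voxel (0,0,0).
struct CbGrid {
  int nx, ny, nz;
  double dx, dy, dz;
  double ox, oy, oz;

  double xmin() const { return ox - 0.5 * dx; }
  double ymin() const { return oy - 0.5 * dy; }
  double zmin() const { return oz - 0.5 * dz; }
  double xmax() const { return xmin() + nx * dx; }
  double ymax() const { return ymin() + ny * dy; }
  double zmax() const { return zmin() + nz * dz; }
};

#endif
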