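#ifndef MORPHATLAS_BSPLINE_H
#define MORPHATLAS_BSPLINE_H

#include <cmath>
#include <algorithm>

// Uniform cubic B-spline basis, t in [0, 1].
inline void bs_weights(double t, double w[4]) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// Derivative of the basis with respect to t.
inline void bs_dweights(double t, double w[4]) {
  const double t2 = t * t;
  w[0] = (-3.0 + 6.0 * t - 3.0 * t2) / 6.0;
  w[1] = (-12.0 * t + 9.0 * t2) / 6.0;
  w[2] = (3.0 + 6.0 * t - 9.0 * t2) / 6.0;
  w[3] = 3.0 * t2 / 6.0;
}

// Knot-cell lookup for a lattice of `intervals` cells over [0, n-1].
// Returns the base coefficient index (0-based into a lattice of
// intervals + 3 control points) and writes the local coordinate to t.
// Positions outside [0, n-1] are clamped to the boundary cells, which
// extrapolates the polynomial of the edge cell (used only transiently by
// the point-inversion iteration).
inline int bs_cell(double x, double h, int intervals, double &t) {
  double s = x / h;
  int i = (int)std::floor(s);
  if (i < 0) i = 0;
  if (i > intervals - 1) i = intervals - 1;
  t = s - i;
  return i;
}

// Displacement of a coefficient lattice (gu, gv, 2), gu = iu + 3, spanning
// the pixel domain [0, nu-1] x [0, nv-1] with cell sizes hu, hv.
inline void disp_at_one(const double *c, int gu, int gv,
                        double hu, double hv, int iu, int iv,
                        double u, double v, double &du, double &dv) {
  double tu, tv, wu[4], wv[4];
  int bi = bs_cell(u, hu, iu, tu);
  int bj = bs_cell(v, hv, iv, tv);
  bs_weights(tu, wu);
  bs_weights(tv, wv);
  du = 0.0; dv = 0.0;
  const int plane = gu * gv;
  for (int m = 0; m < 4; ++m) {
    const int col = (bj + m) * gu + bi;
    const double wm = wv[m];
    for (int l = 0; l < 4; ++l) {
      const double w = wu[l] * wm;
      du += w * c[col + l];
      dv += w * c[plane + col + l];
    }
  }
}

// Spatial Jacobian of the displacement field d (not of T = id + d).
inline void disp_jac_one(const double *c, int gu, int gv,
                         double hu, double hv, int iu, int iv,
                         double u, double v, double J[4]) {
  double tu, tv, wu[4], wv[4], dwu[4], dwv[4];
  int bi = bs_cell(u, hu, iu, tu);
  int bj = bs_cell(v, hv, iv, tv);
  bs_weights(tu, wu);  bs_dweights(tu, dwu);
  bs_weights(tv, wv);  bs_dweights(tv, dwv);
  J[0] = J[1] = J[2] = J[3] = 0.0;  // du/du', du/dv', dv/du', dv/dv'
  const int plane = gu * gv;
  for (int m = 0; m < 4; ++m) {
    const int col = (bj + m) * gu + bi;
    for (int l = 0; l < 4; ++l) {
      const double cu = c[col + l], cv = c[plane + col + l];
      const double wdu = dwu[l] * wv[m] / hu;
      const double wdv = wu[l] * dwv[m] / hv;
      J[0] += wdu * cu; J[1] += wdv * cu;
      J[2] += wdu * cv; J[3] += wdv * cv;
    }
  }
}

inline double sample_bilinear(const double *img, int nu, int nv,
                              double u, double v) {
  if (u < 0.0 || v < 0.0 || u > nu - 1.0 || v > nv - 1.0) return 0.0;
  int i0 = (int)std::floor(u), j0 = (int)std::floor(v);
  if (i0 > nu - 2) i0 = nu - 2;
  if (j0 > nv - 2) j0 = nv - 2;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  double fu = u - i0, fv = v - j0;
  int i1 = std::min(i0 + 1, nu - 1), j1 = std::min(j0 + 1, nv - 1);
  double a = img[j0 * nu + i0], b = img[j0 * nu + i1];
  double cc = img[j1 * nu + i0], d = img[j1 * nu + i1];
  return a * (1 - fu) * (1 - fv) + b * fu * (1 - fv) +
         cc * (1 - fu) * fv + d * fu * fv;
}

inline double sample_nearest(const double *img, int nu, int nv,
                             double u, double v) {
  double ur = std::floor(u + 0.5), vr = std::floor(v + 0.5);
  if (ur < 0 || vr < 0 || ur > nu - 1 || vr > nv - 1) return 0.0;
  return img[(int)vr * nu + (int)ur];
}

#endif
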