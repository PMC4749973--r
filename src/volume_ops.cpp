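#include <Rcpp.h>
#include <vector>
#include <queue>
#include "bspline.h"

using namespace Rcpp;

// Separable Gaussian smoothing of a 3D volume, per-axis sigma in voxels,
// reflected boundaries.
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector vol, NumericVector sigma) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  const int n_[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0.0) continue;
    const int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ks = 0.0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); ks += k[i + r]; }
    for (double &w : k) w /= ks;
    const int n = n_[ax], st = stride[ax];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int idx[3] = {x, y, z};
          double acc = 0.0;
          const int base = x + nx * (y + (long)ny * z);
          for (int i = -r; i <= r; ++i) {
            const int j = refl(idx[ax] + i, n);
            acc += k[i + r] * a[base + (j - idx[ax]) * st];
          }
          b[base] = acc;
        }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// 6-connected component labelling of a binary volume; labels assigned in
// raster-scan discovery order starting at 1.
// [[Rcpp::export]]
IntegerVector cpp_label3d(NumericVector vol) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (vol[s] == 0.0 || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const long cur = stack.back();
      stack.pop_back();
      const int x = cur % nx, y = (cur / nx) % ny, z = cur / ((long)nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        const int X = x + dx[d], Y = y + dy[d], Z = z + dz[d];
        if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
        const long q = X + nx * (Y + (long)ny * Z);
        if (vol[q] != 0.0 && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

namespace {

// 3D cubic B-spline displacement: coeffs (gx, gy, gz, 3) over the voxel
// domain [0, n-1] per axis with `iv[ax]` lattice intervals.
inline void disp3d(const double *c, const int g[3], const double h[3],
                   const int iv[3], double x, double y, double z,
                   double d[3]) {
  double t[3], w[3][4];
  int b[3];
  const double p[3] = {x, y, z};
  for (int ax = 0; ax < 3; ++ax) {
    b[ax] = bs_cell(p[ax], h[ax], iv[ax], t[ax]);
    bs_weights(t[ax], w[ax]);
  }
  const long plane = (long)g[0] * g[1] * g[2];
  d[0] = d[1] = d[2] = 0.0;
  for (int kk = 0; kk < 4; ++kk)
    for (int jj = 0; jj < 4; ++jj) {
      const long base = b[0] + (long)g[0] * ((b[1] + jj) + (long)g[1] * (b[2] + kk));
      const double wjk = w[1][jj] * w[2][kk];
      for (int ii = 0; ii < 4; ++ii) {
        const double wt = w[0][ii] * wjk;
        d[0] += wt * c[base + ii];
        d[1] += wt * c[plane + base + ii];
        d[2] += wt * c[2 * plane + base + ii];
      }
    }
}

inline double sample3d_linear(const double *v, int nx, int ny, int nz,
                              double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0)
    return 0.0;
  int x0 = std::min((int)std::floor(x), nx - 2), y0 = std::min((int)std::floor(y), ny - 2),
      z0 = std::min((int)std::floor(z), nz - 2);
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        const int X = std::min(x0 + dx, nx - 1), Y = std::min(y0 + dy, ny - 1),
                  Z = std::min(z0 + dz, nz - 1);
        const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
        acc += w * v[X + nx * (Y + (long)ny * Z)];
      }
  return acc;
}

}  // namespace

// Backward warp of a volume through a 3D B-spline lattice:
// out(p) = vol(p + d(p)). interp: 0 nearest, 1 linear.
// [[Rcpp::export]]
NumericVector cpp_warp3d_bspline(NumericVector vol, NumericVector coeffs,
                                 IntegerVector gdim, IntegerVector intervals,
                                 int interp) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int g[3] = {gdim[0], gdim[1], gdim[2]};
  const int iv[3] = {intervals[0], intervals[1], intervals[2]};
  const double h[3] = {(nx - 1.0) / iv[0], (ny - 1.0) / iv[1], (nz - 1.0) / iv[2]};
  NumericVector out((long)nx * ny * nz);
  out.attr("dim") = dim;
  const double *c = coeffs.begin();
  const double *v = vol.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double d[3];
        disp3d(c, g, h, iv, (double)x, (double)y, (double)z, d);
        const double sx = x + d[0], sy = y + d[1], sz = z + d[2];
        double val;
        if (interp == 0) {
          const double xr = std::floor(sx + 0.5), yr = std::floor(sy + 0.5),
                       zr = std::floor(sz + 0.5);
          val = (xr < 0 || yr < 0 || zr < 0 || xr > nx - 1 || yr > ny - 1 ||
                 zr > nz - 1)
                    ? 0.0
                    : v[(int)xr + nx * ((int)yr + (long)ny * (int)zr)];
        } else {
          val = sample3d_linear(v, nx, ny, nz, sx, sy, sz);
        }
        out[x + nx * (y + (long)ny * z)] = val;
      }
  return out;
}

// 3D B-spline displacement at arbitrary voxel-space points (m x 3).
// [[Rcpp::export]]
NumericMatrix cpp_disp3d_at(NumericVector coeffs, IntegerVector gdim,
                            IntegerVector vdim, IntegerVector intervals,
                            NumericMatrix pts) {
  const int g[3] = {gdim[0], gdim[1], gdim[2]};
  const int iv[3] = {intervals[0], intervals[1], intervals[2]};
  const double h[3] = {(vdim[0] - 1.0) / iv[0], (vdim[1] - 1.0) / iv[1],
                       (vdim[2] - 1.0) / iv[2]};
  NumericMatrix out(pts.nrow(), 3);
  for (int k = 0; k < pts.nrow(); ++k) {
    double d[3];
    disp3d(coeffs.begin(), g, h, iv, pts(k, 0), pts(k, 1), pts(k, 2), d);
    out(k, 0) = d[0]; out(k, 1) = d[1]; out(k, 2) = d[2];
  }
  return out;
}

// Fixed-point inversion in 3D: p with p + d(p) = q.
// [[Rcpp::export]]
List cpp_invert_points3d(NumericVector coeffs, IntegerVector gdim,
                         IntegerVector vdim, IntegerVector intervals,
                         NumericMatrix q, double tol, int max_iter) {
  const int g[3] = {gdim[0], gdim[1], gdim[2]};
  const int iv[3] = {intervals[0], intervals[1], intervals[2]};
  const double h[3] = {(vdim[0] - 1.0) / iv[0], (vdim[1] - 1.0) / iv[1],
                       (vdim[2] - 1.0) / iv[2]};
  NumericMatrix out(q.nrow(), 3);
  LogicalVector conv(q.nrow());
  for (int k = 0; k < q.nrow(); ++k) {
    double p[3] = {q(k, 0), q(k, 1), q(k, 2)}, d[3];
    bool ok = false;
    for (int it = 0; it < max_iter; ++it) {
      disp3d(coeffs.begin(), g, h, iv, p[0], p[1], p[2], d);
      double step = 0.0;
      for (int ax = 0; ax < 3; ++ax) {
        const double np = q(k, ax) - d[ax];
        step += (np - p[ax]) * (np - p[ax]);
        p[ax] = np;
      }
      if (std::sqrt(step) <= tol) { ok = true; break; }
    }
    out(k, 0) = p[0]; out(k, 1) = p[1]; out(k, 2) = p[2];
    conv[k] = ok;
  }
  return List::create(_["points"] = out, _["converged"] = conv);
}
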