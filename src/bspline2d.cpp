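#include <Rcpp.h>
#include "bspline.h"

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_disp_at(NumericVector coeffs, int gu, int gv,
                          int nu, int nv, int iu, int iv,
                          NumericMatrix pts) {
  const double hu = (nu - 1.0) / iu, hv = (nv - 1.0) / iv;
  const int m = pts.nrow();
  NumericMatrix out(m, 2);
  const double *c = coeffs.begin();
  for (int k = 0; k < m; ++k) {
    double du, dv;
    disp_at_one(c, gu, gv, hu, hv, iu, iv, pts(k, 0), pts(k, 1), du, dv);
    out(k, 0) = du; out(k, 1) = dv;
  }
  return out;
}

// Backward warp: out(p) = img(p + d(p)). interp: 0 nearest, 1 linear.
// [[Rcpp::export]]
NumericMatrix cpp_warp2d(NumericMatrix img, NumericVector coeffs,
                         int gu, int gv, int iu, int iv, int interp) {
  const int nu = img.nrow(), nv = img.ncol();
  const double hu = (nu - 1.0) / iu, hv = (nv - 1.0) / iv;
  NumericMatrix out(nu, nv);
  const double *c = coeffs.begin();
  const double *im = img.begin();
  for (int v = 0; v < nv; ++v) {
    for (int u = 0; u < nu; ++u) {
      double du, dv;
      disp_at_one(c, gu, gv, hu, hv, iu, iv, (double)u, (double)v, du, dv);
      const double su = u + du, sv = v + dv;
      out(u, v) = interp == 0 ? sample_nearest(im, nu, nv, su, sv)
                              : sample_bilinear(im, nu, nv, su, sv);
    }
  }
  return out;
}

// Fixed-point inversion: find p with p + d(p) = q for each query point.
// [[Rcpp::export]]
List cpp_invert_points(NumericVector coeffs, int gu, int gv,
                       int nu, int nv, int iu, int iv,
                       NumericMatrix q, double tol, int max_iter) {
  const double hu = (nu - 1.0) / iu, hv = (nv - 1.0) / iv;
  const int m = q.nrow();
  NumericMatrix out(m, 2);
  LogicalVector conv(m);
  const double *c = coeffs.begin();
  for (int k = 0; k < m; ++k) {
    const double qu = q(k, 0), qv = q(k, 1);
    double pu = qu, pv = qv, du = 0.0, dv = 0.0;
    bool ok = false;
    for (int it = 0; it < max_iter; ++it) {
      disp_at_one(c, gu, gv, hu, hv, iu, iv, pu, pv, du, dv);
      const double nu_ = qu - du, nv_ = qv - dv;
      const double step = std::hypot(nu_ - pu, nv_ - pv);
      pu = nu_; pv = nv_;
      if (step <= tol) { ok = true; break; }
    }
    disp_at_one(c, gu, gv, hu, hv, iu, iv, pu, pv, du, dv);
    if (std::hypot(pu + du - qu, pv + dv - qv) <= tol) ok = true;
    out(k, 0) = pu; out(k, 1) = pv;
    conv[k] = ok;
  }
  return List::create(_["points"] = out, _["converged"] = conv);
}

// Full displacement field over the pixel grid; returned as (nu, nv, 2).
// [[Rcpp::export]]
NumericVector cpp_disp_field(NumericVector coeffs, int gu, int gv,
                             int nu, int nv, int iu, int iv) {
  const double hu = (nu - 1.0) / iu, hv = (nv - 1.0) / iv;
  NumericVector out(nu * nv * 2);
  const double *c = coeffs.begin();
  for (int v = 0; v < nv; ++v)
    for (int u = 0; u < nu; ++u) {
      double du, dv;
      disp_at_one(c, gu, gv, hu, hv, iu, iv, (double)u, (double)v, du, dv);
      out[v * nu + u] = du;
      out[nu * nv + v * nu + u] = dv;
    }
  out.attr("dim") = IntegerVector::create(nu, nv, 2);
  return out;
}
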