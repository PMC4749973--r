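#include <Rcpp.h>
#include <vector>
#include "bspline.h"

using namespace Rcpp;

namespace {

struct Geo {
  int nu, nv, iu, iv, gu, gv;
  double hu, hv;
  int ncoef() const { return gu * gv * 2; }
};

// Separable Gaussian smoothing with reflected boundaries; sigma <= 0 copies.
void gauss_smooth2d(const std::vector<double> &in, int nu, int nv,
                    double sigma, std::vector<double> &out) {
  if (sigma <= 0.0) { out = in; return; }
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &w : k) w /= s;
  std::vector<double> tmp(nu * nv);
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int v = 0; v < nv; ++v)
    for (int u = 0; u < nu; ++u) {
      double a = 0.0;
      for (int i = -r; i <= r; ++i) a += k[i + r] * in[v * nu + refl(u + i, nu)];
      tmp[v * nu + u] = a;
    }
  out.resize(nu * nv);
  for (int v = 0; v < nv; ++v)
    for (int u = 0; u < nu; ++u) {
      double a = 0.0;
      for (int i = -r; i <= r; ++i) a += k[i + r] * tmp[refl(v + i, nv) * nu + u];
      out[v * nu + u] = a;
    }
}

void gradients(const std::vector<double> &img, int nu, int nv,
               std::vector<double> &gx, std::vector<double> &gy) {
  gx.assign(nu * nv, 0.0);
  gy.assign(nu * nv, 0.0);
  for (int v = 0; v < nv; ++v)
    for (int u = 0; u < nu; ++u) {
      const int up = std::min(u + 1, nu - 1), um = std::max(u - 1, 0);
      const int vp = std::min(v + 1, nv - 1), vm = std::max(v - 1, 0);
      gx[v * nu + u] = (img[v * nu + up] - img[v * nu + um]) / (up - um > 0 ? up - um : 1);
      gy[v * nu + u] = (img[vp * nu + u] - img[vm * nu + u]) / (vp - vm > 0 ? vp - vm : 1);
    }
}

// Mean squared difference of moving(p + d(p)) vs fixed(p), with gradient
// accumulation into the coefficient lattice when grad != nullptr.
double mse_term(const Geo &g, const double *c,
                const double *mov, const double *gmx, const double *gmy,
                const double *fix, double *grad) {
  const int N = g.nu * g.nv, plane = g.gu * g.gv;
  double E = 0.0;
  for (int v = 0; v < g.nv; ++v)
    for (int u = 0; u < g.nu; ++u) {
      double du, dv;
      disp_at_one(c, g.gu, g.gv, g.hu, g.hv, g.iu, g.iv,
                  (double)u, (double)v, du, dv);
      const double su = u + du, sv = v + dv;
      const double m = sample_bilinear(mov, g.nu, g.nv, su, sv);
      const double r = m - fix[v * g.nu + u];
      E += r * r;
      if (grad) {
        const double mx = sample_bilinear(gmx, g.nu, g.nv, su, sv);
        const double my = sample_bilinear(gmy, g.nu, g.nv, su, sv);
        const double fu_ = 2.0 * r * mx / N, fv_ = 2.0 * r * my / N;
        if (fu_ == 0.0 && fv_ == 0.0) continue;
        double tu, tv, wu[4], wv[4];
        const int bi = bs_cell((double)u, g.hu, g.iu, tu);
        const int bj = bs_cell((double)v, g.hv, g.iv, tv);
        bs_weights(tu, wu);
        bs_weights(tv, wv);
        for (int m2 = 0; m2 < 4; ++m2) {
          const int col = (bj + m2) * g.gu + bi;
          for (int l = 0; l < 4; ++l) {
            const double w = wu[l] * wv[m2];
            grad[col + l] += w * fu_;
            grad[plane + col + l] += w * fv_;
          }
        }
      }
    }
  return E / N;
}

// Bending penalty: squared second derivatives of the continuous
// displacement field, approximated by coefficient second differences
// scaled by the lattice cell sizes (so the penalty is the discrete
// thin-plate bending energy of d, invariant to lattice density).
double bending_term(const Geo &g, const double *c, double *grad) {
  const int gu = g.gu, gv = g.gv, plane = gu * gv;
  double E = 0.0;
  const double nuu = 1.0 / (g.hu * g.hu), nvv = 1.0 / (g.hv * g.hv),
               nuv = 1.0 / (g.hu * g.hv);
  const double norm = 1.0 / (gu * gv);
  for (int comp = 0; comp < 2; ++comp) {
    const double *cc = c + comp * plane;
    double *gg = grad ? grad + comp * plane : nullptr;
    for (int j = 0; j < gv; ++j)
      for (int i = 1; i < gu - 1; ++i) {
        const double d2 = nuu * (cc[j * gu + i + 1] - 2 * cc[j * gu + i] +
                                 cc[j * gu + i - 1]);
        E += norm * d2 * d2;
        if (gg) {
          const double f = 2.0 * norm * nuu * d2;
          gg[j * gu + i + 1] += f; gg[j * gu + i] -= 2 * f; gg[j * gu + i - 1] += f;
        }
      }
    for (int j = 1; j < gv - 1; ++j)
      for (int i = 0; i < gu; ++i) {
        const double d2 = nvv * (cc[(j + 1) * gu + i] - 2 * cc[j * gu + i] +
                                 cc[(j - 1) * gu + i]);
        E += norm * d2 * d2;
        if (gg) {
          const double f = 2.0 * norm * nvv * d2;
          gg[(j + 1) * gu + i] += f; gg[j * gu + i] -= 2 * f; gg[(j - 1) * gu + i] += f;
        }
      }
    for (int j = 0; j < gv - 1; ++j)
      for (int i = 0; i < gu - 1; ++i) {
        const double dm = nuv * (cc[(j + 1) * gu + i + 1] - cc[j * gu + i + 1] -
                                 cc[(j + 1) * gu + i] + cc[j * gu + i]);
        E += 2.0 * norm * dm * dm;
        if (gg) {
          const double f = 4.0 * norm * nuv * dm;
          gg[(j + 1) * gu + i + 1] += f; gg[j * gu + i + 1] -= f;
          gg[(j + 1) * gu + i] -= f; gg[j * gu + i] += f;
        }
      }
  }
  return E;
}

// Inverse-consistency penalty |T_b(T_a(p)) - p|^2 on a strided pixel grid.
// Gradient w.r.t. c_b is exact; w.r.t. c_a the chain is taken through
// (I + J_b) evaluated at the composed point.
double consistency_term(const Geo &g, const double *ca, const double *cb,
                        double *ga, double *gb) {
  const int plane = g.gu * g.gv, stride = 2;
  // measured relative to the squared lattice cell area: the coupling only
  // needs to keep the forward/reverse lattices mutually inverse, and a
  // stronger scale makes the penalty fight the (intensity-scaled)
  // similarity term in low-gradient regions
  const double sc = 1.0 / (g.hu * g.hv * g.hu * g.hv);
  double E = 0.0;
  int n = 0;
  for (int v = 0; v < g.nv; v += stride)
    for (int u = 0; u < g.nu; u += stride) ++n;
  for (int v = 0; v < g.nv; v += stride)
    for (int u = 0; u < g.nu; u += stride) {
      double dau, dav;
      disp_at_one(ca, g.gu, g.gv, g.hu, g.hv, g.iu, g.iv,
                  (double)u, (double)v, dau, dav);
      const double qu = u + dau, qv = v + dav;
      double dbu, dbv;
      disp_at_one(cb, g.gu, g.gv, g.hu, g.hv, g.iu, g.iv, qu, qv, dbu, dbv);
      const double eu = qu + dbu - u, ev = qv + dbv - v;
      E += sc * (eu * eu + ev * ev);
      if (ga && gb) {
        double tu, tv, wu[4], wv[4];
        // direct part for c_b at the composed point q
        int bi = bs_cell(qu, g.hu, g.iu, tu);
        int bj = bs_cell(qv, g.hv, g.iv, tv);
        bs_weights(tu, wu); bs_weights(tv, wv);
        for (int m2 = 0; m2 < 4; ++m2) {
          const int col = (bj + m2) * g.gu + bi;
          for (int l = 0; l < 4; ++l) {
            const double w = wu[l] * wv[m2];
            gb[col + l] += 2.0 * sc * eu * w / n;
            gb[plane + col + l] += 2.0 * sc * ev * w / n;
          }
        }
        // chained part for c_a through (I + J_b)(q)
        double J[4];
        disp_jac_one(cb, g.gu, g.gv, g.hu, g.hv, g.iu, g.iv, qu, qv, J);
        const double fu_ = eu * (1.0 + J[0]) + ev * J[2];
        const double fv_ = eu * J[1] + ev * (1.0 + J[3]);
        bi = bs_cell((double)u, g.hu, g.iu, tu);
        bj = bs_cell((double)v, g.hv, g.iv, tv);
        bs_weights(tu, wu); bs_weights(tv, wv);
        for (int m2 = 0; m2 < 4; ++m2) {
          const int col = (bj + m2) * g.gu + bi;
          for (int l = 0; l < 4; ++l) {
            const double w = wu[l] * wv[m2];
            ga[col + l] += 2.0 * sc * fu_ * w / n;
            ga[plane + col + l] += 2.0 * sc * fv_ * w / n;
          }
        }
      }
    }
  return E / n;
}

struct Problem {
  Geo geo;
  const std::vector<double> *src, *tgt, *gsx, *gsy, *gtx, *gty;
  double w_sim, w_cons, w_reg;
  bool bidir;

  int npar() const { return geo.ncoef() * (bidir ? 2 : 1); }

  double eval(const std::vector<double> &theta, std::vector<double> *grad) const {
    const double *cf = theta.data();
    double *gf = nullptr, *gr = nullptr;
    if (grad) {
      grad->assign(npar(), 0.0);
      gf = grad->data();
    }
    double E = w_sim * mse_term(geo, cf, src->data(), gsx->data(), gsy->data(),
                                tgt->data(), gf);
    if (gf && w_sim != 1.0)
      for (int i = 0; i < geo.ncoef(); ++i) gf[i] *= w_sim;
    if (w_reg > 0.0) {
      std::vector<double> tmp;
      if (gf) tmp.assign(geo.ncoef(), 0.0);
      E += w_reg * bending_term(geo, cf, gf ? tmp.data() : nullptr);
      if (gf) for (int i = 0; i < geo.ncoef(); ++i) gf[i] += w_reg * tmp[i];
    }
    if (bidir) {
      const double *cr = theta.data() + geo.ncoef();
      if (grad) gr = grad->data() + geo.ncoef();
      std::vector<double> tmp;
      if (gr) tmp.assign(geo.ncoef(), 0.0);
      E += w_sim * mse_term(geo, cr, tgt->data(), gtx->data(), gty->data(),
                            src->data(), gr ? tmp.data() : nullptr);
      if (gr) for (int i = 0; i < geo.ncoef(); ++i) gr[i] += w_sim * tmp[i];
      if (w_reg > 0.0) {
        if (gr) tmp.assign(geo.ncoef(), 0.0);
        E += w_reg * bending_term(geo, cr, gr ? tmp.data() : nullptr);
        if (gr) for (int i = 0; i < geo.ncoef(); ++i) gr[i] += w_reg * tmp[i];
      }
      if (w_cons > 0.0) {
        std::vector<double> ta, tb;
        if (grad) { ta.assign(geo.ncoef(), 0.0); tb.assign(geo.ncoef(), 0.0); }
        double C = consistency_term(geo, cf, cr,
                                    grad ? ta.data() : nullptr,
                                    grad ? tb.data() : nullptr);
        C += consistency_term(geo, cr, cf,
                              grad ? tb.data() : nullptr,
                              grad ? ta.data() : nullptr);
        E += w_cons * C;
        if (grad)
          for (int i = 0; i < geo.ncoef(); ++i) {
            gf[i] += w_cons * ta[i];
            gr[i] += w_cons * tb[i];
          }
      }
    }
    return E;
  }
};

// Backtracking gradient descent; step is the maximum coefficient change in
// pixels per accepted iteration. Fully deterministic.
void optimize(const Problem &prob, std::vector<double> &theta,
              int max_steps, double tol) {
  std::vector<double> grad, trial;
  double E = prob.eval(theta, &grad);
  double step = 1.0;
  for (int it = 0; it < max_steps; ++it) {
    double gmax = 0.0;
    for (double g : grad) gmax = std::max(gmax, std::fabs(g));
    if (gmax < 1e-14) break;
    bool accepted = false;
    double Et = E;
    while (step >= 1e-5) {
      trial.resize(theta.size());
      const double a = step / gmax;
      for (size_t i = 0; i < theta.size(); ++i) trial[i] = theta[i] - a * grad[i];
      Et = prob.eval(trial, nullptr);
      if (Et < E) { accepted = true; break; }
      step *= 0.5;
    }
    if (!accepted) break;
    const double rel = (E - Et) / std::max(E, 1e-300);
    theta.swap(trial);
    E = Et;
    if (rel < tol) break;
    step = std::min(step * 1.5, 4.0);
    prob.eval(theta, &grad);
  }
}

}  // namespace

// Pair-wise consistent elastic registration. Returns the forward lattice
// (resampling src through it approximates tgt) and, when bidirectional,
// the reverse lattice. Coarse-to-fine is realized by decreasing Gaussian
// smoothing of both images over `levels` passes on a fixed lattice.
// [[Rcpp::export]]
List cpp_register_pair(NumericMatrix src, NumericMatrix tgt,
                       int iu, int iv, int levels, int max_steps, double tol,
                       double w_sim, double w_cons, double w_reg) {
  Geo g;
  g.nu = src.nrow(); g.nv = src.ncol();
  g.iu = iu; g.iv = iv; g.gu = iu + 3; g.gv = iv + 3;
  g.hu = (g.nu - 1.0) / iu; g.hv = (g.nv - 1.0) / iv;
  const bool bidir = w_cons > 0.0;

  std::vector<double> s0(src.begin(), src.end()), t0(tgt.begin(), tgt.end());
  std::vector<double> theta(g.ncoef() * (bidir ? 2 : 1), 0.0);

  for (int level = levels; level >= 1; --level) {
    const double sigma = (double)(1 << (level - 1)) - 1.0;
    std::vector<double> ss, ts, gsx, gsy, gtx, gty;
    gauss_smooth2d(s0, g.nu, g.nv, sigma, ss);
    gauss_smooth2d(t0, g.nu, g.nv, sigma, ts);
    gradients(ss, g.nu, g.nv, gsx, gsy);
    gradients(ts, g.nu, g.nv, gtx, gty);
    Problem prob;
    prob.geo = g;
    prob.src = &ss; prob.tgt = &ts;
    prob.gsx = &gsx; prob.gsy = &gsy; prob.gtx = &gtx; prob.gty = &gty;
    prob.w_sim = w_sim; prob.w_cons = w_cons; prob.w_reg = w_reg;
    prob.bidir = bidir;
    optimize(prob, theta, max_steps, tol);
  }

  NumericVector fwd(theta.begin(), theta.begin() + g.ncoef());
  fwd.attr("dim") = IntegerVector::create(g.gu, g.gv, 2);
  List out = List::create(_["forward"] = fwd, _["reverse"] = R_NilValue);
  if (bidir) {
    NumericVector rev(theta.begin() + g.ncoef(), theta.end());
    rev.attr("dim") = IntegerVector::create(g.gu, g.gv, 2);
    out["reverse"] = rev;
  }
  return out;
}
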