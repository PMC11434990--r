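#include <Rcpp.h>
using namespace Rcpp;

// Two-compartment disposition with zero-order (constant-rate) infusion input,
// parametrized in CL, Vc, Q, Vp.  Micro-constants k10 = CL/Vc, k12 = Q/Vc,
// k21 = Q/Vp; hybrid rate constants alpha, beta from
//   alpha + beta = k10 + k12 + k21,  alpha * beta = k10 * k21.
// The central concentration after a single infusion of rate R0 over [t0, t0+dur]
// is the convolution of the unit-bolus biexponential with the input, summed
// over doses (superposition; parameters constant over the window).

struct Disp2 {
  double vc, alpha, beta, A, B;     // unit-bolus C(t) = (A e^{-a t} + B e^{-b t})/vc
  bool one_cpt;                     // Q or Vp ~ 0: monoexponential limit
  double k10;
};

static Disp2 make_disp2(double cl, double vc, double q, double vp) {
  Disp2 d;
  d.vc = vc;
  d.k10 = cl / vc;
  if (q <= 0.0 || vp <= 0.0) {        // peripheral compartment unreachable
    d.one_cpt = true;
    d.alpha = d.k10; d.beta = 0.0; d.A = 1.0; d.B = 0.0;
    return d;
  }
  d.one_cpt = false;
  double k12 = q / vc, k21 = q / vp;
  double s = d.k10 + k12 + k21;
  double p = d.k10 * k21;
  double disc = s * s - 4.0 * p;
  double sq = disc > 0.0 ? std::sqrt(disc) : 0.0;
  // degenerate alpha ~= beta: epsilon-perturbation of the separation, which
  // keeps the closed form finite with O(1e-8) relative error
  double floor_sq = s * 1e-8;
  if (sq < floor_sq) sq = floor_sq;
  d.alpha = 0.5 * (s + sq);
  d.beta  = 0.5 * (s - sq);
  if (d.beta <= 0.0) d.beta = p / d.alpha; // numerical safety
  d.A = (d.alpha - k21) / sq;
  d.B = (k21 - d.beta) / sq;
  return d;
}

// contribution of one infusion (rate r0 over [t0, t0+dur]) at time t
static double conc_one_dose(const Disp2& d, double t, double t0, double r0,
                            double dur) {
  double tt = t - t0;
  if (tt <= 0.0) return 0.0;
  double out = 0.0;
  if (d.one_cpt) {
    double cl = d.k10 * d.vc;
    if (tt <= dur) {
      out = (r0 / cl) * (1.0 - std::exp(-d.k10 * tt));
    } else {
      out = (r0 / cl) * (1.0 - std::exp(-d.k10 * dur)) *
            std::exp(-d.k10 * (tt - dur));
    }
    return out;
  }
  double ca, cb;
  if (tt <= dur) {
    ca = d.A / d.alpha * (1.0 - std::exp(-d.alpha * tt));
    cb = d.B / d.beta  * (1.0 - std::exp(-d.beta  * tt));
  } else {
    double tp = tt - dur;
    ca = d.A / d.alpha * (1.0 - std::exp(-d.alpha * dur)) * std::exp(-d.alpha * tp);
    cb = d.B / d.beta  * (1.0 - std::exp(-d.beta  * dur)) * std::exp(-d.beta  * tp);
  }
  out = (r0 / d.vc) * (ca + cb);
  return out > 0.0 ? out : 0.0;
}

// [[Rcpp::export]]
NumericVector conc2cpt_cpp(NumericVector times,
                           NumericVector dose_start,
                           NumericVector dose_amt,
                           NumericVector dose_dur,
                           double cl, double vc, double q, double vp) {
  Disp2 d = make_disp2(cl, vc, q, vp);
  int n = times.size(), nd = dose_start.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double c = 0.0;
    for (int k = 0; k < nd; ++k) {
      c += conc_one_dose(d, times[i], dose_start[k],
                         dose_amt[k] / dose_dur[k], dose_dur[k]);
    }
    out[i] = c;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Subject-level joint -2 log density g(u) for the Laplace approximation.
//
// u = (eta_cl, eta_vc [, kappa_1..kappa_K])  (components present per flags)
// Occasion k parameters: CL_k = tvcl * clm_k * exp(eta_cl + kappa_k),
//                        Vc_k = tvvc * vcm_k * exp(eta_vc),
//                        Q_k  = tvq * qm_k,  Vp_k = tvvp * vpm_k.
// Proportional residual error y = f (1 + sigma e), conditional (interaction)
// variance sigma^2 f(u)^2.
// ---------------------------------------------------------------------------

struct SubjData {
  double tvcl, tvvc, tvq, tvvp;
  std::vector<double> clm, vcm, qm, vpm;       // per occasion
  double oi11, oi12, oi22, ldet_eta;           // Omega^{-1}, log((2pi)^2 det Omega)
  double wbov2, sigma2;
  std::vector<double> obs_t, obs_y;
  std::vector<int> obs_occ;                    // 1-based occasion of each obs
  // doses grouped by occasion
  std::vector<double> d_start, d_amt, d_dur;
  std::vector<int> d_occ;
  int K;                                       // number of occasions
  bool est_eta, est_bov;
};

static void predict_subject(const SubjData& S, const double* u,
                            std::vector<double>& f) {
  int off = S.est_eta ? 2 : 0;
  double e1 = S.est_eta ? u[0] : 0.0;
  double e2 = S.est_eta ? u[1] : 0.0;
  int n = (int)S.obs_t.size();
  f.assign(n, 0.0);
  for (int k = 0; k < S.K; ++k) {
    double kap = S.est_bov ? u[off + k] : 0.0;
    double cl = S.tvcl * S.clm[k] * std::exp(e1 + kap);
    double vc = S.tvvc * S.vcm[k] * std::exp(e2);
    Disp2 d = make_disp2(cl, vc, S.tvq * S.qm[k], S.tvvp * S.vpm[k]);
    for (size_t j = 0; j < S.obs_t.size(); ++j) {
      if (S.obs_occ[j] != k + 1) continue;
      double c = 0.0;
      for (size_t m = 0; m < S.d_start.size(); ++m) {
        if (S.d_occ[m] != k + 1) continue;
        c += conc_one_dose(d, S.obs_t[j], S.d_start[m],
                           S.d_amt[m] / S.d_dur[m], S.d_dur[m]);
      }
      f[j] = c;
    }
  }
}

static const double LOG2PI = 1.8378770664093454836;

static double g_of_u(const SubjData& S, const double* u) {
  std::vector<double> f;
  predict_subject(S, u, f);
  double g = 0.0;
  for (size_t j = 0; j < f.size(); ++j) {
    double fj = f[j] > 1e-12 ? f[j] : 1e-12;
    double v = S.sigma2 * fj * fj;
    double r = S.obs_y[j] - fj;
    g += std::log(2.0 * M_PI * v) + r * r / v;
  }
  if (S.est_eta) {
    double e1 = u[0], e2 = u[1];
    g += e1 * e1 * S.oi11 + 2.0 * e1 * e2 * S.oi12 + e2 * e2 * S.oi22;
    g += S.ldet_eta;
  }
  if (S.est_bov) {
    int off = S.est_eta ? 2 : 0;
    for (int k = 0; k < S.K; ++k) {
      double kap = u[off + k];
      g += kap * kap / S.wbov2 + std::log(2.0 * M_PI * S.wbov2);
    }
  }
  return g;
}

static SubjData unpack(List subj, NumericVector par, NumericMatrix oinv,
                       double ldet_eta, double wbov2, double sigma,
                       bool est_eta, bool est_bov) {
  SubjData S;
  S.tvcl = par[0]; S.tvvc = par[1]; S.tvq = par[2]; S.tvvp = par[3];
  S.clm = as<std::vector<double> >(subj["clm"]);
  S.vcm = as<std::vector<double> >(subj["vcm"]);
  S.qm  = as<std::vector<double> >(subj["qm"]);
  S.vpm = as<std::vector<double> >(subj["vpm"]);
  S.obs_t = as<std::vector<double> >(subj["obs_t"]);
  S.obs_y = as<std::vector<double> >(subj["obs_y"]);
  S.obs_occ = as<std::vector<int> >(subj["obs_occ"]);
  S.d_start = as<std::vector<double> >(subj["d_start"]);
  S.d_amt = as<std::vector<double> >(subj["d_amt"]);
  S.d_dur = as<std::vector<double> >(subj["d_dur"]);
  S.d_occ = as<std::vector<int> >(subj["d_occ"]);
  S.K = (int)S.clm.size();
  S.oi11 = oinv(0, 0); S.oi12 = oinv(0, 1); S.oi22 = oinv(1, 1);
  S.ldet_eta = ldet_eta;
  S.wbov2 = wbov2;
  S.sigma2 = sigma * sigma;
  S.est_eta = est_eta;
  S.est_bov = est_bov;
  return S;
}

// [[Rcpp::export]]
double subj_g_cpp(NumericVector u, List subj, NumericVector par,
                  NumericMatrix oinv, double ldet_eta, double wbov2,
                  double sigma, bool est_eta, bool est_bov) {
  SubjData S = unpack(subj, par, oinv, ldet_eta, wbov2, sigma, est_eta, est_bov);
  return g_of_u(S, u.begin());
}

// [[Rcpp::export]]
NumericVector subj_pred_cpp(NumericVector u, List subj, NumericVector par,
                            NumericMatrix oinv, double ldet_eta, double wbov2,
                            double sigma, bool est_eta, bool est_bov) {
  SubjData S = unpack(subj, par, oinv, ldet_eta, wbov2, sigma, est_eta, est_bov);
  std::vector<double> f;
  std::vector<double> uu(u.begin(), u.end());
  if (uu.empty()) uu.push_back(0.0);
  predict_subject(S, &uu[0], f);
  return wrap(f);
}

// central finite differences of g
static void grad_hess(const SubjData& S, std::vector<double>& u,
                      std::vector<double>& gr, std::vector<std::vector<double> >& H) {
  int d = (int)u.size();
  gr.assign(d, 0.0);
  H.assign(d, std::vector<double>(d, 0.0));
  double g0 = g_of_u(S, &u[0]);
  std::vector<double> h(d);
  for (int i = 0; i < d; ++i) h[i] = 1e-4 * (1.0 + std::fabs(u[i]));
  std::vector<double> gp(d), gm(d);
  for (int i = 0; i < d; ++i) {
    double ui = u[i];
    u[i] = ui + h[i]; gp[i] = g_of_u(S, &u[0]);
    u[i] = ui - h[i]; gm[i] = g_of_u(S, &u[0]);
    u[i] = ui;
    gr[i] = (gp[i] - gm[i]) / (2.0 * h[i]);
    H[i][i] = (gp[i] - 2.0 * g0 + gm[i]) / (h[i] * h[i]);
  }
  for (int i = 0; i < d; ++i) {
    for (int j = i + 1; j < d; ++j) {
      double ui = u[i], uj = u[j];
      u[i] = ui + h[i]; u[j] = uj + h[j]; double gpp = g_of_u(S, &u[0]);
      u[j] = uj - h[j];                   double gpm = g_of_u(S, &u[0]);
      u[i] = ui - h[i];                   double gmm = g_of_u(S, &u[0]);
      u[j] = uj + h[j];                   double gmp = g_of_u(S, &u[0]);
      u[i] = ui; u[j] = uj;
      H[i][j] = H[j][i] = (gpp - gpm - gmp + gmm) / (4.0 * h[i] * h[j]);
    }
  }
}

// Cholesky of H + ridge; returns log det and factor in L; grows ridge until PD
static bool chol_logdet(std::vector<std::vector<double> > H, int d,
                        std::vector<std::vector<double> >& L, double& logdet) {
  double ridge = 0.0, maxd = 1e-8;
  for (int i = 0; i < d; ++i) maxd = std::max(maxd, std::fabs(H[i][i]));
  for (int attempt = 0; attempt < 12; ++attempt) {
    L.assign(d, std::vector<double>(d, 0.0));
    bool ok = true;
    logdet = 0.0;
    for (int i = 0; i < d && ok; ++i) {
      for (int j = 0; j <= i; ++j) {
        double s = H[i][j] + (i == j ? ridge : 0.0);
        for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
        if (i == j) {
          if (s <= 0.0) { ok = false; break; }
          L[i][i] = std::sqrt(s);
          logdet += 2.0 * std::log(L[i][i]);
        } else {
          L[i][j] = s / L[j][j];
        }
      }
    }
    if (ok) return true;
    ridge = ridge == 0.0 ? 1e-8 * maxd : ridge * 10.0;
  }
  return false;
}

static void chol_solve(const std::vector<std::vector<double> >& L, int d,
                       const std::vector<double>& b, std::vector<double>& x) {
  std::vector<double> y(d);
  for (int i = 0; i < d; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i][k] * y[k];
    y[i] = s / L[i][i];
  }
  x.assign(d, 0.0);
  for (int i = d - 1; i >= 0; --i) {
    double s = y[i];
    for (int k = i + 1; k < d; ++k) s -= L[k][i] * x[k];
    x[i] = s / L[i][i];
  }
}

// Newton with backtracking on g(u); returns mode, g at mode and the Laplace
// log-determinant term log det(H/2).
// [[Rcpp::export]]
List subj_laplace_cpp(NumericVector u0, List subj, NumericVector par,
                      NumericMatrix oinv, double ldet_eta, double wbov2,
                      double sigma, bool est_eta, bool est_bov,
                      int maxit = 100, double tol = 1e-8) {
  SubjData S = unpack(subj, par, oinv, ldet_eta, wbov2, sigma, est_eta, est_bov);
  int d = u0.size();
  if (d == 0) {
    double g0 = g_of_u(S, NULL);
    return List::create(_["u"] = NumericVector(0), _["g"] = g0,
                        _["logdet_half"] = 0.0, _["conv"] = true,
                        _["nll2"] = g0);
  }
  std::vector<double> u(u0.begin(), u0.end());
  double g0 = g_of_u(S, &u[0]);
  if (!std::isfinite(g0)) { std::fill(u.begin(), u.end(), 0.0); g0 = g_of_u(S, &u[0]); }
  std::vector<double> gr;
  std::vector<std::vector<double> > H, L;
  bool conv = false;
  for (int it = 0; it < maxit; ++it) {
    grad_hess(S, u, gr, H);
    double gmax = 0.0;
    for (int i = 0; i < d; ++i) gmax = std::max(gmax, std::fabs(gr[i]));
    if (gmax < tol) { conv = true; break; }
    double logdet;
    if (!chol_logdet(H, d, L, logdet)) break;
    std::vector<double> step;
    chol_solve(L, d, gr, step);
    double t = 1.0;
    bool improved = false;
    for (int ls = 0; ls < 30; ++ls) {
      std::vector<double> ut(d);
      for (int i = 0; i < d; ++i) ut[i] = u[i] - t * step[i];
      double gt = g_of_u(S, &ut[0]);
      if (std::isfinite(gt) && gt < g0 - 1e-14) {
        u = ut;
        if (g0 - gt < 1e-12 * (1.0 + std::fabs(g0))) { g0 = gt; conv = true; }
        else g0 = gt;
        improved = true;
        break;
      }
      t *= 0.5;
    }
    if (!improved) { conv = true; break; }  // at numerical minimum
    if (conv) break;
  }
  grad_hess(S, u, gr, H);
  double logdet = 0.0;
  bool pd = chol_logdet(H, d, L, logdet);
  // log det(H/2) = log det H - d log 2
  double logdet_half = pd ? (logdet - d * std::log(2.0)) : NA_REAL;
  double nll2 = g0 - d * LOG2PI + logdet_half;   // subject -2 log marginal L
  return List::create(_["u"] = wrap(u), _["g"] = g0,
                      _["logdet_half"] = logdet_half,
                      _["conv"] = conv && pd, _["nll2"] = nll2);
}
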