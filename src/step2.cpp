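// Step-2 marginal likelihood for the longitudinal latent-variable model.
//
// For every subject the conditional likelihood of the item responses given
// the subject-level random effects is integrated out with a per-subject
// Laplace approximation over the smooth effects (psi0, the additive effect
// on slope/r_max, log-MET).  For the step model the response-time effect
// makes the likelihood piecewise constant, so that dimension is integrated
// by Gauss-Hermite quadrature on its lognormal prior instead.
//
// The inner Newton iterations use analytic gradients and Hessians whenever
// the latent trajectory is linear in the smooth effects (linear, power and
// step models); the asymptotic/weibull trajectories, which are non-linear
// in the log-progression-time effect, fall back to finite differences.
//
// theta (natural scale, fixed length 11):
//   0 p1_drug   1 p1_placebo    (slope or r_max)
//   2 p2_drug   3 p2_placebo    (t_prog or t_r; unused for linear/power)
//   4 gamma                      (power/weibull)
//   5 v_psi0    6 v_p1   7 v_p2  (IIV variances)
//   8 met0      9 met_slope  10 v_met
// model_id: 1 linear, 2 power, 3 asymptotic, 4 weibull, 5 step

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Bank {
  std::vector<double> a;
  std::vector<std::vector<double>> b;
  std::vector<int> K;
};

struct Subj {
  std::vector<double> days;
  std::vector<std::vector<int>> Y;  // [day][item]
  int arm;                          // 0 drug, 1 placebo
};

inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// category probability plus first/second derivative wrt psi
inline void cat_prob_d(const Bank& bank, int j, double psi, int y,
                       double& p, double& dp, double& d2p) {
  const double a = bank.a[j];
  double lo = 1.0, dlo = 0.0, d2lo = 0.0;
  if (y >= 1) {
    lo = logistic(a * (psi - bank.b[j][y - 1]));
    dlo = a * lo * (1.0 - lo);
    d2lo = a * dlo * (1.0 - 2.0 * lo);
  }
  double hi = 0.0, dhi = 0.0, d2hi = 0.0;
  if (y < bank.K[j]) {
    hi = logistic(a * (psi - bank.b[j][y]));
    dhi = a * hi * (1.0 - hi);
    d2hi = a * dhi * (1.0 - 2.0 * hi);
  }
  p = lo - hi;
  if (p < 1e-300) p = 1e-300;
  dp = dlo - dhi;
  d2p = d2lo - d2hi;
}

inline double cat_prob(const Bank& bank, int j, double psi, int y) {
  double p, dp, d2p;
  cat_prob_d(bank, j, psi, y, p, dp, d2p);
  return p;
}

struct Model {
  const Bank* bank;
  int model_id;
  bool markov;
  const double* th;

  double psi_at(const Subj& s, double t, double psi0, double eta_p1,
                double eta_p2) const {
    const double p1 = th[s.arm == 0 ? 0 : 1] + eta_p1;
    switch (model_id) {
      case 1: return psi0 + p1 * t;
      case 2: return psi0 + p1 * std::pow(t, th[4]);
      case 3: {
        const double tp = th[s.arm == 0 ? 2 : 3] * std::exp(eta_p2);
        return psi0 + (p1 - psi0) * (1.0 - std::exp(-M_LN2 / tp * t));
      }
      case 4: {
        const double tp = th[s.arm == 0 ? 2 : 3] * std::exp(eta_p2);
        return psi0 + p1 * (1.0 - std::exp(-std::pow(M_LN2 / tp * t, th[4])));
      }
      default: {
        const double tr = th[s.arm == 0 ? 2 : 3] * std::exp(eta_p2);
        return (t > tr) ? psi0 + p1 : psi0;
      }
    }
  }

  // d psi / d eta_p1 for the linear-in-effects models
  double dpsi_dp1(const Subj& s, double t, double eta_p2) const {
    switch (model_id) {
      case 1: return t;
      case 2: return std::pow(t, th[4]);
      default: {  // step
        const double tr = th[s.arm == 0 ? 2 : 3] * std::exp(eta_p2);
        return (t > tr) ? 1.0 : 0.0;
      }
    }
  }

  bool linear_in_effects() const {
    return model_id == 1 || model_id == 2 || model_id == 5;
  }

  double cond_loglik(const Subj& s, double psi0, double eta_p1,
                     double eta_p2, double eta_met) const {
    const int D = (int)s.days.size();
    const int J = (int)bank->a.size();
    double ll = 0.0;
    for (int m = 0; m < D; ++m) {
      const double t = s.days[m];
      const double psi = psi_at(s, t, psi0, eta_p1, eta_p2);
      if (m == 0 || !markov) {
        for (int j = 0; j < J; ++j)
          ll += std::log(cat_prob(*bank, j, psi, s.Y[m][j]));
      } else {
        const double dt = t - s.days[m - 1];
        const double met = (th[8] + th[9] * t) * std::exp(eta_met);
        const double e = std::exp(-dt / met);
        for (int j = 0; j < J; ++j) {
          const double pi_y = cat_prob(*bank, j, psi, s.Y[m][j]);
          double p = (s.Y[m][j] == s.Y[m - 1][j]) ? e + (1.0 - e) * pi_y
                                                  : (1.0 - e) * pi_y;
          if (p < 1e-300) p = 1e-300;
          ll += std::log(p);
        }
      }
    }
    return ll;
  }
};

// penalized objective: cond loglik + normal prior terms of the *inner*
// (Laplace) effects.  eta_p2 is fixed (quadrature handles its prior)
// except when it joins the Laplace set (asymptotic/weibull, index 3).
struct Inner {
  const Model* model;
  const Subj* subj;
  double eta_p2;
  // active inner dims: indices into {0:psi0, 1:eta_p1, 2:eta_met, 3:eta_p2}
  std::vector<int> act;
  std::vector<double> var;  // prior variances matching act

  void unpack(const std::vector<double>& x, double& psi0, double& e1,
              double& em, double& e2) const {
    psi0 = 0.0; e1 = 0.0; em = 0.0; e2 = eta_p2;
    for (size_t d = 0; d < act.size(); ++d) {
      if (act[d] == 0) psi0 = x[d];
      else if (act[d] == 1) e1 = x[d];
      else if (act[d] == 2) em = x[d];
      else e2 = x[d];
    }
  }

  double eval(const std::vector<double>& x) const {
    double psi0, e1, em, e2;
    unpack(x, psi0, e1, em, e2);
    double g = model->cond_loglik(*subj, psi0, e1, e2, em);
    for (size_t d = 0; d < act.size(); ++d)
      g += -0.5 * std::log(2.0 * M_PI * var[d]) -
           0.5 * x[d] * x[d] / var[d];
    return g;
  }

  bool analytic() const {
    if (!model->linear_in_effects()) return false;
    for (size_t d = 0; d < act.size(); ++d)
      if (act[d] == 3) return false;
    return true;
  }

  // analytic value/gradient/Hessian over the active dims (requires
  // analytic() == true: psi linear in (psi0, eta_p1), plus eta_met)
  double eval_d(const std::vector<double>& x, std::vector<double>& grad,
                std::vector<double>& hess) const {
    const int d = (int)act.size();
    double psi0, e1, em, e2;
    unpack(x, psi0, e1, em, e2);
    const Subj& s = *subj;
    const Model& M = *model;
    const Bank& bank = *M.bank;
    const int D = (int)s.days.size();
    const int J = (int)bank.a.size();
    // accumulate in the canonical basis (psi0, e1, emet) = (0, 1, 2)
    double g3[3] = {0, 0, 0};
    double H3[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    double ll = 0.0;
    for (int m = 0; m < D; ++m) {
      const double t = s.days[m];
      const double psi = M.psi_at(s, t, psi0, e1, e2);
      const double v = M.dpsi_dp1(s, t, e2);  // d psi / d e1
      double e = 0.0, c = 0.0;
      const bool mk = M.markov && m > 0;
      if (mk) {
        const double dt = t - s.days[m - 1];
        const double met = (M.th[8] + M.th[9] * t) * std::exp(em);
        c = dt / met;
        e = std::exp(-c);
      }
      for (int j = 0; j < J; ++j) {
        double pi, dpi, d2pi;
        cat_prob_d(bank, j, psi, s.Y[m][j], pi, dpi, d2pi);
        double p, p_psi, p_psi2, p_eta = 0.0, p_eta2 = 0.0, p_cross = 0.0;
        if (!mk) {
          p = pi; p_psi = dpi; p_psi2 = d2pi;
        } else {
          const bool same = (s.Y[m][j] == s.Y[m - 1][j]);
          // de/dem = e*c ; d2e/dem2 = e*c*(c-1)
          const double de = e * c;
          const double d2e = e * c * (c - 1.0);
          if (same) {
            p = e + (1.0 - e) * pi;
            p_psi = (1.0 - e) * dpi;
            p_psi2 = (1.0 - e) * d2pi;
            p_eta = (1.0 - pi) * de;
            p_eta2 = (1.0 - pi) * d2e;
            p_cross = -dpi * de;
          } else {
            p = (1.0 - e) * pi;
            p_psi = (1.0 - e) * dpi;
            p_psi2 = (1.0 - e) * d2pi;
            p_eta = -pi * de;
            p_eta2 = -pi * d2e;
            p_cross = -dpi * de;
          }
        }
        if (p < 1e-300) p = 1e-300;
        ll += std::log(p);
        const double lp = p_psi / p;            // d log p / d psi
        const double lpp = p_psi2 / p - lp * lp;
        g3[0] += lp;
        g3[1] += lp * v;
        H3[0][0] += lpp;
        H3[0][1] += lpp * v;
        H3[1][1] += lpp * v * v;
        if (mk) {
          const double le = p_eta / p;
          const double lee = p_eta2 / p - le * le;
          const double lpe = p_cross / p - lp * le;
          g3[2] += le;
          H3[2][2] += lee;
          H3[0][2] += lpe;
          H3[1][2] += lpe * v;
        }
      }
    }
    // priors and mapping to the active set
    grad.assign(d, 0.0);
    hess.assign(d * d, 0.0);
    for (int i = 0; i < d; ++i) {
      grad[i] = g3[act[i]] - x[i] / var[i];
      ll += -0.5 * std::log(2.0 * M_PI * var[i]) -
            0.5 * x[i] * x[i] / var[i];
      for (int jj = 0; jj < d; ++jj) {
        const int ai = act[i] <= act[jj] ? act[i] : act[jj];
        const int aj = act[i] <= act[jj] ? act[jj] : act[i];
        hess[i * d + jj] = H3[ai][aj];
      }
      hess[i * d + i] -= 1.0 / var[i];
    }
    return ll;
  }
};

// dense symmetric solve + log-determinant via Cholesky (d <= 4)
bool chol_logdet_solve(std::vector<double>& A, int d,
                       std::vector<double>& rhs, double& logdet) {
  logdet = 0.0;
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * d + j];
      for (int k = 0; k < j; ++k) s -= A[i * d + k] * A[j * d + k];
      if (i == j) {
        if (s <= 0.0) return false;
        A[i * d + i] = std::sqrt(s);
        logdet += 2.0 * std::log(A[i * d + i]);
      } else {
        A[i * d + j] = s / A[j * d + j];
      }
    }
  }
  for (int i = 0; i < d; ++i) {
    double s = rhs[i];
    for (int k = 0; k < i; ++k) s -= A[i * d + k] * rhs[k];
    rhs[i] = s / A[i * d + i];
  }
  for (int i = d - 1; i >= 0; --i) {
    double s = rhs[i];
    for (int k = i + 1; k < d; ++k) s -= A[k * d + i] * rhs[k];
    rhs[i] = s / A[i * d + i];
  }
  return true;
}

// finite-difference gradient+Hessian of inner.eval (fallback models)
double fd_derivs(const Inner& inner, const std::vector<double>& x,
                 std::vector<double>& grad, std::vector<double>& H) {
  const int d = (int)x.size();
  const double h = 1e-4;
  const double g0 = inner.eval(x);
  grad.assign(d, 0.0);
  H.assign(d * d, 0.0);
  std::vector<double> fp(d), fm(d);
  for (int i = 0; i < d; ++i) {
    std::vector<double> xp = x, xm = x;
    xp[i] += h; xm[i] -= h;
    fp[i] = inner.eval(xp);
    fm[i] = inner.eval(xm);
    grad[i] = (fp[i] - fm[i]) / (2.0 * h);
    H[i * d + i] = (fp[i] - 2.0 * g0 + fm[i]) / (h * h);
  }
  for (int i = 0; i < d; ++i)
    for (int j = i + 1; j < d; ++j) {
      std::vector<double> xpp = x, xpm = x, xmp = x, xmm = x;
      xpp[i] += h; xpp[j] += h;
      xpm[i] += h; xpm[j] -= h;
      xmp[i] -= h; xmp[j] += h;
      xmm[i] -= h; xmm[j] -= h;
      const double v = (inner.eval(xpp) - inner.eval(xpm) -
                        inner.eval(xmp) + inner.eval(xmm)) /
                       (4.0 * h * h);
      H[i * d + j] = H[j * d + i] = v;
    }
  return g0;
}

// Laplace-approximated log integral over the active inner effects.
// The Newton mode search runs to a tight, start-independent tolerance so
// the result does not depend on the warm start.
double laplace_marginal(const Inner& inner, std::vector<double>& mode) {
  const int d = (int)inner.act.size();
  if (d == 0) return inner.eval(mode);
  const bool analytic = inner.analytic();
  std::vector<double> x = mode, grad, H;
  double g0 = analytic ? inner.eval_d(x, grad, H)
                       : fd_derivs(inner, x, grad, H);
  for (int iter = 0; iter < 100; ++iter) {
    double gmax = 0.0;
    for (int i = 0; i < d; ++i) gmax = std::max(gmax, std::fabs(grad[i]));
    if (gmax < 1e-8) break;
    double ridge = 0.0;
    std::vector<double> step;
    double logdet;
    for (int attempt = 0; attempt < 10; ++attempt) {
      std::vector<double> A(d * d);
      for (int i = 0; i < d * d; ++i) A[i] = -H[i];
      for (int i = 0; i < d; ++i) A[i * d + i] += ridge;
      step = grad;
      if (chol_logdet_solve(A, d, step, logdet)) break;
      ridge = (ridge == 0.0) ? 1e-4 : ridge * 10.0;
      step.clear();
    }
    if (step.empty()) break;
    double alpha = 1.0;
    bool moved = false;
    for (int ls = 0; ls < 20; ++ls) {
      std::vector<double> xn = x;
      for (int i = 0; i < d; ++i) xn[i] += alpha * step[i];
      const double gn = inner.eval(xn);
      if (gn >= g0 - 1e-13) {
        x = xn;
        moved = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!moved) break;
    g0 = analytic ? inner.eval_d(x, grad, H)
                  : fd_derivs(inner, x, grad, H);
  }
  // curvature at the mode (H already holds the Hessian at x)
  double logdet = 0.0;
  double ridge = 0.0;
  for (int attempt = 0; attempt < 12; ++attempt) {
    std::vector<double> A(d * d);
    for (int i = 0; i < d * d; ++i) A[i] = -H[i];
    for (int i = 0; i < d; ++i) A[i * d + i] += ridge;
    std::vector<double> r0(d, 0.0);
    if (chol_logdet_solve(A, d, r0, logdet)) break;
    ridge = (ridge == 0.0) ? 1e-6 : ridge * 10.0;
  }
  mode = x;
  return g0 + 0.5 * d * std::log(2.0 * M_PI) - 0.5 * logdet;
}

}  // namespace

// [[Rcpp::export]]
List cpp_step2_loglik(NumericVector theta, List subjects, List bank_list,
                      int model_id, bool markov, NumericVector q_nodes,
                      NumericVector q_weights,
                      Nullable<NumericMatrix> warm_modes) {
  Bank bank;
  NumericVector a = bank_list["a"];
  NumericMatrix b = bank_list["b"];
  IntegerVector K = bank_list["K"];
  const int J = a.size();
  bank.a.assign(a.begin(), a.end());
  bank.K.assign(K.begin(), K.end());
  bank.b.resize(J);
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < K[j]; ++k) bank.b[j].push_back(b(j, k));

  const int n = subjects.size();
  std::vector<Subj> subj(n);
  for (int i = 0; i < n; ++i) {
    List si = subjects[i];
    NumericVector days = si["days"];
    IntegerMatrix Y = si["Y"];
    subj[i].days.assign(days.begin(), days.end());
    subj[i].arm = as<int>(si["arm"]);
    subj[i].Y.resize(Y.nrow(), std::vector<int>(J));
    for (int m = 0; m < Y.nrow(); ++m)
      for (int j = 0; j < J; ++j) subj[i].Y[m][j] = Y(m, j);
  }

  Model model;
  model.bank = &bank;
  model.model_id = model_id;
  model.markov = markov;
  model.th = theta.begin();

  const double v_psi0 = theta[5], v_p1 = theta[6], v_p2 = theta[7];
  const double v_met = theta[10];
  const bool has_p2 = (model_id >= 3);
  const bool step_quad = (model_id == 5) && v_p2 > 0.0;

  std::vector<int> act;
  std::vector<double> var;
  if (v_psi0 > 0.0) { act.push_back(0); var.push_back(v_psi0); }
  if (v_p1 > 0.0) { act.push_back(1); var.push_back(v_p1); }
  if (markov && v_met > 0.0) { act.push_back(2); var.push_back(v_met); }
  const bool p2_laplace = has_p2 && model_id != 5 && v_p2 > 0.0;
  const int d_inner = (int)act.size() + (p2_laplace ? 1 : 0);

  const int nq = step_quad ? q_nodes.size() : 1;
  NumericMatrix modes(n, std::max(1, nq * std::max(1, d_inner)));
  bool have_warm = warm_modes.isNotNull();
  NumericMatrix warm;
  if (have_warm) {
    warm = NumericMatrix(warm_modes);
    if (warm.nrow() != n || warm.ncol() != modes.ncol()) have_warm = false;
  }

  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double li;
    if (!step_quad) {
      Inner inner;
      inner.model = &model;
      inner.subj = &subj[i];
      inner.eta_p2 = 0.0;
      inner.act = act;
      inner.var = var;
      if (p2_laplace) {
        inner.act.push_back(3);
        inner.var.push_back(v_p2);
      }
      std::vector<double> mode(inner.act.size(), 0.0);
      if (have_warm)
        for (size_t d = 0; d < mode.size(); ++d) mode[d] = warm(i, d);
      li = inner.act.empty() ? inner.eval(mode)
                             : laplace_marginal(inner, mode);
      for (size_t d = 0; d < mode.size(); ++d) modes(i, d) = mode[d];
    } else {
      std::vector<double> vals(nq);
      double vmax = -1e300;
      for (int q = 0; q < nq; ++q) {
        Inner inner;
        inner.model = &model;
        inner.subj = &subj[i];
        inner.eta_p2 = std::sqrt(v_p2) * q_nodes[q];
        inner.act = act;
        inner.var = var;
        std::vector<double> mode(act.size(), 0.0);
        if (have_warm)
          for (size_t d = 0; d < mode.size(); ++d)
            mode[d] = warm(i, q * act.size() + d);
        double lv = act.empty() ? inner.eval(mode)
                                : laplace_marginal(inner, mode);
        vals[q] = std::log(q_weights[q]) + lv;
        if (vals[q] > vmax) vmax = vals[q];
        for (size_t d = 0; d < mode.size(); ++d)
          modes(i, q * act.size() + d) = mode[d];
      }
      double s = 0.0;
      for (int q = 0; q < nq; ++q) s += std::exp(vals[q] - vmax);
      li = vmax + std::log(s);
    }
    total += li;
  }

  return List::create(_["loglik"] = total, _["modes"] = modes);
}
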