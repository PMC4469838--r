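#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Cox partial-likelihood machinery.
//
// Patients are pre-sorted by increasing survival time on the R side.
//   grp[i]  : 0-based first index of the tie group containing position i
//   gend[i] : 0-based last index of that tie group
// Under the Breslow convention the risk set of an event at position i is
// positions grp[i] .. n-1 (everyone with t_r >= t_i).

namespace {

inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

struct Work {
  int n;
  std::vector<double> expeta;  // exp(eta - max(eta)), centring cancels in all ratios
  std::vector<double> suf;     // suffix sums of expeta, length n+1
  std::vector<double> d;       // score residuals: delta_r - exp(eta_r) * H(t_r)
  std::vector<double> w;       // diagonal Hessian weights (IRLS)
  explicit Work(int n_) : n(n_), expeta(n_), suf(n_ + 1), d(n_), w(n_) {}
};

// Fills expeta/suf/d/w at eta; returns the log partial likelihood.
double fill_residuals(const std::vector<double>& eta,
                      const int* delta, const int* grp,
                      Work& wk) {
  const int n = wk.n;
  double mx = eta[0];
  for (int i = 1; i < n; ++i) if (eta[i] > mx) mx = eta[i];
  for (int i = 0; i < n; ++i) wk.expeta[i] = std::exp(eta[i] - mx);
  wk.suf[n] = 0.0;
  for (int i = n - 1; i >= 0; --i) wk.suf[i] = wk.suf[i + 1] + wk.expeta[i];

  double ll = 0.0, hrun = 0.0, grun = 0.0;
  int i = 0;
  while (i < n) {
    int a = grp[i];
    int b = a;
    while (b + 1 < n && grp[b + 1] == a) ++b;   // end of the tie group
    double S = wk.suf[a];
    int nev = 0;
    for (int r = a; r <= b; ++r)
      if (delta[r]) { ++nev; ll += eta[r] - (std::log(S) + mx); }
    if (nev) { hrun += nev / S; grun += nev / (S * S); }
    for (int r = a; r <= b; ++r) {
      double e = wk.expeta[r];
      wk.d[r] = (delta[r] ? 1.0 : 0.0) - e * hrun;
      double wr = e * hrun - e * e * grun;
      wk.w[r] = (wr > 0.0) ? wr : 0.0;
    }
    i = b + 1;
  }
  return ll;
}

// Log partial likelihood only (no residuals), for line searches.
double loglik_only(const std::vector<double>& eta, const int* delta,
                   const int* grp, int n) {
  double mx = eta[0];
  for (int i = 1; i < n; ++i) if (eta[i] > mx) mx = eta[i];
  std::vector<double> suf(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) suf[i] = suf[i + 1] + std::exp(eta[i] - mx);
  double ll = 0.0;
  for (int i = 0; i < n; ++i)
    if (delta[i]) ll += eta[i] - (std::log(suf[grp[i]]) + mx);
  return ll;
}

// Hessian of -l restricted to the active coordinates (m x m, column-major,
// full symmetric fill).
void active_hessian(const NumericMatrix& X, const std::vector<int>& active,
                    const int* delta, const int* grp, const Work& wk,
                    std::vector<double>& H) {
  const int n = wk.n, m = (int)active.size();
  H.assign((size_t)m * m, 0.0);
  std::vector<double> sx(m, 0.0), sxx((size_t)m * m, 0.0), xr(m);
  int i = n - 1;
  while (i >= 0) {
    int a = grp[i];
    for (int r = i; r >= a; --r) {
      double e = wk.expeta[r];
      for (int u = 0; u < m; ++u) xr[u] = X(r, active[u]);
      for (int u = 0; u < m; ++u) {
        double xe = xr[u] * e;
        sx[u] += xe;
        double* col = &sxx[(size_t)u * m];
        for (int v = u; v < m; ++v) col[v] += xe * xr[v];
      }
    }
    int nev = 0;
    for (int r = a; r <= i; ++r) if (delta[r]) ++nev;
    if (nev) {
      double S = wk.suf[a];
      for (int u = 0; u < m; ++u) {
        double su = sx[u] / S;
        const double* col = &sxx[(size_t)u * m];
        for (int v = u; v < m; ++v) {
          double huv = nev * (col[v] / S - su * (sx[v] / S));
          H[(size_t)u * m + v] += huv;
        }
      }
    }
    i = a - 1;
  }
  for (int u = 0; u < m; ++u)
    for (int v = 0; v < u; ++v)
      H[(size_t)u * m + v] = H[(size_t)v * m + u];
}

// In-place Cholesky; returns false if not positive definite.
bool cholesky(std::vector<double>& A, int m) {
  for (int j = 0; j < m; ++j) {
    double d = A[(size_t)j * m + j];
    for (int q = 0; q < j; ++q) {
      double v = A[(size_t)q * m + j];
      d -= v * v;
    }
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    A[(size_t)j * m + j] = d;
    for (int i = j + 1; i < m; ++i) {
      double s = A[(size_t)j * m + i];
      for (int q = 0; q < j; ++q)
        s -= A[(size_t)q * m + i] * A[(size_t)q * m + j];
      A[(size_t)j * m + i] = s / d;
    }
  }
  return true;
}

// Solves A x = b given the Cholesky factor stored as produced above
// (factor in the upper triangle addressed as A[col*m + row] with row>=col).
void chol_solve(const std::vector<double>& L, int m, std::vector<double>& b) {
  for (int i = 0; i < m; ++i) {
    double s = b[i];
    for (int q = 0; q < i; ++q) s -= L[(size_t)q * m + i] * b[q];
    b[i] = s / L[(size_t)i * m + i];
  }
  for (int i = m - 1; i >= 0; --i) {
    double s = b[i];
    for (int q = i + 1; q < m; ++q) s -= L[(size_t)i * m + q] * b[q];
    b[i] = s / L[(size_t)i * m + i];
  }
}

} // namespace

// Log partial likelihood and its gradient at beta.
// [[Rcpp::export]]
List cox_stats_cpp(NumericMatrix X, IntegerVector delta, IntegerVector grp,
                   NumericVector beta) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> eta(n, 0.0);
  for (int j = 0; j < p; ++j) {
    double b = beta[j];
    if (b != 0.0) {
      const double* xj = &X(0, j);
      for (int r = 0; r < n; ++r) eta[r] += b * xj[r];
    }
  }
  Work wk(n);
  double ll = fill_residuals(eta, &delta[0], &grp[0], wk);
  NumericVector g(p);
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double s = 0.0;
    for (int r = 0; r < n; ++r) s += xj[r] * wk.d[r];
    g[j] = s;
  }
  return List::create(_["loglik"] = ll, _["gradient"] = g);
}

// L1-penalized Cox fit at a single lambda: maximizes l(beta) - lam * ||beta||_1
// by proximal-Newton (IRLS) with coordinate descent on the local quadratic
// model, warm-started from beta_init.  Exits only when the KKT system holds:
//   |dl/dbeta_j| <= lam + kkt_tol            for beta_j = 0
//   |dl/dbeta_j - lam * sign(beta_j)| <= kkt_tol  for beta_j != 0
// [[Rcpp::export]]
List cox_cd_solve(NumericMatrix X, IntegerVector delta, IntegerVector grp,
                  double lam, NumericVector beta_init,
                  double kkt_tol, int max_outer, int max_cycles) {
  const int n = X.nrow(), p = X.ncol();
  const int* del = &delta[0];
  const int* gr = &grp[0];

  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> eta(n, 0.0);
  std::vector<int> active;
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      active.push_back(j);
      const double* xj = &X(0, j);
      for (int r = 0; r < n; ++r) eta[r] += beta[j] * xj[r];
    }
  }

  Work wk(n);
  double ll = fill_residuals(eta, del, gr, wk);
  const double inner_tol = std::max(kkt_tol * 1e-3, 1e-12);

  std::vector<double> z(n), hdiag;
  std::vector<double> beta_old, eta_old;
  int cycles = 0;
  bool converged = false;
  double kkt_zero = 0.0, kkt_act = 0.0;

  for (int outer = 0; outer < max_outer && !converged; ++outer) {
    // --- one IRLS round: quadratic model at current eta ---
    beta_old = beta;
    eta_old = eta;
    double ll_old = ll;
    double pen_old = 0.0;
    for (size_t a = 0; a < active.size(); ++a) pen_old += std::fabs(beta[active[a]]);

    for (int r = 0; r < n; ++r) z[r] = wk.d[r];     // working residual
    hdiag.assign(active.size(), -1.0);              // lazy per-coordinate curvature

    for (int it = 0; it < max_cycles; ++it) {
      double maxdel = 0.0;
      for (size_t a = 0; a < active.size(); ++a) {
        int j = active[a];
        const double* xj = &X(0, j);
        if (hdiag[a] < 0.0) {
          double h = 0.0;
          for (int r = 0; r < n; ++r) h += wk.w[r] * xj[r] * xj[r];
          hdiag[a] = h;
        }
        double h = hdiag[a];
        if (h < 1e-12) continue;
        double g = 0.0;
        for (int r = 0; r < n; ++r) g += xj[r] * z[r];
        double nb = soft(beta[j] + g / h, lam / h);
        double dstep = nb - beta[j];
        if (dstep > 2.0) dstep = 2.0; else if (dstep < -2.0) dstep = -2.0;
        if (dstep != 0.0) {
          beta[j] += dstep;
          for (int r = 0; r < n; ++r) {
            eta[r] += dstep * xj[r];
            z[r] -= dstep * wk.w[r] * xj[r];
          }
          double ad = std::fabs(dstep);
          if (ad > maxdel) maxdel = ad;
        }
      }
      ++cycles;
      if (maxdel < inner_tol) break;
    }

    // --- exact objective with step halving if the Newton step overshot ---
    ll = fill_residuals(eta, del, gr, wk);
    double pen_new = 0.0;
    for (size_t a = 0; a < active.size(); ++a) pen_new += std::fabs(beta[active[a]]);
    int halves = 0;
    while (ll - lam * pen_new < ll_old - lam * pen_old - 1e-12 && halves < 20) {
      for (size_t a = 0; a < active.size(); ++a) {
        int j = active[a];
        beta[j] = 0.5 * (beta[j] + beta_old[j]);
      }
      for (int r = 0; r < n; ++r) eta[r] = 0.5 * (eta[r] + eta_old[r]);
      ll = fill_residuals(eta, del, gr, wk);
      pen_new = 0.0;
      for (size_t a = 0; a < active.size(); ++a) pen_new += std::fabs(beta[active[a]]);
      ++halves;
    }

    // prune exact zeros from the active set
    std::vector<int> act2;
    for (size_t a = 0; a < active.size(); ++a)
      if (beta[active[a]] != 0.0) act2.push_back(active[a]);
    active.swap(act2);

    // --- Newton polish on the active set: coordinate descent slows down
    // when the active set grows towards n, so finish with full Newton
    // steps (ridge-guarded Cholesky, sign-preserving line search) ---
    for (int np = 0; np < 8 && !active.empty(); ++np) {
      int m = (int)active.size();
      std::vector<double> gpen(m);
      double resid = 0.0;
      for (int u = 0; u < m; ++u) {
        int j = active[u];
        const double* xj = &X(0, j);
        double s = 0.0;
        for (int r = 0; r < n; ++r) s += xj[r] * wk.d[r];
        gpen[u] = s - lam * (beta[j] > 0.0 ? 1.0 : -1.0);
        resid = std::max(resid, std::fabs(gpen[u]));
      }
      if (resid <= 0.5 * kkt_tol) break;
      std::vector<double> H;
      active_hessian(X, active, del, gr, wk, H);
      double tr = 0.0;
      for (int u = 0; u < m; ++u) tr += H[(size_t)u * m + u];
      double ridge = 1e-9 * (tr / m + 1.0);
      std::vector<double> Hf;
      bool ok = false;
      for (int attempt = 0; attempt < 6 && !ok; ++attempt) {
        Hf = H;
        for (int u = 0; u < m; ++u) Hf[(size_t)u * m + u] += ridge;
        ok = cholesky(Hf, m);
        if (!ok) ridge *= 100.0;
      }
      if (!ok) break;
      std::vector<double> dir(gpen);
      chol_solve(Hf, m, dir);
      // largest step not crossing zero
      double tmax = 1.0;
      for (int u = 0; u < m; ++u) {
        int j = active[u];
        if (beta[j] * dir[u] < 0.0 && std::fabs(dir[u]) > 0.0) {
          double tc = -beta[j] / dir[u];
          if (tc < tmax) tmax = tc;
        }
      }
      double pen_cur = 0.0;
      for (int u = 0; u < m; ++u) pen_cur += std::fabs(beta[active[u]]);
      double obj_cur = ll - lam * pen_cur;
      std::vector<double> eta_c(n);
      double t = tmax;
      bool accepted = false;
      for (int ls = 0; ls < 15; ++ls) {
        for (int r = 0; r < n; ++r) eta_c[r] = eta[r];
        double pen_c = 0.0;
        for (int u = 0; u < m; ++u) {
          int j = active[u];
          double bc = beta[j] + t * dir[u];
          if (std::fabs(bc) < 1e-14) bc = 0.0;
          const double* xj = &X(0, j);
          double db = bc - beta[j];
          if (db != 0.0)
            for (int r = 0; r < n; ++r) eta_c[r] += db * xj[r];
          pen_c += std::fabs(bc);
        }
        double ll_c = loglik_only(eta_c, del, gr, n);
        if (ll_c - lam * pen_c > obj_cur + 1e-13) {
          for (int u = 0; u < m; ++u) {
            int j = active[u];
            double bc = beta[j] + t * dir[u];
            if (std::fabs(bc) < 1e-14) bc = 0.0;
            beta[j] = bc;
          }
          eta.swap(eta_c);
          ll = fill_residuals(eta, del, gr, wk);
          accepted = true;
          break;
        }
        t *= 0.5;
      }
      if (!accepted) break;
      // drop coefficients driven exactly to zero
      act2.clear();
      for (size_t a = 0; a < active.size(); ++a)
        if (beta[active[a]] != 0.0) act2.push_back(active[a]);
      active.swap(act2);
    }

    // --- exact KKT sweep over all coordinates ---
    kkt_zero = 0.0; kkt_act = 0.0;
    std::vector<int> viol;
    for (int j = 0; j < p; ++j) {
      const double* xj = &X(0, j);
      double s = 0.0;
      for (int r = 0; r < n; ++r) s += xj[r] * wk.d[r];
      if (beta[j] == 0.0) {
        double v = std::fabs(s) - lam;
        if (v > kkt_zero) kkt_zero = v;
        if (v > kkt_tol) viol.push_back(j);
      } else {
        double v = std::fabs(s - lam * (beta[j] > 0.0 ? 1.0 : -1.0));
        if (v > kkt_act) kkt_act = v;
      }
    }
    if (viol.empty() && kkt_act <= kkt_tol) { converged = true; break; }
    for (size_t q = 0; q < viol.size(); ++q) active.push_back(viol[q]);
    std::sort(active.begin(), active.end());
    active.erase(std::unique(active.begin(), active.end()), active.end());
  }

  NumericVector bout(p);
  IntegerVector aout(active.size());
  for (int j = 0; j < p; ++j) bout[j] = beta[j];
  for (size_t a = 0; a < active.size(); ++a) aout[a] = active[a] + 1;  // 1-based
  return List::create(_["beta"] = bout, _["active"] = aout,
                      _["m"] = (int)active.size(), _["loglik"] = ll,
                      _["cycles"] = cycles, _["converged"] = converged,
                      _["kkt_zero"] = std::max(kkt_zero, 0.0),
                      _["kkt_active"] = kkt_act);
}

// EM for the Laplace(0, b) + sum_c Normal(mu_c, sigma_c^2) mixture on the
// nonzero lasso estimates.  Component weights wts = (pi_0, pi_1, ..., pi_C)
// are fixed when update_props = false (the tracking hypotheses) and updated
// by EM otherwise.  init = (b, mu_1..mu_C, sigma_1..sigma_C).
// [[Rcpp::export]]
List mix_em_cpp(NumericVector x, NumericVector wts, bool update_props,
                NumericVector init, double mu_floor, double mu_scale_mult,
                double sigma_floor, double scale_floor, double tol,
                int maxit) {
  const int m = x.size();
  const int C = wts.size() - 1;
  std::vector<double> pr(wts.begin(), wts.end());
  double b = std::max(init[0], scale_floor);
  // The true-positive means are nonzero by assumption; enforce separation
  // from the false-positive component: |mu_c| >= mu_scale_mult * b.
  double mfloor = std::max(mu_floor, mu_scale_mult * b);
  std::vector<double> mu(C), sg(C);
  for (int c = 0; c < C; ++c) {
    mu[c] = init[1 + c];
    if (std::fabs(mu[c]) < mfloor) mu[c] = (mu[c] >= 0.0 ? mfloor : -mfloor);
    sg[c] = std::max(init[1 + C + c], sigma_floor);
  }

  const double LOG2PI = 1.8378770664093453;
  std::vector<double> ld(C + 1), resp(C + 1);
  double ll = -1e300, ll_prev = -1e300;
  double best_ll = -1e300, best_b = b;
  std::vector<double> best_mu(mu), best_sg(sg), best_pr(pr);
  int it = 0;
  bool converged = false;

  for (it = 0; it < maxit; ++it) {
    double r0 = 0.0, r0ax = 0.0;
    std::vector<double> rc(C, 0.0), rcx(C, 0.0), rcx2(C, 0.0);
    ll = 0.0;
    for (int i = 0; i < m; ++i) {
      double xi = x[i];
      double mxl = -1e300;
      ld[0] = (pr[0] > 0.0)
        ? std::log(pr[0]) - std::log(2.0 * b) - std::fabs(xi) / b
        : -1e300;
      if (ld[0] > mxl) mxl = ld[0];
      for (int c = 0; c < C; ++c) {
        double dlt = (xi - mu[c]) / sg[c];
        ld[1 + c] = (pr[1 + c] > 0.0)
          ? std::log(pr[1 + c]) - 0.5 * LOG2PI - std::log(sg[c]) - 0.5 * dlt * dlt
          : -1e300;
        if (ld[1 + c] > mxl) mxl = ld[1 + c];
      }
      double se = 0.0;
      for (int c = 0; c <= C; ++c) se += std::exp(ld[c] - mxl);
      double lse = mxl + std::log(se);
      ll += lse;
      for (int c = 0; c <= C; ++c) resp[c] = std::exp(ld[c] - lse);
      r0 += resp[0]; r0ax += resp[0] * std::fabs(xi);
      for (int c = 0; c < C; ++c) {
        rc[c] += resp[1 + c];
        rcx[c] += resp[1 + c] * xi;
        rcx2[c] += resp[1 + c] * xi * xi;
      }
    }
    if (ll > best_ll) {
      best_ll = ll; best_b = b; best_mu = mu; best_sg = sg; best_pr = pr;
    }
    if (it > 0 && std::fabs(ll - ll_prev) < tol * (std::fabs(ll_prev) + 1.0)) {
      converged = true; break;
    }
    ll_prev = ll;
    // M-step
    if (r0 > 1e-12) b = std::max(r0ax / r0, scale_floor);
    mfloor = std::max(mu_floor, mu_scale_mult * b);
    for (int c = 0; c < C; ++c) {
      if (rc[c] > 1e-12) {
        double mc = rcx[c] / rc[c];
        if (std::fabs(mc) < mfloor) mc = (mc >= 0.0 ? mfloor : -mfloor);
        double s2 = rcx2[c] / rc[c] - 2.0 * mc * (rcx[c] / rc[c]) + mc * mc;
        mu[c] = mc;
        sg[c] = std::max(std::sqrt(std::max(s2, 0.0)), sigma_floor);
      }
    }
    if (update_props) {
      pr[0] = r0 / m;
      for (int c = 0; c < C; ++c) pr[1 + c] = rc[c] / m;
    }
  }

  return List::create(_["loglik"] = best_ll, _["b"] = best_b,
                      _["mu"] = NumericVector(best_mu.begin(), best_mu.end()),
                      _["sigma"] = NumericVector(best_sg.begin(), best_sg.end()),
                      _["props"] = NumericVector(best_pr.begin(), best_pr.end()),
                      _["iterations"] = it + 1, _["converged"] = converged);
}
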