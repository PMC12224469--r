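// Sliding-window local maximum-likelihood fitter for the inverse-Gaussian
// point-process heart-rate model.  Mirrors the reference R implementation
// (pp_newton_solve and friends); the R path remains the oracle in tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

// log survival of the inverse-Gaussian at elapsed time q
static double ig_log_surv(double q, double mu, double xi0) {
  if (mu <= 0.0 || xi0 <= 0.0 || q <= 0.0) return R_NegInf;
  double s = std::sqrt(xi0 / q);
  double z1 = s * (q / mu - 1.0);
  double z2 = s * (q / mu + 1.0);
  double t1 = R::pnorm(-z1, 0.0, 1.0, 1, 1);
  double t2 = 2.0 * xi0 / mu + R::pnorm(-z2, 0.0, 1.0, 1, 1);
  double d = t2 - t1;
  if (d > -1e-16) d = -1e-16;
  return t1 + std::log1p(-std::exp(d));
}

// local log-likelihood: weighted interval terms + optional censoring
static double objective(const arma::vec& theta, const arma::mat& X,
                        const arma::vec& w, const arma::vec& wt,
                        bool cens, const arma::rowvec& x_c, double tau) {
  const arma::uword p = X.n_cols;
  arma::vec g = theta.subvec(0, p - 1);
  double eta = theta(p);
  double xi0 = std::exp(eta);
  arma::vec mu = X * g;
  if (mu.min() <= 0.0) return R_NegInf;
  arma::vec e = w - mu;
  double ll = arma::dot(wt, 0.5 * (eta - LOG2PI - 3.0 * arma::log(w)) -
                        0.5 * xi0 * arma::square(e) / (arma::square(mu) % w));
  if (cens) {
    double mu_c = arma::dot(x_c, g);
    if (mu_c <= 0.0) return R_NegInf;
    ll += ig_log_surv(tau, mu_c, xi0);
  }
  return ll;
}

struct GradHess {
  arma::vec grad;
  arma::mat H;
  bool ok;
};

// analytic gradient/Hessian of the interval part; censoring enters the
// gradient via numeric central differences in (mu_c, eta)
static GradHess grad_hess(const arma::vec& theta, const arma::mat& X,
                          const arma::vec& w, const arma::vec& wt,
                          bool cens, const arma::rowvec& x_c, double tau) {
  GradHess out; out.ok = false;
  const arma::uword p = X.n_cols;
  arma::vec g = theta.subvec(0, p - 1);
  double eta = theta(p);
  double xi0 = std::exp(eta);
  arma::vec mu = X * g;
  if (mu.min() <= 0.0) return out;
  arma::vec e = w - mu;
  arma::vec mu2 = arma::square(mu);
  arma::vec mu3 = mu2 % mu;
  arma::vec A = arma::square(e) / (mu2 % w);
  arma::vec dmu = wt % (xi0 * e / mu3);
  arma::vec d2mu = wt % (xi0 * (2.0 * mu - 3.0 * w) / (mu3 % mu));
  arma::vec deta = wt % (0.5 - 0.5 * xi0 * A);
  double d2eta = arma::sum(wt % (-0.5 * xi0 * A));
  out.grad = arma::vec(p + 1);
  out.grad.subvec(0, p - 1) = X.t() * dmu;
  out.grad(p) = arma::sum(deta);
  out.H = arma::mat(p + 1, p + 1);
  out.H.submat(0, 0, p - 1, p - 1) = X.t() * (X.each_col() % d2mu);
  arma::vec Hge = X.t() * dmu;          // cross term equals dmu weights
  out.H.submat(0, p, p - 1, p) = Hge;
  out.H.submat(p, 0, p, p - 1) = Hge.t();
  out.H(p, p) = d2eta;
  if (cens) {
    double mu_c = arma::dot(x_c, g);
    if (mu_c <= 0.0) return out;
    double hm = 1e-6 * std::max(1.0, std::fabs(mu_c));
    double he = 1e-6 * std::max(1.0, std::fabs(eta));
    double dm = (ig_log_surv(tau, mu_c + hm, xi0) -
                 ig_log_surv(tau, mu_c - hm, xi0)) / (2.0 * hm);
    double de = (ig_log_surv(tau, mu_c, std::exp(eta + he)) -
                 ig_log_surv(tau, mu_c, std::exp(eta - he))) / (2.0 * he);
    out.grad.subvec(0, p - 1) += dm * x_c.t();
    out.grad(p) += de;
  }
  out.ok = true;
  return out;
}

// Newton ascent direction with ridge escalation, gradient fallback
static arma::vec newton_direction(const arma::mat& H, const arma::vec& grad) {
  arma::mat nH = -H;
  double sc = arma::mean(arma::abs(nH.diag())) + 1e-12;
  const double ridges[4] = {0.0, 1e-10, 1e-6, 1e-2};
  for (int i = 0; i < 4; ++i) {
    arma::mat cf;
    if (arma::chol(cf, nH + ridges[i] * sc * arma::eye(nH.n_rows, nH.n_cols))) {
      return arma::solve(arma::trimatu(cf),
                         arma::solve(arma::trimatl(cf.t()), grad));
    }
  }
  return grad / (sc + arma::norm(grad));
}

// [[Rcpp::export(name = ".pp_fit_cpp")]]
List pp_fit_cpp(NumericVector times_r, NumericVector u_r, NumericVector hp_r,
                NumericMatrix des_r, int kmin, double W, bool censor,
                double forgetting, int max_iter, double grad_tol,
                NumericVector theta0_r) {
  arma::vec times(times_r.begin(), times_r.size(), false);
  arma::vec u(u_r.begin(), u_r.size(), false);
  arma::vec hp(hp_r.begin(), hp_r.size(), false);
  arma::mat des(des_r.begin(), des_r.nrow(), des_r.ncol(), false);
  const int nT = times.n_elem;
  const int K = u.n_elem;
  const int p = des.n_cols;             // g0 + g1 block

  arma::mat G(nT, p, arma::fill::value(NA_REAL));
  arma::vec eta_out(nT, arma::fill::value(NA_REAL));
  arma::vec ll_out(nT, arma::fill::value(NA_REAL));
  arma::vec mu_out(nT, arma::fill::value(NA_REAL));
  arma::ivec conv(nT, arma::fill::zeros);
  arma::ivec nb(nT, arma::fill::zeros);
  arma::mat accA(p + 1, p + 1, arma::fill::zeros);
  arma::vec accb(p + 1, arma::fill::zeros);

  arma::vec theta;
  bool have_theta = theta0_r.size() == p + 1;
  if (have_theta) theta = arma::vec(theta0_r.begin(), p + 1);

  int k_lo = kmin, k_hi = kmin - 1;     // 1-based interval indices
  for (int it = 0; it < nT; ++it) {
    double t = times(it);
    while (k_hi + 1 <= K && u(k_hi) <= t) ++k_hi;           // u(k_hi) is u_{k_hi+1}
    while (k_lo <= k_hi && u(k_lo - 2) < t - W) ++k_lo;
    if (k_lo < kmin) k_lo = kmin;
    int n_int = k_hi - k_lo + 1;
    nb(it) = n_int;
    if (n_int < 2) continue;

    arma::mat X = des.rows(k_lo - 1, k_hi - 1);
    arma::vec w = hp.subvec(k_lo - 1, k_hi - 1);
    arma::vec wt(n_int, arma::fill::ones);
    if (forgetting > 0)
      wt = arma::exp(-forgetting * (t - u.subvec(k_lo - 1, k_hi - 1)));
    int kc = k_hi + 1;
    bool cens = censor && kc <= K + 1 && kc >= kmin && t > u(k_hi - 1);
    arma::rowvec x_c;
    double tau = NA_REAL;
    if (cens) { x_c = des.row(kc - 1); tau = t - u(k_hi - 1); }
    arma::rowvec x_next = des.row(std::min(kc, K + 1) - 1);

    if (!have_theta) {
      double mw = arma::mean(w);
      double vw = arma::var(w);
      theta = arma::vec(p + 1, arma::fill::zeros);
      theta(0) = mw;
      theta(p) = std::log(mw * mw * mw / std::max(vw, 1e-8));
      have_theta = true;
    }

    double ll = objective(theta, X, w, wt, cens, x_c, tau);
    if (!std::isfinite(ll)) {
      double mw = arma::mean(w);
      double vw = arma::var(w);
      theta.zeros();
      theta(0) = mw;
      theta(p) = std::log(mw * mw * mw / std::max(vw, 1e-8));
      ll = objective(theta, X, w, wt, cens, x_c, tau);
    }
    bool converged = false;
    arma::mat H_last;
    bool have_H = false;
    for (int iter = 0; iter < max_iter; ++iter) {
      GradHess gh = grad_hess(theta, X, w, wt, cens, x_c, tau);
      if (!gh.ok) break;
      H_last = gh.H; have_H = true;
      if (arma::norm(gh.grad) < grad_tol) { converged = true; break; }
      arma::vec dir = newton_direction(gh.H, gh.grad);
      if (arma::norm(dir) < 1e-7 * (1.0 + arma::norm(theta))) {
        // step below the objective's resolution: take it outright and let
        // the gradient test decide (any ll change is sub-roundoff)
        arma::vec cand = theta + dir;
        double llc = objective(cand, X, w, wt, cens, x_c, tau);
        if (std::isfinite(llc)) { theta = cand; if (llc > ll) ll = llc; }
        continue;
      }
      double tstep = 1.0;
      bool accepted = false;
      for (int bt = 0; bt < 40; ++bt) {
        arma::vec cand = theta + tstep * dir;
        double llc = objective(cand, X, w, wt, cens, x_c, tau);
        if (std::isfinite(llc) && llc > ll) {
          double gain = llc - ll;
          theta = cand; ll = llc; accepted = true;
          if (gain < 1e-13 * (1.0 + std::fabs(ll))) {
            GradHess gh2 = grad_hess(theta, X, w, wt, cens, x_c, tau);
            if (gh2.ok) {
              H_last = gh2.H; have_H = true;
              converged = arma::norm(gh2.grad) < grad_tol;
            }
            accepted = false;          // stop iterating
          }
          break;
        }
        tstep *= 0.5;
      }
      if (!accepted) break;
    }
    G.row(it) = theta.subvec(0, p - 1).t();
    eta_out(it) = theta(p);
    ll_out(it) = ll;
    conv(it) = converged ? 1 : 0;
    mu_out(it) = arma::dot(x_next, theta.subvec(0, p - 1));
    if (converged && have_H) {
      accA += -H_last;
      accb += (-H_last) * theta;
    }
  }
  return List::create(_["G"] = G, _["eta"] = eta_out, _["loglik"] = ll_out,
                      _["mu_hp"] = mu_out, _["converged"] = conv,
                      _["n_beats"] = nb, _["accA"] = accA, _["accb"] = accb);
}
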