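#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One-random-factor LMM  y = X beta + Z u + e,  u ~ N(0, s2u I),  e ~ N(0, s2e I).
// All routines work on the rotated scale: with ZZ' = Q D Q' (eigen), set
// ytilde = Q'y, Xtilde = Q'X; then V = s2e (I + lambda D) is diagonal,
// lambda = s2u / s2e.  Every evaluation is O(n p^2) with tiny n, p.

static double crit_lambda(const arma::mat& X, const arma::vec& y,
                          const arma::vec& d, double lambda, bool reml,
                          double* sigma2out, arma::vec* betaout) {
  const int n = y.n_elem, p = X.n_cols;
  arma::vec w = 1.0 / (1.0 + lambda * d);
  arma::mat Xw = X.each_col() % w;
  arma::mat XtWX = X.t() * Xw;
  arma::vec beta = arma::solve(XtWX, Xw.t() * y, arma::solve_opts::likely_sympd);
  arma::vec r = y - X * beta;
  double rss = arma::dot(r % w, r);
  double ldet = -arma::accu(arma::log(w));
  double crit;
  if (reml) {
    double s2 = std::max(rss / (n - p), 1e-300);
    double ld2, sign;
    arma::log_det(ld2, sign, XtWX);
    crit = (n - p) * (std::log(2.0 * M_PI * s2) + 1.0) + ldet + ld2;
    if (sigma2out) *sigma2out = s2;
  } else {
    double s2 = std::max(rss / n, 1e-300);
    crit = n * (std::log(2.0 * M_PI * s2) + 1.0) + ldet;
    if (sigma2out) *sigma2out = s2;
  }
  if (betaout) *betaout = beta;
  return crit;
}

// [[Rcpp::export(name = ".crit_lambda_cpp")]]
double crit_lambda_cpp(const arma::mat& Xt, const arma::vec& yt,
                       const arma::vec& d, double lambda, bool reml) {
  return crit_lambda(Xt, yt, d, lambda, reml, nullptr, nullptr);
}

// -2 log-lik as a function of both variance components (unprofiled); used for
// the numeric REML Hessian behind Satterthwaite df.
// [[Rcpp::export(name = ".crit_theta_cpp")]]
double crit_theta_cpp(const arma::mat& Xt, const arma::vec& yt,
                      const arma::vec& d, double s2e, double s2u, bool reml) {
  const int n = yt.n_elem;
  arma::vec v = s2e + s2u * d;
  v.transform([](double x) { return std::max(x, 1e-300); });
  arma::vec w = 1.0 / v;
  arma::mat Xw = Xt.each_col() % w;
  arma::mat XtWX = Xt.t() * Xw;
  arma::vec beta = arma::solve(XtWX, Xw.t() * yt, arma::solve_opts::likely_sympd);
  arma::vec r = yt - Xt * beta;
  double crit = n * std::log(2.0 * M_PI) + arma::accu(arma::log(v)) +
                arma::dot(r % w, r);
  if (reml) {
    double ld, sign;
    arma::log_det(ld, sign, XtWX);
    crit += ld;
  }
  return crit;
}

// L' (X' V^{-1} X)^{-1} L at given variances (V^{-1} absorbed the sigma2).
// [[Rcpp::export(name = ".cvc_cpp")]]
arma::mat cvc_cpp(const arma::mat& Xt, const arma::vec& d, double s2e,
                  double s2u, const arma::mat& L) {
  arma::vec v = s2e + s2u * d;
  v.transform([](double x) { return std::max(x, 1e-300); });
  arma::mat Xw = Xt.each_col() % (1.0 / v);
  arma::mat A = arma::inv_sympd(arma::symmatu(Xt.t() * Xw));
  return L * A * L.t();
}

// Golden-section search on log(lambda) with an explicit boundary check at 0.
// [[Rcpp::export(name = ".fit_vc_cpp")]]
List fit_vc_cpp(const arma::mat& Xt, const arma::vec& yt, const arma::vec& d,
                bool reml, double tol) {
  const int n = yt.n_elem, p = Xt.n_cols;
  // perfect fit (e.g. constant probe): define the degenerate case at
  // lambda = 0 so all fixed-effect structures get comparable likelihoods
  {
    arma::vec b0 = arma::solve(Xt, yt);
    arma::vec r0 = yt - Xt * b0;
    if (arma::dot(r0, r0) < 1e-20 * n) {
      // pin the variance at a common floor so likelihoods of different
      // fixed-effect structures remain comparable
      const double s2f = 1e-300;
      arma::mat XtX = arma::symmatu(Xt.t() * Xt);
      double ld, sign;
      arma::log_det(ld, sign, XtX);
      double crit_ml0 = n * (std::log(2.0 * M_PI * s2f) + 1.0);
      double crit_reml0 = (n - p) * (std::log(2.0 * M_PI * s2f) + 1.0) + ld;
      return List::create(
          _["lambda"] = 0.0, _["sigma2_resid"] = 0.0, _["sigma2_sow"] = 0.0,
          _["beta"] = b0, _["cov_unscaled"] = arma::inv_sympd(XtX),
          _["loglik_ml"] = -0.5 * crit_ml0,
          _["loglik_reml"] = -0.5 * crit_reml0,
          _["crit"] = (reml ? crit_reml0 : crit_ml0), _["n"] = n, _["p"] = p);
    }
  }
  const double lo = -16.0, hi = 12.0;  // log(lambda) bracket
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = lo, b = hi;
  double c1 = b - gr * (b - a), c2 = a + gr * (b - a);
  double f1 = crit_lambda(Xt, yt, d, std::exp(c1), reml, nullptr, nullptr);
  double f2 = crit_lambda(Xt, yt, d, std::exp(c2), reml, nullptr, nullptr);
  for (int it = 0; it < 200 && (b - a) > 1e-9; ++it) {
    if (f1 < f2) {
      b = c2; c2 = c1; f2 = f1;
      c1 = b - gr * (b - a);
      f1 = crit_lambda(Xt, yt, d, std::exp(c1), reml, nullptr, nullptr);
    } else {
      a = c1; c1 = c2; f1 = f2;
      c2 = a + gr * (b - a);
      f2 = crit_lambda(Xt, yt, d, std::exp(c2), reml, nullptr, nullptr);
    }
    if (std::abs(f1 - f2) < tol && (b - a) < 1e-6) break;
  }
  double lam = std::exp((a + b) / 2.0);
  double fmid = crit_lambda(Xt, yt, d, lam, reml, nullptr, nullptr);
  double f0 = crit_lambda(Xt, yt, d, 0.0, reml, nullptr, nullptr);
  if (f0 <= fmid) lam = 0.0;

  double s2;
  arma::vec beta;
  double crit = crit_lambda(Xt, yt, d, lam, reml, &s2, &beta);
  // both likelihoods at the chosen lambda (each with its own profiled sigma2)
  double s2_ml, s2_reml;
  arma::vec btmp;
  double crit_ml = crit_lambda(Xt, yt, d, lam, false, &s2_ml, &btmp);
  double crit_reml = crit_lambda(Xt, yt, d, lam, true, &s2_reml, &btmp);

  arma::vec w = 1.0 / (1.0 + lam * d);
  arma::mat Xw = Xt.each_col() % w;
  arma::mat XtWX = arma::symmatu(Xt.t() * Xw);
  arma::mat cov_unscaled = arma::inv_sympd(XtWX);

  return List::create(
      _["lambda"] = lam, _["sigma2_resid"] = s2, _["sigma2_sow"] = lam * s2,
      _["beta"] = beta, _["cov_unscaled"] = cov_unscaled,
      _["loglik_ml"] = -0.5 * crit_ml, _["loglik_reml"] = -0.5 * crit_reml,
      _["crit"] = crit, _["n"] = n, _["p"] = p);
}

// Batch fit over the rows of a rotated expression matrix (probes x samples),
// returning the per-probe summaries needed by the genome-wide scans.
// [[Rcpp::export(name = ".fit_vc_batch_cpp")]]
List fit_vc_batch_cpp(const arma::mat& Xt, const arma::mat& Yt,
                      const arma::vec& d, bool reml, double tol) {
  const int m = Yt.n_rows, p = Xt.n_cols;
  arma::vec lambda(m), s2e(m), s2u(m), ll_ml(m), ll_reml(m);
  arma::mat betas(m, p);
  for (int j = 0; j < m; ++j) {
    arma::vec y = Yt.row(j).t();
    List f = fit_vc_cpp(Xt, y, d, reml, tol);
    lambda[j] = as<double>(f["lambda"]);
    s2e[j] = as<double>(f["sigma2_resid"]);
    s2u[j] = as<double>(f["sigma2_sow"]);
    ll_ml[j] = as<double>(f["loglik_ml"]);
    ll_reml[j] = as<double>(f["loglik_reml"]);
    betas.row(j) = as<arma::vec>(f["beta"]).t();
  }
  return List::create(_["lambda"] = lambda, _["sigma2_resid"] = s2e,
                      _["sigma2_sow"] = s2u, _["loglik_ml"] = ll_ml,
                      _["loglik_reml"] = ll_reml, _["beta"] = betas);
}
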