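// Hot path of the estimator: class-specific restricted skew-t log-densities
// and the two-class mixture log-likelihood, evaluated from the packed
// free-parameter vector. Mirrors the R reference implementation in
// R/loglik_fast.R exactly (asserted by the test suite).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double NU_LOWER = 2.1;

// log-density rows of one class's observed rMST distribution; ty is p x n.
// Non-static: the gradient translation unit reuses it for the nu coordinate.
arma::vec class_logpdf_only(const arma::vec& theta, int c, int m,
                            const arma::mat& ty, int j,
                            bool free_delta, double fix_delta,
                            bool free_nu, double fix_nu) {
  const int p = 2 * j;
  const int n = ty.n_cols;
  int k = (c - 1) * m;
  const double l2 = theta[k++];
  const double a2 = theta[k++];
  const double muT = theta[k++];
  const double s2T = std::exp(theta[k++]);
  const double dT = free_delta ? theta[k++] : fix_delta;
  const double nu = free_nu ? NU_LOWER + std::exp(theta[k++]) : fix_nu;
  const double vI = std::exp(theta[k++]);
  const double vO = std::exp(theta[k++]);
  const double vE1 = std::exp(theta[k++]);
  const double vEj = std::exp(theta[k++]);

  arma::vec lt(p), li(p), mu(p);
  for (int jj = 0; jj < j; ++jj) {
    lt[2 * jj] = 1.0;      lt[2 * jj + 1] = l2;
    li[2 * jj] = 0.0;      li[2 * jj + 1] = 1.0;
    mu[2 * jj] = muT;      mu[2 * jj + 1] = a2 + l2 * muT;
  }
  arma::vec delta = lt * dT;
  // Omega = Sigma + delta delta' assembled directly
  arma::mat omega = (s2T + dT * dT) * (lt * lt.t()) + vI * (li * li.t());
  for (int jj = 0; jj < j; ++jj) {
    const double ve = (jj == 0) ? vE1 : vEj;
    omega(2 * jj, 2 * jj) += vO + ve;
    omega(2 * jj + 1, 2 * jj + 1) += vO + ve;
    omega(2 * jj, 2 * jj + 1) += vO;
    omega(2 * jj + 1, 2 * jj) += vO;
  }
  arma::mat L;
  if (!arma::chol(L, omega, "lower")) {
    Rcpp::stop("scale matrix not positive definite");
  }
  arma::mat zt = ty;
  zt.each_col() -= mu;
  arma::mat u = arma::solve(arma::trimatl(L), zt);
  arma::rowvec Q = arma::sum(u % u, 0);
  arma::vec od = arma::solve(arma::trimatu(L.t()),
                             arma::solve(arma::trimatl(L), delta));
  const double lam = 1.0 - arma::dot(delta, od);
  arma::rowvec mm = (od.t() * zt) / std::sqrt(lam);
  const double logdet = arma::sum(arma::log(L.diag())); // = log|Omega| / 2
  const double cst = std::lgamma((nu + p) / 2.0) - std::lgamma(nu / 2.0) -
    (p / 2.0) * std::log(nu * M_PI) - logdet + std::log(2.0);
  arma::vec out(n);
  for (int i = 0; i < n; ++i) {
    const double q = Q[i];
    out[i] = cst - ((nu + p) / 2.0) * std::log1p(q / nu) +
      R::pt(mm[i] * std::sqrt((nu + p) / (nu + q)), nu + p, 1, 1);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_mixture_loglik(const arma::vec& theta, const arma::mat& ty, int j,
                          int n_classes, Rcpp::NumericVector fix_delta,
                          Rcpp::NumericVector fix_nu) {
  const bool free_delta = fix_delta.size() == 0;
  const bool free_nu = fix_nu.size() == 0;
  const double fd = free_delta ? 0.0 : fix_delta[0];
  const double fn = free_nu ? 0.0 : fix_nu[0];
  const int m = 10 - (free_delta ? 0 : 1) - (free_nu ? 0 : 1);
  double total = 0.0;
  if (n_classes == 1) {
    arma::vec ll = class_logpdf_only(theta, 1, m, ty, j, free_delta, fd, free_nu, fn);
    if (!ll.is_finite()) Rcpp::stop("non-finite mixture density");
    total = arma::sum(ll);
  } else {
    const double logit = theta[theta.n_elem - 1];
    const double lw1 = -std::log1p(std::exp(-logit));
    const double lw2 = -std::log1p(std::exp(logit));
    arma::vec lp1 = class_logpdf_only(theta, 1, m, ty, j, free_delta, fd, free_nu, fn);
    arma::vec lp2 = class_logpdf_only(theta, 2, m, ty, j, free_delta, fd, free_nu, fn);
    for (arma::uword i = 0; i < lp1.n_elem; ++i) {
      const double a = lp1[i] + lw1, b = lp2[i] + lw2;
      const double mx = std::max(a, b);
      const double v = mx + std::log(std::exp(a - mx) + std::exp(b - mx));
      if (!std::isfinite(v)) Rcpp::stop("non-finite mixture density");
      total += v;
    }
  }
  return total;
}
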