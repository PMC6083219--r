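// Analytic gradient of the mixture log-likelihood on the packed scale.
//
// Per class, log f(y) = log 2 + log t_p(z; Omega, nu) + log T_{nu+p}(s) with
// z = y - mu, Q = z' Omega^-1 z, u = Omega^-1 z, w = Omega^-1 delta,
// lambda = 1 - delta' w, m = delta'u / sqrt(lambda),
// s = m * kappa, kappa = sqrt((nu+p)/(nu+Q)).
//
// For a perturbation (dmu, dOmega = D, ddelta):
//   dQ       = -2 u'dmu - u'Du
//   dg       =  u'ddelta - w'dmu - w'Du          (g = delta'u)
//   dlambda  = -2 w'ddelta + w'Dw
//   dm       =  dg/sqrt(lambda) - m dlambda / (2 lambda)
//   ds       =  kappa dm - s dQ / (2 (nu+Q))
//   dlogf    = -tr(Omega^-1 D)/2 - (nu+p)/(2(nu+Q)) dQ + r ds,
// with r = t_{nu+p}(s)/T_{nu+p}(s). Every structural parameter of the LST
// class model perturbs Omega by a low-rank matrix, so all quadratic forms
// reduce to scalars built from lt'U, li'U, B'U and masked column sums.
// The degrees-of-freedom coordinate (density depends on nu through the
// t kernel and CDF order) is differenced numerically per class.
//
// Verified against a finite-difference gradient of the reference
// log-likelihood in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double NU_LOWER = 2.1;

struct ClassWork {
  arma::vec logf;        // n: per-observation class log-density
  arma::mat dlogf;       // n x nslots: per-observation slot derivatives
};

// forward declaration of the plain evaluator from mixture_loglik.cpp
arma::vec class_logpdf_only(const arma::vec& theta, int c, int m,
                            const arma::mat& ty, int j,
                            bool free_delta, double fix_delta,
                            bool free_nu, double fix_nu);

static arma::vec eval_class_logpdf(const arma::vec& theta, int c, int m,
                                   const arma::mat& ty, int j,
                                   bool free_delta, double fix_delta,
                                   bool free_nu, double fix_nu) {
  return class_logpdf_only(theta, c, m, ty, j, free_delta, fix_delta,
                           free_nu, fix_nu);
}

static ClassWork class_grad(const arma::vec& theta, int c, int m,
                            const arma::mat& ty, int j,
                            bool free_delta, double fix_delta,
                            bool free_nu, double fix_nu) {
  const int p = 2 * j;
  const int n = ty.n_cols;
  int k = (c - 1) * m;
  const int base = k;
  const double l2 = theta[k++];
  const double a2 = theta[k++];
  const double muT = theta[k++];
  const double s2T = std::exp(theta[k++]);
  const double dT = free_delta ? theta[k++] : fix_delta;
  const int nu_slot = free_nu ? k : -1;
  const double nu = free_nu ? NU_LOWER + std::exp(theta[k++]) : fix_nu;
  const double vI = std::exp(theta[k++]);
  const double vO = std::exp(theta[k++]);
  const double vE1 = std::exp(theta[k++]);
  const double vEj = std::exp(theta[k++]);

  arma::vec lt(p), li(p), mu(p);
  for (int jj = 0; jj < j; ++jj) {
    lt[2 * jj] = 1.0;  lt[2 * jj + 1] = l2;
    li[2 * jj] = 0.0;  li[2 * jj + 1] = 1.0;
    mu[2 * jj] = muT;  mu[2 * jj + 1] = a2 + l2 * muT;
  }
  const double c2 = s2T + dT * dT;
  arma::mat omega = c2 * (lt * lt.t()) + vI * (li * li.t());
  for (int jj = 0; jj < j; ++jj) {
    const double ve = (jj == 0) ? vE1 : vEj;
    omega(2 * jj, 2 * jj) += vO + ve;
    omega(2 * jj + 1, 2 * jj + 1) += vO + ve;
    omega(2 * jj, 2 * jj + 1) += vO;
    omega(2 * jj + 1, 2 * jj) += vO;
  }
  arma::mat Minv = arma::inv_sympd(omega);
  arma::mat zt = ty;
  zt.each_col() -= mu;
  arma::mat U = Minv * zt;                      // p x n
  arma::vec Q(n);
  for (int i = 0; i < n; ++i) Q[i] = arma::dot(zt.col(i), U.col(i));
  arma::vec h = Minv * lt;                      // Omega^-1 lt
  const double lt_h = arma::dot(lt, h);
  const double li_h = arma::dot(li, h);
  const double lam = 1.0 - dT * dT * lt_h;      // 1 - delta' Omega^-1 delta
  const double sqlam = std::sqrt(lam);

  arma::rowvec alpha = lt.t() * U;              // lt'u_i
  arma::rowvec beta = li.t() * U;               // li'u_i
  // occasion-block products
  arma::mat BU(j, n);
  arma::vec Bh(j);
  double trMB = 0.0, hB2 = 0.0;
  for (int jj = 0; jj < j; ++jj) {
    BU.row(jj) = U.row(2 * jj) + U.row(2 * jj + 1);
    Bh[jj] = h[2 * jj] + h[2 * jj + 1];
    trMB += Minv(2 * jj, 2 * jj) + Minv(2 * jj + 1, 2 * jj + 1) +
      2.0 * Minv(2 * jj, 2 * jj + 1);
    hB2 += Bh[jj] * Bh[jj];
  }
  arma::rowvec gamma = arma::sum(BU % BU, 0);       // u'(occ)u
  arma::rowvec hBU = Bh.t() * BU;                    // w-side occ product / dT
  // diagonal masks: first occasion rows 0,1; later rows 2..p-1
  arma::rowvec d1 = arma::sum(arma::square(U.rows(0, 1)), 0);
  arma::rowvec djv = arma::sum(arma::square(U.rows(2, p - 1)), 0);
  arma::rowvec hU1 = h.subvec(0, 1).t() * U.rows(0, 1);
  arma::rowvec hUj = h.subvec(2, p - 1).t() * U.rows(2, p - 1);
  const double trM1 = Minv(0, 0) + Minv(1, 1);
  double trMd = arma::trace(Minv) - trM1;
  const double h2_1 = arma::dot(h.subvec(0, 1), h.subvec(0, 1));
  const double h2_j = arma::dot(h.subvec(2, p - 1), h.subvec(2, p - 1));

  // t kernel pieces
  const double a = (nu + p) / 2.0;
  arma::vec kap(n), mvec(n), svec(n), r(n), logf(n);
  const double logdet_half = -0.5 * std::log(arma::det(omega));
  const double cst = std::lgamma(a) - std::lgamma(nu / 2.0) -
    (p / 2.0) * std::log(nu * M_PI) + logdet_half + std::log(2.0);
  for (int i = 0; i < n; ++i) {
    kap[i] = std::sqrt((nu + p) / (nu + Q[i]));
    mvec[i] = dT * alpha[i] / sqlam;
    svec[i] = mvec[i] * kap[i];
    const double lpdf = R::dt(svec[i], nu + p, 1);
    const double lcdf = R::pt(svec[i], nu + p, 1, 1);
    r[i] = std::exp(lpdf - lcdf);
    logf[i] = cst - a * std::log1p(Q[i] / nu) + lcdf;
  }

  ClassWork out;
  out.logf = logf;
  out.dlogf.zeros(n, m);

  // generic accumulator for one slot given per-observation scalars
  auto add_slot = [&](int slot, double trD,
                      const arma::rowvec* u_dmu, double w_dmu,
                      const arma::rowvec* u_ddelta, double w_ddelta,
                      const arma::rowvec* uDu, const arma::rowvec* wDu,
                      double wDw, double chain) {
    for (int i = 0; i < n; ++i) {
      double dQ = 0.0, dg = 0.0;
      if (u_dmu) dQ += -2.0 * (*u_dmu)[i];
      if (uDu) dQ += -(*uDu)[i];
      if (u_ddelta) dg += (*u_ddelta)[i];
      dg += -w_dmu;
      if (wDu) dg += -(*wDu)[i];
      const double dlam = -2.0 * w_ddelta + wDw;
      const double dm = dg / sqlam - mvec[i] * dlam / (2.0 * lam);
      const double ds = kap[i] * dm - svec[i] * dQ / (2.0 * (nu + Q[i]));
      out.dlogf(i, slot) = (-0.5 * trD - a * dQ / (nu + Q[i]) + r[i] * ds) *
        chain;
    }
  };

  // slot offsets within the class block
  int off = 0;
  const int s_l2 = off++;
  const int s_a2 = off++;
  const int s_muT = off++;
  const int s_s2T = off++;
  const int s_dT = free_delta ? off++ : -1;
  if (free_nu) off++;                       // nu handled by FD below
  const int s_vI = off++;
  const int s_vO = off++;
  const int s_vE1 = off++;
  const int s_vEj = off++;

  // lambda_T2: dmu = muT*li, ddelta = dT*li, D = c2 (li lt' + lt li')
  {
    arma::rowvec u_dmu = muT * beta;
    arma::rowvec u_dd = dT * beta;
    arma::rowvec uDu = 2.0 * c2 * (alpha % beta);
    arma::rowvec wDu = c2 * dT * (li_h * alpha + lt_h * beta);
    const double w_dmu = dT * li_h * muT;       // w' (muT li) = muT dT li'h
    const double w_dd = dT * dT * li_h;         // w' (dT li)
    const double wDw = 2.0 * c2 * dT * dT * li_h * lt_h;
    add_slot(s_l2, 2.0 * c2 * li_h, &u_dmu, w_dmu, &u_dd, w_dd,
             &uDu, &wDu, wDw, 1.0);
  }
  // alpha_2: dmu = li
  add_slot(s_a2, 0.0, &beta, dT * li_h, nullptr, 0.0, nullptr, nullptr, 0.0,
           1.0);
  // mu_T: dmu = lt
  add_slot(s_muT, 0.0, &alpha, dT * lt_h, nullptr, 0.0, nullptr, nullptr, 0.0,
           1.0);
  // sigma2_T: D = lt lt' (chain: packed log scale -> * s2T)
  {
    arma::rowvec uDu = alpha % alpha;
    arma::rowvec wDu = dT * lt_h * alpha;
    add_slot(s_s2T, lt_h, nullptr, 0.0, nullptr, 0.0, &uDu, &wDu,
             dT * dT * lt_h * lt_h, s2T);
  }
  // delta_T: ddelta = lt, D = 2 dT lt lt'
  if (free_delta) {
    arma::rowvec uDu = 2.0 * dT * (alpha % alpha);
    arma::rowvec wDu = 2.0 * dT * dT * lt_h * alpha;
    add_slot(s_dT, 2.0 * dT * lt_h, nullptr, 0.0, &alpha, dT * lt_h,
             &uDu, &wDu, 2.0 * dT * dT * dT * lt_h * lt_h, 1.0);
  }
  // var_IST2: D = li li'
  {
    arma::rowvec uDu = beta % beta;
    arma::rowvec wDu = dT * li_h * beta;
    add_slot(s_vI, arma::as_scalar(li.t() * Minv * li), nullptr, 0.0,
             nullptr, 0.0, &uDu, &wDu, dT * dT * li_h * li_h, vI);
  }
  // var_O: D = sum_j b_j b_j'
  {
    arma::rowvec wDu = dT * hBU;
    add_slot(s_vO, trMB, nullptr, 0.0, nullptr, 0.0, &gamma, &wDu,
             dT * dT * hB2, vO);
  }
  // var_E1 / var_Ej: diagonal masks
  {
    arma::rowvec wDu1 = dT * hU1;
    add_slot(s_vE1, trM1, nullptr, 0.0, nullptr, 0.0, &d1, &wDu1,
             dT * dT * h2_1, vE1);
    arma::rowvec wDuj = dT * hUj;
    add_slot(s_vEj, trMd, nullptr, 0.0, nullptr, 0.0, &djv, &wDuj,
             dT * dT * h2_j, vEj);
  }
  // nu: central finite difference of the class log-density on the packed
  // coordinate (the CDF order derivative has no closed form)
  if (free_nu) {
    const double h0 = 1e-5 * std::max(1.0, std::abs(theta[nu_slot]));
    arma::vec thp = theta, thm = theta;
    thp[nu_slot] += h0; thm[nu_slot] -= h0;
    arma::vec fp = eval_class_logpdf(thp, c, m, ty, j, free_delta, fix_delta,
                                     free_nu, fix_nu);
    arma::vec fm = eval_class_logpdf(thm, c, m, ty, j, free_delta, fix_delta,
                                     free_nu, fix_nu);
    out.dlogf.col(nu_slot - base) = (fp - fm) / (2.0 * h0);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_mixture_loglik_grad(const arma::vec& theta, const arma::mat& ty,
                                   int j, int n_classes,
                                   Rcpp::NumericVector fix_delta,
                                   Rcpp::NumericVector fix_nu) {
  const bool free_delta = fix_delta.size() == 0;
  const bool free_nu = fix_nu.size() == 0;
  const double fd = free_delta ? 0.0 : fix_delta[0];
  const double fn = free_nu ? 0.0 : fix_nu[0];
  const int m = 10 - (free_delta ? 0 : 1) - (free_nu ? 0 : 1);
  const int n = ty.n_cols;
  arma::vec grad(theta.n_elem, arma::fill::zeros);
  double total = 0.0;

  if (n_classes == 1) {
    ClassWork w1 = class_grad(theta, 1, m, ty, j, free_delta, fd, free_nu, fn);
    if (!w1.logf.is_finite()) Rcpp::stop("non-finite mixture density");
    total = arma::sum(w1.logf);
    for (int s = 0; s < m; ++s) grad[s] = arma::sum(w1.dlogf.col(s));
  } else {
    ClassWork w1 = class_grad(theta, 1, m, ty, j, free_delta, fd, free_nu, fn);
    ClassWork w2 = class_grad(theta, 2, m, ty, j, free_delta, fd, free_nu, fn);
    const double logit = theta[theta.n_elem - 1];
    const double lw1 = -std::log1p(std::exp(-logit));
    const double lw2 = -std::log1p(std::exp(logit));
    const double pi1 = std::exp(lw1);
    for (int i = 0; i < n; ++i) {
      const double a1 = w1.logf[i] + lw1, b1 = w2.logf[i] + lw2;
      const double mx = std::max(a1, b1);
      const double ll = mx + std::log(std::exp(a1 - mx) + std::exp(b1 - mx));
      if (!std::isfinite(ll)) Rcpp::stop("non-finite mixture density");
      total += ll;
      const double wt1 = std::exp(a1 - ll);
      const double wt2 = 1.0 - wt1;
      for (int s = 0; s < m; ++s) {
        grad[s] += wt1 * w1.dlogf(i, s);
        grad[m + s] += wt2 * w2.dlogf(i, s);
      }
      grad[2 * m] += wt1 - pi1;           // d/dlogit
    }
  }
  return Rcpp::List::create(Rcpp::Named("value") = total,
                            Rcpp::Named("gradient") = grad);
}
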