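test_that("parameter constructor enforces the domain invariants", {
  expect_s3_class(rmst_params(0, 1, 2.8, 5), "rmst_params")
  expect_error(rmst_params(c(0, 0), matrix(c(1, 2, 2, 1), 2), 0, 5),
               "positive definite")
  expect_error(rmst_params(0, 1, 0, 2), "> 2")
  expect_error(rmst_params(c(0, 0), 1, c(0, 0, 0), 5), "length")
  expect_error(rmst_params(c(0, 0), matrix(c(1, 0.5, 0, 1), 2), c(0, 0), 5),
               "symmetric")
  expect_error(rmst_logpdf(rmst_params(c(0, 0), diag(2), 0, 5), c(1, 2, 3)),
               "length")
})

test_that("log-density matches the mixing-variable quadrature oracle", {
  # frozen values from quad_rmst_density() at (mu=0, s2=1, delta=2.8, nu=5)
  frozen <- data.frame(
    y = c(-1, 0, 0.5, 2, 5),
    f = c(0.041429295, 0.127675546, 0.172559511, 0.187497747, 0.066334269))
  p <- rmst_params(0, 1, 2.8, 5)
  expect_equal(exp(rmst_logpdf(p, matrix(frozen$y))), frozen$f,
               tolerance = 1e-6)
  # live quadrature at one point, different parameter set
  p2 <- rmst_params(0.5, 2, -1.5, 7)
  expect_equal(exp(rmst_logpdf(p2, 0.2)),
               quad_rmst_density(0.2, 0.5, 2, -1.5, 7), tolerance = 1e-6)
})

test_that("univariate density normalizes to 1 over the (delta, nu) grid", {
  for (d in c(0, 2.8, 6)) {
    for (nu in c(5, 30, 10000)) {
      p <- rmst_params(0, 1, d, nu)
      val <- stats::integrate(function(y) exp(rmst_logpdf(p, matrix(y))),
                              -60, 250, rel.tol = 1e-9)$value
      expect_equal(val, 1, tolerance = 1e-4,
                   label = sprintf("integral at delta=%g nu=%g", d, nu))
    }
  }
})

test_that("special cases reduce to t, skew-normal and normal", {
  # delta = 0: equals the multivariate t density (hand-coded) pointwise
  mu <- c(0.3, -0.2); sig <- matrix(c(1, 0.4, 0.4, 2), 2); nu <- 6
  p <- rmst_params(mu, sig, c(0, 0), nu)
  pts <- rbind(c(0, 0), c(1, -1), c(2.5, 3), c(-4, 0.5))
  mvt_logpdf <- function(y) {
    q <- as.numeric(t(y - mu) %*% solve(sig) %*% (y - mu))
    lgamma((nu + 2) / 2) - lgamma(nu / 2) - log(nu * pi) -
      0.5 * log(det(sig)) - (nu + 2) / 2 * log1p(q / nu)
  }
  for (i in seq_len(nrow(pts))) {
    expect_equal(rmst_logpdf(p, pts[i, ]), mvt_logpdf(pts[i, ]),
                 tolerance = 1e-8)
  }
  # delta = 0, nu = 10000: standard normal at the origin and elsewhere
  pn <- rmst_params(0, 1, 0, 10000)
  expect_equal(rmst_logpdf(pn, 0), stats::dnorm(0, log = TRUE),
               tolerance = 1e-3)
  expect_equal(exp(rmst_logpdf(pn, matrix(c(-2, 1)))), stats::dnorm(c(-2, 1)),
               tolerance = 1e-3)
  # large nu, delta free: skew-normal density 2 phi(y) Phi(alpha y)
  psn <- rmst_params(0, 1, 2, 10000)
  alpha <- 2 / sqrt(1)  # delta / sqrt(sigma2) for the direct parameterization
  y <- c(-1, 0, 1.5)
  expect_equal(exp(rmst_logpdf(psn, matrix(y))),
               2 * stats::dnorm(y, sd = sqrt(5)) *
                 stats::pnorm(alpha * y / sqrt(5)),
               tolerance = 1e-3)
})

test_that("moment formulas agree with limits and the sampling oracle", {
  # normal limit
  mu <- c(1, 2); sig <- matrix(c(2, 0.3, 0.3, 1), 2)
  m0 <- rmst_moments(rmst_params(mu, sig, c(0, 0), 10000))
  expect_equal(m0$mean, mu)
  expect_equal(m0$cov, sig, tolerance = 1e-3)
  expect_equal(m0$skewness, c(0, 0), tolerance = 1e-6)
  # symmetric t: variance nu/(nu-2), zero skewness
  mt <- rmst_moments(rmst_params(0, 1, 0, 5))
  expect_equal(mt$cov[1, 1], 5 / 3)
  expect_equal(mt$skewness, 0)
  # mean formula: b_5 * 2.8
  m1 <- rmst_moments(rmst_params(0, 1, 2.8, 5))
  expect_equal(m1$mean, sqrt(5 / pi) * gamma(2) / gamma(2.5) * 2.8,
               tolerance = 1e-10)
  # sampling oracle at the design's skewness levels, 1e6 draws, 3 MC SEs
  for (d in c(2.8, 6)) {
    p <- rmst_params(0, 1, d, 5)
    m <- rmst_moments(p)
    x <- as.numeric(rmst_sample(p, 1e6, seed = 1))
    expect_lt(abs(mean(x) - m$mean), 3 * stats::sd(x) / 1000)
    se_var <- stats::sd((x - mean(x))^2) / 1000
    expect_lt(abs(stats::var(x) - m$cov[1, 1]), 3 * se_var)
    se_skew <- jackknife_se(x, sample_skewness)
    expect_lt(abs(sample_skewness(x) - m$skewness), 3 * se_skew)
  }
  expect_error(rmst_moments(structure(list(mu = 0, sigma = diag(1), delta = 0,
                                           nu = 1.5, p = 1L),
                                      class = "rmst_params")),
               "undefined")
})

test_that("variance is monotone in the scale parameter", {
  v <- vapply(c(0.5, 1, 2, 4), function(s2) {
    rmst_moments(rmst_params(0, s2, 2.8, 5))$cov[1, 1]
  }, 0)
  expect_true(all(diff(v) > 0))
})

test_that("delta sign convention: positive delta gives right skew", {
  for (d in c(-3, -0.5, 0.5, 3)) {
    p <- rmst_params(0, 1, d, 8)
    expect_equal(sign(rmst_moments(p)$skewness), sign(d))
    x <- as.numeric(rmst_sample(p, 2e5, seed = 9))
    expect_equal(sign(sample_skewness(x)), sign(d))
  }
})

test_that("sampler and density agree by goodness of fit", {
  p <- rmst_params(0, 1, 2.8, 5)
  x <- as.numeric(rmst_sample(p, 1e5, seed = 3))
  cdf <- numeric_cdf_fun(p, -40, 150)
  ks <- suppressWarnings(stats::ks.test(x, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampling is reproducible given a seed and leaves RNG state alone", {
  p <- rmst_params(c(0, 1), diag(2), c(1, -1), 5)
  set.seed(123); before <- stats::runif(1)
  a <- rmst_sample(p, 100, seed = 7)
  b <- rmst_sample(p, 100, seed = 7)
  expect_identical(a, b)
  set.seed(123)
  expect_identical(stats::runif(1), before)
})

test_that("linear combinations keep the rMST skewness structure", {
  p <- rmst_params(c(0, 0), matrix(c(1, 0.3, 0.3, 1.5), 2), c(2, 0.5), 6)
  a <- c(0.7, -0.4)
  x <- rmst_sample(p, 5e5, seed = 11) %*% a
  sk <- rmst_linear_skewness(p, a)
  se <- jackknife_se(as.numeric(x), sample_skewness)
  expect_lt(abs(sample_skewness(as.numeric(x)) - sk), 3 * se)
})
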