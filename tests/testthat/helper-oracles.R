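# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: densities via quadrature over the mixing
# variables, moments via raw sampling statistics, normal-theory results via
# hand-built SEM matrices.

# univariate rMST density by 2-D adaptive quadrature over (|U0|, W)
quad_rmst_density <- function(y, mu, sigma2, delta, nu) {
  inner <- function(h) {
    vapply(h, function(hh) {
      stats::integrate(function(w) {
        stats::dnorm(y, mu + delta * hh / sqrt(w), sqrt(sigma2 / w)) *
          stats::dgamma(w, shape = nu / 2, rate = nu / 2)
      }, 0, Inf, rel.tol = 1e-10)$value
    }, 0)
  }
  stats::integrate(function(h) inner(h) * 2 * stats::dnorm(h), 0, Inf,
                   rel.tol = 1e-10)$value
}

# numeric CDF of a univariate rMST density as a function usable by ks.test
numeric_cdf_fun <- function(params, lo, hi, n_grid = 4000) {
  grid <- seq(lo, hi, length.out = n_grid)
  dens <- exp(rmst_logpdf(params, matrix(grid)))
  cdf <- cumsum((dens[-1] + dens[-n_grid]) / 2 * diff(grid))
  cdf <- c(0, cdf) / max(cdf)
  stats::approxfun(grid, cdf, yleft = 0, yright = 1)
}

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

# block-jackknife standard error for a heavy-tailed statistic
jackknife_se <- function(x, stat, B = 200) {
  n <- length(x)
  idx <- rep(seq_len(B), each = ceiling(n / B))[seq_len(n)]
  loo <- vapply(seq_len(B), function(b) stat(x[idx != b]), 0)
  sqrt((B - 1) / B * sum((loo - mean(loo))^2))
}

# straightforward non-vectorized mixture log-likelihood: one row at a time
naive_mixture_loglik <- function(mp, spec, data) {
  pars <- lapply(mp$class_params, function(cp) build_class_moments(spec, cp))
  total <- 0
  for (i in seq_len(nrow(data))) {
    fi <- 0
    for (c in seq_along(pars)) {
      fi <- fi + mp$pi[c] * exp(rmst_logpdf(pars[[c]], data[i, ]))
    }
    total <- total + log(fi)
  }
  total
}

# hand-built model-implied normal moments (independent of build_class_moments)
normal_sem_moments <- function(j, cp) {
  p <- 2 * j
  lam <- matrix(0, p, j + 2)
  mu <- numeric(p)
  for (jj in seq_len(j)) {
    r1 <- 2 * jj - 1; r2 <- 2 * jj
    lam[r1, 1] <- 1; lam[r2, 1] <- cp$lambda_T2
    lam[r2, 2] <- 1
    lam[r1, 2 + jj] <- 1; lam[r2, 2 + jj] <- 1
    mu[r1] <- cp$mu_T; mu[r2] <- cp$alpha_2 + cp$lambda_T2 * cp$mu_T
  }
  phi <- diag(c(cp$sigma2_T, cp$var_IST2, rep(cp$var_O, j)))
  theta <- diag(rep(c(cp$var_E1, rep(cp$var_Ej, j - 1)), each = 2))
  list(mu = mu, sigma = lam %*% phi %*% t(lam) + theta)
}

# multivariate-normal SEM log-likelihood from the hand-built moments
mvn_sem_loglik <- function(j, cp, data) {
  mo <- normal_sem_moments(j, cp)
  L <- chol(mo$sigma)
  z <- sweep(data, 2, mo$mu)
  q <- colSums(backsolve(L, t(z), transpose = TRUE)^2)
  n <- nrow(data); p <- ncol(data)
  -n * p / 2 * log(2 * pi) - n * sum(log(diag(L))) - sum(q) / 2
}

# normal-theory (expected-information) SEM standard errors for the
# single-class normal submodel, derivatives by central finite differences of
# the hand-built moments; raw parameter scale, order as in `free`
expected_info_se <- function(j, cp, N,
                             free = c("lambda_T2", "alpha_2", "mu_T",
                                      "sigma2_T", "var_IST2", "var_O",
                                      "var_E1", "var_Ej")) {
  k <- length(free)
  x0 <- unlist(cp[free])
  moments_at <- function(x) {
    cpx <- cp
    for (i in seq_len(k)) cpx[[free[i]]] <- x[i]
    normal_sem_moments(j, cpx)
  }
  base <- moments_at(x0)
  dmu <- vector("list", k); dsig <- vector("list", k)
  for (i in seq_len(k)) {
    h <- 1e-5 * max(1, abs(x0[i]))
    xp <- x0; xp[i] <- x0[i] + h
    xm <- x0; xm[i] <- x0[i] - h
    mp_ <- moments_at(xp); mm_ <- moments_at(xm)
    dmu[[i]] <- (mp_$mu - mm_$mu) / (2 * h)
    dsig[[i]] <- (mp_$sigma - mm_$sigma) / (2 * h)
  }
  siginv <- solve(base$sigma)
  info <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in a:k) {
      info[a, b] <- info[b, a] <-
        as.numeric(t(dmu[[a]]) %*% siginv %*% dmu[[b]]) +
        sum(diag(siginv %*% dsig[[a]] %*% siginv %*% dsig[[b]])) / 2
    }
  }
  se <- sqrt(diag(solve(N * info)))
  names(se) <- free
  se
}

# fabricate an lst_fit object without running the optimizer (for postprocess
# and evaluation unit tests)
make_fake_fit <- function(mp, spec, loglik = -100, converged = TRUE,
                          warnings = character(0), ses = NULL) {
  rep_est <- report_params(mp, spec)
  if (is.null(ses)) {
    ses <- stats::setNames(rep(0.1, length(rep_est)), names(rep_est))
  }
  structure(list(estimates = mp, theta = pack_params(mp, spec),
                 est_report = rep_est, standard_errors = ses,
                 loglik = loglik, start_loglik = loglik - 1,
                 converged = converged, n_iterations = 10L,
                 warnings = warnings,
                 estimated_class1_proportion = mp$pi[1], spec = spec),
            class = "lst_fit")
}
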