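# Internal fast path for the optimizer: evaluates the mixture log-likelihood
# from the packed vector without constructing parameter objects or
# re-validating inputs on every call. The compiled routine and the pure-R
# closure below are kept in exact agreement with the public
# mixture_loglik() (asserted by the test suite).

make_loglik_fn <- function(spec, data) {
  data <- as.matrix(data)
  if (ncol(data) != spec$p) stop("'data' must have ", spec$p, " columns")
  ty <- t(data)
  j <- spec$n_occasions
  k <- spec$n_classes
  fd <- if (is.null(spec$fix_delta)) numeric(0) else spec$fix_delta
  fn <- if (is.null(spec$fix_nu)) numeric(0) else spec$fix_nu
  function(theta) cpp_mixture_loglik(theta, ty, j, k, fd, fn)
}

# analytic gradient of the log-likelihood on the packed scale (the nu
# coordinates are differenced inside the compiled routine); returns
# list(value, gradient)
make_loglik_grad_fn <- function(spec, data) {
  data <- as.matrix(data)
  if (ncol(data) != spec$p) stop("'data' must have ", spec$p, " columns")
  ty <- t(data)
  j <- spec$n_occasions
  k <- spec$n_classes
  fd <- if (is.null(spec$fix_delta)) numeric(0) else spec$fix_delta
  fn <- if (is.null(spec$fix_nu)) numeric(0) else spec$fix_nu
  function(theta) cpp_mixture_loglik_grad(theta, ty, j, k, fd, fn)
}

make_loglik_fn_r <- function(spec, data) {
  data <- as.matrix(data)
  if (ncol(data) != spec$p) stop("'data' must have ", spec$p, " columns")
  n <- nrow(data)
  p <- spec$p
  j <- spec$n_occasions
  k <- spec$n_classes
  ty <- t(data)                       # p x n, reused every evaluation
  li <- rep(c(0, 1), j)
  # 2x2 occasion blocks of Var(O) on the diagonal
  occ_block <- matrix(0, p, p)
  for (jj in seq_len(j)) occ_block[2 * jj - (1:0), 2 * jj - (1:0)] <- 1
  err_first <- rep(c(1, 0), c(2L, p - 2L))
  err_later <- 1 - err_first
  # per-class slot layout within theta (delta/nu may be fixed by the spec)
  slots <- CLASS_PARAM_NAMES
  if (!is.null(spec$fix_delta)) slots <- setdiff(slots, "delta_T")
  if (!is.null(spec$fix_nu)) slots <- setdiff(slots, "nu")
  m <- length(slots)
  pos <- function(c, nm) (c - 1L) * m + match(nm, slots)
  l2p <- log(2 * pi)

  class_logpdf <- function(theta, c) {
    l2 <- theta[pos(c, "lambda_T2")]
    a2 <- theta[pos(c, "alpha_2")]
    muT <- theta[pos(c, "mu_T")]
    s2T <- exp(theta[pos(c, "sigma2_T")])
    dT <- if (is.null(spec$fix_delta)) theta[pos(c, "delta_T")] else spec$fix_delta
    nu <- if (is.null(spec$fix_nu)) NU_LOWER + exp(theta[pos(c, "nu")]) else spec$fix_nu
    vI <- exp(theta[pos(c, "var_IST2")])
    vO <- exp(theta[pos(c, "var_O")])
    vE1 <- exp(theta[pos(c, "var_E1")])
    vEj <- exp(theta[pos(c, "var_Ej")])
    lt <- rep(c(1, l2), j)
    mu <- rep(c(0, a2), j) + lt * muT
    delta <- lt * dT
    omega <- (s2T + dT * dT) * tcrossprod(lt) + vI * tcrossprod(li) +
      vO * occ_block + diag(vE1 * err_first + vEj * err_later, p)
    L <- chol(omega)
    zt <- ty - mu                       # p x n by column recycling
    u <- backsolve(L, zt, transpose = TRUE)
    Q <- .colSums(u * u, p, n)
    oinv_delta <- backsolve(L, backsolve(L, delta, transpose = TRUE))
    lam <- 1 - sum(delta * oinv_delta)
    mm <- as.numeric(crossprod(oinv_delta, zt)) / sqrt(lam)
    logdet <- 2 * sum(log(diag(L)))
    logt <- lgamma((nu + p) / 2) - lgamma(nu / 2) - (p / 2) * log(nu * pi) -
      logdet / 2 - ((nu + p) / 2) * log1p(Q / nu)
    log(2) + logt +
      stats::pt(mm * sqrt((nu + p) / (nu + Q)), df = nu + p, log.p = TRUE)
  }

  function(theta) {
    if (k == 1L) {
      ll <- class_logpdf(theta, 1L)
    } else {
      logit <- theta[length(theta)]
      lp1 <- class_logpdf(theta, 1L) + stats::plogis(logit, log.p = TRUE)
      lp2 <- class_logpdf(theta, 2L) + stats::plogis(-logit, log.p = TRUE)
      mx <- pmax(lp1, lp2)
      ll <- mx + log(exp(lp1 - mx) + exp(lp2 - mx))
    }
    if (any(!is.finite(ll))) stop("non-finite mixture density")
    sum(ll)
  }
}
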