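test_that("mixture log-likelihood matches the naive per-row oracle", {
  spec <- lst_model_spec(2)
  truth <- default_truth(2.8)
  ds <- simulate_dataset(sim_condition(200, 2, 2.8, base_seed = 3), 1, truth)
  theta <- pack_params(truth, spec)
  ll <- mixture_loglik(theta, spec, ds$data)
  expect_equal(ll, naive_mixture_loglik(truth, spec, ds$data),
               tolerance = 1e-10)
  # compiled fast path and pure-R fast path agree with the reference
  fC <- skewtlst:::make_loglik_fn(spec, ds$data)
  fR <- skewtlst:::make_loglik_fn_r(spec, ds$data)
  expect_equal(fC(unname(theta)), ll, tolerance = 1e-12)
  expect_equal(fR(unname(theta)), ll, tolerance = 1e-12)
  # at a second, far-from-truth point too
  th2 <- unname(theta) + seq(-0.2, 0.2, length.out = 21)
  expect_equal(fC(th2), mixture_loglik(th2, spec, ds$data), tolerance = 1e-12)
  expect_equal(fR(th2), mixture_loglik(th2, spec, ds$data), tolerance = 1e-12)
  expect_error(mixture_loglik(theta, spec, ds$data[, 1:3]), "columns")
})

test_that("single-class normal limit equals the SEM normal log-likelihood", {
  spec <- lst_model_spec(3, n_classes = 1, fix_delta = 0, fix_nu = 10000)
  cp <- default_truth(0, nu = 10000)$class_params[[1]]
  truth <- mixture_params(list(cp))
  y <- rmst_sample(build_class_moments(spec, cp), 400, seed = 17)
  ll <- mixture_loglik(pack_params(truth, spec), spec, y)
  expect_lt(abs(ll - mvn_sem_loglik(3, cp, y)) / nrow(y), 1e-3)
})

test_that("likelihood is invariant to the logit for identical classes", {
  spec <- lst_model_spec(2)
  cp <- default_truth(2.8)$class_params[[1]]
  y <- rmst_sample(build_class_moments(spec, cp), 100, seed = 5)
  ll <- vapply(c(-2, 0, 1.15, 3), function(lg) {
    mp <- mixture_params(list(cp, cp), logit_pi1 = lg)
    mixture_loglik(pack_params(mp, spec), spec, y)
  }, 0)
  expect_equal(max(ll) - min(ll), 0, tolerance = 1e-8)
})

test_that("likelihood is invariant under class-label permutation", {
  spec <- lst_model_spec(2)
  truth <- default_truth(2.8)
  ds <- simulate_dataset(sim_condition(150, 2, 2.8), 1, truth)
  swapped <- mixture_params(rev(truth$class_params), -truth$logit_pi1)
  expect_equal(mixture_loglik(pack_params(truth, spec), spec, ds$data),
               mixture_loglik(pack_params(swapped, spec), spec, ds$data),
               tolerance = 1e-10)
})

test_that("fitting improves the likelihood and refitting is a fixed point", {
  spec <- lst_model_spec(2)
  truth <- default_truth(2.8)
  # monotone improvement holds on every replication, converged or not
  for (r in 1:3) {
    ds <- simulate_dataset(sim_condition(150, 2, 2.8, base_seed = 8), r, truth)
    fit <- fit_mixture(ds$data, spec, truth, compute_se = FALSE)
    expect_gte(fit$loglik, fit$start_loglik)
  }
  # restarting from a previous solution reproduces it (whether the solution
  # is interior or sits near a variance boundary)
  spec3 <- lst_model_spec(3)
  ds <- simulate_dataset(sim_condition(500, 3, 2.8, base_seed = 8), 1, truth)
  fit <- fit_mixture(ds$data, spec3, truth, compute_se = FALSE)
  refit <- fit_mixture(ds$data, spec3, fit$estimates, compute_se = FALSE)
  expect_lt(abs(refit$loglik - fit$loglik), 1e-6 * max(1, abs(fit$loglik)))
})

test_that("complete-data class-wise fits never beat the mixture optimum", {
  spec <- lst_model_spec(2)
  truth <- default_truth(2.8)
  ds <- simulate_dataset(sim_condition(300, 2, 2.8, base_seed = 12), 1, truth)
  fit <- fit_mixture(ds$data, spec, truth, compute_se = FALSE)
  spec1 <- lst_model_spec(2, n_classes = 1)
  cps <- lapply(1:2, function(c) {
    sub <- ds$data[ds$true_class == c, , drop = FALSE]
    f <- fit_mixture(sub, spec1, mixture_params(truth$class_params[c]),
                     compute_se = FALSE)
    f$estimates$class_params[[1]]
  })
  assembled <- mixture_params(cps, stats::qlogis(mean(ds$true_class == 1)))
  ll_assembled <- mixture_loglik(pack_params(assembled, spec), spec, ds$data)
  expect_lte(ll_assembled, fit$loglik + 1e-6 * abs(fit$loglik))
})

test_that("standard errors match normal-theory SEM standard errors", {
  j <- 2
  spec <- lst_model_spec(j, n_classes = 1, fix_delta = 0, fix_nu = 10000)
  cp <- default_truth(0, nu = 10000)$class_params[[1]]
  truth <- mixture_params(list(cp))
  N <- 4000
  y <- rmst_sample(build_class_moments(spec, cp), N, seed = 31)
  fit <- fit_mixture(y, spec, truth)
  expect_true(fit$converged)
  se_oracle <- expected_info_se(j, cp, N)
  se_fit <- fit$standard_errors[paste0(names(se_oracle), "_c1")]
  expect_lt(max(abs(se_fit / se_oracle - 1)), 0.10)
})

test_that("standard errors are invariant to the packing transform", {
  spec <- lst_model_spec(2, n_classes = 1)
  cp <- default_truth(2.8)$class_params[[1]]
  truth <- mixture_params(list(cp))
  y <- rmst_sample(build_class_moments(spec, cp), 2000, seed = 41)
  fit <- fit_mixture(y, spec, truth)
  i <- match("sigma2_T_c1", spec$free_names)
  # log-scale Hessian + delta method (what the package reports)
  se_log <- fit$standard_errors[[i]]
  # direct-scale Hessian of the same objective, reparameterized by hand
  raw0 <- fit$est_report
  to_packed <- function(raw) {
    th <- raw
    lg <- grepl("^(sigma2_T|var_IST2|var_O|var_E1|var_Ej)_c", spec$free_names)
    th[lg] <- log(raw[lg])
    nup <- grepl("^nu_c", spec$free_names)
    th[nup] <- log(raw[nup] - 2.1)
    th
  }
  llfn <- skewtlst:::make_loglik_fn(spec, y)
  f_raw <- function(raw) -llfn(unname(to_packed(raw)))
  H_raw <- skewtlst:::num_hessian(f_raw, raw0, h = 1e-4)
  se_raw <- sqrt(diag(solve(H_raw)))[i]
  expect_lt(abs(se_log / se_raw - 1), 0.05)
})

test_that("reported SEs track the sampling SD of the estimates", {
  run <- normal_sim_study()
  for (nm in c("mu_T_c1", "lambda_T2_c1", "alpha_2_c1")) {
    ratio <- mean(run$se[, nm]) / stats::sd(run$est[, nm])
    expect_gt(ratio, 0.85)
    expect_lt(ratio, 1.15)
  }
})

test_that("optimizer failures surface as flagged fits, not crashes", {
  spec <- lst_model_spec(2)
  truth <- default_truth(2.8)
  ds <- simulate_dataset(sim_condition(60, 2, 2.8, base_seed = 14), 1, truth)
  # absurd starting values: must return a FitResult, never raise
  bad_cp <- lst_class_params(lambda_T2 = 50, alpha_2 = -40, mu_T = 90,
                             sigma2_T = 1e-6, delta_T = 80, nu = 2.11,
                             var_IST2 = 1e-6, var_O = 1e-6, var_E1 = 1e-6,
                             var_Ej = 1e-6)
  fit <- fit_mixture(ds$data, spec, mixture_params(list(bad_cp, bad_cp), 0),
                     max_iter = 20, compute_se = FALSE)
  expect_s3_class(fit, "lst_fit")
  expect_gte(fit$loglik, fit$start_loglik)
})
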