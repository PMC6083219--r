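fixture_cp1 <- function(delta_T = 2.8, nu = 5) {
  lst_class_params(lambda_T2 = 0.9, alpha_2 = 0.2, mu_T = 1.0, sigma2_T = 0.8,
                   delta_T = delta_T, nu = nu, var_IST2 = 0.3, var_O = 0.5,
                   var_E1 = 0.5, var_Ej = 0.35)
}

test_that("free-parameter counting follows the constraint map", {
  # two-class design: 21 for every occasion count
  for (j in 2:6) {
    expect_identical(count_free_parameters(lst_model_spec(j)), 21L)
  }
  # single-class version: 10 (no mixing logit)
  expect_identical(count_free_parameters(lst_model_spec(4, n_classes = 1)), 10L)
  # fixing delta and nu in both classes removes 2 parameters per class
  expect_identical(
    count_free_parameters(lst_model_spec(4, fix_delta = 2.8, fix_nu = 5)), 17L)
  # equality classes: exactly 10 free groups per class
  cm <- constraint_map(lst_model_spec(5))
  free1 <- unique(cm$free_group[cm$status == "free" & cm$class %in% 1])
  expect_length(free1, 10L)
  # fixed values are what identification demands
  expect_true(all(cm$fixed_value[cm$parameter == "lambda_O"] == 1))
  expect_true(all(cm$fixed_value[cm$parameter == "alpha" &
                                   cm$indicator == 1] == 0))
})

test_that("observed skewness vector follows the trait loading pattern", {
  spec <- lst_model_spec(2)
  cp <- fixture_cp1()
  cp$lambda_T2 <- 0.8
  cp$delta_T <- 3
  pars <- build_class_moments(spec, cp)
  expect_equal(unname(pars$delta), c(3, 2.4, 3, 2.4))
  expect_equal(pars$nu, cp$nu)
})

test_that("normal special case yields the classical LST moment structure", {
  spec <- lst_model_spec(3)
  cp <- fixture_cp1(delta_T = 0, nu = 10000)
  pars <- build_class_moments(spec, cp)
  oracle <- normal_sem_moments(3, cp)
  expect_equal(unname(pars$mu), oracle$mu)
  expect_equal(unname(pars$sigma), unname(oracle$sigma))
  mo <- rmst_moments(pars)
  expect_equal(unname(mo$cov), unname(oracle$sigma), tolerance = 1e-3)
  expect_equal(mo$skewness, rep(0, 6), tolerance = 1e-6)
})

test_that("cross-occasion covariance of indicator 1 is trait-only", {
  spec <- lst_model_spec(4)
  cp <- fixture_cp1()
  pars <- build_class_moments(spec, cp)
  # scale matrix: occasions are uncorrelated beyond the trait/IST block
  ind1 <- seq(1, spec$p, by = 2)
  for (a in ind1) for (b in setdiff(ind1, a)) {
    expect_equal(pars$sigma[a, b], cp$sigma2_T)
  }
  # and the model-implied covariance equals the trait variance contribution
  mo <- rmst_moments(pars)
  trait_var <- rmst_moments(rmst_params(0, cp$sigma2_T, cp$delta_T, cp$nu))$cov[1, 1]
  expect_equal(mo$cov[1, 3], trait_var)
})

test_that("factor-wise shared-mixing generation matches the analytic moments", {
  spec <- lst_model_spec(3)
  cp <- fixture_cp1()
  pars <- build_class_moments(spec, cp)
  mo <- rmst_moments(pars)
  n <- 1e5
  y <- simulate_lst_factors(spec, cp, n, mixing = "shared", seed = 21)
  for (col in seq_len(spec$p)) {
    se_mean <- stats::sd(y[, col]) / sqrt(n)
    expect_lt(abs(mean(y[, col]) - mo$mean[col]), 3 * se_mean)
  }
  # covariance entries within 3 empirical SEs
  ctr <- sweep(y, 2, colMeans(y))
  for (a in c(1, 2, 5)) for (b in c(1, 3, 6)) {
    prod <- ctr[, a] * ctr[, b]
    expect_lt(abs(mean(prod) - mo$cov[a, b]), 3 * stats::sd(prod) / sqrt(n))
  }
  # independent-normal mixing changes the tails but not mean/covariance
  y2 <- simulate_lst_factors(spec, cp, n, mixing = "independent", seed = 22)
  expect_lt(max(abs(colMeans(y2) - mo$mean)), 0.1)
})

test_that("pack/unpack is an exact coordinate-wise bijection", {
  spec <- lst_model_spec(3)
  truth <- default_truth(2.8)
  theta <- pack_params(truth, spec)
  expect_length(theta, 21L)
  back <- unpack_params(theta, spec)
  expect_equal(report_params(back, spec), report_params(truth, spec))
  # zeros decode to unit variances, nu = 3.1, even mixing
  zero <- unpack_params(rep(0, 21), spec)
  expect_equal(zero$class_params[[1]]$sigma2_T, 1)
  expect_equal(zero$class_params[[2]]$var_Ej, 1)
  expect_equal(zero$class_params[[1]]$nu, 3.1)
  expect_equal(zero$pi[1], 0.5)
  # perturbing one packed coordinate changes exactly one reported parameter
  for (i in c(1, 5, 8, 14, 21)) {
    th2 <- theta
    th2[i] <- th2[i] + 0.1
    diff <- report_params(unpack_params(th2, spec), spec) -
      report_params(truth, spec)
    expect_identical(sum(abs(diff) > 1e-9), 1L)
    expect_gt(abs(diff[i]), 1e-9)
  }
  expect_error(unpack_params(rep(0, 20), spec), "length 21")
  # specs with fixed skew-t parameters pack shorter vectors
  spec17 <- lst_model_spec(3, fix_delta = 2.8, fix_nu = 5)
  th17 <- pack_params(truth, spec17)
  expect_length(th17, 17L)
  expect_equal(report_params(unpack_params(th17, spec17), spec17),
               report_params(truth, spec17))
})

test_that("class parameter validation rejects impossible values", {
  expect_error(fixture_cp1(nu = 1.5), "nu")
  cp <- fixture_cp1()
  expect_error(do.call(lst_class_params, `$<-`(unclass(cp), "var_O", -1)),
               "positive")
})

test_that("default fixture obeys the stated class orderings", {
  truth <- default_truth(2.8)
  c1 <- truth$class_params[[1]]; c2 <- truth$class_params[[2]]
  expect_lt(c1$mu_T, c2$mu_T)          # class 1: lower average trait
  expect_gt(c1$sigma2_T, c2$sigma2_T)  # larger trait variance
  expect_gt(c1$var_O, c2$var_O)        # larger occasion fluctuations
  expect_gt(c1$var_E1, c2$var_E1)      # larger measurement error
  expect_gt(c1$var_Ej, c2$var_Ej)
  for (cp in truth$class_params) expect_gt(cp$var_E1, cp$var_Ej)  # Socratic
  expect_equal(truth$pi[1], stats::plogis(1.15))
})
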