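# Expensive simulation runs shared across test files, computed lazily and
# cached for the duration of the test session.

.simrun_cache <- new.env(parent = emptyenv())

# Replications of the well-specified single-class normal submodel (delta
# fixed at 0, nu fixed at 10000) at N = 1000, j = 2, population starting
# values. Used for the SE-consistency, seb and coverage oracles. 400 reps
# rather than 200: the SD denominator of the ratio/seb checks carries ~5%
# Monte Carlo noise at 200 reps, underpowering a +/-15% band.
normal_sim_study <- function(n_reps = 400L, N = 1000L, j = 2L) {
  key <- sprintf("normal_%d_%d_%d", n_reps, N, j)
  if (!is.null(.simrun_cache[[key]])) return(.simrun_cache[[key]])
  spec <- lst_model_spec(j, n_classes = 1L, fix_delta = 0, fix_nu = 10000)
  cp <- lst_class_params(lambda_T2 = 0.9, alpha_2 = 0.2, mu_T = 1.0,
                         sigma2_T = 0.8, delta_T = 0, nu = 10000,
                         var_IST2 = 0.3, var_O = 0.5, var_E1 = 0.5,
                         var_Ej = 0.35)
  truth <- mixture_params(list(cp))
  pars <- build_class_moments(spec, cp)
  est <- se <- matrix(NA_real_, n_reps, count_free_parameters(spec),
                      dimnames = list(NULL, spec$free_names))
  for (r in seq_len(n_reps)) {
    y <- rmst_sample(pars, N, seed = 50000 + r)
    fit <- fit_mixture(y, spec, truth)
    est[r, ] <- fit$est_report
    se[r, ] <- fit$standard_errors
  }
  out <- list(est = est, se = se, truth = report_params(truth, spec),
              spec = spec, cp = cp, N = N, j = j)
  .simrun_cache[[key]] <- out
  out
}

# scaled-down corner study: {N = 125, 1000} x {j = 2, 6}, delta_T = 2.8,
# 50 replications per cell, population starts, base seed 1. The inclusion
# threshold is lowered to 2 so small cells still yield evaluation rows
# (the design's 50-replication sufficiency rule is unit-tested separately).
corner_study <- function(n_reps = 50L) {
  key <- sprintf("corner_%d", n_reps)
  if (!is.null(.simrun_cache[[key]])) return(.simrun_cache[[key]])
  cfg <- run_config(N_levels = c(125, 1000), j_levels = c(2, 6),
                    delta_levels = 2.8, n_reps = n_reps, base_seed = 1L,
                    out_dir = file.path(tempdir(), "corner_study"),
                    min_included = 2L)
  res <- run_study(cfg)
  .simrun_cache[[key]] <- res
  res
}
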