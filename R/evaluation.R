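#' Monte Carlo evaluation criteria
#'
#' Per-parameter criteria computed over the included replications of one
#' design cell:
#' \itemize{
#'   \item `compute_peb()`: parameter estimation bias, the mean relative
#'     deviation \eqn{\frac{1}{n_r}\sum_r (\hat\theta_{pr} - \theta_p) /
#'     \theta_p}; undefined (error) for a true value of zero;
#'   \item `compute_seb()`: standard-error bias, the mean relative deviation
#'     of reported SEs from the empirical SD of the estimates across the same
#'     replications, \eqn{\frac{1}{n_r}\sum_r (SE_{pr} - SD_p) / SD_p};
#'   \item `compute_mse()`: mean of squared deviations from the true value,
#'     on the raw parameter scale;
#'   \item `compute_coverage()`: proportion of per-replication Wald intervals
#'     \eqn{\hat\theta \pm z_{1-\alpha/2} SE} containing the true value;
#'     replications without a usable SE are dropped from the denominator.
#' }
#'
#' @param estimates numeric vector of per-replication estimates.
#' @param theta_true true (population) value; must be nonzero for `peb`.
#' @param aggregate `"mean"` (the headline definition) or `"median"` (the
#'   outlier-robust supplementary variant) for `peb` and `seb`.
#' @return A scalar.
#' @name evaluation-criteria
NULL

#' @rdname evaluation-criteria
#' @export
compute_peb <- function(estimates, theta_true, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (length(estimates) < 1) stop("need at least one replication")
  if (!is.finite(theta_true) || theta_true == 0) {
    stop("peb undefined for a true value of zero")
  }
  agg <- if (aggregate == "mean") mean else stats::median
  agg((estimates - theta_true) / theta_true)
}

#' @rdname evaluation-criteria
#' @param ses numeric vector of per-replication standard errors (same order
#'   as `estimates`).
#' @export
compute_seb <- function(ses, estimates, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (length(estimates) < 2) stop("need at least two replications for SD")
  sd_p <- stats::sd(estimates)
  if (!is.finite(sd_p) || sd_p == 0) stop("seb undefined: zero SD of estimates")
  ok <- is.finite(ses)
  if (!any(ok)) stop("seb undefined: no finite SEs")
  agg <- if (aggregate == "mean") mean else stats::median
  agg((ses[ok] - sd_p) / sd_p)
}

#' @rdname evaluation-criteria
#' @export
compute_mse <- function(estimates, theta_true) {
  if (length(estimates) < 1) stop("need at least one replication")
  mean((estimates - theta_true)^2)
}

#' @rdname evaluation-criteria
#' @param level confidence level (default 0.95).
#' @export
compute_coverage <- function(estimates, ses, theta_true, level = 0.95) {
  ok <- is.finite(ses) & is.finite(estimates)
  if (!any(ok)) stop("coverage undefined: no replications with finite SEs")
  z <- stats::qnorm(1 - (1 - level) / 2)
  mean(abs(estimates[ok] - theta_true) <= z * ses[ok])
}

#' Classify a criterion value against the design's thresholds
#'
#' Bias criteria (`peb`, `seb`): absolute value at most 0.1 is `acceptable`,
#' between 0.1 and 0.3 is `medium`, above 0.3 is `large`. Coverage: below
#' 0.91 is `low`, within \[0.91, 0.98\] `acceptable`, above 0.98 `high`.
#'
#' @param value criterion value (finite).
#' @param kind `"bias"` for peb/seb, `"coverage"` for coverage rates.
#' @return A classification label string.
#' @export
classify_criteria <- function(value, kind = c("bias", "coverage")) {
  kind <- match.arg(kind)
  stopifnot(is.finite(value))
  if (kind == "bias") {
    v <- abs(value)
    if (v <= 0.1) "acceptable" else if (v <= 0.3) "medium" else "large"
  } else {
    if (value < 0.91) "low" else if (value <= 0.98) "acceptable" else "high"
  }
}

#' Evaluate all free parameters for one design cell
#'
#' Computes peb, seb, MSE and 95% coverage for every free parameter from the
#' included replications of one condition, with threshold classifications.
#'
#' @param fits list of included (post-filter) `lst_fit` objects.
#' @param truth the generating [mixture_params()].
#' @param spec the [lst_model_spec()] used for fitting.
#' @param condition optional [sim_condition()] recorded in the output rows.
#' @param aggregate `"mean"` or `"median"` central tendency for peb/seb.
#' @return A data frame with one row per free parameter: `parameter`,
#'   `true_value`, `peb`, `seb`, `mse`, `coverage`, `n_included`, and the
#'   classification columns `peb_class`, `seb_class`, `coverage_class`.
#' @export
evaluate_condition <- function(fits, truth, spec, condition = NULL,
                               aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(fits) >= 2)
  theta_true <- report_params(truth, spec)
  est <- do.call(rbind, lapply(fits, `[[`, "est_report"))
  ses <- do.call(rbind, lapply(fits, `[[`, "standard_errors"))
  rows <- lapply(spec$free_names, function(nm) {
    e <- est[, nm]; s <- ses[, nm]; tv <- theta_true[[nm]]
    peb <- compute_peb(e, tv, aggregate)
    seb <- tryCatch(compute_seb(s, e, aggregate), error = function(err) NA_real_)
    cov <- tryCatch(compute_coverage(e, s, tv), error = function(err) NA_real_)
    data.frame(parameter = nm, true_value = tv, peb = peb, seb = seb,
               mse = compute_mse(e, tv), coverage = cov,
               n_included = length(e),
               peb_class = classify_criteria(peb, "bias"),
               seb_class = if (is.finite(seb)) classify_criteria(seb, "bias") else NA,
               coverage_class = if (is.finite(cov)) classify_criteria(cov, "coverage") else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(condition)) {
    out <- cbind(data.frame(N = condition$N, j = condition$j,
                            delta_T = condition$delta_T), out)
  }
  out
}

#' Summarize the evaluation table of one design cell
#'
#' Aggregates the per-parameter rows of [evaluate_condition()] into the
#' cell-level summaries used to compare conditions: mean absolute peb, mean
#' absolute seb, mean MSE across parameters, and the number of parameters
#' (out of the free-parameter count) exceeding each cut-off.
#'
#' @param eval_table output of [evaluate_condition()] for one condition.
#' @param n_parameters expected number of parameter rows (error if any are
#'   missing); defaults to the number of rows supplied.
#' @return A list with `mean_abs_peb`, `mean_abs_seb`, `mean_mse`,
#'   `n_exceed_peb`, `n_exceed_seb`, `n_coverage_out` and `n_parameters`.
#' @export
summarize_condition <- function(eval_table, n_parameters = nrow(eval_table)) {
  if (nrow(eval_table) != n_parameters) {
    stop("missing parameter rows: expected ", n_parameters, ", got ",
         nrow(eval_table))
  }
  list(
    mean_abs_peb = mean(abs(eval_table$peb)),
    mean_abs_seb = mean(abs(eval_table$seb), na.rm = TRUE),
    mean_mse = mean(eval_table$mse),
    n_exceed_peb = sum(abs(eval_table$peb) > 0.1),
    n_exceed_seb = sum(abs(eval_table$seb) > 0.1, na.rm = TRUE),
    n_coverage_out = sum(eval_table$coverage < 0.91 | eval_table$coverage > 0.98,
                         na.rm = TRUE),
    n_parameters = n_parameters)
}
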