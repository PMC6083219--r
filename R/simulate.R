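#' Default population parameter fixture
#'
#' The true population values of the original design live in unpublished
#' supplementary material, so this package ships a synthetic,
#' implementer-chosen fixture that obeys every ordering the design states:
#' Class 1 (the larger class, logit 1.15, i.e. 76%) has the lower trait
#' location, the larger trait scale, larger occasion-specific variance and
#' larger error variances, and within each class the first-occasion error
#' variance exceeds the later ones (Socratic effect). The trait skewness
#' `delta_T` is shared by both classes and `nu = 5` in both.
#'
#' These are NOT the original study's values; they are a stand-in with the
#' same qualitative structure.
#'
#' @param delta_T trait skewness used in both classes (design levels 2.8, 6).
#' @param nu degrees of freedom used in both classes (design value 5).
#' @return A [mixture_params()] object with `logit_pi1 = 1.15`.
#' @export
default_truth <- function(delta_T = 2.8, nu = 5) {
  mixture_params(
    list(
      lst_class_params(lambda_T2 = 0.9, alpha_2 = 0.2, mu_T = 1.0,
                       sigma2_T = 0.8, delta_T = delta_T, nu = nu,
                       var_IST2 = 0.3, var_O = 0.5, var_E1 = 0.5,
                       var_Ej = 0.35),
      lst_class_params(lambda_T2 = 1.1, alpha_2 = -0.1, mu_T = 2.0,
                       sigma2_T = 0.3, delta_T = delta_T, nu = nu,
                       var_IST2 = 0.15, var_O = 0.2, var_E1 = 0.25,
                       var_Ej = 0.15)
    ),
    logit_pi1 = 1.15)
}

#' One cell of the Monte Carlo design grid
#'
#' @param N sample size (design levels 125, 250, 500, 1000).
#' @param j number of occasions (design levels 2..6).
#' @param delta_T trait skewness (design levels 2.8, 6).
#' @param n_reps replications planned for this cell (design value 500).
#' @param base_seed integer base seed for the seed scheme.
#' @return An object of class `sim_condition`.
#' @export
sim_condition <- function(N, j, delta_T, n_reps = 500L, base_seed = 1L) {
  stopifnot(N >= 1, j >= 2, j <= 6, n_reps >= 1)
  structure(list(N = as.integer(N), j = as.integer(j),
                 delta_T = as.numeric(delta_T), n_reps = as.integer(n_reps),
                 base_seed = as.integer(base_seed)),
            class = "sim_condition")
}

#' @export
print.sim_condition <- function(x, ...) {
  cat(sprintf("Condition: N = %d, j = %d, delta_T = %g (%d reps, base seed %d)\n",
              x$N, x$j, x$delta_T, x$n_reps, x$base_seed))
  invisible(x)
}

#' Enumerate the full simulation design grid
#'
#' Builds the Cartesian product of the design factors in a stable order
#' (skewness slowest, then occasions, then sample size). The default levels
#' give the 4 x 5 x 2 = 40-cell grid with 500 replications each, i.e. 20,000
#' planned replications.
#'
#' @param N_levels sample sizes.
#' @param j_levels occasion counts.
#' @param delta_levels trait skewness levels.
#' @param n_reps replications per cell.
#' @param base_seed integer base seed.
#' @return A list of [sim_condition()] objects with attribute `grid` (a data
#'   frame of the factor levels, one row per cell).
#' @export
enumerate_conditions <- function(N_levels = c(125, 250, 500, 1000),
                                 j_levels = 2:6,
                                 delta_levels = c(2.8, 6),
                                 n_reps = 500L, base_seed = 1L) {
  if (length(N_levels) == 0 || length(j_levels) == 0 || length(delta_levels) == 0) {
    stop("all factor level lists must be non-empty")
  }
  grid <- expand.grid(N = N_levels, j = j_levels, delta_T = delta_levels,
                      KEEP.OUT.ATTRS = FALSE)
  conds <- lapply(seq_len(nrow(grid)), function(k) {
    sim_condition(grid$N[k], grid$j[k], grid$delta_T[k], n_reps, base_seed)
  })
  attr(conds, "grid") <- grid
  conds
}

# deterministic per-replication seed, kept inside 32-bit integer range so any
# replication is reproducible in isolation
replication_seed <- function(base_seed, cond_index, rep_index) {
  s <- (as.double(base_seed) * 1000003 + as.double(cond_index) * 10007 +
          as.double(rep_index)) %% 2147483629
  as.integer(s) + 1L
}

#' Simulate one replication dataset
#'
#' Draws class labels with \eqn{\pi_1 = \mathrm{logit}^{-1}} of the truth's
#' logit parameter, then draws each row from the model-implied rMST
#' distribution of its class ([build_class_moments()] + [rmst_sample()]).
#' Deterministic given `(base_seed, cond_index, rep_index)`.
#'
#' @param cond a [sim_condition()].
#' @param rep_index replication number within the cell (1-based).
#' @param truth a [mixture_params()] object; its class-1/2 `delta_T` should
#'   equal `cond$delta_T` (checked).
#' @param cond_index index of the condition in its grid, used by the seed
#'   scheme (default 1).
#' @return A list of class `sim_dataset` with elements `data` (`N x 2j`
#'   matrix, columns `y_<indicator>_<occasion>`), `true_class` (labels in
#'   {1,2}, retained for oracle tests only and never used by the estimator),
#'   `condition`, `rep_index` and `seed`.
#' @export
simulate_dataset <- function(cond, rep_index, truth, cond_index = 1L) {
  stopifnot(inherits(cond, "sim_condition"), inherits(truth, "mixture_params"))
  deltas <- vapply(truth$class_params, `[[`, 0, "delta_T")
  if (any(abs(deltas - cond$delta_T) > 1e-12)) {
    stop("truth's delta_T does not match the condition's delta_T level")
  }
  seed <- replication_seed(cond$base_seed, cond_index, rep_index)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  spec <- lst_model_spec(cond$j, n_classes = length(truth$class_params))
  n <- cond$N
  labels <- 1L + (stats::runif(n) > truth$pi[1])
  y <- matrix(NA_real_, n, spec$p, dimnames = list(NULL, observed_names(spec)))
  for (c in seq_along(truth$class_params)) {
    idx <- which(labels == c)
    if (length(idx) > 0) {
      pars <- build_class_moments(spec, truth$class_params[[c]])
      y[idx, ] <- rmst_sample(pars, length(idx))
    }
  }
  structure(list(data = y, true_class = labels, condition = cond,
                 rep_index = as.integer(rep_index), seed = seed),
            class = "sim_dataset")
}

#' Factor-wise generator for one class
#'
#' Generates observed data by explicitly drawing each latent component
#' (trait, indicator-specific trait residual, occasion factors, errors)
#' rather than sampling the observed vector directly. With
#' `mixing = "shared"` all symmetric components are divided by the same
#' \eqn{\sqrt{W}} as the trait's half-normal part, so the observed vector is
#' exactly rMST and this routine is an independent oracle for
#' [build_class_moments()]. With `mixing = "independent"` the O, IST and E
#' components are plain normals (the literal reading of the model equations),
#' which is only approximately rMST at finite `nu`.
#'
#' @param spec an [lst_model_spec()].
#' @param cp an [lst_class_params()].
#' @param n number of rows.
#' @param mixing `"shared"` (exact rMST) or `"independent"`.
#' @param seed optional integer seed.
#' @return An `n x 2j` matrix of observed scores.
#' @export
simulate_lst_factors <- function(spec, cp, n,
                                 mixing = c("shared", "independent"),
                                 seed = NULL) {
  mixing <- match.arg(mixing)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  j <- spec$n_occasions
  w <- stats::rgamma(n, shape = cp$nu / 2, rate = cp$nu / 2)
  sw <- if (mixing == "shared") sqrt(w) else rep(1, n)
  # trait: mu_T + (delta_T |U0| + N(0, sigma2_T)) / sqrt(W), always t-mixed
  xi <- (cp$delta_T * abs(stats::rnorm(n)) +
           stats::rnorm(n, 0, sqrt(cp$sigma2_T))) / sqrt(w)
  trait <- cp$mu_T + xi
  ist <- stats::rnorm(n, 0, sqrt(cp$var_IST2)) / sw
  o <- matrix(stats::rnorm(n * j, 0, sqrt(cp$var_O)), n, j) / sw
  y <- matrix(NA_real_, n, spec$p, dimnames = list(NULL, observed_names(spec)))
  for (jj in seq_len(j)) {
    sdE <- if (jj == 1L) sqrt(cp$var_E1) else sqrt(cp$var_Ej)
    e1 <- stats::rnorm(n, 0, sdE) / sw
    e2 <- stats::rnorm(n, 0, sdE) / sw
    y[, 2 * jj - 1L] <- trait + o[, jj] + e1
    y[, 2 * jj] <- cp$alpha_2 + cp$lambda_T2 * trait + ist + o[, jj] + e2
  }
  y
}

#' Write / read a simulated dataset as delimited text
#'
#' The dataset is stored as a CSV with the observed columns
#' `y_<indicator>_<occasion>` followed by `true_class`; the condition and
#' seed are stored in a JSON manifest next to it (same path with extension
#' `.manifest.json`).
#'
#' @param ds a `sim_dataset` from [simulate_dataset()].
#' @param path CSV file path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `sim_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "sim_dataset"))
  df <- data.frame(ds$data, check.names = FALSE)
  df$true_class <- ds$true_class
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- list(N = ds$condition$N, j = ds$condition$j,
                   delta_T = ds$condition$delta_T,
                   n_reps = ds$condition$n_reps,
                   base_seed = ds$condition$base_seed,
                   rep_index = ds$rep_index, seed = ds$seed)
  jsonlite::write_json(manifest, manifest_path(path), auto_unbox = TRUE)
  invisible(path)
}

manifest_path <- function(path) sub("\\.csv$", "", path) |> paste0(".manifest.json")

#' @rdname write_dataset
#' @param path CSV file path previously written by [write_dataset()].
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  man <- jsonlite::read_json(manifest_path(path), simplifyVector = TRUE)
  y <- as.matrix(df[, setdiff(names(df), "true_class"), drop = FALSE])
  cond <- sim_condition(man$N, man$j, man$delta_T, man$n_reps, man$base_seed)
  structure(list(data = y, true_class = as.integer(df$true_class),
                 condition = cond, rep_index = as.integer(man$rep_index),
                 seed = as.integer(man$seed)),
            class = "sim_dataset")
}
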