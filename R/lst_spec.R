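#' Mixture latent state-trait model specification
#'
#' Describes the structure of the measurement-invariant latent state-trait
#' (LST) model used throughout the package: two indicators per occasion, a
#' common trait `T`, one indicator-specific trait residual factor `IST_2`,
#' one occasion-specific factor `O_j` per occasion, and measurement errors
#' `E_ij`. Within each latent class the observed variable is
#' \deqn{Y_{ijc} = \alpha_{ic} + \lambda_{Tic} T_c + \lambda_{Iic} IST_{ic}
#'   + O_{jc} + E_{ijc},}
#' under strict measurement invariance over time (equal intercepts, loadings
#' and occasion-specific variances) except that the first occasion carries its
#' own, larger, error variance (the Socratic effect). Identification fixes
#' \eqn{\lambda_{T1c} = \lambda_{I2c} = \lambda_{O1c} = \lambda_{O2c} = 1}
#' and \eqn{\alpha_{1c} = 0}; the `IST` and `O` factors have zero means.
#'
#' The trait is \eqn{T_c = \mu_{Tc} + \xi_{Tc}} with
#' \eqn{\xi_{Tc} \sim rMST(0, \sigma^2_{Tc}, \delta_{Tc}, \nu_c)}; all other
#' latent components are symmetric. Under the shared t-mixing construction
#' (all components within a class divided by the same \eqn{\sqrt{W}}) the
#' observed `2j`-vector is exactly rMST, which yields the closed-form mixture
#' likelihood used by [fit_mixture()].
#'
#' @param n_occasions number of measurement occasions `j`, between 2 and 6.
#' @param n_classes number of latent classes, 1 or 2.
#' @param n_indicators number of indicators per occasion; fixed at 2.
#' @param fix_delta optional numeric: fix the trait skewness \eqn{\delta_T} at
#'   this value in every class instead of estimating it.
#' @param fix_nu optional numeric: fix the degrees of freedom \eqn{\nu} at
#'   this value in every class instead of estimating it.
#' @return An object of class `lst_model_spec` with the observed dimension
#'   `p = 2 * n_occasions`, the constraint map (see [constraint_map()]) and
#'   the free-parameter template used by [pack_params()].
#' @seealso [lst_class_params()], [mixture_params()], [build_class_moments()],
#'   [count_free_parameters()]
#' @export
lst_model_spec <- function(n_occasions, n_classes = 2L, n_indicators = 2L,
                           fix_delta = NULL, fix_nu = NULL) {
  n_occasions <- as.integer(n_occasions)
  n_classes <- as.integer(n_classes)
  if (n_indicators != 2L) stop("the design uses exactly 2 indicators")
  if (n_occasions < 2L || n_occasions > 6L) stop("'n_occasions' must be in 2..6")
  if (!n_classes %in% c(1L, 2L)) stop("'n_classes' must be 1 or 2")
  spec <- structure(
    list(n_indicators = 2L, n_occasions = n_occasions, n_classes = n_classes,
         p = 2L * n_occasions, fix_delta = fix_delta, fix_nu = fix_nu),
    class = "lst_model_spec")
  spec$constraint_map <- constraint_map(spec)
  spec$free_names <- free_parameter_names(spec)
  spec
}

#' @export
print.lst_model_spec <- function(x, ...) {
  cat("Mixture LST model spec: 2 indicators x", x$n_occasions, "occasions,",
      x$n_classes, if (x$n_classes == 1) "class;" else "classes;",
      count_free_parameters(x), "free parameters\n")
  if (!is.null(x$fix_delta)) cat("  delta_T fixed at", x$fix_delta, "\n")
  if (!is.null(x$fix_nu)) cat("  nu fixed at", x$fix_nu, "\n")
  invisible(x)
}

# names of per-class structural parameters on the reporting scale
CLASS_PARAM_NAMES <- c("lambda_T2", "alpha_2", "mu_T", "sigma2_T", "delta_T",
                       "nu", "var_IST2", "var_O", "var_E1", "var_Ej")
# which of those are positivity-constrained (log-transformed when packed)
CLASS_LOG_PARAMS <- c("sigma2_T", "var_IST2", "var_O", "var_E1", "var_Ej")
NU_LOWER <- 2.1
NU_UPPER <- 10000

#' Constraint map of the saturated LST parameterization
#'
#' Enumerates every parameter of the saturated per-class LST measurement
#' model (all intercepts, loadings, factor means/variances, error variances,
#' plus the trait skewness/degrees of freedom and the class logit) and marks
#' it as `fixed` (with its fixed value), or assigns it to a free equality
#' class. [count_free_parameters()] counts the distinct equality classes, so
#' the identification and measurement-invariance rules — not a hard-coded
#' constant — determine the free-parameter count.
#'
#' @param spec an [lst_model_spec()].
#' @return A data frame with columns `parameter`, `class`, `occasion`,
#'   `indicator`, `status` (`"fixed"`/`"free"`), `fixed_value` and
#'   `free_group` (equality-class label, `NA` when fixed).
#' @export
constraint_map <- function(spec) {
  j <- spec$n_occasions
  rows <- list()
  add <- function(parameter, class, occasion, indicator, status, fixed_value,
                  free_group) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, class = class, occasion = occasion,
      indicator = indicator, status = status, fixed_value = fixed_value,
      free_group = free_group, stringsAsFactors = FALSE)
  }
  for (c in seq_len(spec$n_classes)) {
    cc <- paste0("c", c)
    for (jj in seq_len(j)) {
      for (i in 1:2) {
        # intercepts: alpha_1c fixed to 0, alpha_2c free, time-invariant
        if (i == 1L) {
          add("alpha", c, jj, i, "fixed", 0, NA)
        } else {
          add("alpha", c, jj, i, "free", NA, paste0("alpha_2_", cc))
        }
        # trait loadings: lambda_T1c fixed to 1, lambda_T2c free, invariant
        if (i == 1L) {
          add("lambda_T", c, jj, i, "fixed", 1, NA)
        } else {
          add("lambda_T", c, jj, i, "free", NA, paste0("lambda_T2_", cc))
        }
        # IST loading exists for i = 2 only and is fixed to 1
        if (i == 2L) add("lambda_I", c, jj, i, "fixed", 1, NA)
        # occasion loadings both fixed to 1 (two-indicator residual factor)
        add("lambda_O", c, jj, i, "fixed", 1, NA)
        # error variances: occasion 1 has its own value, j > 1 share one,
        # equal across indicators
        grp <- if (jj == 1L) paste0("var_E1_", cc) else paste0("var_Ej_", cc)
        add("var_E", c, jj, i, "free", NA, grp)
      }
      # occasion-specific factor: zero mean, time-invariant variance
      add("mean_O", c, jj, NA, "fixed", 0, NA)
      add("var_O", c, jj, NA, "free", NA, paste0("var_O_", cc))
    }
    # trait location/scale/skewness/df and IST residual factor
    add("mu_T", c, NA, NA, "free", NA, paste0("mu_T_", cc))
    add("sigma2_T", c, NA, NA, "free", NA, paste0("sigma2_T_", cc))
    if (is.null(spec$fix_delta)) {
      add("delta_T", c, NA, NA, "free", NA, paste0("delta_T_", cc))
    } else {
      add("delta_T", c, NA, NA, "fixed", spec$fix_delta, NA)
    }
    if (is.null(spec$fix_nu)) {
      add("nu", c, NA, NA, "free", NA, paste0("nu_", cc))
    } else {
      add("nu", c, NA, NA, "fixed", spec$fix_nu, NA)
    }
    add("mean_IST2", c, NA, NA, "fixed", 0, NA)
    add("var_IST2", c, NA, NA, "free", NA, paste0("var_IST2_", cc))
  }
  if (spec$n_classes > 1L) {
    add("logit_pi1", NA, NA, NA, "free", NA, "logit_pi1")
  }
  do.call(rbind, rows)
}

#' Count free parameters of a mixture LST specification
#'
#' Counts the distinct equality classes of free parameters in the
#' [constraint_map()], i.e. the length of the packed parameter vector. For
#' the two-class design with free skewness and degrees of freedom this is 21
#' (10 per class plus the mixing logit) regardless of the number of
#' occasions.
#'
#' @param spec an [lst_model_spec()].
#' @return Integer count of free parameters.
#' @export
count_free_parameters <- function(spec) {
  cm <- spec$constraint_map
  length(unique(cm$free_group[cm$status == "free"]))
}

# ordered names of the free parameters (reporting scale), classes first
free_parameter_names <- function(spec) {
  nm <- character(0)
  keep <- CLASS_PARAM_NAMES
  if (!is.null(spec$fix_delta)) keep <- setdiff(keep, "delta_T")
  if (!is.null(spec$fix_nu)) keep <- setdiff(keep, "nu")
  for (c in seq_len(spec$n_classes)) nm <- c(nm, paste0(keep, "_c", c))
  if (spec$n_classes > 1L) nm <- c(nm, "logit_pi1")
  nm
}

#' Per-class structural parameters of the LST model
#'
#' @param lambda_T2 trait loading of indicator 2.
#' @param alpha_2 intercept of indicator 2.
#' @param mu_T trait location parameter.
#' @param sigma2_T trait scale parameter (> 0).
#' @param delta_T trait skewness parameter.
#' @param nu degrees of freedom (> 2).
#' @param var_IST2 variance of the indicator-specific trait residual (> 0).
#' @param var_O occasion-specific variance, equal over occasions (> 0).
#' @param var_E1 error variance at the first occasion (> 0).
#' @param var_Ej error variance at occasions j > 1 (> 0).
#' @return An object of class `lst_class_params`.
#' @export
lst_class_params <- function(lambda_T2, alpha_2, mu_T, sigma2_T, delta_T, nu,
                             var_IST2, var_O, var_E1, var_Ej) {
  vars <- c(sigma2_T = sigma2_T, var_IST2 = var_IST2, var_O = var_O,
            var_E1 = var_E1, var_Ej = var_Ej)
  if (any(!is.finite(vars)) || any(vars <= 0)) {
    stop("variance/scale parameters must be positive: ",
         paste(names(vars)[!(is.finite(vars) & vars > 0)], collapse = ", "))
  }
  if (nu <= 2) stop("'nu' must be > 2")
  structure(list(lambda_T2 = lambda_T2, alpha_2 = alpha_2, mu_T = mu_T,
                 sigma2_T = sigma2_T, delta_T = delta_T, nu = nu,
                 var_IST2 = var_IST2, var_O = var_O, var_E1 = var_E1,
                 var_Ej = var_Ej),
            class = "lst_class_params")
}

#' Full mixture parameter set
#'
#' @param class_params list of [lst_class_params()], one per class.
#' @param logit_pi1 log-odds of membership in Class 1 (ignored for a
#'   single-class model).
#' @return An object of class `mixture_params` with element `pi` holding the
#'   implied mixing proportions.
#' @export
mixture_params <- function(class_params, logit_pi1 = 0) {
  stopifnot(is.list(class_params),
            all(vapply(class_params, inherits, TRUE, "lst_class_params")))
  k <- length(class_params)
  pi1 <- stats::plogis(logit_pi1)
  pis <- if (k == 1L) 1 else c(pi1, 1 - pi1)
  structure(list(class_params = class_params, logit_pi1 = logit_pi1, pi = pis),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  k <- length(x$class_params)
  cat("Mixture LST parameters,", k, if (k == 1) "class\n" else "classes\n")
  if (k > 1) cat("  pi:", paste(signif(x$pi, 4), collapse = " "),
                 " (logit_pi1 =", signif(x$logit_pi1, 4), ")\n")
  tab <- do.call(rbind, lapply(x$class_params, function(cp)
    unlist(cp[CLASS_PARAM_NAMES])))
  rownames(tab) <- paste0("class ", seq_len(k))
  print(round(tab, 4))
  invisible(x)
}

# observed-variable layout: occasion-major, indicator fastest:
# (y_1_1, y_2_1, y_1_2, y_2_2, ...) with names y_<indicator>_<occasion>
observed_names <- function(spec) {
  as.vector(outer(1:2, seq_len(spec$n_occasions),
                  function(i, j) paste0("y_", i, "_", j)))
}

#' Model-implied observed-variable distribution of one class
#'
#' Maps class parameters to the rMST distribution of the observed
#' `p = 2j`-vector. With loading matrix \eqn{\Lambda} stacking the trait
#' column (1, \eqn{\lambda_{T2}} per occasion), the IST column (0, 1 per
#' occasion) and one indicator column of ones per occasion factor:
#' \eqn{\mu = \alpha + \Lambda_T \mu_T},
#' \eqn{\Sigma = \Lambda\,\mathrm{diag}(\sigma^2_T, Var(IST_2), Var(O),
#' \ldots)\,\Lambda' + \Theta}, \eqn{\delta_{obs} = \Lambda_T \delta_T},
#' and \eqn{\nu} carried over. This is exact under shared t-mixing of all
#' latent components within the class.
#'
#' @param spec an [lst_model_spec()].
#' @param cp an [lst_class_params()].
#' @return An [rmst_params()] object of dimension `2 * n_occasions`.
#' @export
build_class_moments <- function(spec, cp) {
  stopifnot(inherits(spec, "lst_model_spec"), inherits(cp, "lst_class_params"))
  j <- spec$n_occasions
  p <- spec$p
  lambda_T <- rep(c(1, cp$lambda_T2), j)
  lambda_I <- rep(c(0, 1), j)
  lambda_O <- matrix(0, p, j)
  for (jj in seq_len(j)) lambda_O[2 * jj - (1:0), jj] <- 1
  lambda <- cbind(lambda_T, lambda_I, lambda_O)
  phi <- diag(c(cp$sigma2_T, cp$var_IST2, rep(cp$var_O, j)), nrow = j + 2L)
  theta <- diag(rep(c(cp$var_E1, rep(cp$var_Ej, j - 1L)), each = 2L), nrow = p)
  mu <- rep(c(0, cp$alpha_2), j) + lambda_T * cp$mu_T
  sigma <- lambda %*% phi %*% t(lambda) + theta
  out <- rmst_params(mu = mu, sigma = sigma, delta = lambda_T * cp$delta_T,
                     nu = cp$nu)
  names(out$mu) <- observed_names(spec)
  out
}

#' Pack mixture parameters into a free-parameter vector
#'
#' `pack_params()` maps a [mixture_params()] object to the packed vector used
#' by the optimizer; `unpack_params()` is its exact inverse. Transforms are
#' log for variances/scales, `log(nu - 2.1)` for degrees of freedom, and
#' identity for loadings, intercepts, locations, skewness and the logit, so
#' a packed vector of zeros decodes to unit variances, `nu = 3.1` and
#' `pi_1 = 0.5`.
#'
#' @param mp a [mixture_params()] object.
#' @param spec an [lst_model_spec()].
#' @return `pack_params()`: a named numeric vector of length
#'   `count_free_parameters(spec)`. `unpack_params()`: a [mixture_params()].
#' @export
pack_params <- function(mp, spec) {
  stopifnot(inherits(mp, "mixture_params"), inherits(spec, "lst_model_spec"))
  theta <- numeric(0)
  for (c in seq_len(spec$n_classes)) {
    cp <- mp$class_params[[c]]
    for (nm in CLASS_PARAM_NAMES) {
      if (nm == "delta_T" && !is.null(spec$fix_delta)) next
      if (nm == "nu" && !is.null(spec$fix_nu)) next
      val <- cp[[nm]]
      packed <- if (nm %in% CLASS_LOG_PARAMS) log(val)
                else if (nm == "nu") log(val - NU_LOWER)
                else val
      theta <- c(theta, packed)
    }
  }
  if (spec$n_classes > 1L) theta <- c(theta, mp$logit_pi1)
  names(theta) <- spec$free_names
  theta
}

#' @rdname pack_params
#' @param theta packed free-parameter vector.
#' @export
unpack_params <- function(theta, spec) {
  stopifnot(inherits(spec, "lst_model_spec"))
  k <- count_free_parameters(spec)
  if (length(theta) != k) {
    stop("'theta' must have length ", k, ", got ", length(theta))
  }
  names(theta) <- spec$free_names
  cps <- vector("list", spec$n_classes)
  for (c in seq_len(spec$n_classes)) {
    args <- list()
    for (nm in CLASS_PARAM_NAMES) {
      if (nm == "delta_T" && !is.null(spec$fix_delta)) {
        args[[nm]] <- spec$fix_delta; next
      }
      if (nm == "nu" && !is.null(spec$fix_nu)) {
        args[[nm]] <- spec$fix_nu; next
      }
      val <- theta[[paste0(nm, "_c", c)]]
      args[[nm]] <- if (nm %in% CLASS_LOG_PARAMS) exp(val)
                    else if (nm == "nu") NU_LOWER + exp(val)
                    else val
    }
    cps[[c]] <- do.call(lst_class_params, args)
  }
  logit <- if (spec$n_classes > 1L) theta[["logit_pi1"]] else 0
  mixture_params(cps, logit)
}

#' True parameter values on the reporting scale
#'
#' Returns the named vector of free-parameter values on the raw (reporting)
#' scale, ordered as in [pack_params()]. Used as the truth vector by the
#' evaluation module.
#'
#' @param mp a [mixture_params()] object.
#' @param spec an [lst_model_spec()].
#' @return Named numeric vector of length `count_free_parameters(spec)`.
#' @export
report_params <- function(mp, spec) {
  theta <- numeric(0)
  for (c in seq_len(spec$n_classes)) {
    cp <- mp$class_params[[c]]
    for (nm in CLASS_PARAM_NAMES) {
      if (nm == "delta_T" && !is.null(spec$fix_delta)) next
      if (nm == "nu" && !is.null(spec$fix_nu)) next
      theta <- c(theta, cp[[nm]])
    }
  }
  if (spec$n_classes > 1L) theta <- c(theta, mp$logit_pi1)
  names(theta) <- spec$free_names
  theta
}

# jacobian d(report)/d(packed) at a packed point; diagonal because the
# transforms are coordinate-wise
report_jacobian_diag <- function(theta, spec) {
  nm <- spec$free_names
  out <- rep(1, length(theta))
  logp <- grepl(paste0("^(", paste(CLASS_LOG_PARAMS, collapse = "|"), ")_c"), nm)
  out[logp] <- exp(theta[logp])
  nup <- grepl("^nu_c", nm)
  out[nup] <- exp(theta[nup])
  out
}
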