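#' Profile likelihood of one fitted parameter
#'
#' Computes the profile negative log-likelihood of a parameter over a
#' log-spaced grid spanning one decade either side of its MLE (the
#' window within which non-crossing confidence bounds are reported as
#' infinite): at each grid value the parameter is held fixed and all
#' other free parameters are re-optimized, warm-started from the
#' neighbouring grid point, walking outward from the MLE.
#'
#' @param fit A [cfe_fit()] result.
#' @param data The titration dataset the fit was made on.
#' @param parameter Name of a free parameter of the fit.
#' @param n_grid Number of grid points (odd values center the grid on the
#'   MLE).
#' @param span Half-window as a multiplicative factor (default 10, i.e.
#'   one decade either side).
#' @param control Optimizer control passed to the re-optimizations
#'   (see [cfe_fit()]).
#' @return A tibble of class `cfe_profile` with columns `parameter`,
#'   `value`, `nll`, `converged`; attributes `nll_hat`, `theta_hat_i`,
#'   `df` (the fit's free-parameter count) and `window`.
#' @seealso [likelihood_ci()] to extract confidence bounds.
#' @export
cfe_profile <- function(fit, data, parameter, n_grid = 21, span = 10,
                        control = list()) {
  stopifnot(inherits(fit, "cfe_fit"))
  if (!parameter %in% fit$free) {
    stop("'", parameter, "' is not a free parameter of the fit",
         call. = FALSE)
  }
  data <- as_titration(data)
  ctrl <- utils::modifyList(list(lm_maxiter = 30, polish_maxit = 60),
                            control)
  th_i <- fit$theta_hat[[parameter]]
  grid <- 10^seq(log10(th_i / span), log10(th_i * span),
                 length.out = n_grid)
  others <- setdiff(fit$free, parameter)

  eval_point <- function(value, warm) {
    if (length(others) == 0) {
      p <- fit$theta_hat
      p[parameter] <- value
      return(list(nll = cfe_nll(p, fit$variant, data, fit$noise),
                  warm = warm, ok = TRUE))
    }
    sub <- tryCatch(
      cfe_fit(data, fit$variant, free = others,
              fixed = c(fit$fixed,
                        stats::setNames(value, parameter)),
              bounds = fit$bounds[others],
              noise = fit$noise, start = warm, control = ctrl),
      error = function(e) NULL)
    if (is.null(sub)) {
      return(list(nll = NA_real_, warm = warm, ok = FALSE))
    }
    list(nll = sub$nll_hat, warm = sub$theta_hat[others], ok = TRUE)
  }

  i0 <- which.min(abs(log10(grid) - log10(th_i)))
  nll <- rep(NA_real_, n_grid)
  ok <- rep(FALSE, n_grid)
  warm0 <- fit$theta_hat[others]
  for (dir in list(i0:n_grid, rev(seq_len(i0)))) {
    warm <- warm0
    for (i in dir) {
      if (i == i0 && ok[i0]) next
      res <- eval_point(grid[i], warm)
      nll[i] <- res$nll
      ok[i] <- res$ok
      if (res$ok) warm <- res$warm
    }
  }

  out <- tibble::tibble(parameter = parameter, value = grid,
                        nll = nll, converged = ok)
  class(out) <- c("cfe_profile", class(out))
  attr(out, "nll_hat") <- fit$nll_hat
  attr(out, "theta_hat_i") <- th_i
  attr(out, "df") <- fit$k
  attr(out, "window") <- c(th_i / span, th_i * span)
  out
}

#' Profile an arbitrary negative log-likelihood
#'
#' Generic profiling engine for a user-supplied objective: the target
#' parameter is fixed at each point of a log-spaced grid around its
#' estimate and the objective is minimized over the remaining parameters
#' (Nelder-Mead in log10 space, warm-started from the neighbouring grid
#' point). Useful for toy likelihoods and for models outside the
#' resource-limited family.
#'
#' @param objective Function taking a full named parameter vector
#'   (natural scale) and returning a scalar NLL.
#' @param theta_hat Named vector of estimates (all strictly positive;
#'   profiling is done multiplicatively).
#' @param parameter Name of the parameter to profile.
#' @param n_grid,span Grid size and half-window factor (see
#'   [cfe_profile()]).
#' @return A `cfe_profile` tibble (see [cfe_profile()]); `df` defaults to
#'   `length(theta_hat)`.
#' @export
profile_nll <- function(objective, theta_hat, parameter, n_grid = 21,
                        span = 10) {
  stopifnot(parameter %in% names(theta_hat), all(theta_hat > 0))
  th_i <- theta_hat[[parameter]]
  grid <- 10^seq(log10(th_i / span), log10(th_i * span),
                 length.out = n_grid)
  others <- setdiff(names(theta_hat), parameter)

  eval_point <- function(value, warm) {
    full <- function(lp_others) {
      th <- c(stats::setNames(value, parameter),
              stats::setNames(10^lp_others, others))
      objective(th[names(theta_hat)])
    }
    if (length(others) == 0) {
      return(list(nll = full(numeric(0)), warm = numeric(0)))
    }
    op <- stats::optim(warm, full,
                       method = if (length(others) == 1) "Brent"
                                else "Nelder-Mead",
                       lower = if (length(others) == 1) warm - 6 else -Inf,
                       upper = if (length(others) == 1) warm + 6 else Inf,
                       control = list(maxit = 500, reltol = 1e-12))
    list(nll = op$value, warm = op$par)
  }

  i0 <- which.min(abs(log10(grid) - log10(th_i)))
  nll <- rep(NA_real_, n_grid)
  warm0 <- log10(theta_hat[others])
  done0 <- FALSE
  for (dir in list(i0:n_grid, rev(seq_len(i0)))) {
    warm <- warm0
    for (i in dir) {
      if (i == i0 && done0) next
      res <- eval_point(grid[i], warm)
      nll[i] <- res$nll
      warm <- res$warm
      if (i == i0) done0 <- TRUE
    }
  }
  nll_hat <- objective(theta_hat)
  out <- tibble::tibble(parameter = parameter, value = grid,
                        nll = nll, converged = TRUE)
  class(out) <- c("cfe_profile", class(out))
  attr(out, "nll_hat") <- min(nll_hat, min(nll, na.rm = TRUE))
  attr(out, "theta_hat_i") <- th_i
  attr(out, "df") <- length(theta_hat)
  attr(out, "window") <- c(th_i / span, th_i * span)
  out
}

#' Likelihood-based confidence interval from a profile
#'
#' The interval is the connected region around the estimate where the
#' profiled negative log-likelihood stays below
#' \eqn{NLL(\hat\theta) + \chi^2(\alpha, df)/2}. Crossings are located by
#' linear interpolation between grid points; a side on which the
#' threshold is never crossed within the profiled window is reported as
#' `-Inf` / `+Inf` (non- or weakly-identifiable within that window,
#' conventionally one decade either side of the MLE).
#'
#' The `df = k` convention (all free parameters of the model) follows the
#' simultaneous-interval reading of the threshold and is wider than the
#' pointwise `df = 1` convention, which can be requested explicitly.
#'
#' @param profile A `cfe_profile` tibble (or any tibble with `value` and
#'   `nll` columns sorted by `value`).
#' @param nll_hat NLL at the MLE; defaults to the profile's attribute.
#' @param alpha Confidence level (default 0.95).
#' @param df Degrees of freedom of the chi-squared threshold; defaults to
#'   the profile's `df` attribute (the fit's free-parameter count).
#' @return A one-row tibble: `parameter`, `ci_low`, `ci_high`,
#'   `threshold`, `alpha`, `df`.
#' @export
#' @examples
#' # quadratic toy NLL 0.5*((theta-1)/0.1)^2: CI = 1 +/- 0.1*sqrt(3.84)
#' grid <- 10^seq(-1, 1, length.out = 401)
#' prof <- tibble::tibble(parameter = "theta", value = grid,
#'                        nll = 0.5 * ((grid - 1) / 0.1)^2)
#' likelihood_ci(prof, nll_hat = 0, df = 1)
likelihood_ci <- function(profile, nll_hat = NULL, alpha = 0.95, df = NULL) {
  nll_hat <- nll_hat %||% attr(profile, "nll_hat")
  df <- df %||% attr(profile, "df")
  if (is.null(nll_hat) || is.null(df)) {
    stop("nll_hat and df must be given (or present as attributes)",
         call. = FALSE)
  }
  keep <- is.finite(profile$nll)
  value <- profile$value[keep]
  nll <- profile$nll[keep]
  if (length(value) < 2) stop("profile has too few usable points",
                              call. = FALSE)
  threshold <- nll_hat + stats::qchisq(alpha, df) / 2
  i0 <- which.min(nll)
  if (nll[i0] > threshold + 1e-6) {
    stop("profile minimum lies above the confidence threshold; ",
         "profile and nll_hat are inconsistent", call. = FALSE)
  }

  cross <- function(idx_out, idx_in) {
    # interpolate between the inside point (below) and outside (above)
    v_in <- value[idx_in]; v_out <- value[idx_out]
    f_in <- nll[idx_in]; f_out <- nll[idx_out]
    v_in + (v_out - v_in) * (threshold - f_in) / (f_out - f_in)
  }
  ci_low <- -Inf
  if (i0 > 1) {
    above <- which(nll[seq_len(i0 - 1)] > threshold)
    if (length(above) > 0) {
      j <- max(above)  # nearest point above threshold on the left
      ci_low <- cross(j, j + 1)
    }
  }
  ci_high <- Inf
  if (i0 < length(nll)) {
    above <- which(nll > threshold & seq_along(nll) > i0)
    if (length(above) > 0) {
      j <- min(above)
      ci_high <- cross(j, j - 1)
    }
  }
  tibble::tibble(
    parameter = profile$parameter[1] %||% NA_character_,
    ci_low = ci_low, ci_high = ci_high,
    threshold = threshold, alpha = alpha, df = df
  )
}
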