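#' Noise model specification for the likelihood
#'
#' Measurement errors are modelled as independent Gaussians per channel
#' (mRNA and protein). The channel standard deviations can be supplied
#' (`"fixed"`), estimated from the replicate scatter pooled over time
#' points (`"pooled"`, requires replicated experiments), or profiled out
#' analytically (`"concentrated"`: \eqn{\hat\sigma_c^2 = RSS_c/n_c}, giving
#' the concentrated negative log-likelihood
#' \eqn{n_c/2\,(\log(2\pi RSS_c/n_c) + 1)} per channel).
#'
#' @param method One of `"fixed"`, `"pooled"`, `"concentrated"`.
#' @param sd_rna,sd_protein Channel standard deviations in nM (required
#'   for `"fixed"`).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(method = c("pooled", "fixed", "concentrated"),
                       sd_rna = NULL, sd_protein = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(sd_rna) || is.null(sd_protein) ||
        sd_rna <= 0 || sd_protein <= 0) {
      stop("fixed noise requires positive sd_rna and sd_protein",
           call. = FALSE)
    }
  }
  structure(list(method = method, sd_rna = sd_rna, sd_protein = sd_protein),
            class = "noise_spec")
}

# replace "pooled" by per-channel SDs estimated from replicate scatter
resolve_noise <- function(noise, data) {
  if (noise$method != "pooled") return(noise)
  pooled <- data |>
    dplyr::group_by(.data$template_kind, .data$template_nM, .data$time_h) |>
    dplyr::summarise(n = dplyr::n(),
                     v_rna = stats::var(.data$rna_nM),
                     v_prot = stats::var(.data$protein_nM),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= 2)
  if (nrow(pooled) == 0) {
    stop("pooled noise estimation requires replicated measurements",
         call. = FALSE)
  }
  noise_spec("fixed",
             sd_rna = sqrt(mean(pooled$v_rna)),
             sd_protein = sqrt(mean(pooled$v_prot)))
}

# model predictions matched to every data row
predict_titration <- function(params, variant, data) {
  conds <- titration_conditions(data)
  sims <- purrr::pmap(conds, function(template_kind, template_nM, times) {
    tr <- cfe_simulate(
      params, variant,
      dna0 = if (template_kind == "dna") template_nM else 0,
      rna0 = if (template_kind == "rna") template_nM else 0,
      times = if (times[1] == 0) times else c(0, times)
    )
    tr <- tr[tr$time_h %in% times, ]
    tibble::tibble(template_kind = template_kind,
                   template_nM = template_nM,
                   time_h = tr$time_h,
                   pred_rna = tr$observed_rna_nM,
                   pred_protein = tr$observed_protein_nM)
  })
  dplyr::left_join(
    data, dplyr::bind_rows(sims),
    by = c("template_kind", "template_nM", "time_h")
  )
}

# Sentinel pseudo-NLL returned when the solver fails at extreme parameters,
# so that an optimizer sees a very bad but finite objective.
NLL_PENALTY <- 1e10

# Precomputed evaluation context: unique simulation conditions, row
# indices into the data, and observation vectors. Built once per fit so
# that repeated NLL/residual evaluations stay cheap.
make_nll_ctx <- function(data, variant, noise, rtol = 1e-8,
                         atol = 1e-10) {
  conds <- titration_conditions(data)
  key <- paste(data$template_kind, data$template_nM)
  per_cond <- purrr::pmap(conds, function(template_kind, template_nM,
                                          times) {
    rows <- which(key == paste(template_kind, template_nM))
    list(kind = template_kind, conc = template_nM, times = times,
         rows = rows, idx = match(data$time_h[rows], times))
  })
  list(per_cond = per_cond, obs_rna = data$rna_nM,
       obs_protein = data$protein_nM, n = nrow(data),
       variant = variant, noise = noise, rtol = rtol, atol = atol)
}

ctx_predict <- function(params, ctx) {
  pr <- numeric(ctx$n)
  pp <- numeric(ctx$n)
  for (cd in ctx$per_cond) {
    sim <- sim_observed(params, ctx$variant,
                        dna0 = if (cd$kind == "dna") cd$conc else 0,
                        rna0 = if (cd$kind == "rna") cd$conc else 0,
                        times = cd$times,
                        rtol = ctx$rtol, atol = ctx$atol)
    if (is.null(sim)) return(NULL)
    pr[cd$rows] <- sim$rna[cd$idx]
    pp[cd$rows] <- sim$protein[cd$idx]
  }
  list(rna = pr, protein = pp)
}

ctx_nll <- function(params, ctx) {
  pred <- ctx_predict(params, ctx)
  if (is.null(pred)) return(NLL_PENALTY)
  r_rna <- ctx$obs_rna - pred$rna
  r_prot <- ctx$obs_protein - pred$protein
  n <- ctx$n
  if (ctx$noise$method == "concentrated") {
    n / 2 * (log(2 * pi * max(sum(r_rna^2), 1e-300) / n) + 1) +
      n / 2 * (log(2 * pi * max(sum(r_prot^2), 1e-300) / n) + 1)
  } else {
    n / 2 * log(2 * pi * ctx$noise$sd_rna^2) +
      sum(r_rna^2) / (2 * ctx$noise$sd_rna^2) +
      n / 2 * log(2 * pi * ctx$noise$sd_protein^2) +
      sum(r_prot^2) / (2 * ctx$noise$sd_protein^2)
  }
}

# weighted residuals (fixed-sigma noise only): NLL = const + sum(w^2)/2
ctx_wres <- function(params, ctx) {
  pred <- ctx_predict(params, ctx)
  if (is.null(pred)) return(rep(sqrt(NLL_PENALTY / ctx$n), 2 * ctx$n))
  c((ctx$obs_rna - pred$rna) / ctx$noise$sd_rna,
    (ctx$obs_protein - pred$protein) / ctx$noise$sd_protein)
}

#' Negative log-likelihood of model parameters given titration data
#'
#' Simulates every experiment at its template concentration and returns
#' the summed Gaussian negative log-likelihood over both channels:
#' \deqn{\sum_c \left[ \frac{n_c}{2}\log(2\pi\sigma_c^2) +
#'   \frac{\sum_i r_{ci}^2}{2\sigma_c^2} \right]}
#' with channel residuals \eqn{r_{ci}} and standard deviations per the
#' noise specification. Deterministic given its inputs. If the
#' integration fails at extreme parameters a large finite penalty
#' (`1e10`) is returned instead of an error, so optimizers can continue.
#'
#' @param params A [kinetic_params()] object (or coercible).
#' @param variant A [model_variant()].
#' @param data A titration dataset (see [as_titration()]).
#' @param noise A [noise_spec()].
#' @return Scalar negative log-likelihood.
#' @export
cfe_nll <- function(params, variant, data, noise = noise_spec("pooled")) {
  data <- as_titration(data)
  params <- as_kinetic_params(params)
  noise <- resolve_noise(noise, data)
  ctx_nll(params, make_nll_ctx(data, model_variant(variant), noise))
}

#' Akaike information criterion
#'
#' `AIC = 2k + 2 * nll_hat`, i.e. `2k - 2 log L` at the maximum-likelihood
#' estimate. Lower is better; equal fits are ranked by parsimony.
#'
#' @param k Number of free parameters (>= 0).
#' @param nll_hat Negative log-likelihood at the MLE.
#' @return Scalar AIC.
#' @export
aic <- function(k, nll_hat) {
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  2 * k + 2 * nll_hat
}

#' Fit a model variant by maximum likelihood
#'
#' Maximizes the Gaussian likelihood of the resource-limited expression
#' model over a chosen set of free parameters, with the remaining
#' parameters pinned (by default the independently measured maturation
#' rate `k_mat` and, for bulk data, the measurement lag `tau_l = 0`).
#' Optimization is performed in log10-parameter space within box bounds,
#' from `n_starts` Latin-hypercube starting points: a Levenberg-Marquardt
#' least-squares stage (when the channel SDs are fixed) or an L-BFGS-B
#' stage (concentrated likelihood), followed by a Nelder-Mead polish of
#' the exact objective. Reproducible for a given `(data, config, seed)`.
#'
#' @param data A titration dataset (see [as_titration()]) with at least
#'   two distinct template concentrations.
#' @param variant A [model_variant()]; default `"V1"`.
#' @param free Character vector of parameters to fit. Default: all
#'   parameters active in the variant except those in `fixed`.
#' @param fixed Named numeric vector of pinned parameters. Defaults are
#'   merged in for `k_mat` (2.15 1/h) and `tau_l` (0 h) unless these
#'   appear in `free`.
#' @param bounds Named list of `c(lower, upper)` boxes on the natural
#'   scale; unlisted free parameters get `c(1e-8, 1e8)`.
#' @param n_starts Number of multistart points (ignored when `start` is
#'   given).
#' @param seed Integer seed for the Latin-hypercube starts.
#' @param noise A [noise_spec()]; `"pooled"` is resolved against the data
#'   once, before optimization.
#' @param start Optional named vector of starting values (natural scale)
#'   for a single deterministic start.
#' @param control List: `lm_maxiter` (default 50), `polish_maxit`
#'   (default 150), `polish` (default TRUE), `screen` (optional integer:
#'   rank all starts by their initial objective and optimize only the
#'   best `screen` of them), `hops` (default 0: rounds of seeded
#'   basin-hopping refinement of the best solution, each a log10-space
#'   perturbation of SD `hop_sd` decades followed by a local stage of up
#'   to `hop_maxiter` iterations, kept only on improvement).
#' @return An object of class `cfe_fit` with elements `variant`,
#'   `theta_hat` (full [kinetic_params()]), `free`, `fixed`, `nll_hat`,
#'   `k`, `aic`, `noise`, `starts` (per-start diagnostics tibble),
#'   `data_hash`, `seed`, `bounds`, `n_obs`.
#' @seealso [cfe_profile()] for identifiability analysis,
#'   [rank_models()] for AIC-based selection.
#' @export
cfe_fit <- function(data, variant = model_variant("V1"), free = NULL,
                    fixed = NULL, bounds = NULL, n_starts = 20, seed = 1,
                    noise = noise_spec("pooled"), start = NULL,
                    control = list()) {
  data <- as_titration(data)
  variant <- model_variant(variant)
  ctrl <- utils::modifyList(
    list(lm_maxiter = 50, polish_maxit = 150, polish = TRUE,
         screen = NULL, hops = 0, hop_sd = 0.3,
         hop_maxiter = 40, rtol = 1e-8, atol = 1e-10),
    control)

  n_conc <- dplyr::n_distinct(data[c("template_kind", "template_nM")])
  if (n_conc < 2) {
    stop("joint fitting requires at least 2 distinct template ",
         "concentrations", call. = FALSE)
  }

  # pinned parameters: user-specified, plus conventions for k_mat / tau_l
  fixed <- unlist(fixed %||% numeric(0))
  for (nm in c("k_mat", "tau_l")) {
    if (!nm %in% names(fixed) && !(nm %in% free)) {
      fixed[nm] <- if (nm == "k_mat") 2.15 else 0
    }
  }
  free <- free %||% setdiff(active_params(variant), names(fixed))
  if (length(free) == 0) stop("no free parameters", call. = FALSE)
  if (length(intersect(free, names(fixed))) > 0) {
    stop("parameters cannot be both free and fixed: ",
         paste(intersect(free, names(fixed)), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(fixed), param_names())
  if (length(unknown) > 0) {
    stop("unknown fixed parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- kinetic_params()
  base[names(fixed)] <- fixed
  validate_kinetic_params(base)

  bounds <- bounds %||% list()
  lo <- vapply(free, function(nm) log10((bounds[[nm]] %||% c(1e-8, 1e8))[1]),
               numeric(1))
  hi <- vapply(free, function(nm) log10((bounds[[nm]] %||% c(1e-8, 1e8))[2]),
               numeric(1))

  noise <- resolve_noise(noise, data)
  n_obs <- 2L * nrow(data)
  ctx <- make_nll_ctx(data, variant, noise, rtol = ctrl$rtol,
                      atol = ctrl$atol)

  assemble <- function(lpar) {
    p <- base
    p[free] <- 10^lpar
    p
  }
  nll_fn <- function(lpar) {
    if (any(!is.finite(lpar))) return(NLL_PENALTY)
    ctx_nll(assemble(pmin(pmax(lpar, lo), hi)), ctx)
  }

  # starting points (log10 scale)
  if (!is.null(start)) {
    start <- unlist(start)
    if (!all(free %in% names(start))) {
      stop("start must name every free parameter", call. = FALSE)
    }
    starts <- matrix(log10(start[free]), nrow = 1,
                     dimnames = list(NULL, free))
  } else {
    u <- withr::with_seed(seed, lhs::randomLHS(n_starts, length(free)))
    starts <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
    colnames(starts) <- free
  }

  lm_subset <- function(lpar, subset, rows, maxiter) {
    f <- function(sub) {
      full <- lpar
      full[subset] <- sub
      ctx_wres(assemble(pmin(pmax(full, lo), hi)), ctx)[rows]
    }
    lm <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = lpar[subset], fn = f,
        lower = lo[subset], upper = hi[subset],
        control = minpack.lm::nls.lm.control(maxiter = maxiter))),
      error = function(e) NULL)
    if (!is.null(lm)) {
      lpar[subset] <- pmin(pmax(lm$par, lo[subset]), hi[subset])
    }
    lpar
  }

  run_start <- function(lpar0) {
    lpar <- lpar0
    if (noise$method != "concentrated") {
      # nls.lm warns when it stops on the iteration cap; that is an
      # accepted outcome here (the polish stage follows)
      lm <- tryCatch(
        suppressWarnings(minpack.lm::nls.lm(
          par = lpar,
          fn = function(lp) ctx_wres(assemble(pmin(pmax(lp, lo), hi)),
                                     ctx),
          lower = lo, upper = hi,
          control = minpack.lm::nls.lm.control(
            maxiter = ctrl$lm_maxiter))),
        error = function(e) NULL)
      if (!is.null(lm)) lpar <- pmin(pmax(lm$par, lo), hi)
    } else {
      op <- tryCatch(
        stats::optim(lpar, nll_fn, method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(maxit = 100)),
        error = function(e) NULL)
      if (!is.null(op)) lpar <- op$par
    }
    if (isTRUE(ctrl$polish) && length(free) > 1) {
      nm <- tryCatch(
        stats::optim(lpar, nll_fn, method = "Nelder-Mead",
                     control = list(maxit = ctrl$polish_maxit,
                                    reltol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(nm) && nm$value <= nll_fn(lpar)) {
        lpar <- pmin(pmax(nm$par, lo), hi)
      }
    }
    list(par = lpar, nll = nll_fn(lpar))
  }

  # optionally screen the starts: rank all by their initial objective
  # and run the optimizer only from the most promising ones
  nll0 <- purrr::map_dbl(seq_len(nrow(starts)),
                         function(i) nll_fn(starts[i, ]))
  run_idx <- seq_len(nrow(starts))
  if (!is.null(ctrl$screen) && ctrl$screen < nrow(starts)) {
    run_idx <- order(nll0)[seq_len(ctrl$screen)]
  }
  results <- purrr::map(seq_len(nrow(starts)), function(i) {
    if (i %in% run_idx) run_start(starts[i, ])
    else list(par = starts[i, ], nll = nll0[i])
  })
  nlls <- purrr::map_dbl(results, "nll")
  improved <- nlls <= nll0 + 1e-6
  nlls[!improved] <- pmin(nlls[!improved], nll0[!improved])
  if (all(!is.finite(nlls)) || all(nlls >= NLL_PENALTY)) {
    diag <- tibble::tibble(start = seq_len(nrow(starts)),
                           nll_start = nll0, nll_final = nlls)
    stop(paste0("all ", nrow(starts), " starts failed to converge; ",
                "per-start NLLs: ",
                paste(signif(nlls, 4), collapse = ", ")), call. = FALSE)
  }
  best <- which.min(nlls)
  best_par <- results[[best]]$par
  nll_hat <- nlls[best]

  # optional basin-hopping refinement of the incumbent: perturb the best
  # solution in log10 space and re-run the local stage, keeping
  # improvements (seeded, so reproducible)
  if (ctrl$hops > 0) {
    withr::with_seed(seed * 7L + 13L, {
      for (r in seq_len(ctrl$hops)) {
        lp0 <- pmin(pmax(best_par +
                           stats::rnorm(length(free), 0, ctrl$hop_sd),
                         lo), hi)
        lp1 <- if (noise$method != "concentrated") {
          lm_subset(lp0, free, seq_len(2 * ctx$n), ctrl$hop_maxiter)
        } else {
          op <- tryCatch(
            stats::optim(lp0, nll_fn, method = "L-BFGS-B",
                         lower = lo, upper = hi,
                         control = list(maxit = ctrl$hop_maxiter)),
            error = function(e) NULL)
          if (is.null(op)) lp0 else op$par
        }
        nll1 <- nll_fn(lp1)
        if (nll1 < nll_hat) {
          nll_hat <- nll1
          best_par <- lp1
        }
      }
    })
  }
  theta_hat <- assemble(best_par)
  k <- length(free)

  structure(list(
    variant = variant,
    theta_hat = theta_hat,
    free = free,
    fixed = fixed,
    nll_hat = nll_hat,
    k = k,
    aic = aic(k, nll_hat),
    noise = noise,
    starts = tibble::tibble(
      start = seq_len(nrow(starts)),
      nll_start = nll0,
      nll_final = nlls,
      best = seq_len(nrow(starts)) == best),
    data_hash = titration_hash(data),
    seed = seed,
    bounds = stats::setNames(
      purrr::map(free, function(nm) bounds[[nm]] %||% c(1e-8, 1e8)), free),
    n_obs = n_obs
  ), class = "cfe_fit")
}

#' @export
print.cfe_fit <- function(x, ...) {
  cat("<cfe_fit> variant ", x$variant$code %||% "custom",
      ", ", x$k, " free parameter(s)\n", sep = "")
  cat("  NLL = ", format(x$nll_hat, digits = 6),
      ", AIC = ", format(x$aic, digits = 6), "\n", sep = "")
  est <- x$theta_hat[x$free]
  cat("  MLE:\n")
  print(stats::setNames(signif(as.numeric(est), 4), names(est)))
  invisible(x)
}

#' Tidy a model fit
#'
#' @param x A `cfe_fit`.
#' @param profiles Optional named list of profile curves (from
#'   [cfe_profile()]); when given, likelihood-based CI columns are added.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `parameter`,
#'   `estimate`, `free`, `units`, and (with profiles) `ci_low`/`ci_high`.
#' @method tidy cfe_fit
#' @export
tidy.cfe_fit <- function(x, profiles = NULL, ...) {
  out <- param_units() |>
    dplyr::mutate(estimate = as.numeric(x$theta_hat[.data$parameter]),
                  free = .data$parameter %in% x$free) |>
    dplyr::select("parameter", "estimate", "free", "units")
  if (!is.null(profiles)) {
    cis <- purrr::map_dfr(profiles, likelihood_ci)
    out <- dplyr::left_join(out, cis[c("parameter", "ci_low", "ci_high")],
                            by = "parameter")
  }
  out
}

#' Summarize a model fit in one row
#'
#' @param x A `cfe_fit`.
#' @param ... Unused.
#' @return A one-row tibble: variant code, `k`, `nll`, `aic`, `n_obs`,
#'   number of starts, number of improved starts.
#' @method glance cfe_fit
#' @export
glance.cfe_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant$code %||% NA_character_,
    k = x$k,
    nll = x$nll_hat,
    aic = x$aic,
    n_obs = x$n_obs,
    n_starts = nrow(x$starts),
    n_improved = sum(x$starts$nll_final <= x$starts$nll_start + 1e-6)
  )
}

#' Rank fitted model variants by AIC
#'
#' Orders fits by ascending AIC; ties are broken by smaller parameter
#' count, then by variant code. All fits must have been made on the same
#' dataset.
#'
#' @param fits A list of `cfe_fit` objects (or several fits as `...`).
#' @param ... Additional fits.
#' @return A tibble with columns `variant`, `k`, `nll`, `aic`,
#'   `delta_aic`, sorted best-first.
#' @export
rank_models <- function(fits, ...) {
  if (inherits(fits, "cfe_fit")) fits <- list(fits)
  fits <- c(fits, list(...))
  stopifnot(length(fits) >= 1)
  hashes <- purrr::map_chr(fits, "data_hash")
  if (length(unique(hashes)) > 1) {
    stop("fits were made on different datasets and cannot be ranked ",
         "together", call. = FALSE)
  }
  out <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(variant = f$variant$code %||% NA_character_,
                   k = f$k, nll = f$nll_hat, aic = f$aic)
  })
  out <- dplyr::arrange(out, .data$aic, .data$k, .data$variant)
  dplyr::mutate(out, delta_aic = .data$aic - .data$aic[1])
}
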