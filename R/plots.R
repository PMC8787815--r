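#' Plot a simulated trajectory
#'
#' Observed mRNA and mature-protein channels over time, faceted by
#' channel.
#'
#' @param object A `cfe_trajectory` from [cfe_simulate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cfe_trajectory
#' @export
autoplot.cfe_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("observed_rna_nM", "observed_protein_nM"),
                        names_to = "channel", values_to = "nM") |>
    dplyr::mutate(channel = dplyr::recode(.data$channel,
                                          observed_rna_nM = "mRNA",
                                          observed_protein_nM = "protein"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$nM)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (nM)")
}

#' Plot a titration dataset, optionally with a model fit overlaid
#'
#' Points are the measured channels coloured by template concentration;
#' dashed lines are the fitted model's predictions when a fit is given.
#'
#' @param data A titration dataset (see [as_titration()]).
#' @param fit Optional [cfe_fit()] whose predictions to overlay.
#' @return A ggplot object.
#' @export
plot_titration <- function(data, fit = NULL) {
  data <- as_titration(data)
  long <- data |>
    tidyr::pivot_longer(c("rna_nM", "protein_nM"),
                        names_to = "channel", values_to = "nM") |>
    dplyr::mutate(channel = dplyr::recode(.data$channel,
                                          rna_nM = "mRNA",
                                          protein_nM = "protein"))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(.data$time_h, .data$nM,
                                    colour = factor(.data$template_nM))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_grid(ggplot2::vars(.data$channel),
                        ggplot2::vars(.data$template_kind),
                        scales = "free") +
    ggplot2::labs(x = "time (h)", y = "concentration (nM)",
                  colour = "template (nM)")
  if (!is.null(fit)) {
    pred <- predict_titration(fit$theta_hat, fit$variant, data) |>
      dplyr::distinct(.data$template_kind, .data$template_nM,
                      .data$time_h, .data$pred_rna, .data$pred_protein) |>
      tidyr::pivot_longer(c("pred_rna", "pred_protein"),
                          names_to = "channel", values_to = "nM") |>
      dplyr::mutate(channel = dplyr::recode(.data$channel,
                                            pred_rna = "mRNA",
                                            pred_protein = "protein"))
    p <- p + ggplot2::geom_line(data = pred, linetype = "dashed")
  }
  p
}

#' Plot a profile likelihood curve
#'
#' Profiled NLL against the parameter (log scale) with the MLE and the
#' chi-squared confidence threshold marked.
#'
#' @param object A `cfe_profile` from [cfe_profile()] or
#'   [profile_nll()].
#' @param alpha,df Threshold settings (defaults as in
#'   [likelihood_ci()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cfe_profile
#' @export
autoplot.cfe_profile <- function(object, alpha = 0.95, df = NULL, ...) {
  df <- df %||% attr(object, "df")
  nll_hat <- attr(object, "nll_hat")
  thr <- nll_hat + stats::qchisq(alpha, df) / 2
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$value, .data$nll)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = attr(object, "theta_hat_i"),
                        linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = object$parameter[1], y = "profiled NLL")
}

#' Endpoint histograms of a synthetic-cell population
#'
#' Histograms of cell radius and endpoint mRNA/protein concentrations
#' per population, with the Gaussian implied by the sample mean and
#' variance overlaid.
#'
#' @param traces A per-cell trace table (see [as_cell_traces()]).
#' @param endpoint Endpoint time (h); default the last common time.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_population_endpoints <- function(traces, endpoint = NULL, bins = 15) {
  traces <- as_cell_traces(traces)
  if (is.null(endpoint)) endpoint <- max(traces$time_h)
  ends <- traces |>
    dplyr::filter(.data$time_h == endpoint) |>
    tidyr::pivot_longer(c("radius_um", "rna_nM", "protein_nM"),
                        names_to = "quantity", values_to = "value")
  gauss <- ends |>
    dplyr::group_by(.data$population_id, .data$quantity) |>
    dplyr::summarise(m = mean(.data$value), s = stats::sd(.data$value),
                     n = dplyr::n(), lo = min(.data$value),
                     hi = max(.data$value), .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::reframe(population_id = .data$population_id,
                   quantity = .data$quantity,
                   value = seq(.data$lo, .data$hi, length.out = 100),
                   dens = stats::dnorm(.data$value, .data$m, .data$s))
  ggplot2::ggplot(ends, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70") +
    ggplot2::geom_line(data = gauss, ggplot2::aes(y = .data$dens)) +
    ggplot2::facet_grid(ggplot2::vars(.data$population_id),
                        ggplot2::vars(.data$quantity), scales = "free") +
    ggplot2::labs(x = NULL, y = "density")
}
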