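#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the sample
#' mean; a scale-free dispersion measure for comparing variability of
#' distributions with different measurement scales.
#'
#' @param values Numeric sample, length >= 2, nonzero mean.
#' @return Scalar CV.
#' @export
#' @examples
#' cv(c(28, 30, 32))
cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("cv requires at least 2 values",
                               call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("cv is undefined for zero mean", call. = FALSE)
  stats::sd(values) / m
}

#' Validate a per-cell trace table
#'
#' Per-cell time courses from synthetic-cell populations, in the tidy
#' schema `population_id`, `batch_id`, `cell_id`, `radius_um`, `time_h`,
#' `rna_nM`, `protein_nM`.
#'
#' @param traces A data frame in the schema above.
#' @return The validated tibble.
#' @export
as_cell_traces <- function(traces) {
  need <- c("population_id", "batch_id", "cell_id", "radius_um", "time_h",
            "rna_nM", "protein_nM")
  missing <- setdiff(need, names(traces))
  if (length(missing) > 0) {
    stop("cell traces lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(traces) == 0) stop("cell trace table is empty", call. = FALSE)
  if (any(traces$radius_um <= 0)) stop("radius must be > 0", call. = FALSE)
  if (any(traces$rna_nM < 0, na.rm = TRUE) ||
      any(traces$protein_nM < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  tibble::as_tibble(traces)
}

#' Summarize synthetic-cell populations at an endpoint
#'
#' For each population: number of cells, mean, SD and CV of the cell
#' radius and of the endpoint mRNA and protein concentrations. The mean
#' and SD double as the moments of the Gaussian overlay conventionally
#' drawn over endpoint histograms. The endpoint defaults to the last
#' time point common to all cells (typically 12 h).
#'
#' @param traces A per-cell trace table (see [as_cell_traces()]).
#' @param endpoint Endpoint time (h); must be present for every cell.
#' @return A tibble with one row per population: `population_id`,
#'   `n_cells`, `radius_mean_um`, `radius_sd_um`, `radius_cv`,
#'   `rna_mean_nM`, `rna_sd_nM`, `rna_cv`, `protein_mean_nM`,
#'   `protein_sd_nM`, `protein_cv`, `endpoint_h`.
#' @export
summarize_population <- function(traces, endpoint = NULL) {
  traces <- as_cell_traces(traces)
  if (is.null(endpoint)) {
    endpoint <- traces |>
      dplyr::group_by(.data$population_id, .data$batch_id, .data$cell_id) |>
      dplyr::summarise(tmax = max(.data$time_h), .groups = "drop") |>
      dplyr::pull(.data$tmax) |>
      min()
  }
  ends <- traces |>
    dplyr::filter(.data$time_h == endpoint) |>
    dplyr::distinct(.data$population_id, .data$batch_id, .data$cell_id,
                    .keep_all = TRUE)
  counts <- ends |> dplyr::count(.data$population_id)
  if (nrow(ends) == 0 || any(counts$n < 2)) {
    stop("each population needs >= 2 cells with data at the endpoint ",
         "(SDs are undefined otherwise)", call. = FALSE)
  }
  ends |>
    dplyr::group_by(.data$population_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      radius_mean_um = mean(.data$radius_um),
      radius_sd_um = stats::sd(.data$radius_um),
      rna_mean_nM = mean(.data$rna_nM),
      rna_sd_nM = stats::sd(.data$rna_nM),
      protein_mean_nM = mean(.data$protein_nM),
      protein_sd_nM = stats::sd(.data$protein_nM),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      radius_cv = .data$radius_sd_um / .data$radius_mean_um,
      rna_cv = .data$rna_sd_nM / .data$rna_mean_nM,
      protein_cv = .data$protein_sd_nM / .data$protein_mean_nM,
      endpoint_h = endpoint
    ) |>
    dplyr::select("population_id", "n_cells",
                  "radius_mean_um", "radius_sd_um", "radius_cv",
                  "rna_mean_nM", "rna_sd_nM", "rna_cv",
                  "protein_mean_nM", "protein_sd_nM", "protein_cv",
                  "endpoint_h")
}

#' Maximum translation rate of a protein time course
#'
#' Maximum of the centered finite differences of the protein series,
#' taken after a moving-average smooth (default width 3). This is the
#' estimator used for batch-to-batch comparisons of maximum translation
#' rates from measured traces.
#'
#' @param time_h Time grid (h).
#' @param protein_nM Protein series (nM), same length.
#' @param smooth_width Odd moving-average window (1 disables smoothing).
#' @return Maximum rate (nM/h).
#' @export
max_translation_rate <- function(time_h, protein_nM, smooth_width = 3) {
  stopifnot(length(time_h) == length(protein_nM), length(time_h) >= 3,
            smooth_width >= 1, smooth_width %% 2 == 1)
  y <- protein_nM
  if (smooth_width > 1) {
    y <- stats::filter(y, rep(1 / smooth_width, smooth_width), sides = 2)
    y <- as.numeric(y)
    keep <- !is.na(y)
    y <- y[keep]
    t <- time_h[keep]
  } else {
    t <- time_h
  }
  n <- length(y)
  if (n < 3) stop("too few points after smoothing", call. = FALSE)
  d <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  max(d)
}

#' Batch-to-batch coefficients of variation
#'
#' CV across batch-level values of the endpoint protein concentration
#' and of the maximum translation rate. Accepts either the batch-level
#' vectors directly, or a per-cell trace table from which the batch
#' means are computed.
#'
#' @param endpoint_protein Numeric vector of per-batch endpoint protein
#'   means, or a per-cell trace table (see [as_cell_traces()]).
#' @param max_rates Numeric vector of per-batch maximum translation
#'   rates (ignored when a trace table is given).
#' @return A one-row tibble: `n_batches`, `cv_endpoint_protein`,
#'   `cv_max_translation_rate`.
#' @export
batch_cv <- function(endpoint_protein, max_rates = NULL) {
  if (is.data.frame(endpoint_protein)) {
    traces <- as_cell_traces(endpoint_protein)
    by_batch <- traces |>
      dplyr::group_by(.data$batch_id, .data$cell_id) |>
      dplyr::summarise(
        end_protein = .data$protein_nM[which.max(.data$time_h)],
        max_rate = max_translation_rate(.data$time_h, .data$protein_nM),
        .groups = "drop_last") |>
      dplyr::summarise(end_protein = mean(.data$end_protein),
                       max_rate = mean(.data$max_rate),
                       .groups = "drop")
    endpoint_protein <- by_batch$end_protein
    max_rates <- by_batch$max_rate
  }
  if (length(endpoint_protein) < 2) {
    stop("batch CV requires at least 2 batches", call. = FALSE)
  }
  tibble::tibble(
    n_batches = length(endpoint_protein),
    cv_endpoint_protein = cv(endpoint_protein),
    cv_max_translation_rate = if (is.null(max_rates)) NA_real_
                              else cv(max_rates)
  )
}

#' Endpoint expression ratio between two reporter channels
#'
#' Per-cell endpoint ratio of channel A over channel B, reported as mean
#' plus/minus SD. Cells with a zero denominator are excluded with a
#' warning.
#'
#' @param channel_a,channel_b Paired per-cell endpoint values.
#' @return A one-row tibble: `n_cells`, `ratio_mean`, `ratio_sd`.
#' @export
expression_ratio <- function(channel_a, channel_b) {
  stopifnot(length(channel_a) == length(channel_b))
  bad <- channel_b == 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with zero denominator excluded",
            call. = FALSE)
    channel_a <- channel_a[!bad]
    channel_b <- channel_b[!bad]
  }
  if (length(channel_a) < 1) stop("no usable cells", call. = FALSE)
  r <- channel_a / channel_b
  tibble::tibble(n_cells = length(r), ratio_mean = mean(r),
                 ratio_sd = if (length(r) > 1) stats::sd(r) else 0)
}

#' Read or write per-cell traces as tidy CSV
#'
#' @param traces A per-cell trace table.
#' @param path File path.
#' @return `read_cell_traces_csv()` returns the validated tibble;
#'   `write_cell_traces_csv()` returns `path` invisibly.
#' @export
read_cell_traces_csv <- function(path) {
  as_cell_traces(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_cell_traces_csv
#' @export
write_cell_traces_csv <- function(traces, path) {
  readr::write_csv(as_cell_traces(traces), path)
  invisible(path)
}
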