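#' Validate a titration dataset
#'
#' A titration dataset is a tidy table of joint mRNA/protein time courses
#' collected at several input template (DNA or mRNA) concentrations, with
#' columns `experiment_id`, `template_kind` (`"dna"` or `"rna"`),
#' `template_nM`, `replicate`, `time_h`, `rna_nM`, `protein_nM`.
#'
#' @param data A data frame in the schema above.
#' @return The validated data as a tibble (invisibly classed
#'   `cfe_titration`).
#' @export
as_titration <- function(data) {
  need <- c("experiment_id", "template_kind", "template_nM", "replicate",
            "time_h", "rna_nM", "protein_nM")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("titration data lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) stop("titration data is empty", call. = FALSE)
  if (!all(data$template_kind %in% c("dna", "rna"))) {
    stop("template_kind must be 'dna' or 'rna'", call. = FALSE)
  }
  if (any(data$template_nM < 0) ||
      any(data$rna_nM < 0, na.rm = TRUE) ||
      any(data$protein_nM < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  ok <- data |>
    dplyr::group_by(.data$experiment_id, .data$replicate) |>
    dplyr::summarise(ok = all(diff(.data$time_h) > 0), .groups = "drop")
  if (!all(ok$ok)) {
    stop("each experiment/replicate time grid must be strictly increasing",
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  if (!inherits(out, "cfe_titration")) {
    class(out) <- c("cfe_titration", class(out))
  }
  out
}

# unique simulation conditions with the union time grid per condition
titration_conditions <- function(data) {
  data |>
    dplyr::group_by(.data$template_kind, .data$template_nM) |>
    dplyr::summarise(times = list(sort(unique(.data$time_h))),
                     .groups = "drop")
}

#' Read or write titration data as tidy CSV
#'
#' @param data A titration dataset (see [as_titration()]).
#' @param path File path.
#' @return `read_titration_csv()` returns a validated `cfe_titration`
#'   tibble; `write_titration_csv()` returns `path` invisibly.
#' @export
read_titration_csv <- function(path) {
  as_titration(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_titration_csv
#' @export
write_titration_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(as_titration(data)), path)
  invisible(path)
}

# order-invariant fingerprint of a dataset, used to refuse ranking fits
# made on different data
titration_hash <- function(data) {
  data <- as_titration(data)
  cols <- c("experiment_id", "template_kind", "template_nM", "replicate",
            "time_h", "rna_nM", "protein_nM")
  d <- as.data.frame(data)[cols]
  d <- d[do.call(order, d), , drop = FALSE]
  rownames(d) <- NULL
  rlang::hash(d)
}
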