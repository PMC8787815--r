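#' Kinetic parameters of the resource-limited expression model
#'
#' Construct the full parameter set of the coarse-grained resource-limited
#' transcription/translation model. All thirteen parameters are always
#' carried; which ones are dynamically active depends on the
#' [model_variant()] in use (e.g. `K_r` is inactive under mass-action
#' transcription).
#'
#' @param k_r Maximal transcription rate (nM/h).
#' @param K_r RNA-polymerase/DNA dissociation constant (nM).
#' @param delta_r First-order RNA degradation rate (1/h).
#' @param k_p Maximal translation rate (nM/h).
#' @param K_p Ribosome/RNA dissociation constant (nM).
#' @param k_mat First-order fluorophore (mCherry) maturation rate (1/h).
#'   Typically measured independently and held fixed during fitting.
#' @param delta_TsR First-order degradation rate of the transcription
#'   resource pool TsR (1/h).
#' @param delta_TlR Degradation rate of the translation resource pool TlR
#'   (1/h).
#' @param K_l Michaelis-Menten constant for TlR degradation (on the
#'   unitless resource scale).
#' @param a Consumption of TsR per unit of transcription flux (1/nM).
#' @param b Consumption of TlR per unit of translation flux (1/nM).
#' @param tau_d Translation delay (h): translation at time t uses the
#'   transcript concentration at t - tau_d.
#' @param tau_l Lag between reaction start and the first measurement (h);
#'   a pure reporting-time shift, not a dynamical quantity.
#'
#' @return An object of class `kinetic_params`: a named numeric vector of
#'   length 13.
#'
#' @details All values must be non-negative. A zero Michaelis constant is
#'   allowed (the saturated limit) as long as the corresponding substrate
#'   is nonzero wherever the rate is evaluated.
#'
#' @seealso [theta_bulk()], [theta_cell()] for the reference estimates
#'   shipped with the package.
#' @export
#' @examples
#' p <- kinetic_params(k_r = 2894, K_r = 3.67, delta_r = 0.0392,
#'                     k_p = 2568, K_p = 703)
#' p["k_r"]
kinetic_params <- function(k_r = 0, K_r = 1, delta_r = 0, k_p = 0, K_p = 1,
                           k_mat = 2.15, delta_TsR = 0, delta_TlR = 0,
                           K_l = 1, a = 0, b = 0, tau_d = 0, tau_l = 0) {
  p <- c(k_r = k_r, K_r = K_r, delta_r = delta_r, k_p = k_p, K_p = K_p,
         k_mat = k_mat, delta_TsR = delta_TsR, delta_TlR = delta_TlR,
         K_l = K_l, a = a, b = b, tau_d = tau_d, tau_l = tau_l)
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

param_names <- function() {
  c("k_r", "K_r", "delta_r", "k_p", "K_p", "k_mat", "delta_TsR",
    "delta_TlR", "K_l", "a", "b", "tau_d", "tau_l")
}

validate_kinetic_params <- function(p) {
  nm <- param_names()
  if (!all(nm %in% names(p))) {
    missing <- setdiff(nm, names(p))
    stop("missing kinetic parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- names(p)[!is.finite(p) | p < 0]
  if (length(bad) > 0) {
    stop("kinetic parameters must be finite and non-negative; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(p)
}

#' Coerce a named vector or list to kinetic parameters
#'
#' Unnamed entries are not allowed; unspecified parameters take the
#' [kinetic_params()] defaults.
#'
#' @param x A named numeric vector/list of parameter values, or an existing
#'   `kinetic_params` object (returned as-is).
#' @return A `kinetic_params` object.
#' @export
as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  x <- unlist(x)
  unknown <- setdiff(names(x), param_names())
  if (length(unknown) > 0) {
    stop("unknown kinetic parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(kinetic_params, as.list(x))
}

#' Replace selected parameter values
#'
#' @param params A `kinetic_params` object.
#' @param ... Named scalar replacements, e.g. `k_r = 3000`.
#' @return The modified `kinetic_params` object.
#' @export
set_params <- function(params, ...) {
  params <- as_kinetic_params(params)
  repl <- c(...)
  unknown <- setdiff(names(repl), param_names())
  if (length(unknown) > 0) {
    stop("unknown kinetic parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params[names(repl)] <- repl
  validate_kinetic_params(params)
  structure(params, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Reference parameter estimates
#'
#' Maximum-likelihood estimates of the resource-limited expression model
#' obtained from bulk DNA/RNA titration experiments (`theta_bulk()`) and
#' from synthetic-cell population DNA titrations (`theta_cell()`) in the
#' PURE system expressing an mCherry/Broccoli dual reporter. These serve as
#' realistic defaults for simulation and as generator ground truth.
#'
#' @return A `kinetic_params` object.
#' @export
theta_bulk <- function() {
  kinetic_params(
    k_r = 2894, K_r = 3.67, delta_r = 0.0392,
    k_p = 2568, K_p = 703, k_mat = 2.15,
    delta_TsR = 0.231, delta_TlR = 0.0884, K_l = 1.21e-6,
    a = 4.45e-4, b = 1.78e-4, tau_d = 0.433, tau_l = 2.81e-9
  )
}

#' @rdname theta_bulk
#' @export
theta_cell <- function() {
  kinetic_params(
    k_r = 1899, K_r = 8.86, delta_r = 0.0081,
    k_p = 1954, K_p = 1319, k_mat = 2.15,
    delta_TsR = 0.154, delta_TlR = 0.244, K_l = 0.232,
    a = 6.60e-4, b = 4.46e-13, tau_d = 0.0576, tau_l = 0.457
  )
}

#' Parameter units
#'
#' @return A tibble with columns `parameter`, `units`, `description`.
#' @export
param_units <- function() {
  tibble::tibble(
    parameter = param_names(),
    units = c("nM/h", "nM", "1/h", "nM/h", "nM", "1/h", "1/h", "1/h",
              "", "1/nM", "1/nM", "h", "h"),
    description = c(
      "RNA transcription rate",
      "dissociation constant between RNAP and DNA",
      "RNA degradation rate",
      "protein translation rate",
      "dissociation constant between ribosome and RNA",
      "fluorophore maturation rate",
      "TsR degradation rate",
      "TlR degradation rate",
      "Michaelis-Menten constant for TlR degradation",
      "TsR consumption scaling with transcription",
      "TlR consumption scaling with translation",
      "time delay for protein translation",
      "time lag between reaction start and data collection"
    )
  )
}

# ---------------------------------------------------------------------------
# Model variants

#' Structural variants of the expression model
#'
#' The model family spans two axes: the kinetic law used for transcription
#' and translation (Michaelis-Menten vs mass action) and the spontaneous
#' degradation law of the two resource pools. `model_variant()` builds a
#' single variant either from a code `"V1"`..`"V7"` or from the explicit
#' four fields; `model_variants()` enumerates the seven candidate
#' structures submitted to AIC-based selection.
#'
#' The canonical members are:
#' \describe{
#'   \item{V1}{MM transcription, MM translation, first-order TsR
#'     degradation, MM TlR degradation (the selected full structure).}
#'   \item{V2}{as V1 but without TsR degradation (resource consumption
#'     only).}
#'   \item{V3}{as V1 but first-order TlR degradation.}
#'   \item{V4}{no TsR degradation and first-order TlR degradation.}
#'   \item{V5}{mass-action transcription, otherwise as V1.}
#'   \item{V6}{mass-action translation, otherwise as V1.}
#'   \item{V7}{mass-action transcription and translation, otherwise as V1.}
#' }
#'
#' @param code A variant code `"V1"`..`"V7"`, or `NULL` when the four
#'   explicit fields are given.
#' @param tx_law,tl_law `"michaelis_menten"` or `"mass_action"`.
#' @param tsr_degradation `"first_order"` or `"none"`.
#' @param tlr_degradation `"michaelis_menten"` or `"first_order"`.
#' @return An object of class `model_variant` (a named list with the four
#'   structure fields, the matching code if canonical, and
#'   `n_free_params`, the number of dynamically active kinetic parameters).
#' @export
#' @examples
#' model_variant("V1")
#' model_variant(tx_law = "mass_action", tl_law = "michaelis_menten",
#'               tsr_degradation = "first_order",
#'               tlr_degradation = "michaelis_menten")
model_variant <- function(code = NULL,
                          tx_law = NULL, tl_law = NULL,
                          tsr_degradation = NULL, tlr_degradation = NULL) {
  defs <- variant_definitions()
  if (!is.null(code)) {
    if (inherits(code, "model_variant")) return(code)
    if (!code %in% names(defs)) {
      stop("unknown variant code '", code, "'; expected one of ",
           paste(names(defs), collapse = ", "), call. = FALSE)
    }
    v <- defs[[code]]
  } else {
    tx_law <- match.arg(tx_law, c("michaelis_menten", "mass_action"))
    tl_law <- match.arg(tl_law, c("michaelis_menten", "mass_action"))
    tsr_degradation <- match.arg(tsr_degradation, c("first_order", "none"))
    tlr_degradation <- match.arg(tlr_degradation,
                                 c("michaelis_menten", "first_order"))
    v <- list(tx_law = tx_law, tl_law = tl_law,
              tsr_degradation = tsr_degradation,
              tlr_degradation = tlr_degradation)
    match <- purrr::detect_index(defs, function(d) {
      identical(d[c("tx_law", "tl_law", "tsr_degradation",
                    "tlr_degradation")],
                v[c("tx_law", "tl_law", "tsr_degradation",
                    "tlr_degradation")])
    })
    v$code <- if (match > 0) names(defs)[match] else NA_character_
  }
  v$n_free_params <- length(active_params(v))
  structure(v, class = "model_variant")
}

variant_definitions <- function() {
  mk <- function(code, tx, tl, tsr, tlr) {
    list(tx_law = tx, tl_law = tl, tsr_degradation = tsr,
         tlr_degradation = tlr, code = code)
  }
  list(
    V1 = mk("V1", "michaelis_menten", "michaelis_menten", "first_order",
            "michaelis_menten"),
    V2 = mk("V2", "michaelis_menten", "michaelis_menten", "none",
            "michaelis_menten"),
    V3 = mk("V3", "michaelis_menten", "michaelis_menten", "first_order",
            "first_order"),
    V4 = mk("V4", "michaelis_menten", "michaelis_menten", "none",
            "first_order"),
    V5 = mk("V5", "mass_action", "michaelis_menten", "first_order",
            "michaelis_menten"),
    V6 = mk("V6", "michaelis_menten", "mass_action", "first_order",
            "michaelis_menten"),
    V7 = mk("V7", "mass_action", "mass_action", "first_order",
            "michaelis_menten")
  )
}

#' @rdname model_variant
#' @return `model_variants()` returns a tibble with one row per canonical
#'   variant and the structure fields as columns.
#' @export
model_variants <- function() {
  defs <- variant_definitions()
  tibble::tibble(
    code = names(defs),
    tx_law = purrr::map_chr(defs, "tx_law"),
    tl_law = purrr::map_chr(defs, "tl_law"),
    tsr_degradation = purrr::map_chr(defs, "tsr_degradation"),
    tlr_degradation = purrr::map_chr(defs, "tlr_degradation"),
    n_free_params = purrr::map_int(
      names(defs), function(cd) model_variant(cd)$n_free_params)
  )
}

#' Dynamically active parameters of a variant
#'
#' Parameters that appear in the right-hand side under the given structure.
#' `tau_l` is always listed (it shifts the observation times); `K_r`/`K_p`
#' drop out under mass action, `delta_TsR` under `tsr_degradation = "none"`,
#' and `K_l` under first-order TlR degradation.
#'
#' @param variant A `model_variant`.
#' @return Character vector of parameter names.
#' @export
active_params <- function(variant) {
  nm <- param_names()
  drop <- character(0)
  if (variant$tx_law == "mass_action") drop <- c(drop, "K_r")
  if (variant$tl_law == "mass_action") drop <- c(drop, "K_p")
  if (variant$tsr_degradation == "none") drop <- c(drop, "delta_TsR")
  if (variant$tlr_degradation == "first_order") drop <- c(drop, "K_l")
  setdiff(nm, drop)
}

#' @export
print.model_variant <- function(x, ...) {
  cat("<model_variant ", if (is.na(x$code)) "(non-canonical)" else x$code,
      ">\n", sep = "")
  cat("  transcription:   ", x$tx_law, "\n",
      "  translation:     ", x$tl_law, "\n",
      "  TsR degradation: ", x$tsr_degradation, "\n",
      "  TlR degradation: ", x$tlr_degradation, "\n",
      "  active params:   ", x$n_free_params, "\n", sep = "")
  invisible(x)
}
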