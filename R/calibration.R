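#' Fit a linear fluorescence calibration curve
#'
#' Ordinary least-squares fit of `rfu ~ known_nM` to a serial-dilution
#' series, used to convert relative fluorescence units (RFU) into nM.
#' The curve is forced linear; a diagnostics warning fires when the fit
#' quality drops below R-squared 0.98.
#'
#' @param dilution_series Data frame with columns `known_nM` and `rfu`
#'   (optionally `channel`, recorded in the result). At least 3 points
#'   and 2 distinct concentrations are required.
#' @return An object of class `calibration_curve`: list with `slope`
#'   (RFU per nM), `intercept` (RFU), `r_squared`, `n`, `channel`, and
#'   the underlying `lm` fit.
#' @export
#' @examples
#' cal <- fit_calibration(data.frame(known_nM = c(0, 5, 10, 20),
#'                                   rfu = c(5, 15, 25, 45)))
#' rfu_to_nm(cal, 25)
fit_calibration <- function(dilution_series) {
  need <- c("known_nM", "rfu")
  if (!all(need %in% names(dilution_series))) {
    stop("dilution series needs columns known_nM and rfu", call. = FALSE)
  }
  if (nrow(dilution_series) < 3) {
    stop("calibration requires at least 3 points", call. = FALSE)
  }
  if (dplyr::n_distinct(dilution_series$known_nM) < 2) {
    stop("calibration requires at least 2 distinct concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(rfu ~ known_nM, data = dilution_series)
  slope <- unname(stats::coef(fit)["known_nM"])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive for an invertible curve",
         call. = FALSE)
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  if (is.finite(r2) && r2 < 0.98) {
    warning("calibration R-squared ", signif(r2, 3),
            " is below 0.98; conversion may be unreliable", call. = FALSE)
  }
  structure(list(
    channel = if ("channel" %in% names(dilution_series))
      as.character(dilution_series$channel[1]) else NA_character_,
    slope = slope,
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = r2,
    n = nrow(dilution_series),
    fit = fit
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve",
      if (!is.na(x$channel)) paste0(" [", x$channel, "]"), ">\n",
      "  rfu = ", signif(x$slope, 5), " * nM + ", signif(x$intercept, 5),
      "   (R^2 = ", signif(x$r_squared, 4), ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(channel = x$channel,
                 term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(channel = x$channel, slope = x$slope,
                 intercept = x$intercept, r_squared = x$r_squared,
                 n = x$n)
}

#' Convert fluorescence to concentration (and back)
#'
#' `rfu_to_nm()` inverts the linear calibration: `(rfu - intercept) /
#' slope`. Readings below the intercept map to negative concentrations;
#' they are flagged with a warning but deliberately not clipped, so that
#' downstream statistics remain unbiased near zero signal.
#'
#' @param curve A [fit_calibration()] result.
#' @param rfu,nm Numeric vectors.
#' @return Numeric vector of concentrations (nM) or fluorescence (RFU).
#' @export
rfu_to_nm <- function(curve, rfu) {
  stopifnot(inherits(curve, "calibration_curve"))
  out <- (rfu - curve$intercept) / curve$slope
  n_neg <- sum(out < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warning(n_neg, " reading(s) below the calibration intercept mapped ",
            "to negative nM (kept, not clipped)", call. = FALSE)
  }
  out
}

#' @rdname rfu_to_nm
#' @export
nm_to_rfu <- function(curve, nm) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$slope * nm + curve$intercept
}

#' Physical constants of the expression construct and reaction
#'
#' Holds the quantities needed to convert fitted bulk rates into
#' per-enzyme rates: transcript length, protein length, and the T7 RNA
#' polymerase and ribosome concentrations of a standard PURE reaction.
#'
#' @param l_rna Transcript length (nt); default 1087.
#' @param l_prot Protein length (aa); default 777.
#' @param c_rnap T7 RNA polymerase concentration (nM); default 100.
#' @param c_ribo Ribosome concentration (nM); default 2400.
#' @return A list of class `unit_context` (includes `avogadro`).
#' @export
unit_context <- function(l_rna = 1087, l_prot = 777, c_rnap = 100,
                         c_ribo = 2400) {
  vals <- c(l_rna = l_rna, l_prot = l_prot, c_rnap = c_rnap,
            c_ribo = c_ribo)
  if (any(vals <= 0)) stop("unit context values must be positive",
                           call. = FALSE)
  structure(list(l_rna = l_rna, l_prot = l_prot, c_rnap = c_rnap,
                 c_ribo = c_ribo, avogadro = 6.02214076e23),
            class = "unit_context")
}

#' Per-enzyme rates from bulk rate constants
#'
#' Converts a bulk transcription rate `k_r` (nM transcript/h) into the
#' per-polymerase elongation rate in NTP/s — `k_r * l_rna / (c_rnap *
#' 3600)` — and a bulk translation rate `k_p` (nM protein/h) into the
#' per-ribosome rate in amino acids/s.
#'
#' @param k_r,k_p Bulk rates (nM/h).
#' @param ctx A [unit_context()].
#' @return Scalar rate (NTP/s or aa/s per enzyme).
#' @export
#' @examples
#' polymerase_rate_ntp_per_s(2894)  # ~8.7 NTP/s
polymerase_rate_ntp_per_s <- function(k_r, ctx = unit_context()) {
  stopifnot(k_r >= 0)
  k_r * ctx$l_rna / (ctx$c_rnap * 3600)
}

#' @rdname polymerase_rate_ntp_per_s
#' @export
ribosome_rate_aa_per_s <- function(k_p, ctx = unit_context()) {
  stopifnot(k_p >= 0)
  k_p * ctx$l_prot / (ctx$c_ribo * 3600)
}

#' Fluorophore maturation half-time
#'
#' `60 * ln(2) / k_mat`, in minutes, for a first-order maturation rate in
#' 1/h.
#'
#' @param k_mat Maturation rate (1/h), strictly positive.
#' @return Half-time in minutes.
#' @export
maturation_half_time <- function(k_mat) {
  if (!is.numeric(k_mat) || any(k_mat <= 0)) {
    stop("k_mat must be > 0", call. = FALSE)
  }
  60 * log(2) / k_mat
}

#' Molecule copy number in a spherical compartment
#'
#' Number of molecules of a species at concentration `conc_nM` inside a
#' sphere of radius `radius_um`: `conc * 1e-9 mol/L * volume(L) *
#' N_Avogadro`. Linear in concentration, cubic in radius.
#'
#' @param radius_um Compartment radius (micrometers), > 0.
#' @param conc_nM Concentration (nM), >= 0.
#' @param ctx A [unit_context()] (for the Avogadro constant).
#' @return Molecule count (numeric, not rounded).
#' @export
#' @examples
#' copy_number(30.4, 3.5)    # DNA in a ~30 um synthetic cell: ~2.5e5
copy_number <- function(radius_um, conc_nM, ctx = unit_context()) {
  if (any(radius_um <= 0)) stop("radius must be > 0", call. = FALSE)
  if (any(conc_nM < 0)) stop("concentration must be >= 0", call. = FALSE)
  volume_l <- 4 / 3 * pi * (radius_um * 1e-5)^3  # um -> dm; dm^3 = L
  conc_nM * 1e-9 * volume_l * ctx$avogadro
}
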