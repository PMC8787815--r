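#' Right-hand side of the resource-limited expression model
#'
#' Evaluate the time derivative of the model state. Transcription and
#' translation draw on unitless resource pools (TsR, TlR) that start at 1
#' and are consumed in proportion to the fluxes and degraded spontaneously;
#' translation uses the transcript concentration at `t - tau_d`, supplied
#' here as `lagged_rna`.
#'
#' The fluxes are
#' \deqn{v_{tx} = k_r \cdot TsR \cdot DNA / (K_r + DNA)}{v_tx = k_r TsR DNA/(K_r+DNA)}
#' (or `k_r * TsR * DNA` under mass action) and
#' \deqn{v_{tl} = k_p \cdot TlR \cdot R_\tau / (K_p + R_\tau)}{v_tl = k_p TlR R_tau/(K_p+R_tau)}
#' with \eqn{R_\tau} the lagged transcript concentration. The state
#' derivatives are `dRNA = v_tx - delta_r*RNA`,
#' `dTsR = -a*v_tx - delta_TsR*TsR` (degradation term per variant),
#' `dTlR = -b*v_tl - delta_TlR*TlR/(K_l+TlR)` (or first-order),
#' `dP_dark = v_tl - k_mat*P_dark`, `dP_mat = k_mat*P_dark`, `dDNA = 0`.
#'
#' @param state Named numeric vector with elements `DNA`, `RNA`, `TsR`,
#'   `TlR`, `P_dark`, `P_mat`.
#' @param lagged_rna Transcript concentration at `t - tau_d` (nM).
#' @param params A [kinetic_params()] object (or coercible).
#' @param variant A [model_variant()].
#' @return Named numeric vector of derivatives, plus the fluxes as
#'   attributes `v_tx` and `v_tl`.
#' @export
#' @examples
#' s <- c(DNA = 3.75, RNA = 0, TsR = 1, TlR = 1, P_dark = 0, P_mat = 0)
#' rhs(s, lagged_rna = 0, theta_bulk(), model_variant("V1"))
rhs <- function(state, lagged_rna, params, variant = model_variant("V1")) {
  params <- as_kinetic_params(params)
  variant <- model_variant(variant)
  need <- c("DNA", "RNA", "TsR", "TlR", "P_dark", "P_mat")
  if (!all(need %in% names(state))) {
    stop("state must contain: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!is.finite(lagged_rna) || lagged_rna < 0) {
    stop("lagged_rna must be finite and >= 0", call. = FALSE)
  }
  DNA <- state[["DNA"]]; RNA <- state[["RNA"]]
  TsR <- state[["TsR"]]; TlR <- state[["TlR"]]
  Pd <- state[["P_dark"]]

  mm_rate <- function(k, Km, S, res, what) {
    if (S == 0 && Km == 0) {
      if (k == 0) return(0)
      stop("singular Michaelis-Menten term for ", what,
           ": zero K with zero substrate", call. = FALSE)
    }
    k * res * S / (Km + S)
  }
  v_tx <- if (variant$tx_law == "michaelis_menten") {
    mm_rate(params[["k_r"]], params[["K_r"]], DNA, TsR, "transcription")
  } else {
    params[["k_r"]] * TsR * DNA
  }
  v_tl <- if (variant$tl_law == "michaelis_menten") {
    mm_rate(params[["k_p"]], params[["K_p"]], lagged_rna, TlR, "translation")
  } else {
    params[["k_p"]] * TlR * lagged_rna
  }
  d_tsr <- if (variant$tsr_degradation == "first_order") {
    params[["delta_TsR"]] * TsR
  } else 0
  d_tlr <- if (variant$tlr_degradation == "michaelis_menten") {
    if (TlR == 0 && params[["K_l"]] == 0) 0
    else params[["delta_TlR"]] * TlR / (params[["K_l"]] + TlR)
  } else {
    params[["delta_TlR"]] * TlR
  }

  out <- c(
    DNA = 0,
    RNA = v_tx - params[["delta_r"]] * RNA,
    TsR = -params[["a"]] * v_tx - d_tsr,
    TlR = -params[["b"]] * v_tl - d_tlr,
    P_dark = v_tl - params[["k_mat"]] * Pd,
    P_mat = params[["k_mat"]] * Pd
  )
  attr(out, "v_tx") <- v_tx
  attr(out, "v_tl") <- v_tl
  out
}

variant_flags <- function(variant) {
  c(tx_mm = as.numeric(variant$tx_law == "michaelis_menten"),
    tl_mm = as.numeric(variant$tl_law == "michaelis_menten"),
    tsr_deg = as.numeric(variant$tsr_degradation == "first_order"),
    tlr_mm = as.numeric(variant$tlr_degradation == "michaelis_menten"))
}

#' Simulate mRNA, protein and resource trajectories
#'
#' Integrate the resource-limited expression model as a delay differential
#' equation. Translation at model time `t` uses the transcript
#' concentration at `t - tau_d`, with the constant pre-start history
#' `RNA(s) = rna0` for `s <= 0` (so mRNA-titration experiments begin
#' translating immediately after the delay). The measurement lag `tau_l`
#' is a pure reporting shift: the observed channels at data time `t` are
#' the model state at `t - tau_l` and are 0 for all model times `<= 0`.
#'
#' Integration uses an adaptive solver (`deSolve::dede()` on the compiled
#' model core, with stored dense history for the lagged term); when
#' `tau_d < 1e-3` h the delay is dynamically negligible and the plain ODE
#' path is used with the lagged transcript replaced by the current one.
#'
#' @param params A [kinetic_params()] object (or coercible named vector).
#' @param variant A [model_variant()]; default `"V1"`.
#' @param dna0 DNA template concentration (nM), held constant.
#' @param rna0 Initial transcript concentration (nM); also the pre-start
#'   delay history.
#' @param times Data-time grid in hours, starting at 0, strictly
#'   increasing.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return A tibble of class `cfe_trajectory` with columns `time_h`,
#'   `dna_nM`, `rna_nM`, `tsr`, `tlr`, `protein_dark_nM`,
#'   `protein_mat_nM`, `v_tx`, `v_tl`, `observed_rna_nM`,
#'   `observed_protein_nM`. State columns refer to model time
#'   `t - tau_l` (frozen at the initial state before the lag); observed
#'   columns are zero for model times `<= 0`.
#' @export
#' @examples
#' traj <- cfe_simulate(theta_bulk(), dna0 = 3.75,
#'                      times = seq(0, 8, by = 0.25))
#' head(traj)
cfe_simulate <- function(params, variant = model_variant("V1"),
                         dna0 = 0, rna0 = 0,
                         times = seq(0, 8, by = 1 / 6),
                         rtol = 1e-8, atol = 1e-10) {
  params <- as_kinetic_params(params)
  variant <- model_variant(variant)
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must start at 0 and be strictly increasing", call. = FALSE)
  }
  if (dna0 < 0 || rna0 < 0) {
    stop("dna0 and rna0 must be >= 0", call. = FALSE)
  }

  tau_l <- params[["tau_l"]]
  tau_d <- params[["tau_d"]]
  use_lag <- tau_d >= 1e-3

  # model times: data time t maps to model time t - tau_l (floored at 0)
  model_times <- pmax(times - tau_l, 0)
  solve_times <- sort(unique(c(0, model_times)))

  y0 <- c(RNA = rna0, TsR = 1, TlR = 1, P_dark = 0, P_mat = 0)
  parms <- c(unname(params[setdiff(param_names(), "tau_l")][1:12]),
             dna0, rna0, unname(variant_flags(variant)),
             as.numeric(use_lag))
  solver_args <- list(
    y = y0, times = solve_times, func = "cfe_derivs", parms = parms,
    dllname = "cfekinetics", initfunc = "cfe_init",
    nout = 2, outnames = c("v_tx", "v_tl"),
    rtol = rtol, atol = atol
  )
  sol <- tryCatch(
    if (use_lag) do.call(deSolve::dede, solver_args)
    else do.call(deSolve::ode, solver_args),
    warning = function(w) {
      stop("integration failed: ", conditionMessage(w), call. = FALSE)
    }
  )
  if (nrow(sol) < length(solve_times)) {
    stop("integration failed at time ", sol[nrow(sol), 1], " h",
         call. = FALSE)
  }
  sol <- as.data.frame(sol)

  # clip tiny numerical excursions; warn if they are not tiny
  state_cols <- c("RNA", "TsR", "TlR", "P_dark", "P_mat", "v_tx", "v_tl")
  worst <- min(0, vapply(sol[state_cols], min, numeric(1)))
  if (worst < -1e-9) {
    warning("state clipped at 0 by up to ", format(-worst, digits = 3),
            " nM during integration", call. = FALSE)
  }
  sol[state_cols] <- lapply(sol[state_cols], pmax, 0)
  sol$TsR <- pmin(sol$TsR, 1)
  sol$TlR <- pmin(sol$TlR, 1)

  idx <- match(model_times, sol$time)
  pre_lag <- (times - tau_l) <= 0
  out <- tibble::tibble(
    time_h = times,
    dna_nM = dna0,
    rna_nM = sol$RNA[idx],
    tsr = sol$TsR[idx],
    tlr = sol$TlR[idx],
    protein_dark_nM = sol$P_dark[idx],
    protein_mat_nM = sol$P_mat[idx],
    v_tx = sol$v_tx[idx],
    v_tl = sol$v_tl[idx],
    observed_rna_nM = ifelse(pre_lag, 0, sol$RNA[idx]),
    observed_protein_nM = ifelse(pre_lag, 0, sol$P_mat[idx])
  )
  class(out) <- c("cfe_trajectory", class(out))
  attr(out, "params") <- params
  attr(out, "variant") <- variant
  attr(out, "rna0") <- rna0
  out
}

# Lean solver core for the fitting hot path: observed channels at the
# requested data times only, no tibble assembly, NULL on solver failure.
sim_observed <- function(params, variant, dna0, rna0, times,
                         rtol = 1e-8, atol = 1e-10) {
  tau_l <- params[["tau_l"]]
  use_lag <- params[["tau_d"]] >= 1e-3
  model_times <- pmax(times - tau_l, 0)
  solve_times <- sort(unique(c(0, model_times)))
  y0 <- c(RNA = rna0, TsR = 1, TlR = 1, P_dark = 0, P_mat = 0)
  parms <- c(unname(params[1:12]), dna0, rna0,
             unname(variant_flags(variant)), as.numeric(use_lag))
  solver <- if (use_lag) deSolve::dede else deSolve::ode
  sol <- tryCatch(
    suppressWarnings(solver(
      y = y0, times = solve_times, func = "cfe_derivs", parms = parms,
      dllname = "cfekinetics", initfunc = "cfe_init",
      nout = 2, outnames = c("v_tx", "v_tl"),
      rtol = rtol, atol = atol)),
    error = function(e) NULL)
  if (is.null(sol) || nrow(sol) < length(solve_times) ||
      anyNA(sol[, c("RNA", "P_mat")])) {
    return(NULL)
  }
  idx <- match(model_times, sol[, "time"])
  rna <- pmax(sol[idx, "RNA"], 0)
  protein <- pmax(sol[idx, "P_mat"], 0)
  pre <- (times - tau_l) <= 0
  rna[pre] <- 0
  protein[pre] <- 0
  list(rna = unname(rna), protein = unname(protein))
}

#' Maximal transcription and translation rates along a trajectory
#'
#' Returns the maxima of the model fluxes `v_tx(t)` and `v_tl(t)` over the
#' simulated grid together with their argmax times. For typical
#' resource-limited kinetics the transcription flux is maximal at the
#' start (TsR and the saturation term only decrease), while the
#' translation flux peaks once enough transcript has accumulated.
#'
#' @param traj A `cfe_trajectory` from [cfe_simulate()].
#' @return A tibble with columns `process` (`"transcription"`,
#'   `"translation"`), `max_rate_nM_h` and `time_h`.
#' @export
max_rates <- function(traj) {
  if (!all(c("v_tx", "v_tl", "time_h") %in% names(traj))) {
    stop("traj must be a cfe_trajectory with flux columns", call. = FALSE)
  }
  if (nrow(traj) < 3) {
    stop("trajectory must have at least 3 points", call. = FALSE)
  }
  i_tx <- which.max(traj$v_tx)
  i_tl <- which.max(traj$v_tl)
  tibble::tibble(
    process = c("transcription", "translation"),
    max_rate_nM_h = c(traj$v_tx[i_tx], traj$v_tl[i_tl]),
    time_h = c(traj$time_h[i_tx], traj$time_h[i_tl])
  )
}

#' Write or read a trajectory as tidy CSV
#'
#' @param traj A `cfe_trajectory`.
#' @param path File path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a tibble.
#' @export
write_trajectory_csv <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj), path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
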