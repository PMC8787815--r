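# Independent oracles used across the suite. These are deliberately
# written from the model definition directly (scalar R arithmetic, fixed
# step sizes) and share no code with the package's solver path.

rel_err <- function(x, ref, floor = 0) {
  abs(x - ref) / pmax(abs(ref), floor)
}

# Fixed-step explicit-Euler integration of the delay system. The delay
# is handled by indexing the stored RNA history (constant rna0 before
# t = 0); the full V1 structure (MM/MM, first-order TsR, MM TlR) is
# hard-coded.
euler_dde <- function(params, dna0 = 0, rna0 = 0, t_end = 8, h = 1e-4) {
  p <- as.list(params)
  n <- round(t_end / h)
  RNA <- numeric(n + 1)
  TsR <- numeric(n + 1)
  TlR <- numeric(n + 1)
  Pd <- numeric(n + 1)
  Pm <- numeric(n + 1)
  RNA[1] <- rna0
  TsR[1] <- 1
  TlR[1] <- 1
  lag_steps <- round(p$tau_d / h)
  for (i in seq_len(n)) {
    lagged <- if (i - lag_steps >= 1) RNA[i - lag_steps] else rna0
    v_tx <- if (dna0 > 0) p$k_r * TsR[i] * dna0 / (p$K_r + dna0) else 0
    v_tl <- if (lagged > 0) {
      p$k_p * TlR[i] * lagged / (p$K_p + lagged)
    } else 0
    d_tlr <- if (TlR[i] > 0) {
      p$delta_TlR * TlR[i] / (p$K_l + TlR[i])
    } else 0
    RNA[i + 1] <- RNA[i] + h * (v_tx - p$delta_r * RNA[i])
    TsR[i + 1] <- max(TsR[i] + h * (-p$a * v_tx - p$delta_TsR * TsR[i]), 0)
    TlR[i + 1] <- max(TlR[i] + h * (-p$b * v_tl - d_tlr), 0)
    Pd[i + 1] <- Pd[i] + h * (v_tl - p$k_mat * Pd[i])
    Pm[i + 1] <- Pm[i] + h * p$k_mat * Pd[i]
  }
  list(time = seq(0, t_end, by = h), RNA = RNA, TsR = TsR, TlR = TlR,
       P_dark = Pd, P_mat = Pm)
}

# sample an euler_dde solution at given times
euler_at <- function(sol, times, what = "RNA") {
  h <- sol$time[2] - sol$time[1]
  sol[[what]][round(times / h) + 1]
}

# a small, fast study design used by several fitting tests
quick_bulk <- function(seed, noise_cv = 0.02,
                       dna_levels = c(0.94, 3.75, 7.5),
                       times = seq(0, 8, by = 0.5), replicates = 3) {
  generate_bulk_titration(generator_config(
    seed = seed, dna_levels = dna_levels, times = times,
    replicates = replicates, noise_cv = noise_cv))
}

# everything except the named rates pinned at the generating values
bulk_fixed_except <- function(free) {
  th <- theta_bulk()
  fx <- as.numeric(th[setdiff(param_names(), free)])
  names(fx) <- setdiff(param_names(), free)
  fx["tau_l"] <- 0
  fx
}
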