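init_state <- function(dna = 0, rna = 0) {
  c(DNA = dna, RNA = rna, TsR = 1, TlR = 1, P_dark = 0, P_mat = 0)
}

test_that("rhs reduces correctly when fluxes vanish", {
  p <- set_params(theta_bulk(), k_r = 0, k_p = 0)
  s <- init_state(dna = 3.75, rna = 100)
  s[["P_dark"]] <- 5
  d <- rhs(s, lagged_rna = 100, p)
  expect_equal(d[["RNA"]], -p[["delta_r"]] * 100)
  expect_equal(d[["P_mat"]], p[["k_mat"]] * 5)
  expect_equal(d[["P_dark"]], -p[["k_mat"]] * 5)
  expect_equal(attr(d, "v_tx"), 0)
  expect_equal(attr(d, "v_tl"), 0)

  # no substrate anywhere: only resource degradation remains
  d0 <- rhs(init_state(), lagged_rna = 0, theta_bulk())
  expect_equal(d0[["RNA"]], 0)
  expect_equal(d0[["P_dark"]], 0)
  expect_equal(d0[["P_mat"]], 0)
  expect_equal(d0[["TsR"]], -theta_bulk()[["delta_TsR"]])
  th <- theta_bulk()
  expect_equal(d0[["TlR"]],
               -th[["delta_TlR"]] * 1 / (th[["K_l"]] + 1))
})

test_that("rhs evaluates the Michaelis-Menten transcription flux", {
  d <- rhs(init_state(dna = 3.75), lagged_rna = 0, theta_bulk())
  expect_equal(d[["RNA"]], 2894 * 1 * 3.75 / (3.67 + 3.75))
  # mass-action variant drops the saturation denominator
  dm <- rhs(init_state(dna = 3.75), lagged_rna = 0, theta_bulk(),
            model_variant("V5"))
  expect_equal(dm[["RNA"]], 2894 * 3.75)
})

test_that("rhs rejects invalid inputs", {
  expect_error(rhs(init_state(), lagged_rna = -1, theta_bulk()),
               "lagged_rna")
  expect_error(as_kinetic_params(c(k_r = -5)), "non-negative")
  # MM with zero K and zero substrate is singular
  p <- set_params(theta_bulk(), K_p = 0)
  expect_error(rhs(init_state(dna = 1), lagged_rna = 0, p), "singular")
})

test_that("simulation without any template stays identically zero", {
  traj <- cfe_simulate(theta_bulk(), dna0 = 0, rna0 = 0,
                       times = seq(0, 4, by = 0.5))
  expect_true(all(traj$observed_rna_nM == 0))
  expect_true(all(traj$observed_protein_nM == 0))
  p0 <- set_params(theta_bulk(), k_r = 0)
  traj2 <- cfe_simulate(p0, dna0 = 3.75, rna0 = 0,
                        times = seq(0, 4, by = 0.5))
  expect_true(all(traj2$observed_rna_nM == 0))
  expect_true(all(traj2$observed_protein_nM == 0))
})

test_that("frozen-resource saturated transcription matches the closed form", {
  # a = 0, delta_TsR = 0 freeze TsR at 1; K_r = 0 saturates the MM term,
  # so RNA follows linear birth-death: (k_r/delta_r)(1 - exp(-delta_r t))
  p <- set_params(theta_bulk(), a = 0, delta_TsR = 0, K_r = 0, tau_l = 0)
  k_r <- p[["k_r"]]
  delta_r <- p[["delta_r"]]
  times <- seq(0, 1 / delta_r, length.out = 41)
  traj <- cfe_simulate(p, dna0 = 3.75, times = times)
  expected <- k_r / delta_r * (1 - exp(-delta_r * times))
  expect_lt(max(rel_err(traj$rna_nM[-1], expected[-1])), 1e-5)
  # spot value at t = 1/delta_r
  expect_equal(traj$rna_nM[41], k_r / delta_r * (1 - exp(-1)),
               tolerance = 1e-5)
})

test_that("adaptive delay solution matches a fixed-step Euler oracle", {
  p <- set_params(theta_bulk(), tau_l = 0)
  times <- seq(0, 8, by = 0.25)
  traj <- cfe_simulate(p, dna0 = 3.75, times = times)
  oracle <- euler_dde(p, dna0 = 3.75, t_end = 8, h = 1e-4)
  for (col in c("rna_nM", "protein_mat_nM")) {
    ref <- euler_at(oracle, times,
                    if (col == "rna_nM") "RNA" else "P_mat")
    scale <- max(ref)
    expect_lt(max(rel_err(traj[[col]][-1], ref[-1], floor = 1e-3 * scale)),
              1e-3)
  }
})

test_that("the delay system with tiny tau_d matches a plain ODE solve", {
  # tau_d below the threshold short-circuits to the ODE path; an
  # independent R-side integration of rhs() is the reference
  p <- set_params(theta_bulk(), tau_d = 0, tau_l = 0)
  times <- seq(0, 6, by = 0.25)
  traj <- cfe_simulate(p, dna0 = 3.75, times = times)
  ref <- deSolve::ode(
    y = c(RNA = 0, TsR = 1, TlR = 1, P_dark = 0, P_mat = 0),
    times = times,
    func = function(t, y, parms) {
      s <- c(DNA = 3.75, y)
      list(unname(rhs(s, lagged_rna = max(y[["RNA"]], 0), p)[-1]))
    },
    parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(rel_err(traj$rna_nM[-1], ref[-1, "RNA"])), 1e-6)
  expect_lt(max(rel_err(traj$protein_mat_nM[-c(1, 2)],
                        ref[-c(1, 2), "P_mat"])), 1e-6)
})

test_that("MM kinetics approach the saturated rate as K -> 0", {
  s <- init_state(dna = 3.75)
  p_sat <- set_params(theta_bulk(), K_r = 1e-8 * 3.75)
  d <- rhs(s, lagged_rna = 0, p_sat)
  expect_equal(d[["RNA"]], p_sat[["k_r"]], tolerance = 1e-6)
})

test_that("resources stay in [0, 1] and decrease; protein accumulates", {
  set.seed(42)
  for (i in 1:5) {
    p <- kinetic_params(
      k_r = 10^runif(1, 2, 4), K_r = 10^runif(1, -1, 1),
      delta_r = 10^runif(1, -2, 0), k_p = 10^runif(1, 2, 4),
      K_p = 10^runif(1, 1, 3), k_mat = 2.15,
      delta_TsR = 10^runif(1, -2, 0), delta_TlR = 10^runif(1, -2, 0),
      K_l = 10^runif(1, -6, 0), a = 10^runif(1, -5, -3),
      b = 10^runif(1, -5, -3), tau_d = runif(1, 0, 0.6))
    traj <- cfe_simulate(p, dna0 = 3.75, rna0 = 50,
                         times = seq(0, 8, by = 0.25))
    expect_true(all(traj$tsr >= 0 & traj$tsr <= 1))
    expect_true(all(traj$tlr >= 0 & traj$tlr <= 1))
    expect_true(all(diff(traj$tsr) <= 1e-12))
    expect_true(all(diff(traj$tlr) <= 1e-12))
    expect_true(all(diff(traj$protein_mat_nM) >= -1e-9))
    total <- traj$protein_dark_nM + traj$protein_mat_nM
    expect_true(all(diff(total) >= -1e-9))
    expect_true(all(traj$rna_nM >= 0))
  }
})

test_that("a delay longer than the simulated span suppresses translation", {
  p <- set_params(theta_bulk(), tau_d = 10, tau_l = 0)
  traj <- cfe_simulate(p, dna0 = 3.75, times = seq(0, 4, by = 0.5))
  expect_true(all(traj$protein_mat_nM == 0))
  expect_gt(max(traj$rna_nM), 0)
  # ... unless there is an rna0 history to translate from
  traj2 <- cfe_simulate(p, dna0 = 0, rna0 = 300,
                        times = seq(0, 4, by = 0.5))
  expect_gt(max(traj2$protein_mat_nM), 0)
})

test_that("the measurement lag shifts and zeroes the observed channels", {
  p <- set_params(theta_bulk(), tau_l = 0.5)
  times <- seq(0, 6, by = 0.25)
  traj <- cfe_simulate(p, dna0 = 3.75, times = times)
  expect_true(all(traj$observed_rna_nM[times <= 0.5] == 0))
  ref <- cfe_simulate(set_params(p, tau_l = 0), dna0 = 3.75,
                      times = times)
  # observed value at t equals the unlagged state at t - tau_l
  expect_equal(traj$observed_rna_nM[times == 3.0],
               ref$rna_nM[times == 2.5], tolerance = 1e-8)
})

test_that("max_rates finds the flux maxima and their times", {
  traj <- cfe_simulate(set_params(theta_bulk(), tau_l = 0), dna0 = 3.75,
                       times = seq(0, 8, by = 0.1))
  mr <- max_rates(traj)
  # transcription flux is a product of non-increasing factors: max at 0
  expect_equal(mr$time_h[mr$process == "transcription"], 0)
  expect_equal(mr$max_rate_nM_h[mr$process == "transcription"],
               2894 * 3.75 / (3.67 + 3.75), tolerance = 1e-6)
  # translation peaks strictly inside the span; brute-force scan agrees
  t_tl <- mr$time_h[mr$process == "translation"]
  expect_gt(t_tl, 0)
  expect_lt(t_tl, 8)
  dense <- cfe_simulate(set_params(theta_bulk(), tau_l = 0), dna0 = 3.75,
                        times = seq(0, 8, by = 0.01))
  expect_equal(t_tl, dense$time_h[which.max(dense$v_tl)],
               tolerance = 0.11)
  # degenerate trajectory: zero everywhere
  z <- cfe_simulate(set_params(theta_bulk(), k_r = 0), dna0 = 0,
                    times = seq(0, 2, by = 0.5))
  mrz <- max_rates(z)
  expect_equal(mrz$max_rate_nM_h, c(0, 0))
  expect_equal(mrz$time_h, c(0, 0))
  expect_error(max_rates(z[1:2, ]), "3 points")
})

test_that("trajectories round-trip through CSV", {
  traj <- cfe_simulate(theta_bulk(), dna0 = 3.75,
                       times = seq(0, 2, by = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$rna_nM, traj$rna_nM)
  expect_equal(back$time_h, traj$time_h)
})

test_that("simulate validates its inputs", {
  expect_error(cfe_simulate(theta_bulk(), dna0 = -1,
                            times = seq(0, 1, 0.5)), ">= 0")
  expect_error(cfe_simulate(theta_bulk(), dna0 = 1,
                            times = c(1, 2)), "start at 0")
  expect_error(cfe_simulate(theta_bulk(), dna0 = 1,
                            times = c(0, 1, 1)), "strictly increasing")
})
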