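test_that("the Gaussian NLL has its closed-form values", {
  # data generated exactly by the parameters: only the scale term remains
  d <- quick_bulk(seed = 1, noise_cv = 0, replicates = 1,
                  times = seq(0, 4, by = 1))
  n <- 2 * nrow(d)
  nll <- cfe_nll(theta_bulk(), "V1", d,
                 noise_spec("fixed", sd_rna = 1, sd_protein = 1))
  expect_equal(nll, n / 2 * log(2 * pi), tolerance = 1e-6)
  # doubling sigma on zero-residual data adds n*log(2)
  nll2 <- cfe_nll(theta_bulk(), "V1", d,
                  noise_spec("fixed", sd_rna = 2, sd_protein = 2))
  expect_equal(nll2 - nll, n * log(2), tolerance = 1e-6)
})

test_that("hand-computed residuals give the expected NLL", {
  # three protein residuals (1, -1, 2) at sigma 1 contribute
  # 3/2 log(2pi) + (1+1+4)/2; build data where only those points differ
  d <- quick_bulk(seed = 1, noise_cv = 0, replicates = 1,
                  times = seq(0, 4, by = 2))
  stopifnot(nrow(d) == 9)
  base <- cfe_nll(theta_bulk(), "V1", d,
                  noise_spec("fixed", sd_rna = 1, sd_protein = 1))
  d2 <- d
  d2$protein_nM[d2$template_nM == 3.75] <-
    pmax(d2$protein_nM[d2$template_nM == 3.75] + c(1, -1, 2), 0)
  nll <- cfe_nll(theta_bulk(), "V1", d2,
                 noise_spec("fixed", sd_rna = 1, sd_protein = 1))
  expect_equal(nll - base, 3.0, tolerance = 1e-6)
})

test_that("NLL returns a finite penalty instead of crashing the optimizer", {
  d <- quick_bulk(seed = 1, noise_cv = 0, replicates = 1,
                  times = seq(0, 2, by = 1))
  p_extreme <- set_params(theta_bulk(), k_r = 1e8, a = 1e8, K_r = 1e-8)
  nll <- cfe_nll(p_extreme, "V1", d,
                 noise_spec("fixed", sd_rna = 1, sd_protein = 1))
  expect_true(is.finite(nll))
})

test_that("aic follows 2k + 2nll and ranks by parsimony", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(12, 100), 224)
  expect_error(aic(-1, 0), ">= 0")
})

test_that("rank_models sorts by AIC with parsimony tie-break", {
  d <- quick_bulk(seed = 2, replicates = 2, times = seq(0, 4, by = 1))
  fx <- bulk_fixed_except(c("k_r", "delta_r"))
  f1 <- cfe_fit(d, free = c("k_r", "delta_r"), fixed = fx,
                bounds = default_bounds(), n_starts = 1,
                start = theta_bulk()[c("k_r", "delta_r")])
  f2 <- cfe_fit(d, free = "k_r",
                fixed = bulk_fixed_except("k_r"),
                bounds = default_bounds(), n_starts = 1,
                start = theta_bulk()["k_r"])
  rk <- rank_models(list(f1, f2))
  expect_equal(nrow(rk), 2)
  expect_true(all(diff(rk$aic) >= 0))
  expect_equal(rk$delta_aic[1], 0)
  # permuting the input order leaves the ranking unchanged
  expect_equal(rank_models(list(f2, f1)), rk)
  # single fit ranks as itself
  expect_equal(rank_models(f1)$variant, "V1")
  # refusing to rank fits on different data
  d3 <- quick_bulk(seed = 3, replicates = 2, times = seq(0, 4, by = 1))
  f3 <- cfe_fit(d3, free = "k_r", fixed = bulk_fixed_except("k_r"),
                bounds = default_bounds(), n_starts = 1,
                start = theta_bulk()["k_r"])
  expect_error(rank_models(list(f1, f3)), "different datasets")
})

test_that("an optimizer start at the truth cannot end worse", {
  d <- quick_bulk(seed = 4, replicates = 2, times = seq(0, 6, by = 1))
  free <- c("k_r", "delta_r", "k_p")
  f <- cfe_fit(d, free = free, fixed = bulk_fixed_except(free),
               bounds = default_bounds(), start = theta_bulk()[free])
  nll_true <- cfe_nll(set_params(theta_bulk(), tau_l = 0), "V1", d,
                      f$noise)
  expect_lte(f$nll_hat, nll_true + 1e-6)
  expect_equal(f$aic, 2 * f$k + 2 * f$nll_hat)
})

test_that("zero-noise data reproduces the generating parameters", {
  d <- quick_bulk(seed = 5, noise_cv = 0)
  free <- c("k_r", "K_r", "delta_r", "k_p", "K_p")
  f <- cfe_fit(d, free = free, fixed = bulk_fixed_except(free),
               bounds = default_bounds(), n_starts = 3, seed = 9,
               noise = noise_spec("fixed", sd_rna = 5, sd_protein = 5))
  expect_lt(max(rel_err(as.numeric(f$theta_hat[free]),
                        as.numeric(theta_bulk()[free]))), 0.01)
})

test_that("fits are reproducible from the seed", {
  d <- quick_bulk(seed = 6, replicates = 2, times = seq(0, 4, by = 1))
  free <- c("k_r", "delta_r")
  args <- list(d, free = free, fixed = bulk_fixed_except(free),
               bounds = default_bounds(), n_starts = 2, seed = 33)
  f1 <- do.call(cfe_fit, args)
  f2 <- do.call(cfe_fit, args)
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_identical(f1$nll_hat, f2$nll_hat)
  expect_identical(glance(f1), glance(f2))
})

test_that("fitting demands two template concentrations", {
  d <- quick_bulk(seed = 1, dna_levels = 3.75, replicates = 2,
                  times = seq(0, 2, by = 1))
  expect_error(cfe_fit(d), "2 distinct template")
})

test_that("tidy and glance expose the fit in broom style", {
  d <- quick_bulk(seed = 7, replicates = 2, times = seq(0, 4, by = 1))
  free <- c("k_r", "delta_r")
  f <- cfe_fit(d, free = free, fixed = bulk_fixed_except(free),
               bounds = default_bounds(), n_starts = 1,
               start = theta_bulk()[free])
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 13)
  expect_equal(sum(td$free), 2)
  expect_equal(td$units[td$parameter == "k_r"], "nM/h")
  gl <- glance(f)
  expect_equal(gl$k, 2)
  expect_equal(gl$aic, f$aic)
})

test_that("profiled NLL reproduces nll_hat at the MLE grid point", {
  d <- quick_bulk(seed = 8, times = seq(0, 6, by = 1))
  free <- c("k_r", "delta_r")
  f <- cfe_fit(d, free = free, fixed = bulk_fixed_except(free),
               bounds = default_bounds(), n_starts = 1,
               start = theta_bulk()[free])
  prof <- cfe_profile(f, d, "k_r", n_grid = 5)
  i0 <- which.min(abs(log10(prof$value) - log10(f$theta_hat[["k_r"]])))
  expect_equal(prof$nll[i0], f$nll_hat, tolerance = 1e-4)
  # profile never undercuts the MLE (within optimizer tolerance)
  expect_true(all(prof$nll >= f$nll_hat - 1e-4))
  expect_error(cfe_profile(f, d, "k_mat"), "not a free parameter")
})

test_that("a quadratic single-parameter profile matches its closed form", {
  # no nuisance parameters: the profile is the objective itself, and the
  # chi-squared CI is exactly 1 +/- 0.1 sqrt(qchisq(0.95, df))
  obj <- function(th) 0.5 * ((th[["theta"]] - 1) / 0.1)^2
  prof <- profile_nll(obj, c(theta = 1), "theta", n_grid = 401)
  expect_equal(prof$nll, 0.5 * ((prof$value - 1) / 0.1)^2,
               tolerance = 1e-12)
  for (df in c(1, 12)) {
    ci <- likelihood_ci(prof, nll_hat = 0, df = df)
    half <- 0.1 * sqrt(qchisq(0.95, df))
    expect_equal(ci$ci_low, 1 - half, tolerance = 1e-3)
    expect_equal(ci$ci_high, 1 + half, tolerance = 1e-3)
  }
})

test_that("an exact likelihood ridge profiles flat with infinite CI", {
  # theta1 * theta2 = c is a perfect ridge: profiling theta1 re-optimizes
  # theta2 to keep the product, so the profile sits at nll_hat everywhere
  obj <- function(th) 0.5 * ((th[["t1"]] * th[["t2"]] - 4) / 0.2)^2
  prof <- profile_nll(obj, c(t1 = 2, t2 = 2), "t1", n_grid = 21)
  expect_lt(max(prof$nll), 1e-6)
  ci <- likelihood_ci(prof, nll_hat = 0, df = 2)
  expect_equal(ci$ci_low, -Inf)
  expect_equal(ci$ci_high, Inf)
})

test_that("likelihood_ci rejects an inconsistent profile", {
  prof <- tibble::tibble(parameter = "x", value = c(1, 2, 3),
                         nll = c(50, 40, 45))
  expect_error(likelihood_ci(prof, nll_hat = 0, df = 1), "inconsistent")
})

test_that("one-sided identifiability yields one infinite bound", {
  grid <- 10^seq(-1, 1, length.out = 101)
  nll <- ifelse(grid < 1, 0.5 * ((grid - 1) / 0.05)^2, 0)
  prof <- tibble::tibble(parameter = "x", value = grid, nll = nll)
  ci <- likelihood_ci(prof, nll_hat = 0, df = 1)
  expect_true(is.finite(ci$ci_low))
  expect_equal(ci$ci_high, Inf)
})

test_that("profile CIs cover the truth at the stated rate", {
  # linear-Gaussian toy: y = m + b x + noise, known sigma; profiling each
  # parameter with the df = k (here 2) convention over-covers relative
  # to the pointwise 95% level, so coverage should be >= 0.95
  set.seed(101)
  x <- seq(-1, 1, length.out = 15)
  sigma <- 0.5
  m_true <- 2
  b_true <- 1.5
  n_rep <- 120
  covered <- matrix(FALSE, n_rep, 2,
                    dimnames = list(NULL, c("m", "b")))
  for (r in seq_len(n_rep)) {
    y <- m_true + b_true * x + rnorm(length(x), 0, sigma)
    obj <- function(th) {
      sum((y - th[["m"]] - th[["b"]] * x)^2) / (2 * sigma^2)
    }
    fit <- lm(y ~ x)
    th_hat <- c(m = unname(coef(fit)[1]), b = unname(coef(fit)[2]))
    if (any(th_hat <= 0)) next  # multiplicative profiling needs > 0
    for (pm in c("m", "b")) {
      prof <- profile_nll(obj, th_hat, pm, n_grid = 41)
      ci <- likelihood_ci(prof, nll_hat = obj(th_hat), df = 2)
      truth <- if (pm == "m") m_true else b_true
      covered[r, pm] <- ci$ci_low <= truth && truth <= ci$ci_high
    }
  }
  expect_gte(mean(covered[, "m"]), 0.95)
  expect_gte(mean(covered[, "b"]), 0.95)
})
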