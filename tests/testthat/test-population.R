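make_traces <- function(n_cells = 4, times = seq(0, 12, by = 3),
                        batch = "batch1", pop = "pop1", radius = 30,
                        protein_end = 1800, seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_cells), function(i) {
      f <- 1 + 0.05 * (i - mean(seq_len(n_cells)))
      tibble::tibble(
        population_id = pop, batch_id = batch,
        cell_id = paste0(batch, "_c", i),
        radius_um = radius * (1 + 0.02 * (i - 2)),
        time_h = times,
        rna_nM = 900 * f * times / max(times),
        protein_nM = protein_end * f * (times / max(times))^2)
    })
  })
}

test_that("cv is the sample SD over the mean, scale-free", {
  expect_equal(cv(c(5, 5, 5)), 0)
  x <- c(28.5, 30.4, 32.3)
  expect_equal(cv(x), sd(x) / mean(x))
  expect_equal(cv(3.7 * x), cv(x))
  expect_equal(cv(c(28.5, 32.3)), cv(c(28.5, 32.3)))
  expect_error(cv(5), "at least 2")
  expect_error(cv(c(-1, 1)), "zero mean")
  # rounded moments of a monodisperse population: SD/mean as printed
  expect_equal(1.9 / 30.4, 0.0625, tolerance = 1e-4)
})

test_that("population summaries recompute CVs from their own moments", {
  traces <- make_traces(n_cells = 6)
  s <- summarize_population(traces)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_cells, 6)
  expect_equal(s$radius_cv, s$radius_sd_um / s$radius_mean_um)
  expect_equal(s$rna_cv, s$rna_sd_nM / s$rna_mean_nM)
  expect_equal(s$protein_cv, s$protein_sd_nM / s$protein_mean_nM)
  expect_equal(s$endpoint_h, 12)
  # permutation invariance in trace order
  shuffled <- traces[rev(seq_len(nrow(traces))), ]
  expect_equal(summarize_population(shuffled), s)
})

test_that("degenerate populations are handled as specified", {
  one <- make_traces(n_cells = 1)
  expect_error(summarize_population(one), ">= 2 cells")
  # duplicated traces of a single cell: zero dispersion
  dup <- dplyr::bind_rows(
    make_traces(n_cells = 1),
    dplyr::mutate(make_traces(n_cells = 1), cell_id = "copy"))
  s <- summarize_population(dup)
  expect_equal(s$radius_cv, 0)
  expect_equal(s$protein_cv, 0)
})

test_that("generated populations recover their configured moments", {
  cfg <- generator_config(
    true_params = theta_cell(), seed = 21, noise_cv = 0,
    population = list(n_cells = 200, radius_mean_um = 30,
                      radius_cv = 0.05, expression_cv = 0.03,
                      dna_nM = 3.5, times = seq(0, 12, by = 1)))
  traces <- generate_population(cfg)
  s <- summarize_population(traces)
  se_mean <- 30 * 0.05 / sqrt(200)
  expect_lt(abs(s$radius_mean_um - 30), 3 * se_mean)
  se_cv <- 0.05 / sqrt(2 * (200 - 1))
  expect_lt(abs(s$radius_cv - 0.05), 3 * se_cv)
  expect_lt(abs(s$protein_cv - 0.03), 3 * 0.03 / sqrt(2 * 199))
  # mRNA and protein carry the same cell-to-cell variability
  expect_lt(abs(s$rna_cv - s$protein_cv), 0.01)
})

test_that("summary statistics converge to generator settings as 1/sqrt(n)", {
  errs <- purrr::map_dbl(c(25, 100, 400), function(n) {
    reps <- purrr::map_dbl(1:6, function(r) {
      cfg <- generator_config(
        true_params = theta_cell(), seed = 1000 + 7 * n + r,
        noise_cv = 0,
        population = list(n_cells = n, radius_mean_um = 30,
                          radius_cv = 0.05, expression_cv = 0.025,
                          dna_nM = 3.5, times = seq(0, 12, by = 4)))
      s <- summarize_population(generate_population(cfg))
      abs(s$radius_cv - 0.05)
    })
    sqrt(mean(reps^2))
  })
  # RMS error shrinks roughly four-fold from n = 25 to n = 400
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.05 / sqrt(2 * 399) * 3)
})

test_that("batch CVs are computed across batch-level values", {
  expect_equal(batch_cv(c(2000, 2000, 2000), c(1, 1, 1)),
               tibble::tibble(n_batches = 3, cv_endpoint_protein = 0,
                              cv_max_translation_rate = 0))
  b <- batch_cv(c(1800, 2000, 2200))
  expect_equal(b$cv_endpoint_protein, 0.1)
  expect_error(batch_cv(2000), "2 batches")
  # from per-cell traces: two identical batches collapse to zero CV
  traces <- dplyr::bind_rows(make_traces(batch = "batch1"),
                             make_traces(batch = "batch2"))
  bt <- batch_cv(traces)
  expect_equal(bt$n_batches, 2)
  expect_equal(bt$cv_endpoint_protein, 0)
  expect_equal(bt$cv_max_translation_rate, 0)
})

test_that("generator batch variability is recovered by batch_cv", {
  ests <- purrr::map_dbl(1:8, function(r) {
    cfg <- generator_config(
      true_params = theta_cell(), seed = 500 + r, noise_cv = 0.01,
      population = list(n_cells = 12, n_batches = 6, batch_cv = 0.10,
                        dna_nM = 3.5, times = seq(0, 12, by = 2)))
    batch_cv(generate_population(cfg))$cv_endpoint_protein
  })
  # centered on the configured 0.10 (sampling SE of a 6-batch CV is
  # roughly 0.10/sqrt(10) ~ 0.03; the mean of 8 replicates is tighter)
  expect_lt(abs(mean(ests) - 0.10), 0.03)
})

test_that("max translation rate picks the steepest smoothed slope", {
  t <- seq(0, 10, by = 0.5)
  # logistic-like protein course: steepest at the midpoint
  prot <- 1000 / (1 + exp(-(t - 5)))
  mr <- max_translation_rate(t, prot)
  # the smoothed finite difference underestimates the true peak slope
  # (250 nM/h) slightly; it must stay close to and below it
  expect_lte(mr, 250)
  expect_equal(mr, 250, tolerance = 0.1)
  # without smoothing the centered difference is sharper
  expect_gte(max_translation_rate(t, prot, smooth_width = 1), mr)
  expect_error(max_translation_rate(t[1:2], prot[1:2]), "length")
})

test_that("expression ratios track paired channels", {
  expect_equal(expression_ratio(c(3, 6, 9), c(1, 2, 3)),
               tibble::tibble(n_cells = 3, ratio_mean = 3, ratio_sd = 0))
  same <- expression_ratio(c(2, 4), c(2, 4))
  expect_equal(same$ratio_mean, 1)
  expect_equal(same$ratio_sd, 0)
  expect_warning(out <- expression_ratio(c(3, 6), c(1, 0)), "zero")
  expect_equal(out$n_cells, 1)
  # round trip at the reference two-reporter ratio
  set.seed(31)
  b <- rnorm(85, 12, 0.5)
  a <- 3.11 * b * (1 + 0.04 * rnorm(85))
  est <- expression_ratio(a, b)
  expect_lt(abs(est$ratio_mean - 3.11),
            3 * est$ratio_sd / sqrt(est$n_cells))
})

test_that("cell traces round-trip through CSV", {
  traces <- make_traces(n_cells = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cell_traces_csv(traces, path)
  back <- read_cell_traces_csv(path)
  expect_equal(back$protein_nM, traces$protein_nM)
  expect_equal(back$cell_id, traces$cell_id)
})
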