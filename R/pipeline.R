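#' Run the end-to-end analysis pipeline from a YAML config
#'
#' Executes the requested stages in order — `generate` (bulk titration
#' and/or population data), `calibrate`, `fit`, `select`, `profile`,
#' `summarize` — and writes their artifacts (CSV/JSON) plus a run
#' manifest to the output directory. Reruns with the same config and
#' seed produce identical outputs.
#'
#' The config is a YAML map with (all optional unless a stage needs
#' them): `seed`, `out_dir`, `stages` (character vector), `params`
#' (named overrides of [theta_bulk()]), `variant` (code or four-field
#' map), `generate` (keys `bulk` and/or `population`, passed to
#' [generator_config()]), `calibrate` (`csv` path of a dilution series),
#' `fit` (`free`, `fixed`, `bounds`, `n_starts`, `noise`), `select`
#' (`variants`, `n_starts`), `profile` (`parameters`, `n_grid`).
#' Unknown keys raise a config error naming the key.
#'
#' @param config_path Path to the YAML configuration.
#' @param out_dir Output directory (overrides the config; default
#'   `"cfe_run"`).
#' @param seed Seed override.
#' @return The run manifest (a list, also written as
#'   `manifest.json`): config hash, seed, package version, per-stage
#'   status and timing, output files, warnings.
#' @export
run_pipeline <- function(config_path, out_dir = NULL, seed = NULL) {
  if (!file.exists(config_path)) {
    stop("config file not found: ", config_path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(config_path)
  known <- c("seed", "out_dir", "stages", "params", "variant", "generate",
             "calibrate", "fit", "select", "profile", "summarize")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  seed <- as.integer(seed %||% cfg$seed %||% 1)
  out_dir <- out_dir %||% cfg$out_dir %||% "cfe_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages %||% c("generate", "fit", "profile", "summarize")

  params <- theta_bulk()
  if (!is.null(cfg$params)) params <- set_params(params,
                                                 unlist(cfg$params))
  variant <- if (is.null(cfg$variant)) model_variant("V1")
             else if (is.character(cfg$variant)) model_variant(cfg$variant)
             else do.call(model_variant, cfg$variant)

  manifest <- list(
    config = normalizePath(config_path),
    config_hash = unname(tools::md5sum(config_path)),
    seed = seed,
    package_version = as.character(utils::packageVersion("cfekinetics")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = list(),
    outputs = character(0),
    warnings = character(0)
  )
  note_warning <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  emit <- function(name) {
    path <- file.path(out_dir, name)
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    status <- tryCatch({
      withCallingHandlers(fun(), warning = note_warning)
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      status = status,
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    if (!identical(status, "ok")) {
      manifest$failed_stage <<- name
      write_manifest()
      stop("stage '", name, "' ", status, call. = FALSE)
    }
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  bulk_data <- NULL
  pop_data <- NULL
  fit <- NULL
  profiles <- list()

  if ("generate" %in% stages) run_stage("generate", function() {
    gen <- cfg$generate %||% list()
    pop <- gen$population %||% list()
    if (is.list(pop$times)) pop$times <- do.call(seq, pop$times)
    if (!is.null(pop$dna_nM)) pop$dna_nM <- unlist(pop$dna_nM)
    gcfg <- generator_config(
      true_params = params, variant = variant,
      dna_levels = unlist(gen$bulk$dna_levels) %||%
        c(0.94, 1.875, 3.75, 7.5),
      rna_levels = unlist(gen$bulk$rna_levels) %||% numeric(0),
      replicates = gen$bulk$replicates %||% 3,
      times = if (!is.null(gen$bulk$times))
        do.call(seq, gen$bulk$times) else seq(0, 8, by = 1 / 6),
      noise_cv = gen$bulk$noise_cv %||% 0.02,
      population = pop,
      seed = seed
    )
    if (!identical(gen$bulk, FALSE)) {
      bulk_data <<- generate_bulk_titration(gcfg)
      write_titration_csv(bulk_data, emit("bulk_data.csv"))
    }
    if (!is.null(gen$population)) {
      pop_data <<- generate_population(gcfg)
      write_cell_traces_csv(pop_data, emit("population_data.csv"))
    }
  })

  if ("calibrate" %in% stages) run_stage("calibrate", function() {
    if (is.null(cfg$calibrate$csv)) {
      stop("calibrate stage needs a 'csv' path")
    }
    series <- readr::read_csv(cfg$calibrate$csv, show_col_types = FALSE)
    curves <- series |>
      dplyr::group_split(.data$channel) |>
      purrr::map_dfr(function(d) glance(fit_calibration(d)))
    readr::write_csv(curves, emit("calibration_curves.csv"))
  })

  if ("fit" %in% stages) run_stage("fit", function() {
    if (is.null(bulk_data)) {
      if (is.null(cfg$fit$csv)) stop("fit stage needs generated data or ",
                                     "a 'csv' path")
      bulk_data <<- read_titration_csv(cfg$fit$csv)
    }
    fit <<- cfe_fit(
      bulk_data, variant,
      free = unlist(cfg$fit$free),
      fixed = unlist(cfg$fit$fixed),
      bounds = cfg$fit$bounds %||% default_bounds(params),
      n_starts = cfg$fit$n_starts %||% 20,
      seed = seed,
      noise = noise_spec(cfg$fit$noise %||% "pooled")
    )
    jsonlite::write_json(
      c(glance(fit), list(config_hash = manifest$config_hash,
                          seed = seed,
                          estimates = as.list(fit$theta_hat))),
      emit("fit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  if ("select" %in% stages) run_stage("select", function() {
    if (is.null(bulk_data)) stop("select stage needs data (run generate ",
                                 "or fit first)")
    codes <- unlist(cfg$select$variants) %||% model_variants()$code
    fits <- purrr::map(codes, function(cd) {
      cfe_fit(bulk_data, model_variant(cd),
              fixed = unlist(cfg$fit$fixed),
              bounds = cfg$fit$bounds %||% default_bounds(params),
              n_starts = cfg$select$n_starts %||% 5,
              seed = seed,
              noise = noise_spec(cfg$fit$noise %||% "pooled"))
    })
    readr::write_csv(rank_models(fits), emit("model_ranking.csv"))
    if (is.null(fit)) fit <<- fits[[which.min(purrr::map_dbl(fits,
                                                             "aic"))]]
  })

  if ("profile" %in% stages) run_stage("profile", function() {
    if (is.null(fit)) stop("profile stage needs a fit")
    pars <- unlist(cfg$profile$parameters) %||% fit$free
    profiles <<- purrr::map(pars, function(pm) {
      cfe_profile(fit, bulk_data, pm,
                  n_grid = cfg$profile$n_grid %||% 11)
    })
    names(profiles) <<- pars
    readr::write_csv(dplyr::bind_rows(profiles), emit("profiles.csv"))
  })

  if ("fit" %in% stages || "select" %in% stages) {
    report <- tidy(fit, profiles = if (length(profiles) > 0) profiles)
    readr::write_csv(report, emit("parameter_report.csv"))
  }

  if ("summarize" %in% stages) run_stage("summarize", function() {
    if (is.null(pop_data)) stop("summarize stage needs population data ",
                                "(configure generate$population)")
    readr::write_csv(summarize_population(pop_data),
                     emit("population_report.csv"))
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  write_manifest()
  manifest$outputs <- c(manifest$outputs,
                        file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Default fitting bounds around a reference parameter set
#'
#' One decade either side of each (positive) reference value; useful as
#' a generic box for multistart fitting.
#'
#' @param params Reference [kinetic_params()].
#' @param decades Half-width in decades.
#' @return Named list of `c(lower, upper)`.
#' @export
default_bounds <- function(params = theta_bulk(), decades = 1) {
  params <- as_kinetic_params(params)
  out <- purrr::map(as.list(params), function(v) {
    v <- max(v, 1e-8)
    c(v / 10^decades, v * 10^decades)
  })
  stats::setNames(out, names(params))
}
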