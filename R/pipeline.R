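#' Configuration for an end-to-end pipeline run
#'
#' Collects every knob of the synth -> fit -> simulate -> validate -> map
#' pipeline in one validated object so a run is fully described by its
#' config (plus the package version). All randomness derives from the
#' single `seed`.
#'
#' @param outdir output directory (created if absent).
#' @param seed master integer seed.
#' @param species reference fixture to draw synthetic data from
#'   (`"rosa"` or `"quilicii"`).
#' @param temperatures constant temperatures for the rearing design and
#'   the life-table simulations.
#' @param n_per_cohort,n_replicates,n_pairs rearing design sizes.
#' @param sim_n individuals per simulated cohort (default 100).
#' @param sim_reps repetitions per temperature (default 50).
#' @param temperature_csv optional path to an annual min/max temperature
#'   CSV (columns `day`, `tmin`, `tmax`) used for validation and the
#'   series-level indices; when `NULL` an outdoor-like synthetic year is
#'   generated.
#' @param raster_rows,raster_cols synthetic climatology dimensions.
#' @param require_reproduction ERI mode (see [compute_eri()]).
#' @param lambda_floor AI floor (see [compute_ai()]).
#' @param establishment_cutoff classification threshold for the ERI map.
#' @return a list of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, species = "rosa",
                       temperatures = c(10, 15, 20, 25, 30, 33, 35),
                       n_per_cohort = 100L, n_replicates = 5L, n_pairs = 15L,
                       sim_n = 100L, sim_reps = 50L,
                       temperature_csv = NULL,
                       raster_rows = 12L, raster_cols = 10L,
                       require_reproduction = FALSE,
                       lambda_floor = 0.5, establishment_cutoff = 0.6) {
  stopifnot(is.character(outdir), length(outdir) == 1L,
            is.numeric(seed), sim_n >= 1, sim_reps >= 2)
  if (!is.null(temperature_csv) && !file.exists(temperature_csv))
    stop("temperature file not found: ", temperature_csv)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full phenology-to-risk pipeline
#'
#' Executes the stages in order and writes per-stage artifacts under
#' `config$outdir`:
#' 1. **synth** -- synthetic cohort and adult observation tables
#'    (`cohort_observations.csv`, `adult_longevity.csv`,
#'    `adult_daily_eggs.csv`), an annual temperature series
#'    (`annual_temperatures.csv`) and a synthetic monthly climatology
#'    (`tmin_01.asc` ... `tmax_12.asc`);
#' 2. **fit** -- the fitted phenology model (`fitted_model.json`) and a
#'    table of fitted parameters with fit statistics
#'    (`fitted_parameters.csv`);
#' 3. **simulate** -- life-table parameter estimates per constant
#'    temperature (`life_table_parameters.csv`) and the quadratic trend
#'    of the finite rate of increase (`lambda_quadratic.json`);
#' 4. **validate** -- Euclidean distances between stage-level summaries
#'    simulated from the fitted model and held-out synthetic observations
#'    under the fluctuating annual series (`validation.csv`);
#' 5. **map** -- `eri.asc`, `gi.asc`, `ai.asc` and
#'    `establishment.asc` over the synthetic climatology, plus
#'    series-level indices (`series_indices.csv`).
#'
#' A `manifest.json` records the config, seeds, package and R versions
#' and the files written. Re-running with an identical config reproduces
#' identical outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  out <- function(f) file.path(config$outdir, f)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- synth ---------------------------------------------------------------
  say("stage synth")
  truth <- reference_model(config$species)
  gen <- generator_config(truth, config$temperatures,
                          config$n_per_cohort, config$n_replicates,
                          config$n_pairs, seed = config$seed)
  cohort <- stage("synth", generate_cohort_observations(gen))
  adults <- stage("synth", generate_adult_observations(gen))
  utils::write.csv(cohort, out("cohort_observations.csv"), row.names = FALSE)
  utils::write.csv(adults$longevity, out("adult_longevity.csv"),
                   row.names = FALSE)
  utils::write.csv(adults$daily_eggs, out("adult_daily_eggs.csv"),
                   row.names = FALSE)
  annual <- if (is.null(config$temperature_csv)) {
    generate_annual_temperatures("outdoor_like", seed = config$seed + 2L)
  } else {
    stage("synth", read_temperature_csv(config$temperature_csv))
  }
  utils::write.csv(annual, out("annual_temperatures.csv"), row.names = FALSE)
  clim <- generate_temperature_raster(config$raster_rows, config$raster_cols,
                                      seed = config$seed + 3L)
  for (m in 1:12) {
    write_ascii_grid(clim$tmin[[m]], out(sprintf("tmin_%02d.asc", m)))
    write_ascii_grid(clim$tmax[[m]], out(sprintf("tmax_%02d.asc", m)))
  }
  files <- c(files, "cohort_observations.csv", "adult_longevity.csv",
             "adult_daily_eggs.csv", "annual_temperatures.csv",
             sprintf("tmin_%02d.asc", 1:12), sprintf("tmax_%02d.asc", 1:12))

  # -- fit -----------------------------------------------------------------
  say("stage fit")
  built <- stage("fit", fit_phenology_model(cohort, adults))
  model <- built$model
  jsonlite::write_json(model_to_list(model), out("fitted_model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ptab <- do.call(rbind, lapply(
    c("egg", "larva", "pupa"), function(s) {
      f <- built$fits[[s]]
      rbind(.fit_row(paste0(s, "_dev_rate"), f$dev_rate),
            .fit_row(paste0(s, "_mortality"), f$mortality))
    }))
  ptab <- rbind(ptab,
                .fit_row("adult_senescence", built$fits$senescence),
                .fit_row("fecundity", built$fits$fecundity),
                .fit_row("oviposition", built$fits$oviposition))
  utils::write.csv(ptab, out("fitted_parameters.csv"), row.names = FALSE)
  files <- c(files, "fitted_model.json", "fitted_parameters.csv")

  # -- simulate ------------------------------------------------------------
  say("stage simulate")
  lt_rows <- list()
  for (temp in config$temperatures) {
    ts <- constant_series(temp, 365L)
    tabs <- lapply(seq_len(config$sim_reps), function(r)
      simulate_cohort(model, ts, config$sim_n,
                      seed = config$seed * 1000L + round(temp) * 10L + r))
    est <- stage("simulate", estimate_life_table_parameters(tabs))
    s <- est$summary
    lt_rows[[length(lt_rows) + 1L]] <-
      cbind(data.frame(temperature_C = temp, n_viable = est$n_viable),
            stats::setNames(as.data.frame(t(s$mean)), s$parameter),
            stats::setNames(as.data.frame(t(s$se)), paste0(s$parameter, "_se")))
  }
  lt <- do.call(rbind, lt_rows)
  utils::write.csv(lt, out("life_table_parameters.csv"), row.names = FALSE)
  ok <- is.finite(lt$lambda)
  lambda_fn <- stage("simulate",
                     fit_lifetable_quadratic(lt$temperature_C[ok], lt$lambda[ok]))
  jsonlite::write_json(spec_to_list(lambda_fn), out("lambda_quadratic.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "life_table_parameters.csv", "lambda_quadratic.json")

  # -- validate ------------------------------------------------------------
  say("stage validate")
  obs_lt <- simulate_cohort(truth, annual, config$sim_n,
                            seed = config$seed + 7L)
  sim_lt <- simulate_cohort(model, annual, config$sim_n,
                            seed = config$seed + 8L)
  vd <- stage("validate", validate_against_observed(
    list(duration = obs_lt$stage_summary$mean_duration[1:3],
         mortality = obs_lt$stage_summary$mortality[1:3]),
    list(duration = sim_lt$stage_summary$mean_duration[1:3],
         mortality = sim_lt$stage_summary$mortality[1:3])))
  utils::write.csv(vd, out("validation.csv"), row.names = FALSE)
  files <- c(files, "validation.csv")

  # -- map -----------------------------------------------------------------
  say("stage map")
  grids <- stage("map", compute_indices_for_grid(
    model, lambda_fn, clim$tmin, clim$tmax,
    require_reproduction = config$require_reproduction,
    lambda_floor = config$lambda_floor))
  write_ascii_grid(grids$eri, out("eri.asc"))
  write_ascii_grid(grids$gi, out("gi.asc"))
  write_ascii_grid(grids$ai, out("ai.asc"))
  write_ascii_grid(classify_establishment(grids$eri,
                                          config$establishment_cutoff),
                   out("establishment.asc"))
  series_idx <- data.frame(
    eri = compute_eri(model, annual, config$require_reproduction),
    gi = compute_gi(model, annual),
    ai = compute_ai(lambda_fn, annual, config$lambda_floor))
  utils::write.csv(series_idx, out("series_indices.csv"), row.names = FALSE)
  files <- c(files, "eri.asc", "gi.asc", "ai.asc", "establishment.asc",
             "series_indices.csv")

  # -- manifest ------------------------------------------------------------
  cfg <- unclass(config)
  cfg$temperature_csv <- if (is.null(cfg$temperature_csv)) NA_character_
                         else cfg$temperature_csv
  manifest <- list(
    package = "phenrisk",
    package_version = as.character(utils::packageVersion("phenrisk")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg,
    seed = config$seed,
    files = files
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", config$outdir)
  invisible(manifest)
}

.fit_row <- function(process, fit) {
  data.frame(process = process, form = fit$spec$form,
             params = paste(sprintf("%s=%.6g", names(fit$spec$params),
                                    fit$spec$params), collapse = "; "),
             aic = fit$aic, r2 = fit$r2, n_obs = fit$n_obs,
             converged = fit$converged)
}

#' Read an annual min/max temperature CSV
#'
#' Expects columns `day`, `tmin`, `tmax` (or `tmin_C`/`tmax_C`).
#'
#' @param path CSV path.
#' @return a [temperature_series()].
#' @export
read_temperature_csv <- function(path) {
  if (!file.exists(path)) stop("temperature file not found: ", path)
  df <- utils::read.csv(path)
  nm <- names(df)
  pick <- function(a, b) if (a %in% nm) df[[a]] else if (b %in% nm) df[[b]]
    else stop("missing column '", a, "' in ", path)
  temperature_series(pick("tmin", "tmin_C"), pick("tmax", "tmax_C"),
                     day = if ("day" %in% nm) df$day else seq_len(nrow(df)))
}
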