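#' Configuration for the synthetic rearing-study generator
#'
#' Describes a constant-temperature life-table study design: the true
#' phenology model the data are drawn from, the set of constant
#' temperatures, the cohort size and replication for immature stages, and
#' the number of adult pairs observed per temperature. Defaults follow
#' the standard tephritid design: seven constant temperatures (10, 15,
#' 20, 25, 30, 33, 35 degrees C), cohorts of 100 replicated five times,
#' and 15 adult pairs per temperature.
#'
#' @param model the true [phenology_model()].
#' @param temperatures constant temperatures, degrees Celsius.
#' @param n_per_cohort individuals per cohort (default 100).
#' @param n_replicates replicates per stage and temperature (default 5).
#' @param n_pairs adult pairs per temperature (default 15).
#' @param seed integer seed; mandatory for reproducibility.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(model,
                             temperatures = c(10, 15, 20, 25, 30, 33, 35),
                             n_per_cohort = 100L, n_replicates = 5L,
                             n_pairs = 15L, seed) {
  stopifnot(inherits(model, "phenology_model"),
            n_per_cohort >= 1, n_replicates >= 1, n_pairs >= 1)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is required")
  structure(list(model = model, temperatures = temperatures,
                 n_per_cohort = as.integer(n_per_cohort),
                 n_replicates = as.integer(n_replicates),
                 n_pairs = as.integer(n_pairs), seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate stage-specific cohort observations
#'
#' Emulates a constant-temperature rearing study: for every stage,
#' temperature and replicate, the number of survivors is drawn
#' Binomial(n, 1 - M(T)) from the stage's mortality curve, and survivor
#' development durations are drawn from the log-logistic distribution
#' with median `1 / r(T)` and shape equal to the stage's development-time
#' slope. Non-viable temperatures (zero development rate or M(T) = 1)
#' yield all-dead cohorts, not an error. Deterministic under the
#' config's seed.
#'
#' @param config a [generator_config()].
#' @return a long data frame with columns `stage`, `temperature_C`,
#'   `replicate`, `individual_id`, `survived`, `duration_days` (NA for
#'   non-survivors).
#' @export
generate_cohort_observations <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  model <- config$model
  out <- list()
  for (st_name in names(model$stages)) {
    st <- model$stages[[st_name]]
    for (temp in config$temperatures) {
      r <- eval_development_rate(st$dev_rate, temp)
      m <- eval_mortality(st$mortality, temp)
      p_surv <- if (r > 0) 1 - m else 0
      for (rep_i in seq_len(config$n_replicates)) {
        n <- config$n_per_cohort
        n_surv <- stats::rbinom(1, n, p_surv)
        dur <- rep(NA_real_, n)
        if (n_surv > 0)
          dur[seq_len(n_surv)] <-
            .stage_threshold(n_surv, st$devtime_slope) / r
        out[[length(out) + 1L]] <- data.frame(
          stage = st_name, temperature_C = temp, replicate = rep_i,
          individual_id = seq_len(n),
          survived = seq_len(n) <= n_surv,
          duration_days = dur)
      }
    }
  }
  do.call(rbind, out)
}

#' Generate adult fecundity and longevity observations
#'
#' Emulates paired-adult observation at constant temperatures: each
#' female's lifespan comes from the senescence-quantile mechanism
#' (threshold `s` over senescence rate `S(T)`; deterministic `s = 1`
#' under the default adult slope), and her daily egg count is Poisson
#' with mean \eqn{f(T)\,[O(x_{d}) - O(x_{d-1})]}, so lifetime totals
#' average \eqn{f(T)\,O(s)}.
#'
#' @param config a [generator_config()].
#' @return a list with `longevity` (one row per female: `temperature_C`,
#'   `pair_id`, `lifespan_days`, `total_eggs`) and `daily_eggs` (one row
#'   per female-day: `temperature_C`, `pair_id`, `day`, `eggs`).
#' @export
generate_adult_observations <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  model <- config$model
  lon <- list(); eggs <- list()
  for (temp in config$temperatures) {
    S <- eval_senescence(model$female_senescence, temp)
    f <- eval_total_fecundity(model$fecundity, temp)
    for (i in seq_len(config$n_pairs)) {
      s <- .stage_threshold(1, model$adult_slope)
      lifespan <- ceiling(s / S)
      x <- pmin(seq_len(lifespan) * S, s)
      dO <- diff(c(eval_oviposition_cdf(model$oviposition, 0),
                   eval_oviposition_cdf(model$oviposition, x)))
      daily <- stats::rpois(lifespan, f * dO)
      lon[[length(lon) + 1L]] <- data.frame(
        temperature_C = temp, pair_id = i,
        lifespan_days = lifespan, total_eggs = sum(daily))
      eggs[[length(eggs) + 1L]] <- data.frame(
        temperature_C = temp, pair_id = i,
        day = seq_len(lifespan), eggs = daily)
    }
  }
  list(longevity = do.call(rbind, lon), daily_eggs = do.call(rbind, eggs))
}

#' Generate an annual daily temperature series
#'
#' Three profiles:
#' * `constant`: `tmin = tmax = temp` on all 365 days;
#' * `sinusoid`: seasonal sinusoid around `mean_tmin` / `mean_tmax` with
#'   the given `amplitude` and optional Gaussian day-to-day noise;
#' * `outdoor_like`: a tropical-highland regime in which daily minima
#'   stay within \[9.14, 16.68\] degrees C and maxima within
#'   \[18.84, 37.66\] (a seasonal sinusoid spanning each band plus noise,
#'   clamped to the band).
#'
#' @param profile `"constant"`, `"sinusoid"` or `"outdoor_like"`.
#' @param seed integer seed (used by the stochastic profiles).
#' @param temp constant profile temperature.
#' @param mean_tmin,mean_tmax,amplitude,noise_sd sinusoid parameters.
#' @param tmin_range,tmax_range outdoor-like bounds `c(lo, hi)`.
#' @param days series length (default 365).
#' @return a [temperature_series()].
#' @export
generate_annual_temperatures <- function(profile = c("constant", "sinusoid",
                                                     "outdoor_like"),
                                         seed = 1L, temp = 25,
                                         mean_tmin = 12, mean_tmax = 26,
                                         amplitude = 5, noise_sd = 0,
                                         tmin_range = c(9.14, 16.68),
                                         tmax_range = c(18.84, 37.66),
                                         days = 365L) {
  profile <- match.arg(profile)
  if (profile == "constant")
    return(temperature_series(rep(temp, days), rep(temp, days)))
  set.seed(seed)
  season <- sin(2 * pi * (seq_len(days) - 1) / 365)
  if (profile == "sinusoid") {
    if (mean_tmin > mean_tmax) stop("mean_tmin must be <= mean_tmax")
    tmin <- mean_tmin + amplitude * season + stats::rnorm(days, 0, noise_sd)
    tmax <- mean_tmax + amplitude * season + stats::rnorm(days, 0, noise_sd)
    return(temperature_series(pmin(tmin, tmax), pmax(tmin, tmax)))
  }
  if (tmin_range[1] > tmin_range[2] || tmax_range[1] > tmax_range[2])
    stop("inverted temperature bounds")
  mid <- function(rg) (rg[1] + rg[2]) / 2
  amp <- function(rg) (rg[2] - rg[1]) / 2
  tmin <- mid(tmin_range) + 0.7 * amp(tmin_range) * season +
    stats::rnorm(days, 0, 0.25 * amp(tmin_range))
  tmax <- mid(tmax_range) + 0.7 * amp(tmax_range) * season +
    stats::rnorm(days, 0, 0.25 * amp(tmax_range))
  tmin <- pmin(pmax(tmin, tmin_range[1]), tmin_range[2])
  tmax <- pmin(pmax(tmax, tmax_range[1]), tmax_range[2])
  temperature_series(tmin, pmax(tmin, tmax))
}

#' Generate synthetic monthly temperature rasters
#'
#' Builds 12 monthly minimum- and 12 monthly maximum-temperature grids
#' with a north-south (row-wise) temperature gradient, a seasonal cycle,
#' and an optional nodata speckle shared by all months.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param t_north,t_south annual-mean daily mean temperature at the first
#'   (northern) and last (southern) row; intermediate rows are linear.
#' @param diurnal_range constant tmax - tmin spread (degrees C).
#' @param seasonal_amplitude amplitude of the monthly cycle (degrees C).
#' @param nodata_fraction fraction of cells masked as nodata in every
#'   month (default 0).
#' @param seed integer seed (nodata speckle placement).
#' @param cellsize,xll,yll grid geometry.
#' @return list with `tmin` and `tmax`, each a list of 12
#'   [raster_grid()]s.
#' @export
generate_temperature_raster <- function(n_rows, n_cols,
                                        t_north = 12, t_south = 28,
                                        diurnal_range = 10,
                                        seasonal_amplitude = 4,
                                        nodata_fraction = 0,
                                        seed = 1L,
                                        cellsize = 0.5, xll = 0, yll = 0) {
  stopifnot(n_rows >= 1, n_cols >= 1, diurnal_range >= 0,
            nodata_fraction >= 0, nodata_fraction < 1)
  set.seed(seed)
  base <- matrix(seq(t_north, t_south, length.out = n_rows), n_rows, n_cols)
  mask <- matrix(stats::runif(n_rows * n_cols) < nodata_fraction,
                 n_rows, n_cols)
  months <- seq_len(12)
  cyc <- seasonal_amplitude * sin(2 * pi * (months - 1) / 12)
  make <- function(m, off) {
    v <- base + cyc[m] + off
    v[mask] <- NA_real_
    raster_grid(v, xll, yll, cellsize)
  }
  list(tmin = lapply(months, make, off = -diurnal_range / 2),
       tmax = lapply(months, make, off = diurnal_range / 2))
}

#' Packaged reference phenology models
#'
#' Two compiled fixture models for the Natal fruit fly species pair:
#' `"rosa"` (lowland type) and `"quilicii"` (highland type). The immature
#' mortality, adult senescence, lifetime fecundity and cumulative
#' oviposition parameters are the published rearing-study estimates for
#' these species, loaded verbatim; the mortality curves are interpreted
#' on the percent scale (see the package vignette: on the proportion
#' scale the published larval/pupal parameters imply certain death at
#' every temperature, which contradicts the observed life tables). The
#' Briere-1 development-rate parameters and the development-time
#' dispersion slopes are NOT published for these species and are
#' synthetic placeholders, chosen so that development durations at
#' favourable temperatures match the reported stage durations (about
#' 2.3, 9.1 and 11.9 days for egg, larva and pupa).
#'
#' Note that the published parameter set for the quilicii pupal mortality
#' curve is internally inconsistent (its quadratic coefficient is orders
#' of magnitude out of range) and renders that fixture non-viable at all
#' temperatures; it is still loaded verbatim. The `"rosa"` fixture is
#' viable at intermediate temperatures (roughly 20-33 degrees C) and is
#' the one used for simulation examples.
#'
#' @param species `"rosa"` or `"quilicii"`.
#' @return a [phenology_model()].
#' @export
reference_model <- function(species = c("rosa", "quilicii")) {
  species <- match.arg(species)
  pct <- "percent"
  if (species == "rosa") {
    mort <- list(
      egg   = thermal_spec("mortality_expquad",
                           c(b1 = 10.271, b2 = -0.909, b3 = 0.019), scale = pct),
      larva = thermal_spec("mortality_expquad",
                           c(b1 = 9.621, b2 = -0.453, b3 = 0.009), scale = pct),
      pupa  = thermal_spec("mortality_expquad",
                           c(b1 = 7.178, b2 = -0.570, b3 = 0.014), scale = pct))
    sen_f <- thermal_spec("senescence_exponential", c(b1 = 0.0098, b2 = 0.0403))
    sen_m <- thermal_spec("senescence_exponential", c(b1 = 0.0049, b2 = 0.0689))
    fec <- thermal_spec("fecundity_exppoly",
                        c(b1 = -7.851, b2 = 1.064, b3 = -0.019))
    ovip <- thermal_spec("ovip_logistic", c(a = 3.94859, b = -3.43037))
    tmin <- 10; tmax <- 38
  } else {
    mort <- list(
      egg   = thermal_spec("mortality_expquad",
                           c(b1 = 5.183, b2 = -0.422, b3 = 0.009), scale = pct),
      larva = thermal_spec("mortality_expquad",
                           c(b1 = 4.812, b2 = -0.290, b3 = 0.007), scale = pct),
      pupa  = thermal_spec("mortality_expquad",
                           c(b1 = 5.8716, b2 = 0.3892, b3 = 141.781), scale = pct))
    sen_f <- thermal_spec("senescence_exponential", c(b1 = 0.0061, b2 = 0.056))
    sen_m <- thermal_spec("senescence_exponential", c(b1 = 0.0058, b2 = 0.0624))
    fec <- thermal_spec("fecundity_gaussian",
                        c(y0 = -41393.36, a = 41971.86, b = 74.63, x0 = 25.126))
    ovip <- thermal_spec("ovip_gamma", c(a = 3.404, b = 3.906))
    tmin <- 5; tmax <- 35
  }
  # synthetic development-rate parameters (not published for these
  # species): scaled so r(25 C) matches the reported stage durations
  denom <- 25 * (25 - tmin) * sqrt(tmax - 25)
  briere <- function(days_at_25)
    thermal_spec("briere1",
                 c(a = signif(1 / (days_at_25 * denom), 3),
                   Tmin = tmin, Tmax = tmax))
  phenology_model(
    egg   = life_stage(briere(2.3), 8, mort$egg),
    larva = life_stage(briere(9.1), 8, mort$larva),
    pupa  = life_stage(briere(11.9), 8, mort$pupa),
    female_senescence = sen_f, male_senescence = sen_m,
    fecundity = fec, oviposition = ovip,
    female_ratio = 0.5)
}
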