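#' Build a fitted phenology model from rearing-study tables
#'
#' The "model builder" step: turns stage-specific cohort observations and
#' paired-adult observations from a constant-temperature study into a
#' compiled [phenology_model()].
#'
#' Per immature stage it fits
#' * the development-time distribution (logit on log time, common slope
#'   across temperatures) from survivor durations;
#' * the Briere-1 development rate to per-replicate median rates
#'   (1 / median duration) at each temperature with completers;
#' * the exponential-quadratic mortality to per-replicate mortality
#'   fractions.
#'
#' For adults it fits the exponential senescence rate to per-temperature
#' inverse mean lifespans, selects the lifetime-fecundity form
#' (exponential-polynomial vs Gaussian) by AIC, and selects the
#' cumulative-oviposition form (logistic, gamma, cubic-exponential) by
#' AIC on the pooled per-female cumulative egg fractions against
#' normalized age. Because simulated females stop laying when their
#' accumulated senescence reaches the (default deterministic) threshold
#' of 1, observed lifetime totals estimate \eqn{f(T)\,O(1)}; the fitted
#' fecundity curve is therefore rescaled by the fitted \eqn{1/O(1)} so
#' the compiled model reproduces the observed totals.
#'
#' @param cohort_obs data frame from [generate_cohort_observations()] (or
#'   real data in the same long format).
#' @param adult_obs list as from [generate_adult_observations()].
#' @param devtime_min_n minimum completers per temperature for the
#'   development-time fit.
#' @param female_ratio female ratio of the compiled model.
#' @return a list with `model` (the compiled [phenology_model()]) and
#'   `fits` (the per-process [fit_response()] results and development-time
#'   specs, for inspection).
#' @export
fit_phenology_model <- function(cohort_obs, adult_obs,
                                devtime_min_n = 10L, female_ratio = 0.5) {
  stopifnot(all(c("stage", "temperature_C", "replicate", "survived",
                  "duration_days") %in% names(cohort_obs)))
  fits <- list()
  stages <- list()
  for (st_name in c("egg", "larva", "pupa")) {
    so <- cohort_obs[cohort_obs$stage == st_name, ]
    if (!nrow(so)) stop("no observations for stage ", st_name)
    surv <- so[so$survived & !is.na(so$duration_days), ]

    # development-time distribution: temperatures with enough completers
    n_per_t <- table(surv$temperature_C)
    keep_t <- as.numeric(names(n_per_t))[n_per_t >= devtime_min_n]
    dd <- surv[surv$temperature_C %in% keep_t, ]
    dt_spec <- fit_devtime_common_slope(
      data.frame(temperature = dd$temperature_C,
                 duration_days = dd$duration_days),
      min_n = devtime_min_n)

    # development rate: per-replicate median rates
    agg <- stats::aggregate(duration_days ~ temperature_C + replicate,
                            data = surv, FUN = stats::median)
    rate_fit <- fit_response(agg$temperature_C, 1 / agg$duration_days,
                             "briere1")

    # mortality: per-replicate death fractions (all temperatures)
    magg <- stats::aggregate(survived ~ temperature_C + replicate,
                             data = so, FUN = function(v) 1 - mean(v))
    mort_fit <- fit_response(magg$temperature_C, magg$survived,
                             "mortality_expquad")

    fits[[st_name]] <- list(devtime = dt_spec, dev_rate = rate_fit,
                            mortality = mort_fit)
    stages[[st_name]] <- life_stage(rate_fit$spec,
                                    dt_spec$params[["b"]],
                                    mort_fit$spec)
  }

  lon <- adult_obs$longevity
  stopifnot(all(c("temperature_C", "lifespan_days", "total_eggs") %in% names(lon)))
  mean_life <- stats::aggregate(lifespan_days ~ temperature_C, data = lon,
                                FUN = mean)
  sen_fit <- fit_response(mean_life$temperature_C, 1 / mean_life$lifespan_days,
                          "senescence_exponential")
  fits$senescence <- sen_fit

  # oviposition: pooled per-female cumulative fractions vs normalized age
  de <- adult_obs$daily_eggs
  de <- merge(de, lon[, c("temperature_C", "pair_id", "lifespan_days",
                          "total_eggs")],
              by = c("temperature_C", "pair_id"))
  de <- de[de$total_eggs > 0, ]
  de <- de[order(de$temperature_C, de$pair_id, de$day), ]
  cum <- stats::ave(de$eggs, interaction(de$temperature_C, de$pair_id),
                    FUN = cumsum)
  xnorm <- de$day / de$lifespan_days
  ofits <- lapply(c("ovip_logistic", "ovip_gamma", "ovip_cubic_exponential"),
                  function(f) tryCatch(
                    fit_response(xnorm, cum / de$total_eggs, f),
                    error = function(e) NULL))
  ofits <- Filter(Negate(is.null), ofits)
  ovip_fit <- select_best_model(ofits)
  fits$oviposition <- ovip_fit

  # fecundity: observed totals estimate f(T) * O(1); rescale
  o1 <- eval_oviposition_cdf(ovip_fit$spec, 1)
  ffits <- lapply(c("fecundity_exppoly", "fecundity_gaussian"),
                  function(f) tryCatch(
                    fit_response(lon$temperature_C, lon$total_eggs / o1, f),
                    error = function(e) NULL))
  ffits <- Filter(Negate(is.null), ffits)
  fec_fit <- select_best_model(ffits)
  fits$fecundity <- fec_fit

  model <- phenology_model(
    egg = stages$egg, larva = stages$larva, pupa = stages$pupa,
    female_senescence = sen_fit$spec, male_senescence = sen_fit$spec,
    fecundity = fec_fit$spec, oviposition = ovip_fit$spec,
    female_ratio = female_ratio)
  list(model = model, fits = fits)
}
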