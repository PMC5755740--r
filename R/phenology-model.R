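#' Immature life-stage description
#'
#' Bundles the three temperature responses that drive one immature stage
#' (egg, larva or pupa) in a phenology model: the Briere-1 development
#' rate, the dispersion of individual development times (the common slope
#' `b` of the logit-on-log-time distribution, with individual stage
#' thresholds drawn from the median-1 log-logistic it implies), and the
#' exponential-quadratic whole-stage mortality.
#'
#' @param dev_rate a `thermal_spec` of form `briere1`.
#' @param devtime_slope positive slope of the development-time
#'   distribution; `Inf` means deterministic durations.
#' @param mortality a `thermal_spec` of form `mortality_expquad`.
#' @return a list of class `life_stage`.
#' @export
life_stage <- function(dev_rate, devtime_slope, mortality) {
  .expect_form(dev_rate, "briere1")
  .expect_form(mortality, "mortality_expquad")
  stopifnot(is.numeric(devtime_slope), length(devtime_slope) == 1L,
            devtime_slope > 0)
  structure(list(dev_rate = dev_rate, devtime_slope = devtime_slope,
                 mortality = mortality), class = "life_stage")
}

#' Compile a stage-structured phenology model
#'
#' The compiled model drives the stochastic cohort simulation and the
#' risk indices: per immature stage a [life_stage()]; for adults a
#' senescence spec per sex, a lifetime-fecundity spec and a cumulative
#' oviposition spec; and the female ratio (0.5 by default, the value used
#' for tephritid rearing studies).
#'
#' @param egg,larva,pupa [life_stage()] objects.
#' @param female_senescence,male_senescence `thermal_spec`s of form
#'   `senescence_exponential` or `senescence_stinner`.
#' @param fecundity a `thermal_spec` of form `fecundity_exppoly` or
#'   `fecundity_gaussian`.
#' @param oviposition a `thermal_spec` of one of the `ovip_*` forms.
#' @param female_ratio fraction of emerging adults that are female.
#' @param adult_slope dispersion of adult senescence thresholds (same
#'   log-logistic mechanism as development times); `Inf` (default) makes
#'   every adult die exactly when its accumulated senescence reaches 1.
#' @return a list of class `phenology_model`.
#' @export
phenology_model <- function(egg, larva, pupa,
                            female_senescence, male_senescence,
                            fecundity, oviposition,
                            female_ratio = 0.5, adult_slope = Inf) {
  for (st in list(egg, larva, pupa))
    if (!inherits(st, "life_stage")) stop("egg/larva/pupa must be life_stage objects")
  .expect_form(female_senescence, c("senescence_exponential", "senescence_stinner"))
  .expect_form(male_senescence, c("senescence_exponential", "senescence_stinner"))
  .expect_form(fecundity, c("fecundity_exppoly", "fecundity_gaussian"))
  .expect_form(oviposition, c("ovip_cubic_exponential", "ovip_logistic",
                              "ovip_gamma"))
  stopifnot(is.numeric(female_ratio), female_ratio >= 0, female_ratio <= 1,
            is.numeric(adult_slope), adult_slope > 0)
  structure(list(
    stages = list(egg = egg, larva = larva, pupa = pupa),
    female_senescence = female_senescence,
    male_senescence = male_senescence,
    fecundity = fecundity,
    oviposition = oviposition,
    female_ratio = female_ratio,
    adult_slope = adult_slope
  ), class = "phenology_model")
}

#' @export
print.phenology_model <- function(x, ...) {
  cat("<phenology_model>\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-6s dev %s, slope %.3g, mortality %s%s\n", s,
                st$dev_rate$form, st$devtime_slope, st$mortality$form,
                if (identical(st$mortality$scale, "percent")) " (percent scale)" else ""))
  }
  cat(sprintf("  adult  senescence %s/%s, fecundity %s, oviposition %s\n",
              x$female_senescence$form, x$male_senescence$form,
              x$fecundity$form, x$oviposition$form))
  cat(sprintf("  female ratio %.2f, adult slope %.3g\n",
              x$female_ratio, x$adult_slope))
  invisible(x)
}

#' Serialize a phenology model to and from a plain list
#'
#' @param model a [phenology_model()].
#' @return `model_to_list()`: a nested plain list (JSON/YAML-ready);
#'   `model_from_list()` reverses it.
#' @export
model_to_list <- function(model) {
  stopifnot(inherits(model, "phenology_model"))
  list(
    stages = lapply(model$stages, function(st) list(
      dev_rate = spec_to_list(st$dev_rate),
      devtime_slope = st$devtime_slope,
      mortality = spec_to_list(st$mortality))),
    female_senescence = spec_to_list(model$female_senescence),
    male_senescence = spec_to_list(model$male_senescence),
    fecundity = spec_to_list(model$fecundity),
    oviposition = spec_to_list(model$oviposition),
    female_ratio = model$female_ratio,
    adult_slope = model$adult_slope
  )
}

#' @rdname model_to_list
#' @param x a list as produced by `model_to_list()`.
#' @export
model_from_list <- function(x) {
  stg <- lapply(x$stages, function(st)
    life_stage(spec_from_list(st$dev_rate), st$devtime_slope,
               spec_from_list(st$mortality)))
  phenology_model(stg$egg, stg$larva, stg$pupa,
                  spec_from_list(x$female_senescence),
                  spec_from_list(x$male_senescence),
                  spec_from_list(x$fecundity),
                  spec_from_list(x$oviposition),
                  female_ratio = x$female_ratio,
                  adult_slope = if (is.null(x$adult_slope)) Inf
                                else as.numeric(x$adult_slope))
}

#' Daily minimum/maximum temperature series
#'
#' @param tmin,tmax daily minima and maxima, degrees Celsius
#'   (`tmin <= tmax` every day; constant-temperature runs use
#'   `tmin == tmax`).
#' @param day day indices (default `1..N`).
#' @return a data frame of class `temperature_series`.
#' @export
temperature_series <- function(tmin, tmax, day = seq_along(tmin)) {
  stopifnot(length(tmin) == length(tmax), length(tmin) >= 1)
  if (anyNA(tmin) || anyNA(tmax)) stop("temperatures must not be NA")
  if (any(tmin > tmax)) stop("tmin must be <= tmax on every day")
  structure(data.frame(day = day, tmin = tmin, tmax = tmax),
            class = c("temperature_series", "data.frame"))
}

#' @rdname temperature_series
#' @param temp constant temperature for a flat series.
#' @param days number of days.
#' @export
constant_series <- function(temp, days = 365L) {
  temperature_series(rep(temp, days), rep(temp, days))
}

#' Within-day temperature cycle by cosine interpolation
#'
#' Standard degree-day interpolation between a day's minimum and maximum:
#' \eqn{T(h) = \frac{t_{max}+t_{min}}{2} - \frac{t_{max}-t_{min}}{2}
#' \cos(2\pi h / H)} evaluated at `h = 0, ..., H-1`. The mean over the day
#' is exactly `(tmin + tmax) / 2` and both extremes are attained (for even
#' `H`). With `steps_per_day = 1` the daily mean is returned.
#'
#' @param tmin,tmax the day's minimum and maximum, `tmin <= tmax`.
#' @param steps_per_day number of within-day steps `H` (>= 1).
#' @return numeric vector of length `steps_per_day`.
#' @export
interpolate_daily_cycle <- function(tmin, tmax, steps_per_day = 24L) {
  stopifnot(length(tmin) == 1L, length(tmax) == 1L, steps_per_day >= 1)
  if (tmin > tmax) stop("tmin must be <= tmax")
  if (steps_per_day == 1L) return((tmin + tmax) / 2)
  h <- seq(0, steps_per_day - 1)
  (tmax + tmin) / 2 - (tmax - tmin) / 2 * cos(2 * pi * h / steps_per_day)
}

# Per-day effective rates for each unique day of a temperature series:
# rate summation over the within-day cosine cycle for development and
# senescence; mortality and fecundity at the daily mean temperature.
.daily_rates <- function(model, temps, steps_per_day = 24L) {
  stopifnot(inherits(temps, "data.frame"), all(c("tmin", "tmax") %in% names(temps)))
  n <- nrow(temps)
  if (any(temps$tmin > temps$tmax)) stop("tmin must be <= tmax on every day")
  # within-day cosine cycle, all days at once (steps x days)
  meanT_d <- (temps$tmax + temps$tmin) / 2
  amp <- (temps$tmax - temps$tmin) / 2
  cosw <- if (steps_per_day == 1L) 0
          else cos(2 * pi * seq(0, steps_per_day - 1) / steps_per_day)
  hourly <- matrix(rep(meanT_d, each = steps_per_day), nrow = steps_per_day) -
    cosw * matrix(rep(amp, each = steps_per_day), nrow = steps_per_day)
  meanT <- (temps$tmin + temps$tmax) / 2
  dev <- vapply(model$stages, function(st)
    colMeans(matrix(eval_development_rate(st$dev_rate, as.vector(hourly)),
                    nrow = steps_per_day)), numeric(n))
  dev <- matrix(dev, nrow = n,
                dimnames = list(NULL, names(model$stages)))
  mort <- vapply(model$stages, function(st)
    eval_mortality(st$mortality, meanT), numeric(n))
  mort <- matrix(mort, nrow = n,
                 dimnames = list(NULL, names(model$stages)))
  sen_f <- colMeans(matrix(eval_senescence(model$female_senescence,
                                           as.vector(hourly)),
                           nrow = steps_per_day))
  sen_m <- colMeans(matrix(eval_senescence(model$male_senescence,
                                           as.vector(hourly)),
                           nrow = steps_per_day))
  fec <- eval_total_fecundity(model$fecundity, meanT)
  list(dev = dev, mort = mort, sen_f = sen_f, sen_m = sen_m,
       fec = fec, meanT = meanT, n_days = n)
}

# log-logistic stage threshold with median 1: q = exp(logit(u)/b)
.stage_threshold <- function(n, slope) {
  if (!is.finite(slope)) return(rep(1, n))
  u <- stats::runif(n)
  exp(stats::qlogis(u) / slope)
}
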