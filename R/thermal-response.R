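#' Briere-1 development rate
#'
#' Evaluates the Briere-1 thermal performance curve
#' \eqn{r(T) = a T (T - T_{min}) \sqrt{T_{max} - T}}, clamped to zero
#' outside the open interval \eqn{(T_{min}, T_{max})} so the returned rate
#' is never negative.
#'
#' @param spec a `thermal_spec` of form `briere1`.
#' @param T temperature(s), degrees Celsius.
#' @return development rate per day, same length as `T`.
#' @export
eval_development_rate <- function(spec, T) {
  .expect_form(spec, "briere1")
  .check_temperature(T)
  p <- spec$params
  r <- p[["a"]] * T * (T - p[["Tmin"]]) * sqrt(pmax(p[["Tmax"]] - T, 0))
  r[T <= p[["Tmin"]] | T >= p[["Tmax"]]] <- 0
  pmax(r, 0)
}

#' Optimum temperature of a Briere-1 curve
#'
#' Closed form for the temperature maximizing the Briere-1 development
#' rate:
#' \deqn{T_{opt} = \frac{4T_{max} + 3T_{min} +
#'   \sqrt{16T_{max}^2 + 9T_{min}^2 - 16 T_{min} T_{max}}}{10}}
#'
#' @inheritParams eval_development_rate
#' @return the optimum temperature in degrees Celsius, strictly inside
#'   `(Tmin, Tmax)`.
#' @export
optimum_temperature <- function(spec) {
  .expect_form(spec, "briere1")
  tmin <- spec$params[["Tmin"]]; tmax <- spec$params[["Tmax"]]
  if (tmin >= tmax) stop("degenerate interval: Tmin must be < Tmax")
  (4 * tmax + 3 * tmin +
     sqrt(16 * tmax^2 + 9 * tmin^2 - 16 * tmin * tmax)) / 10
}

#' Immature mortality fraction
#'
#' Evaluates the exponential-quadratic stage mortality
#' \eqn{M(T) = \exp(b_1 + b_2 T + b_3 T^2)}, clipped to \[0, 1\]. When the
#' spec carries `scale = "percent"` the exponential is read as a
#' percentage and divided by 100 before clipping. With \eqn{b_3 > 0} the
#' curve is U-shaped with its minimum at \eqn{T = -b_2 / (2 b_3)}.
#'
#' @param spec a `thermal_spec` of form `mortality_expquad`.
#' @inheritParams eval_development_rate
#' @return mortality fraction in \[0, 1\].
#' @export
eval_mortality <- function(spec, T) {
  .expect_form(spec, "mortality_expquad")
  .check_temperature(T)
  p <- spec$params
  m <- exp(p[["b1"]] + p[["b2"]] * T + p[["b3"]] * T^2)
  if (identical(spec$scale, "percent")) m <- m / 100
  pmin(pmax(m, 0), 1)
}

#' Adult senescence rate
#'
#' Evaluates the adult senescence (aging) rate as a function of
#' temperature, either the exponential form \eqn{s(T) = b_1 e^{b_2 T}} or
#' the modified four-parameter Stinner double logistic
#' \eqn{s(T) = C_1/(1+e^{k_1 + k_2 T}) + C_2/(1+e^{k_1 + k_2 (T_0 - T)})}.
#' The expected adult longevity at constant temperature is `1 / s(T)`.
#'
#' @param spec a `thermal_spec` of form `senescence_exponential` or
#'   `senescence_stinner`.
#' @inheritParams eval_development_rate
#' @return senescence rate per day.
#' @export
eval_senescence <- function(spec, T) {
  .expect_form(spec, c("senescence_exponential", "senescence_stinner"))
  .check_temperature(T)
  p <- spec$params
  if (spec$form == "senescence_exponential") {
    p[["b1"]] * exp(p[["b2"]] * T)
  } else {
    p[["C1"]] / (1 + exp(p[["k1"]] + p[["k2"]] * T)) +
      p[["C2"]] / (1 + exp(p[["k1"]] + p[["k2"]] * (p[["T0"]] - T)))
  }
}

#' Lifetime fecundity
#'
#' Total eggs laid per female over her life as a function of rearing
#' temperature: either the exponential-polynomial
#' \eqn{f(T) = \exp(b_1 + b_2 T + b_3 T^2)} (maximum at
#' \eqn{-b_2/(2 b_3)} when \eqn{b_3 < 0}) or the Gaussian
#' \eqn{f(T) = y_0 + a \exp(-\frac{1}{2}((T-x_0)/b)^2)} (maximum `y0 + a`
#' at `x0`), floored at zero for the negative Gaussian tails.
#'
#' @param spec a `thermal_spec` of form `fecundity_exppoly` or
#'   `fecundity_gaussian`.
#' @inheritParams eval_development_rate
#' @return lifetime eggs per female (non-negative).
#' @export
eval_total_fecundity <- function(spec, T) {
  .expect_form(spec, c("fecundity_exppoly", "fecundity_gaussian"))
  .check_temperature(T)
  p <- spec$params
  f <- if (spec$form == "fecundity_exppoly") {
    exp(p[["b1"]] + p[["b2"]] * T + p[["b3"]] * T^2)
  } else {
    p[["y0"]] + p[["a"]] * exp(-0.5 * ((T - p[["x0"]]) / p[["b"]])^2)
  }
  pmax(f, 0)
}

#' Cumulative oviposition against normalized female age
#'
#' Cumulative fraction of lifetime eggs laid by normalized female age `x`
#' (age in days divided by mean survival time). Three families:
#' cubic-exponential \eqn{y = 1 - e^{-(a x + b x^2 + c x^3)}}, logistic
#' \eqn{y = 1/(1 + e^{a + b x})} (capped at 1), and the gamma CDF with
#' shape `a` and rate `b`.
#'
#' @param spec a `thermal_spec` of form `ovip_cubic_exponential`,
#'   `ovip_logistic` or `ovip_gamma`.
#' @param x normalized female age(s), non-negative.
#' @return cumulative fraction in \[0, 1\].
#' @export
eval_oviposition_cdf <- function(spec, x) {
  .expect_form(spec, c("ovip_cubic_exponential", "ovip_logistic",
                       "ovip_gamma"))
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop("normalized age x must be numeric and >= 0")
  p <- spec$params
  switch(spec$form,
    ovip_cubic_exponential = {
      y <- 1 - exp(-(p[["a"]] * x + p[["b"]] * x^2 + p[["c"]] * x^3))
      pmin(pmax(y, 0), 1)
    },
    ovip_logistic = pmin(1 / (1 + exp(p[["a"]] + p[["b"]] * x)), 1),
    ovip_gamma = stats::pgamma(x, shape = p[["a"]], rate = p[["b"]])
  )
}

#' Quantile of the cumulative oviposition curve
#'
#' Inverts [eval_oviposition_cdf()]: the normalized female age at which a
#' fraction `prob` of lifetime eggs has been laid. Closed form for the
#' logistic and gamma families, bracketed root finding for the
#' cubic-exponential.
#'
#' @inheritParams eval_oviposition_cdf
#' @param prob target cumulative fraction in (0, 1).
#' @return normalized age; `Inf` if the curve never reaches `prob`.
#' @export
oviposition_quantile <- function(spec, prob) {
  .expect_form(spec, c("ovip_cubic_exponential", "ovip_logistic",
                       "ovip_gamma"))
  stopifnot(is.numeric(prob), length(prob) == 1L, prob > 0, prob < 1)
  p <- spec$params
  switch(spec$form,
    ovip_logistic = {
      # 1/(1+exp(a+bx)) = prob  =>  x = (log(1/prob - 1) - a) / b
      if (p[["b"]] >= 0) return(Inf)
      max((log(1 / prob - 1) - p[["a"]]) / p[["b"]], 0)
    },
    ovip_gamma = stats::qgamma(prob, shape = p[["a"]], rate = p[["b"]]),
    ovip_cubic_exponential = {
      g <- function(x) eval_oviposition_cdf(spec, x) - prob
      hi <- 1
      while (g(hi) < 0 && hi < 1e6) hi <- hi * 2
      if (g(hi) < 0) return(Inf)
      stats::uniroot(g, c(0, hi), tol = 1e-10)$root
    }
  )
}

#' Development-time distribution (logit on log time)
#'
#' Probability of having completed development by time `x` (days) at the
#' temperature indexed by `temperature_index`:
#' \eqn{F(x) = 1/(1 + e^{-(a_i + b \ln x)})}, a log-logistic CDF with
#' per-temperature intercepts and a common slope `b`. The median
#' development time at temperature `i` is \eqn{\exp(-a_i / b)}.
#'
#' @param spec a `thermal_spec` of form `devtime_logit` with parameters
#'   `a1..ak` and `b`.
#' @param x development time in days, strictly positive.
#' @param temperature_index which intercept to use (default 1).
#' @return probability in \[0, 1\].
#' @export
eval_devtime_cdf <- function(spec, x, temperature_index = 1L) {
  .expect_form(spec, "devtime_logit")
  if (!is.numeric(x) || anyNA(x) || any(x <= 0))
    stop("development time x must be > 0")
  a <- spec$params[setdiff(names(spec$params), "b")]
  if (temperature_index < 1L || temperature_index > length(a))
    stop("temperature_index out of range")
  b <- spec$params[["b"]]
  1 / (1 + exp(-(a[[temperature_index]] + b * log(x))))
}

#' Median development times implied by a devtime_logit spec
#'
#' @inheritParams eval_devtime_cdf
#' @return vector of per-temperature medians \eqn{\exp(-a_i/b)}.
#' @export
devtime_medians <- function(spec) {
  .expect_form(spec, "devtime_logit")
  a <- spec$params[setdiff(names(spec$params), "b")]
  exp(-unlist(a) / spec$params[["b"]])
}

#' Lethal temperatures of a U-shaped mortality curve
#'
#' Finds the temperatures at which the exponential-quadratic mortality
#' crosses a given level on the search interval \[-20, 60\] degrees C, by
#' bisection to a tolerance of 1e-6 degrees. For `level = 1` the crossings
#' of the clipping boundary (`exp(.) = 1`, i.e. the roots of
#' \eqn{b_1 + b_2 T + b_3 T^2 = 0} on the proportion scale) are returned.
#' Values are `NA` when the curve never reaches the level on the interval.
#'
#' @param spec a `thermal_spec` of form `mortality_expquad` with
#'   \eqn{b_3 > 0} (U shape).
#' @param level mortality fraction in (0, 1\].
#' @return a list of class `lethal_temperatures` with elements `lower` and
#'   `upper` (degrees C or `NA`) and the `level`.
#' @export
lethal_temperatures <- function(spec, level) {
  .expect_form(spec, "mortality_expquad")
  stopifnot(is.numeric(level), length(level) == 1L)
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  if (spec$params[["b3"]] <= 0) stop("lethal temperatures need b3 > 0 (U shape)")
  lo <- -20; hi <- 60
  if (level == 1) {
    # boundaries of the clipped region: exp(.) = 1 (or 100 on the percent
    # scale), i.e. quadratic roots of b1' + b2 T + b3 T^2 = 0
    p <- spec$params
    b1 <- p[["b1"]] - if (identical(spec$scale, "percent")) log(100) else 0
    disc <- p[["b2"]]^2 - 4 * p[["b3"]] * b1
    if (disc < 0)
      return(structure(list(lower = NA_real_, upper = NA_real_, level = 1),
                       class = "lethal_temperatures"))
    r <- sort((-p[["b2"]] + c(-1, 1) * sqrt(disc)) / (2 * p[["b3"]]))
    r[r < lo | r > hi] <- NA_real_
    return(structure(list(lower = r[1], upper = r[2], level = 1),
                     class = "lethal_temperatures"))
  }
  tmin <- -spec$params[["b2"]] / (2 * spec$params[["b3"]])  # mortality minimum
  tmin <- min(max(tmin, lo), hi)
  g <- function(T) eval_mortality(spec, T) - level
  bisect <- function(a, b) {
    # g(a), g(b) of opposite sign
    for (i in 1:200) {
      m <- (a + b) / 2
      if (b - a < 1e-6) break
      if (sign(g(m)) == sign(g(a))) a <- m else b <- m
    }
    (a + b) / 2
  }
  lower <- upper <- NA_real_
  if (g(tmin) < 0) {   # minimum below the level: interior crossings possible
    if (g(lo) > 0) lower <- bisect(lo, tmin)
    if (g(hi) > 0) upper <- bisect(tmin, hi)
  } else if (g(tmin) == 0) {
    lower <- upper <- tmin
  }
  # g >= 0 everywhere (mortality never drops below the level): no thresholds
  structure(list(lower = lower, upper = upper, level = level),
            class = "lethal_temperatures")
}

#' Lower development threshold from a linear rate regression
#'
#' The temperature at which the fitted line \eqn{r(T) = a + bT} crosses
#' zero rate, \eqn{-a/b}.
#'
#' @param intercept intercept `a` of the linear rate model.
#' @param slope slope `b`, strictly positive.
#' @return threshold temperature in degrees Celsius.
#' @export
linear_lower_threshold <- function(intercept, slope) {
  stopifnot(is.numeric(intercept), is.numeric(slope))
  if (slope <= 0) stop("slope must be > 0")
  -intercept / slope
}

#' Evaluate a fitted quadratic life-table trend
#'
#' @param spec a `thermal_spec` of form `lifetable_quadratic`.
#' @inheritParams eval_development_rate
#' @return \eqn{a + bT + cT^2}.
#' @export
eval_lifetable_quadratic <- function(spec, T) {
  .expect_form(spec, "lifetable_quadratic")
  .check_temperature(T)
  p <- spec$params
  p[["a"]] + p[["b"]] * T + p[["c"]] * T^2
}
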