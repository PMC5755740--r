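#' Gaussian least-squares AIC
#'
#' \eqn{AIC = n \ln(RSS/n) + 2k}, the form appropriate for comparing
#' least-squares fits to the same response. A perfect fit (`rss = 0`)
#' returns `-Inf` so it always wins a comparison.
#'
#' @param rss residual sum of squares (>= 0).
#' @param n_obs number of observations (> 0).
#' @param k_params number of fitted parameters.
#' @return the AIC value.
#' @export
compute_aic <- function(rss, n_obs, k_params) {
  stopifnot(rss >= 0, n_obs > 0, k_params >= 0)
  if (rss == 0) return(-Inf)
  n_obs * log(rss / n_obs) + 2 * k_params
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - RSS/TSS} with TSS about the observed mean.
#'
#' @param observed,predicted equal-length numeric vectors, `n >= 2`.
#' @return R-squared (at most 1; negative when the fit is worse than the
#'   mean).
#' @export
compute_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("zero total variance: R2 undefined")
  1 - sum((observed - predicted)^2) / tss
}

# prediction function for a parameter vector, by form
.pred_fun <- function(form) {
  switch(form,
    briere1 = function(p, x) {
      r <- p[["a"]] * x * (x - p[["Tmin"]]) * sqrt(pmax(p[["Tmax"]] - x, 0))
      r[x <= p[["Tmin"]] | x >= p[["Tmax"]]] <- 0
      pmax(r, 0)
    },
    mortality_expquad = function(p, x)
      exp(p[["b1"]] + p[["b2"]] * x + p[["b3"]] * x^2),
    senescence_exponential = function(p, x) p[["b1"]] * exp(p[["b2"]] * x),
    senescence_stinner = function(p, x)
      p[["C1"]] / (1 + exp(p[["k1"]] + p[["k2"]] * x)) +
        p[["C2"]] / (1 + exp(p[["k1"]] + p[["k2"]] * (p[["T0"]] - x))),
    fecundity_exppoly = function(p, x)
      exp(p[["b1"]] + p[["b2"]] * x + p[["b3"]] * x^2),
    fecundity_gaussian = function(p, x)
      p[["y0"]] + p[["a"]] * exp(-0.5 * ((x - p[["x0"]]) / p[["b"]])^2),
    ovip_cubic_exponential = function(p, x)
      1 - exp(-(p[["a"]] * x + p[["b"]] * x^2 + p[["c"]] * x^3)),
    ovip_logistic = function(p, x) 1 / (1 + exp(p[["a"]] + p[["b"]] * x)),
    ovip_gamma = function(p, x)
      stats::pgamma(x, shape = max(p[["a"]], 1e-8), rate = max(p[["b"]], 1e-8)),
    linear_rate = function(p, x) p[["a"]] + p[["b"]] * x,
    lifetable_quadratic = function(p, x)
      p[["a"]] + p[["b"]] * x + p[["c"]] * x^2,
    stop("no least-squares predictor for form ", form)
  )
}

# deterministic grid of starting parameter vectors, by form
.start_grid <- function(form, x, y) {
  rng <- range(x)
  eps <- 1e-8
  cl <- function(v, lo = eps) pmax(v, lo)
  switch(form,
    briere1 = {
      pos <- y > 0
      starts <- list()
      for (dlo in c(2, 0.5, 5)) for (dhi in c(2, 0.5, 5)) {
        tmin <- rng[1] - dlo; tmax <- rng[2] + dhi
        inside <- pos & x > tmin & x < tmax
        a <- if (any(inside))
          stats::median(y[inside] /
            (x[inside] * (x[inside] - tmin) * sqrt(tmax - x[inside])))
        else 1e-4
        starts[[length(starts) + 1L]] <- c(a = cl(a), Tmin = tmin, Tmax = tmax)
      }
      starts
    },
    mortality_expquad = ,
    fecundity_exppoly = {
      z <- log(cl(y, 1e-8))
      co <- stats::coef(stats::lm(z ~ x + I(x^2)))
      list(c(b1 = unname(co[1]), b2 = unname(co[2]), b3 = unname(co[3])))
    },
    senescence_exponential = {
      z <- log(cl(y, 1e-8))
      co <- stats::coef(stats::lm(z ~ x))
      list(c(b1 = cl(exp(unname(co[1]))), b2 = unname(co[2])))
    },
    senescence_stinner = {
      ymax <- max(y)
      starts <- list()
      for (k2 in c(-0.2, -0.1)) for (t0 in c(rng[2], rng[2] + 5))
        for (c2f in c(0.05, 0.5)) {
          starts[[length(starts) + 1L]] <-
            c(C1 = 2 * ymax, C2 = c2f * ymax, k1 = 4, k2 = k2, T0 = t0)
        }
      starts
    },
    fecundity_gaussian = {
      x0 <- x[which.max(y)]
      starts <- list()
      for (bf in c(4, 2, 8)) for (y0 in c(min(y), 0)) {
        starts[[length(starts) + 1L]] <-
          c(y0 = y0, a = max(y) - y0, b = diff(rng) / bf, x0 = x0)
      }
      starts
    },
    ovip_cubic_exponential = {
      z <- -log(1 - pmin(pmax(y, 0), 0.999))
      co <- stats::coef(stats::lm(z ~ x + I(x^2) + I(x^3) - 1))
      co[is.na(co)] <- 0
      list(c(a = unname(co[1]), b = unname(co[2]), c = unname(co[3])))
    },
    ovip_logistic = {
      yc <- pmin(pmax(y, 1e-4), 1 - 1e-4)
      co <- stats::coef(stats::lm(stats::qlogis(yc) ~ x))
      list(c(a = -unname(co[1]), b = -unname(co[2])))
    },
    ovip_gamma = {
      x50 <- if (any(y >= 0.5)) x[which.max(y >= 0.5)] else max(x)
      lapply(c(1, 2, 4), function(sh)
        c(a = sh, b = sh / cl(x50 * 1.1, 0.05)))
    },
    stop("no start grid for form ", form)
  )
}

#' Fit a thermal response function by nonlinear least squares
#'
#' Fits any of the closed-form thermal response families to observed
#' (input, response) pairs by Levenberg-Marquardt least squares, starting
#' from a deterministic grid of initial values and keeping the converged
#' start with the lowest residual sum of squares. `linear_rate` and
#' `lifetable_quadratic` are linear in their parameters and are fitted by
#' ordinary least squares.
#'
#' For the temperature-response families `x` is temperature in degrees
#' Celsius; for the oviposition families it is normalized female age.
#'
#' @param x input values (temperature or normalized age).
#' @param y observed responses (rate, mortality fraction, eggs, or
#'   cumulative fraction), same length as `x`.
#' @param form one of the least-squares forms of [thermal_spec()] (all
#'   except `devtime_logit`).
#' @param weights optional non-negative case weights (e.g. replicate
#'   counts).
#' @return an object of class `fit_result`: a list with elements `spec`
#'   (a [thermal_spec()] with fitted parameters and standard errors),
#'   `aic`, `r2`, `rss`, `n_obs`, `converged`.
#' @export
fit_response <- function(x, y, form, weights = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA")
  k <- length(.spec_arity[[form]])
  if (is.null(k) || form == "devtime_logit")
    stop("use fit_devtime_common_slope() for the development-time distribution")
  n <- length(x)
  linear <- form %in% c("linear_rate", "lifetable_quadratic")
  # linear forms may interpolate exactly (n == k); nonlinear fits need
  # residual degrees of freedom
  if (if (linear) n < k else n <= k)
    stop("under-determined fit: need more observations than parameters")
  w <- if (is.null(weights)) rep(1, n) else {
    stopifnot(length(weights) == n, all(weights >= 0))
    weights
  }

  if (linear) {
    fit <- if (form == "linear_rate")
      stats::lm(y ~ x, weights = w)
    else
      stats::lm(y ~ x + I(x^2), weights = w)
    co <- stats::coef(fit)
    se <- if (stats::df.residual(fit) > 0)
      suppressWarnings(sqrt(diag(stats::vcov(fit)))) else NULL
    nm <- .spec_arity[[form]]
    names(co) <- nm
    if (!is.null(se)) names(se) <- nm
    rss <- sum(w * stats::residuals(fit)^2)
    return(.make_fit_result(form, co, se, x, y, w, rss, converged = TRUE))
  }

  pred <- .pred_fun(form)
  starts <- .start_grid(form, x, y)
  sw <- sqrt(w)
  resid_fn <- function(p, start_names) {
    names(p) <- start_names
    r <- sw * (y - pred(p, x))
    r[!is.finite(r)] <- 1e6
    r
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, start_names = names(st),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    rss <- fit$deviance
    if (!is.finite(rss)) next
    if (is.null(best) || (ok && !best$ok) || (ok == best$ok && rss < best$rss))
      best <- list(fit = fit, rss = rss, ok = ok)
  }
  if (is.null(best)) stop("fit_response: no start converged for form ", form)
  p <- best$fit$par
  names(p) <- .spec_arity[[form]]
  se <- tryCatch({
    s <- summary(best$fit)
    se <- s$coefficients[, "Std. Error"]
    names(se) <- names(p)
    se
  }, error = function(e) NULL)
  .make_fit_result(form, p, se, x, y, w, best$rss, converged = best$ok)
}

.make_fit_result <- function(form, params, se, x, y, w, rss, converged) {
  k <- length(params)
  pred <- .pred_fun(form)
  spec <- tryCatch(thermal_spec(form, params, param_se = se),
                   error = function(e) NULL)
  if (is.null(spec)) {
    # fitted parameters violate a form invariant (e.g. exp rate b1 <= 0)
    spec <- structure(list(form = form, params = params, param_se = se,
                           scale = NULL), class = "thermal_spec")
    converged <- FALSE
  }
  structure(list(
    spec = spec,
    aic = compute_aic(rss, length(y), k),
    # constant responses have no total variance; record NA rather than fail
    r2 = tryCatch(compute_r2(y, pred(params, x)),
                  error = function(e) NA_real_),
    rss = rss,
    n_obs = length(y),
    converged = converged
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s  (n=%d, AIC=%.3f, R2=%.4f, %s)\n",
              x$spec$form, x$n_obs, x$aic, x$r2,
              if (x$converged) "converged" else "NOT converged"))
  print(x$spec$params)
  invisible(x)
}

#' Select the best-fitting response model
#'
#' Picks the candidate with the lowest AIC; exact AIC ties are broken by
#' higher R-squared, then by fewer parameters. Non-converged candidates
#' are excluded; an empty or all-failed candidate list is an error.
#'
#' @param candidates a list of [fit_response()] results.
#' @return the winning `fit_result`.
#' @export
select_best_model <- function(candidates) {
  if (length(candidates) == 0) stop("no candidate models")
  stopifnot(all(vapply(candidates, inherits, TRUE, "fit_result")))
  conv <- Filter(function(f) isTRUE(f$converged), candidates)
  if (length(conv) == 0) stop("no converged candidate models")
  aic <- vapply(conv, `[[`, 0, "aic")
  r2 <- vapply(conv, `[[`, 0, "r2")
  k <- vapply(conv, function(f) length(f$spec$params), 0)
  ord <- order(aic, -r2, k)
  conv[[ord[1]]]
}

#' Fit the development-time distribution with a common slope
#'
#' Fits the logit-on-log-time development-time model
#' \eqn{F(x) = 1/(1 + e^{-(a_i + b \ln x)})} as a single binomial
#' regression over all temperatures pooled: for each temperature the
#' individual durations are reduced to cumulative completed counts at each
#' distinct observation time, and a GLM with one intercept per temperature
#' and a shared slope on \eqn{\ln x} is fitted. A shared slope encodes the
#' assumption that development-time distributions at different
#' temperatures have the same shape and differ only in their median
#' \eqn{\exp(-a_i/b)}.
#'
#' @param durations a data frame with columns `temperature` and
#'   `duration_days` (one row per individual that completed the stage), or
#'   a named list of numeric duration vectors, one element per temperature.
#' @param min_n minimum individuals required per temperature (default 10).
#' @return a `thermal_spec` of form `devtime_logit` with intercepts
#'   `a1..ak` (ordered by increasing temperature, recorded in the
#'   `temperatures` attribute) and common slope `b`.
#' @export
fit_devtime_common_slope <- function(durations, min_n = 10L) {
  if (is.data.frame(durations)) {
    stopifnot(all(c("temperature", "duration_days") %in% names(durations)))
    durations <- split(durations$duration_days, durations$temperature)
  }
  if (length(durations) < 2L)
    stop("need durations at >= 2 temperatures")
  ns <- vapply(durations, length, 0L)
  if (any(ns < min_n))
    stop("need at least ", min_n, " individuals per temperature")
  spreads <- vapply(durations, function(d) diff(range(d)), 0)
  if (any(spreads == 0))
    stop("all durations identical at some temperature: distribution spread is zero")
  if (any(unlist(durations) <= 0)) stop("durations must be > 0")

  rows <- lapply(seq_along(durations), function(i) {
    d <- sort(durations[[i]])
    t_distinct <- unique(d)
    k <- vapply(t_distinct, function(t) sum(d <= t), 0L)
    data.frame(temp_idx = i, lnx = log(t_distinct),
               completed = k, pending = length(d) - k)
  })
  df <- do.call(rbind, rows)
  df$temp_idx <- factor(df$temp_idx)
  fit <- stats::glm(cbind(completed, pending) ~ 0 + temp_idx + lnx,
                    family = stats::binomial(), data = df)
  co <- stats::coef(fit)
  b <- co[["lnx"]]
  if (b <= 0) stop("fitted common slope is not positive")
  a <- co[grep("^temp_idx", names(co))]
  params <- c(stats::setNames(a, paste0("a", seq_along(a))), b = b)
  se <- sqrt(diag(stats::vcov(fit)))
  se <- c(stats::setNames(se[grep("^temp_idx", names(se))],
                          paste0("a", seq_along(a))), b = se[["lnx"]])
  spec <- thermal_spec("devtime_logit", params, param_se = se)
  attr(spec, "temperatures") <- suppressWarnings(as.numeric(names(durations)))
  spec
}

#' Fit a quadratic trend to life-table parameters across temperature
#'
#' Ordinary least squares of a life-table parameter (e.g. rm or the
#' finite rate of increase) on temperature and temperature squared. With
#' exactly three distinct temperatures the quadratic interpolates the
#' points exactly.
#'
#' @param temperature temperatures in degrees Celsius (>= 3 distinct
#'   values required across >= 3 points).
#' @param value the life-table parameter at each temperature.
#' @return a `thermal_spec` of form `lifetable_quadratic`.
#' @export
fit_lifetable_quadratic <- function(temperature, value) {
  stopifnot(length(temperature) == length(value))
  if (length(temperature) < 3L || length(unique(temperature)) < 3L)
    stop("need >= 3 distinct temperatures for a quadratic fit")
  fr <- fit_response(temperature, value, "lifetable_quadratic")
  fr$spec
}
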