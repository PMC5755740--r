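# continuous-time threshold crossings over a daily rate vector.
# C0 = c(0, cumsum(rate)); accumulation at continuous time tau (days,
# 0 = start of day 1) is G(tau) = C0[i+1] + (tau - i) * rate[i+1], i = floor(tau).
# Returns the earliest tau* with G(tau*) = G(tau0) + threshold, or Inf.
.cross_time <- function(rate, tau0, threshold) {
  D <- length(rate)
  C0 <- c(0, cumsum(rate))
  i <- pmin(floor(tau0), D - 1)
  g0 <- C0[i + 1] + (tau0 - i) * rate[i + 1]
  A <- g0 + threshold
  j <- findInterval(A, C0)            # largest j with C0[j] <= A
  out <- rep(Inf, length(tau0))
  exact <- is.finite(tau0) & C0[j] == A        # reached at integer time j-1
  out[exact] <- j[exact] - 1
  inside <- is.finite(tau0) & !exact & j <= D  # crossing within day j
  if (any(inside)) {
    ji <- j[inside]
    r <- rate[ji]
    t <- (ji - 1) + (A[inside] - C0[ji]) / r
    t[r <= 0 | !is.finite(t)] <- Inf
    out[inside] <- t
  }
  out
}

# generation lengths for a vector of start days over a one-year rate set
.generation_lengths <- function(rates, model, start_days, cap_years = 5) {
  reps <- ceiling(cap_years)
  dev <- apply(rates$dev, 2, function(v) rep(v, reps))
  sen <- rep(rates$sen_f, reps)
  tau <- start_days - 1
  for (st in colnames(rates$dev)) tau <- .cross_time(dev[, st], tau, 1)
  x50 <- oviposition_quantile(model$oviposition, 0.5)
  tau <- .cross_time(sen, tau, x50)
  tx <- tau - (start_days - 1)
  tx[tx > cap_years * 365] <- Inf
  tx
}

#' Generation length from a given start day
#'
#' Deterministic median-individual forward simulation: starting at Julian
#' day `start_day`, the time for the egg, larva and pupa stages to each
#' accumulate one unit of development (rate summation over the within-day
#' cosine cycle, the year cycled as needed), plus the time for the adult
#' female to reach the age of 50% cumulative oviposition. Returns `Inf`
#' when the generation does not complete within `cap_years`.
#'
#' @param model a [phenology_model()].
#' @param temps a [temperature_series()] of exactly 365 days.
#' @param start_day Julian start day(s), 1..365.
#' @param cap_years give up after this many years (default 5).
#' @param steps_per_day within-day steps for rate summation.
#' @return generation length(s) in days (possibly `Inf`).
#' @export
compute_generation_length <- function(model, temps, start_day,
                                      cap_years = 5, steps_per_day = 24L) {
  .check_year(temps)
  if (any(start_day < 1 | start_day > 365)) stop("start_day must be in 1..365")
  rates <- .daily_rates(model, temps, steps_per_day)
  .generation_lengths(rates, model, start_day, cap_years)
}

.check_year <- function(temps) {
  if (!is.data.frame(temps) || !all(c("tmin", "tmax") %in% names(temps)))
    stop("temps must be a temperature_series data frame")
  if (nrow(temps) != 365L)
    stop("need exactly one year (365 days) of temperatures, got ", nrow(temps))
  invisible(temps)
}

#' Establishment risk index (ERI)
#'
#' The fraction of days in the year on which every immature stage can
#' survive, \eqn{ERI = \frac{1}{365}\sum_{i=1}^{365} I_i}, where
#' \eqn{I_i = 1} iff \eqn{M_s(\bar T_i) < 1} for egg, larva and pupa at
#' day i's mean temperature. The index is 1 when all immature stages
#' survive throughout the year; values below 1 mark areas where
#' establishment is restricted to part of the year. With
#' `require_reproduction = TRUE` a day additionally requires positive
#' lifetime fecundity \eqn{f(\bar T_i) > 0}.
#'
#' @inheritParams compute_generation_length
#' @param require_reproduction also require reproduction to be possible.
#' @return a fraction in \[0, 1\].
#' @export
compute_eri <- function(model, temps, require_reproduction = FALSE) {
  .check_year(temps)
  meanT <- (temps$tmin + temps$tmax) / 2
  ok <- rep(TRUE, 365L)
  for (st in model$stages)
    ok <- ok & (eval_mortality(st$mortality, meanT) < 1)
  if (require_reproduction)
    ok <- ok & (eval_total_fecundity(model$fecundity, meanT) > 0)
  mean(ok)
}

#' Generation index (GI)
#'
#' The mean number of generations achievable within the year:
#' \eqn{GI = \frac{1}{365}\sum_{x=1}^{365} 365 / T_x} with \eqn{T_x} the
#' generation length starting at Julian day `x`
#' ([compute_generation_length()]); start days whose generation never
#' completes contribute 0.
#'
#' @inheritParams compute_generation_length
#' @return generations per year (>= 0).
#' @export
compute_gi <- function(model, temps, cap_years = 5, steps_per_day = 24L) {
  .check_year(temps)
  rates <- .daily_rates(model, temps, steps_per_day)
  tx <- .generation_lengths(rates, model, 1:365, cap_years)
  mean(ifelse(is.finite(tx), 365 / tx, 0))
}

#' Activity index (AI)
#'
#' The log10 of the product of daily finite rates of increase over the
#' year, \eqn{AI = \log_{10} \prod_{x=1}^{365} \lambda_x =
#' \sum_x \log_{10} \lambda(\bar T_x)}, with \eqn{\lambda} evaluated from
#' the quadratic life-table trend at each day's mean temperature and
#' floored at `lambda_floor` outside the fitted viable range (so the
#' index is bounded below instead of diverging). Every unit of AI is a
#' 10-fold annual population increase; an AI of 3 means a 1000-fold
#' increase.
#'
#' @param lambda_fn a `thermal_spec` of form `lifetable_quadratic` fitted
#'   to the finite rate of increase against temperature.
#' @inheritParams compute_generation_length
#' @param lambda_floor lower bound for the daily finite rate (default
#'   0.5).
#' @return the activity index (real; negative for declining populations).
#' @export
compute_ai <- function(lambda_fn, temps, lambda_floor = 0.5) {
  .expect_form(lambda_fn, "lifetable_quadratic")
  .check_year(temps)
  stopifnot(lambda_floor > 0)
  meanT <- (temps$tmin + temps$tmax) / 2
  lam <- pmax(eval_lifetable_quadratic(lambda_fn, meanT), lambda_floor)
  sum(log10(lam))
}

#' Risk indices over raster grids
#'
#' Computes per-cell ERI, GI and AI from 12 monthly minimum- and 12
#' monthly maximum-temperature rasters sharing one geometry. Monthly
#' values are interpolated to 365 daily values per cell (linear between
#' month midpoints, wrapped across the year boundary). Cells that are
#' nodata in any input are nodata in all three outputs.
#'
#' @param model a [phenology_model()].
#' @param lambda_fn quadratic finite-rate-of-increase trend for
#'   [compute_ai()].
#' @param tmin_rasters,tmax_rasters lists of 12 [raster_grid()]s each.
#' @inheritParams compute_eri
#' @inheritParams compute_ai
#' @inheritParams compute_generation_length
#' @return a list with elements `eri`, `gi`, `ai`, each a [raster_grid()].
#' @export
compute_indices_for_grid <- function(model, lambda_fn,
                                     tmin_rasters, tmax_rasters,
                                     require_reproduction = FALSE,
                                     lambda_floor = 0.5,
                                     cap_years = 5, steps_per_day = 24L) {
  stopifnot(length(tmin_rasters) == 12L, length(tmax_rasters) == 12L)
  all_g <- c(tmin_rasters, tmax_rasters)
  g0 <- all_g[[1]]
  for (g in all_g)
    if (!.same_geometry(g, g0)) stop("raster geometry mismatch")
  nr <- nrow(g0$values); nc <- ncol(g0$values)
  tmin_m <- vapply(tmin_rasters, function(g) as.vector(g$values),
                   numeric(nr * nc))
  tmax_m <- vapply(tmax_rasters, function(g) as.vector(g$values),
                   numeric(nr * nc))
  valid <- rowSums(is.na(tmin_m)) == 0 & rowSums(is.na(tmax_m)) == 0
  eri <- gi <- ai <- rep(NA_real_, nr * nc)
  for (cell in which(valid)) {
    tmin_d <- .monthly_to_daily(tmin_m[cell, ])
    tmax_d <- .monthly_to_daily(tmax_m[cell, ])
    ts <- temperature_series(pmin(tmin_d, tmax_d), pmax(tmin_d, tmax_d))
    eri[cell] <- compute_eri(model, ts, require_reproduction)
    gi[cell] <- compute_gi(model, ts, cap_years, steps_per_day)
    ai[cell] <- compute_ai(lambda_fn, ts, lambda_floor)
  }
  as_grid <- function(v) raster_grid(matrix(v, nr, nc), g0$xll, g0$yll,
                                     g0$cellsize, g0$nodata)
  list(eri = as_grid(eri), gi = as_grid(gi), ai = as_grid(ai))
}

#' Classify an establishment-risk grid at a cutoff
#'
#' Binary establishment layer: 1 where the index exceeds the cutoff
#' (0.6 by default, the threshold associated with potential permanent
#' establishment), 0 elsewhere, nodata propagated.
#'
#' @param grid a [raster_grid()] of ERI values.
#' @param cutoff classification threshold (default 0.6).
#' @return a [raster_grid()] of 0/1 values.
#' @export
classify_establishment <- function(grid, cutoff = 0.6) {
  stopifnot(inherits(grid, "raster_grid"))
  raster_grid((grid$values > cutoff) * 1, grid$xll, grid$yll,
              grid$cellsize, grid$nodata)
}

# month midpoints of a 365-day year, wrapped linear interpolation
.month_midpoints <- function() {
  len <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  cumsum(len) - len / 2
}

.monthly_to_daily <- function(monthly) {
  stopifnot(length(monthly) == 12L)
  mid <- .month_midpoints()
  xs <- c(mid - 365, mid, mid + 365)
  ys <- rep(monthly, 3)
  stats::approx(xs, ys, xout = seq(0.5, 364.5), method = "linear")$y
}
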