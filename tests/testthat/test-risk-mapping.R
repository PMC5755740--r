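test_that("ERI boundary cases and day counting", {
  m <- reference_model("rosa")
  expect_equal(compute_eri(m, constant_series(25, 365)), 1)
  # a series too cold for the larval stage on every day
  expect_equal(compute_eri(m, constant_series(5, 365)), 0)
  # counting: survivable on exactly 146 days -> 0.4
  # custom mortality M(T) = exp(T - 30): < 1 iff T < 30
  hot <- thermal_spec("mortality_expquad", c(b1 = -30, b2 = 1, b3 = 0))
  mm <- toy_model()
  for (s in c("egg", "larva", "pupa")) mm$stages[[s]]$mortality <- hot
  ts <- constant_series(25, 365)
  ts$tmin[147:365] <- ts$tmax[147:365] <- 35
  expect_equal(compute_eri(mm, ts), 146 / 365)
  expect_equal(146 / 365, 0.4)
  expect_error(compute_eri(m, constant_series(25, 200)), "365")
  # stricter mode: reproduction additionally required
  nofec <- toy_model()
  nofec$fecundity <- thermal_spec("fecundity_gaussian",
                                  c(y0 = -0.5, a = 2, b = 3, x0 = 25))
  ts2 <- constant_series(40, 365)   # fecundity 0 far from x0, mortality fine
  nofec$stages$egg$mortality <- thermal_spec("mortality_expquad",
                                             c(b1 = -5, b2 = 0, b3 = 0))
  expect_gt(compute_eri(nofec, constant_series(25, 365)), 0)
  expect_equal(compute_eri(nofec, constant_series(25, 365),
                           require_reproduction = TRUE), 1)
  far <- constant_series(25, 365); far$tmin[] <- far$tmax[] <- 32
  expect_equal(compute_eri(nofec, far, require_reproduction = TRUE), 0)
})

test_that("ERI never increases when mortality is raised pointwise", {
  base <- c(egg = 0.05, larva = 0.2, pupa = 0.1)
  ts <- generate_annual_temperatures("sinusoid", seed = 3, mean_tmin = 10,
                                     mean_tmax = 30, amplitude = 10)
  prev <- Inf
  for (delta in c(0, 0.3, 0.6, 0.9)) {
    # shift b1 upward: M is multiplied by exp(delta) at every temperature
    m <- toy_model(mortality = base)
    for (s in names(m$stages)) {
      p <- m$stages[[s]]$mortality$params
      m$stages[[s]]$mortality <- thermal_spec("mortality_expquad",
                                              c(p[["b1"]] + delta * 8,
                                                p[["b2"]], p[["b3"]]))
    }
    e <- compute_eri(m, ts)
    expect_lte(e, prev)
    prev <- e
  }
})

test_that("generation length follows the closed-form rate summation", {
  # r = 0.1/day per immature stage, oviposition median at x = 0.5,
  # senescence 0.05/day: 3 x 10 + 0.5/0.05 = 40 days
  m <- toy_model(rate25 = c(egg = 0.1, larva = 0.1, pupa = 0.1),
                 senescence = 0.05,
                 ovip = thermal_spec("ovip_logistic", c(a = 2, b = -4)))
  expect_equal(oviposition_quantile(m$oviposition, 0.5), 0.5)
  ts <- constant_series(25, 365)
  expect_equal(compute_generation_length(m, ts, 1), 40, tolerance = 1e-6)
  # translation invariance at constant temperature
  tx <- compute_generation_length(m, ts, c(1, 90, 180, 300, 365))
  expect_true(all(abs(tx - 40) < 1e-6))
  # non-viable temperature: infinite sentinel
  expect_true(is.infinite(compute_generation_length(m, constant_series(5, 365), 1)))
  expect_error(compute_generation_length(m, ts, 0), "start_day")
})

test_that("winter starts are no faster than summer starts under seasonal forcing", {
  # keep the whole seasonal range below the optimum so r(T) is monotone
  m <- toy_model(tmin = 8, tmax = 40)   # optimum ~ 31.5
  ts <- generate_annual_temperatures("sinusoid", seed = 1, mean_tmin = 14,
                                     mean_tmax = 24, amplitude = 6)
  # the sinusoid peaks near day 92 and bottoms near day 274
  tx <- compute_generation_length(m, ts, c(274, 92))  # winter vs summer start
  expect_gte(tx[1], tx[2])
})

test_that("GI equals 365 / generation length at constant temperature", {
  # T_x = 30 + 0.5/S with S = 0.5/6.5 -> 36.5 days, GI = 10
  m <- toy_model(rate25 = c(egg = 0.1, larva = 0.1, pupa = 0.1),
                 senescence = 0.5 / 6.5,
                 ovip = thermal_spec("ovip_logistic", c(a = 2, b = -4)))
  ts <- constant_series(25, 365)
  tx <- compute_generation_length(m, ts, 1)
  expect_equal(tx, 36.5, tolerance = 1e-9)
  expect_equal(compute_gi(m, ts), 10, tolerance = 1e-9)
  expect_equal(compute_gi(m, ts), 365 / tx, tolerance = 1e-12)
  # all days non-viable -> 0
  expect_equal(compute_gi(m, constant_series(2, 365)), 0)
})

test_that("AI telescopes the product of daily finite rates", {
  flat <- function(lam) thermal_spec("lifetable_quadratic",
                                     c(a = lam, b = 0, c = 0))
  ts <- constant_series(25, 365)
  expect_equal(compute_ai(flat(1), ts), 0)
  expect_equal(compute_ai(flat(10^(1 / 365)), ts), 1)
  expect_equal(compute_ai(flat(1.02), ts), 365 * log10(1.02))
  expect_equal(round(365 * log10(1.02), 2), 3.14)
  # additivity: multiplying every lambda by 10^(1/365) adds exactly 1
  expect_equal(compute_ai(flat(1.02 * 10^(1 / 365)), ts) -
                 compute_ai(flat(1.02), ts), 1, tolerance = 1e-9)
  # flooring bounds AI below
  expect_equal(compute_ai(flat(0.01), ts, lambda_floor = 0.5),
               365 * log10(0.5))
  expect_error(compute_ai(flat(1), constant_series(25, 100)), "365")
})

test_that("ASCII grid round-trips values, geometry and nodata", {
  set.seed(99)
  g <- raster_grid(matrix(rnorm(20), 5, 4), xll = -10.25, yll = 3.5,
                   cellsize = 0.25)
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(g, p)
  r <- read_ascii_grid(p)
  expect_identical(r$values, g$values)
  expect_identical(c(r$xll, r$yll, r$cellsize), c(g$xll, g$yll, g$cellsize))
  # nodata sentinel masked on read
  g2 <- g; g2$values[2, 3] <- NA
  write_ascii_grid(g2, p)
  r2 <- read_ascii_grid(p)
  expect_true(is.na(r2$values[2, 3]))
  expect_identical(r2$values, g2$values)
  # 1x1 grid
  g3 <- raster_grid(matrix(pi, 1, 1))
  write_ascii_grid(g3, p)
  expect_identical(read_ascii_grid(p)$values, g3$values)
  # malformed inputs rejected with line numbers
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "1 2", "3"), p)
  expect_error(read_ascii_grid(p), "line 7")
  writeLines(c("ncols 2", "nrows 2"), p)
  expect_error(read_ascii_grid(p), "xllcorner")
})

test_that("grid indices equal per-cell scalar computation and propagate nodata", {
  m <- toy_model()
  lam <- thermal_spec("lifetable_quadratic", c(a = -1, b = 0.18, c = -0.0036))
  clim <- generate_temperature_raster(4, 3, t_north = 18, t_south = 28,
                                      diurnal_range = 8, seed = 12)
  clim$tmin[[5]]$values[2, 2] <- NA   # single nodata cell in one month
  res <- compute_indices_for_grid(m, lam, clim$tmin, clim$tmax,
                                  steps_per_day = 24)
  expect_true(all(is.na(c(res$eri$values[2, 2], res$gi$values[2, 2],
                          res$ai$values[2, 2]))))
  # broadcast equivalence on a non-masked cell
  cell_monthly_min <- vapply(clim$tmin, function(g) g$values[3, 1], 0)
  cell_monthly_max <- vapply(clim$tmax, function(g) g$values[3, 1], 0)
  daily_min <- phenrisk:::.monthly_to_daily(cell_monthly_min)
  daily_max <- phenrisk:::.monthly_to_daily(cell_monthly_max)
  ts <- temperature_series(daily_min, daily_max)
  expect_equal(res$eri$values[3, 1], compute_eri(m, ts))
  expect_equal(res$gi$values[3, 1], compute_gi(m, ts))
  expect_equal(res$ai$values[3, 1], compute_ai(lam, ts))
  # uniform grid: every cell equals the series-level index
  uni <- generate_temperature_raster(3, 2, t_north = 24, t_south = 24,
                                     diurnal_range = 6, seed = 13)
  resu <- compute_indices_for_grid(m, lam, uni$tmin, uni$tmax)
  expect_equal(max(abs(resu$gi$values - resu$gi$values[1, 1])), 0)
  expect_equal(max(abs(resu$ai$values - resu$ai$values[1, 1])), 0)
  # geometry mismatch rejected
  bad <- clim
  bad$tmax[[1]] <- raster_grid(bad$tmax[[1]]$values, xll = 99, yll = 0,
                               cellsize = 0.5)
  expect_error(compute_indices_for_grid(m, lam, bad$tmin, bad$tmax),
               "geometry")
})

test_that("ERI declines along a latitudinal gradient out of the viable envelope", {
  m <- toy_model(tmin = 12, tmax = 34)
  lam <- thermal_spec("lifetable_quadratic", c(a = 1, b = 0, c = 0))
  # north rows too cold for development -> mortality never matters, but
  # use temperature-dependent mortality so ERI itself responds
  cold_mort <- thermal_spec("mortality_expquad", c(b1 = 3, b2 = -0.3, b3 = 0.006))
  for (s in names(m$stages)) m$stages[[s]]$mortality <- cold_mort
  clim <- generate_temperature_raster(20, 3, t_north = -5, t_south = 30,
                                      diurnal_range = 8,
                                      seasonal_amplitude = 3, seed = 20)
  res <- compute_indices_for_grid(m, lam, clim$tmin, clim$tmax)
  col_eri <- res$eri$values[, 1]
  expect_true(all(diff(col_eri) >= 0))   # warming southward here
  expect_lt(col_eri[1], col_eri[20])
})

test_that("establishment classification applies the cutoff and keeps nodata", {
  g <- raster_grid(matrix(c(0.1, 0.7, NA, 0.61), 2, 2))
  cl <- classify_establishment(g, 0.6)
  expect_identical(cl$values, matrix(c(0, 1, NA, 1), 2, 2))
})
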