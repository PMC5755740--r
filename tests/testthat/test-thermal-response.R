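test_that("Briere-1 development rate is clamped outside thresholds and exact inside", {
  sp <- thermal_spec("briere1", c(a = 1e-4, Tmin = 10, Tmax = 35))
  expect_identical(eval_development_rate(sp, 10), 0)
  expect_identical(eval_development_rate(sp, 35), 0)
  expect_identical(eval_development_rate(sp, 5), 0)
  expect_identical(eval_development_rate(sp, 40), 0)
  # direct arithmetic: 1e-4 * 25 * 15 * sqrt(10)
  expect_equal(eval_development_rate(sp, 25), 1e-4 * 25 * 15 * sqrt(10))
  expect_equal(round(eval_development_rate(sp, 25), 5), 0.11859)
  Ts <- seq(10.01, 34.99, by = 0.5)
  expect_true(all(eval_development_rate(sp, Ts) > 0))
  expect_error(eval_development_rate(sp, NaN), "finite")
  expect_error(thermal_spec("briere1", c(a = 1, Tmin = 20, Tmax = 10)),
               "Tmin < Tmax")
})

test_that("optimum temperature closed form matches brute-force argmax", {
  sp <- thermal_spec("briere1", c(a = 1e-4, Tmin = 10, Tmax = 35))
  topt <- optimum_temperature(sp)
  expect_equal(round(topt, 4), 29.2066)
  grid <- seq(10, 35, by = 1e-4)
  expect_lt(abs(topt - grid[which.max(eval_development_rate(sp, grid))]), 0.01)
  expect_error(thermal_spec("briere1", c(a = 1, Tmin = 0, Tmax = 0)))
  # property: closed form = argmax for random threshold pairs
  set.seed(42)
  for (i in 1:100) {
    tmin <- runif(1, -5, 18); tmax <- tmin + runif(1, 5, 30)
    spi <- thermal_spec("briere1", c(a = 1e-4, Tmin = tmin, Tmax = tmax))
    gr <- seq(tmin, tmax, length.out = 200001)
    best <- gr[which.max(eval_development_rate(spi, gr))]
    expect_lt(abs(optimum_temperature(spi) - best), 0.01)
  }
})

test_that("exponential-quadratic mortality evaluates, clips and is U-shaped", {
  # published egg-mortality parameters for the lowland species
  sp <- thermal_spec("mortality_expquad", c(b1 = 10.271, b2 = -0.909, b3 = 0.019))
  expect_equal(eval_mortality(sp, 25), exp(10.271 - 0.909 * 25 + 0.019 * 625))
  expect_equal(round(eval_mortality(sp, 25), 4), 0.5605)
  # clipping contract: raw exp >= 1 returns exactly 1
  expect_identical(eval_mortality(sp, 0), 1)
  expect_identical(eval_mortality(sp, 60), 1)
  # vanishing mortality limit
  low <- thermal_spec("mortality_expquad", c(b1 = -500, b2 = 0, b3 = 0))
  expect_lt(eval_mortality(low, 25), 1e-200)
  # percent scale divides by 100
  pct <- thermal_spec("mortality_expquad",
                      c(b1 = 10.271, b2 = -0.909, b3 = 0.019), scale = "percent")
  expect_equal(eval_mortality(pct, 25), eval_mortality(sp, 25) / 100)
  # bounded in [0,1] for arbitrary finite parameters (property)
  set.seed(7)
  for (i in 1:50) {
    spi <- thermal_spec("mortality_expquad", rnorm(3, 0, 5))
    m <- eval_mortality(spi, seq(-20, 60, by = 0.5))
    expect_true(all(m >= 0 & m <= 1))
  }
  # U shape: minimum at -b2/(2 b3)
  tmin <- 0.909 / (2 * 0.019)
  tt <- seq(-20, 60, by = 0.01)
  expect_equal(tt[which.min(eval_mortality(sp, tt))], tmin, tolerance = 0.01)
})

test_that("senescence rates: exponential and Stinner forms", {
  # published female senescence parameters, lowland species
  sp <- thermal_spec("senescence_exponential", c(b1 = 0.0098, b2 = 0.0403))
  r15 <- eval_senescence(sp, 15)
  expect_equal(r15, 0.0098 * exp(0.0403 * 15))
  expect_equal(round(r15, 6), 0.017937)
  expect_equal(1 / r15, 55.75, tolerance = 1e-4)  # implied longevity in days
  flat <- thermal_spec("senescence_exponential", c(b1 = 0.01, b2 = 0))
  expect_equal(eval_senescence(flat, c(0, 20, 40)), rep(0.01, 3))
  expect_error(thermal_spec("senescence_exponential", c(b1 = -1, b2 = 0)),
               "b1 > 0")
  # Stinner with C2 = 0 reduces to a single logistic term
  st <- thermal_spec("senescence_stinner",
                     c(C1 = 0.5, C2 = 0, k1 = 4, k2 = -0.2, T0 = 35))
  Ts <- seq(0, 40, by = 5)
  expect_equal(eval_senescence(st, Ts), 0.5 / (1 + exp(4 - 0.2 * Ts)))
})

test_that("lifetime fecundity: exponential-polynomial and Gaussian forms", {
  # published total-eggs curve, lowland species
  ep <- thermal_spec("fecundity_exppoly", c(b1 = -7.851, b2 = 1.064, b3 = -0.019))
  expect_equal(eval_total_fecundity(ep, 25), exp(-7.851 + 1.064 * 25 - 0.019 * 625))
  expect_equal(eval_total_fecundity(ep, 25), 966.9, tolerance = 1e-3)
  # maximum at -b2/(2 b3) = 28.0
  expect_equal(-1.064 / (2 * -0.019), 28.0)
  tt <- seq(10, 40, by = 0.01)
  expect_equal(tt[which.max(eval_total_fecundity(ep, tt))], 28.0,
               tolerance = 0.01)
  # published Gaussian curve, highland species: peak y0 + a at x0
  ga <- thermal_spec("fecundity_gaussian",
                     c(y0 = -41393.36, a = 41971.86, b = 74.63, x0 = 25.126))
  expect_equal(eval_total_fecundity(ga, 25.126), -41393.36 + 41971.86)
  expect_equal(eval_total_fecundity(ga, 25.126), 578.50)
  # negative tails floored at zero
  expect_identical(eval_total_fecundity(ga, -200), 0)
})

test_that("cumulative oviposition CDFs are valid and invertible", {
  gam <- thermal_spec("ovip_gamma", c(a = 3.404, b = 3.906))
  expect_identical(eval_oviposition_cdf(gam, 0), 0)
  # mean of the implied density = shape/rate, against numerical integration
  xs <- seq(0, 30, by = 1e-3)
  dens_mean <- sum(xs[-1] * diff(eval_oviposition_cdf(gam, xs)))
  expect_equal(dens_mean, 3.404 / 3.906, tolerance = 1e-3)
  expect_equal(round(3.404 / 3.906, 4), 0.8715)
  # published logistic curve: 50% oviposition age = -a/b
  lg <- thermal_spec("ovip_logistic", c(a = 3.94859, b = -3.43037))
  x50 <- oviposition_quantile(lg, 0.5)
  expect_equal(x50, 3.94859 / 3.43037)
  expect_equal(round(x50, 4), 1.1511)
  expect_equal(eval_oviposition_cdf(lg, x50), 0.5)
  # monotone non-decreasing and bounded in [0,1] for random parameters
  set.seed(11)
  xs <- seq(0, 5, by = 0.01)
  for (i in 1:20) {
    sps <- list(
      thermal_spec("ovip_gamma", c(a = runif(1, 0.5, 6), b = runif(1, 0.5, 6))),
      thermal_spec("ovip_logistic", c(a = runif(1, 0.5, 6), b = -runif(1, 0.5, 6))),
      thermal_spec("ovip_cubic_exponential",
                   c(a = runif(1, 0, 2), b = runif(1, 0, 2), c = runif(1, 0, 2))))
    for (sp in sps) {
      y <- eval_oviposition_cdf(sp, xs)
      expect_true(all(diff(y) >= -1e-12))
      expect_true(all(y >= 0 & y <= 1))
    }
  }
  expect_error(eval_oviposition_cdf(gam, -0.1), ">= 0")
  expect_error(thermal_spec("ovip_gamma", c(a = -1, b = 2)), "shape")
})

test_that("development-time logit CDF has the median and limit properties", {
  b <- 4
  sp <- thermal_spec("devtime_logit", c(a1 = -b * log(5), b = b))
  expect_equal(eval_devtime_cdf(sp, 5), 0.5)
  expect_equal(devtime_medians(sp)[[1]], 5)
  expect_lt(eval_devtime_cdf(sp, 1e-9), 1e-12)
  expect_gt(eval_devtime_cdf(sp, 1e9), 1 - 1e-12)
  # invert by hand: with a=0, b=2, F = 0.75 at ln x = log(3)/2
  sp2 <- thermal_spec("devtime_logit", c(a1 = 0, b = 2))
  expect_equal(eval_devtime_cdf(sp2, exp(log(3) / 2)), 0.75)
  # strictly increasing
  xs <- seq(0.1, 30, by = 0.1)
  expect_true(all(diff(eval_devtime_cdf(sp, xs)) > 0))
  expect_error(eval_devtime_cdf(sp, 0), "> 0")
  expect_error(thermal_spec("devtime_logit", c(a1 = 1, b = -2)), "positive")
})

test_that("lethal temperatures are roots of the mortality curve", {
  sp <- thermal_spec("mortality_expquad", c(b1 = 10.271, b2 = -0.909, b3 = 0.019))
  # level 1: boundaries of the clipped region, i.e. quadratic-formula
  # roots of b1 + b2 T + b3 T^2 = 0 (independent oracle)
  lt1 <- lethal_temperatures(sp, 1)
  disc <- sqrt(0.909^2 - 4 * 0.019 * 10.271)
  roots <- sort((0.909 + c(-1, 1) * disc) / (2 * 0.019))
  expect_equal(lt1$lower, roots[1], tolerance = 1e-5)
  expect_equal(lt1$upper, roots[2], tolerance = 1e-5)
  expect_equal(round(roots, 2), c(18.30, 29.55))
  # consistency: M(lt) = level within 1e-6 at returned roots
  lt2 <- lethal_temperatures(sp, 0.9)
  for (r in c(lt2$lower, lt2$upper))
    expect_equal(eval_mortality(sp, r), 0.9, tolerance = 1e-6)
  expect_lt(lt2$lower, lt2$upper)
  # nesting: the 90% window is inside the 100% window
  expect_lt(lt1$lower, lt2$lower)
  expect_gt(lt1$upper, lt2$upper)
  # symmetric spec: roots symmetric around 0
  sym <- thermal_spec("mortality_expquad", c(b1 = -2, b2 = 0, b3 = 0.01))
  lts <- lethal_temperatures(sym, 0.5)
  expect_equal(lts$lower, -lts$upper, tolerance = 1e-5)
  # minimum mortality above the level: thresholds absent
  hi <- thermal_spec("mortality_expquad", c(b1 = 0.5, b2 = 0, b3 = 0.01))
  ltn <- lethal_temperatures(hi, 0.9)
  expect_true(is.na(ltn$lower) && is.na(ltn$upper))
  expect_error(lethal_temperatures(sp, 0), "level")
  expect_error(lethal_temperatures(sp, 1.5), "level")
  expect_error(lethal_temperatures(sym <- thermal_spec("mortality_expquad",
                                                       c(0, 0, -1)), 0.5),
               "b3 > 0")
})

test_that("linear lower development threshold is -a/b", {
  expect_equal(linear_lower_threshold(-0.05, 0.005), 10)
  expect_equal(linear_lower_threshold(0, 0.004), 0)
  expect_equal(linear_lower_threshold(-0.048, 0.005), 9.6)
  expect_error(linear_lower_threshold(1, 0), "> 0")
  expect_error(linear_lower_threshold(1, -0.1), "> 0")
})

test_that("thermal_spec validates arity and serializes round-trip", {
  expect_error(thermal_spec("briere1", c(a = 1, Tmin = 0)), "parameters")
  sp <- thermal_spec("mortality_expquad", c(b1 = 1, b2 = -0.1, b3 = 0.002),
                     param_se = c(0.1, 0.01, 0.0002), scale = "percent")
  rt <- spec_from_list(spec_to_list(sp))
  expect_equal(rt$params, sp$params)
  expect_equal(rt$param_se, sp$param_se,
               ignore_attr = TRUE)
  expect_identical(rt$scale, "percent")
  expect_identical(rt$form, sp$form)
})
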