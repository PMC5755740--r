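test_that("cohort generator respects survival and duration distributions", {
  m0 <- toy_model(mortality = c(egg = 1e-12, larva = 1e-12, pupa = 1e-12))
  cfg <- generator_config(m0, temperatures = 25, n_per_cohort = 100,
                          n_replicates = 5, seed = 1)
  obs <- generate_cohort_observations(cfg)
  expect_true(all(obs$survived))

  m4 <- toy_model(mortality = c(egg = 0.4, larva = 0.4, pupa = 0.4))
  cfg4 <- generator_config(m4, temperatures = 25, seed = 2)
  obs4 <- generate_cohort_observations(cfg4)
  egg4 <- obs4[obs4$stage == "egg", ]
  p_hat <- mean(egg4$survived)              # 5 reps x 100
  se <- sqrt(0.6 * 0.4 / 500)
  expect_lt(abs(p_hat - 0.6), 3 * se)

  # survivor median duration ~ 1/r(T) at n = 500
  r25 <- eval_development_rate(m4$stages$egg$dev_rate, 25)
  med <- median(egg4$duration_days[egg4$survived])
  expect_lt(abs(med - 1 / r25) / (1 / r25), 0.05)

  # non-viable temperature: all dead, no error
  cfg_cold <- generator_config(m4, temperatures = 2, seed = 3)
  obs_cold <- generate_cohort_observations(cfg_cold)
  expect_false(any(obs_cold$survived))

  # deterministic under seed
  expect_identical(generate_cohort_observations(cfg4),
                   generate_cohort_observations(cfg4))
})

test_that("adult generator matches fecundity expectation and oviposition curve", {
  m <- toy_model()     # gamma oviposition, senescence 0.04 -> lifespan 25 d
  cfg <- generator_config(m, temperatures = 25, n_pairs = 200, seed = 4)
  ad <- generate_adult_observations(cfg)
  f <- eval_total_fecundity(m$fecundity, 25)
  o1 <- eval_oviposition_cdf(m$oviposition, 1)
  expected <- f * o1
  tot <- ad$longevity$total_eggs
  expect_lt(abs(mean(tot) - expected), 3 * sd(tot) / sqrt(length(tot)))
  # lifespan = ceil(s / S) with deterministic s = 1
  expect_true(all(ad$longevity$lifespan_days == ceiling(1 / 0.04)))

  # cumulative egg fraction tracks O(x): mean curve within KS distance 0.1
  de <- merge(ad$daily_eggs, ad$longevity[c("pair_id", "total_eggs")],
              by = "pair_id")
  de <- de[de$total_eggs > 0, ]
  de <- de[order(de$pair_id, de$day), ]
  cum <- ave(de$eggs, de$pair_id, FUN = cumsum) / de$total_eggs
  xn <- de$day * 0.04
  grid <- seq(0.1, 1, by = 0.05)
  emp <- vapply(grid, function(g) mean(cum[abs(xn - g) < 0.021]), 0)
  theo <- eval_oviposition_cdf(m$oviposition, grid) / o1
  expect_lt(max(abs(emp - theo), na.rm = TRUE), 0.1)

  # zero fecundity -> all-zero egg series
  m0 <- toy_model(fecundity250 = 1e-300)
  ad0 <- generate_adult_observations(generator_config(m0, temperatures = 25,
                                                      seed = 5))
  expect_true(all(ad0$daily_eggs$eggs == 0))
})

test_that("annual temperature profiles have the documented structure", {
  cs <- generate_annual_temperatures("constant", temp = 25)
  expect_equal(nrow(cs), 365)
  expect_true(all(cs$tmin == 25 & cs$tmax == 25))

  out <- generate_annual_temperatures("outdoor_like", seed = 6)
  expect_true(all(out$tmin >= 9.14 & out$tmin <= 16.68))
  expect_true(all(out$tmax >= 18.84 & out$tmax <= 37.66))
  expect_true(all(out$tmin <= out$tmax))

  flat <- generate_annual_temperatures("sinusoid", seed = 7, mean_tmin = 15,
                                       mean_tmax = 25, amplitude = 0,
                                       noise_sd = 0)
  expect_true(all(flat$tmin == 15 & flat$tmax == 25))
  expect_error(generate_annual_temperatures("outdoor_like",
                                            tmin_range = c(10, 5)),
               "inverted")
  # deterministic under seed
  expect_identical(generate_annual_temperatures("outdoor_like", seed = 6),
                   out)
})

test_that("synthetic climatology grids have gradient, cycle and shared mask", {
  flat <- generate_temperature_raster(5, 4, t_north = 20, t_south = 20,
                                      diurnal_range = 10,
                                      seasonal_amplitude = 0, seed = 8)
  for (g in c(flat$tmin, flat$tmax))
    expect_equal(max(g$values) - min(g$values), 0)
  expect_equal(flat$tmax[[1]]$values[1, 1] - flat$tmin[[1]]$values[1, 1], 10)

  grad <- generate_temperature_raster(6, 3, t_north = 5, t_south = 30,
                                      seasonal_amplitude = 0, seed = 9)
  jan <- grad$tmin[[1]]$values
  expect_equal(jan[1, 1], 5 - 5)      # t_north - diurnal_range/2
  expect_equal(jan[6, 1], 30 - 5)
  expect_true(all(diff(jan[, 2]) > 0))

  spek <- generate_temperature_raster(10, 10, nodata_fraction = 0.2, seed = 10)
  masks <- lapply(c(spek$tmin, spek$tmax), function(g) is.na(g$values))
  for (msk in masks) expect_identical(msk, masks[[1]])
  expect_gt(sum(masks[[1]]), 0)
})

test_that("reference models load the published parameters verbatim", {
  rosa <- reference_model("rosa")
  expect_equal(unname(rosa$stages$egg$mortality$params),
               c(10.271, -0.909, 0.019))
  expect_equal(unname(rosa$female_senescence$params), c(0.0098, 0.0403))
  expect_equal(unname(rosa$fecundity$params), c(-7.851, 1.064, -0.019))
  expect_equal(unname(rosa$oviposition$params), c(3.94859, -3.43037))
  expect_equal(rosa$female_ratio, 0.5)

  quil <- reference_model("quilicii")
  expect_equal(quil$fecundity$params[["x0"]], 25.126)
  expect_equal(unname(quil$oviposition$params), c(3.404, 3.906))
  expect_equal(unname(quil$female_senescence$params), c(0.0061, 0.056))

  # the packaged JSON fixtures match the in-code builders
  for (sp in c("rosa", "quilicii")) {
    path <- system.file("extdata",
                        paste0(sp, "_like_model_synthetic_devrates.json"),
                        package = "phenrisk")
    expect_true(nzchar(path))
    mj <- model_from_list(jsonlite::read_json(path))
    mr <- reference_model(sp)
    expect_equal(model_to_list(mj), model_to_list(mr), tolerance = 1e-12)
  }
})

test_that("model list serialization round-trips", {
  m <- reference_model("rosa")
  rt <- model_from_list(model_to_list(m))
  expect_equal(model_to_list(rt), model_to_list(m))
  expect_s3_class(rt, "phenology_model")
})

test_that("refitting generated data recovers the generating curves", {
  set.seed(77)
  # thresholds outside the tested range so observed mortality reflects the
  # mortality curve alone (no deaths from zero development)
  truth <- toy_model(mortality = c(egg = 0.1, larva = 0.3, pupa = 0.15),
                     tmin = 5, tmax = 40)
  # temperature-dependent mortality for a meaningful refit
  for (s in names(truth$stages))
    truth$stages[[s]]$mortality <-
      thermal_spec("mortality_expquad", c(b1 = 2, b2 = -0.35, b3 = 0.007))
  cfg <- generator_config(truth, seed = 11)
  cohort <- generate_cohort_observations(cfg)
  adults <- generate_adult_observations(cfg)
  built <- fit_phenology_model(cohort, adults)
  # development rate at the favourable temperature within 5%
  r_true <- eval_development_rate(truth$stages$egg$dev_rate, 25)
  r_hat <- eval_development_rate(built$model$stages$egg$dev_rate, 25)
  expect_lt(abs(r_hat - r_true) / r_true, 0.05)
  # mortality curve within 3 fitted SEs
  mf <- built$fits$egg$mortality
  expect_true(all(abs(mf$spec$params - c(2, -0.35, 0.007)) <=
                    3 * mf$spec$param_se))
  # development-time slope within 15%
  expect_lt(abs(built$fits$egg$devtime$params[["b"]] - 8) / 8, 0.15)
  # compiled model reproduces observed lifetime fecundity in simulation
  lt <- simulate_cohort(built$model, constant_series(25, 365), 200, seed = 12)
  sim_eggs_per_female <- sum(lt$eggs) / lt$n_adult_female
  obs_mean <- mean(adults$longevity$total_eggs[
    adults$longevity$temperature_C == 25])
  expect_lt(abs(sim_eggs_per_female - obs_mean) / obs_mean, 0.15)
})
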