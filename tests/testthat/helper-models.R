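# shared fixtures built in code

# a small, fully viable model with round numbers, used where the test
# needs controllable rates rather than the packaged species fixtures
toy_model <- function(rate25 = c(egg = 0.25, larva = 0.1, pupa = 0.08),
                      mortality = c(egg = 0.05, larva = 0.2, pupa = 0.1),
                      devtime_slope = 8, adult_slope = Inf,
                      senescence = 0.04, fecundity250 = 400,
                      ovip = thermal_spec("ovip_gamma", c(a = 3.404, b = 3.906)),
                      tmin = 10, tmax = 36) {
  denom <- 25 * (25 - tmin) * sqrt(tmax - 25)
  mk_stage <- function(nm) {
    # constant mortality: b2 = b3 = 0, b1 = log(M)
    life_stage(
      thermal_spec("briere1", c(a = rate25[[nm]] / denom,
                                Tmin = tmin, Tmax = tmax)),
      devtime_slope,
      thermal_spec("mortality_expquad",
                   c(b1 = log(mortality[[nm]]), b2 = 0, b3 = 0)))
  }
  phenology_model(
    egg = mk_stage("egg"), larva = mk_stage("larva"), pupa = mk_stage("pupa"),
    female_senescence = thermal_spec("senescence_exponential",
                                     c(b1 = senescence, b2 = 0)),
    male_senescence = thermal_spec("senescence_exponential",
                                   c(b1 = senescence, b2 = 0)),
    fecundity = thermal_spec("fecundity_exppoly",
                             c(b1 = log(fecundity250), b2 = 0, b3 = 0)),
    oviposition = ovip,
    female_ratio = 0.5, adult_slope = adult_slope)
}

# independent dense-grid root of the Euler-Lotka equation, used as the
# oracle against the bisection solver
grid_euler_lotka <- function(ages, lxmx, lo = -2, hi = 3, n = 20001) {
  f <- function(r) vapply(r, function(ri) sum(exp(-ri * ages) * lxmx) - 1, 0)
  rr <- seq(lo, hi, length.out = n)
  v <- f(rr)
  i <- which(v[-1] * v[-n] <= 0)[1]
  stats::uniroot(function(r) f(r), c(rr[i], rr[i + 1]), tol = 1e-12)$root
}
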