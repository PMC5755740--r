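#' Stochastic cohort simulation by rate summation and cohort updating
#'
#' Advances a cohort of eggs through egg, larva and pupa stages and adult
#' life, one day at a time, under a constant or fluctuating temperature
#' series (cycled as needed until the cohort dies out).
#'
#' Mechanics, per individual:
#' * development in each immature stage accumulates by rate summation,
#'   \eqn{\sum_h r(T_h)\,\Delta t}, over the within-day cosine cycle; the
#'   stage completes when the accumulated physiological age reaches an
#'   individual threshold \eqn{q = \exp(\mathrm{logit}(u)/b)} drawn at
#'   stage entry (the median-1 log-logistic implied by the development-
#'   time distribution slope `b`);
#' * daily within-stage death probability is
#'   \eqn{1 - (1 - M(\bar T_d))^{\Delta}} where \eqn{\Delta} is the
#'   fraction of the individual's stage requirement completed that day, so
#'   whole-stage survival at constant temperature is exactly
#'   \eqn{1 - M(T)};
#' * sex is assigned with probability `female_ratio` (drawn at cohort
#'   initialization; survival is sex-independent so this is equivalent to
#'   assignment at emergence and keeps the female survivorship curve
#'   monotone);
#' * adult normalized age accumulates the senescence rate,
#'   \eqn{x = \sum s(T_h)\,\Delta t}; a female lays
#'   \eqn{f(\bar T_d)\,[O(x_{end}) - O(x_{start})]} eggs per day and dies
#'   when `x` reaches her senescence threshold (1 exactly under the
#'   default deterministic `adult_slope = Inf`).
#'
#' Identical `seed` gives identical output.
#'
#' @param model a [phenology_model()].
#' @param temps a [temperature_series()] (cycled if the cohort outlives
#'   it).
#' @param n_individuals cohort size at the egg stage (default 100).
#' @param seed optional integer seed.
#' @param steps_per_day within-day steps for rate summation (default 24).
#' @param max_days hard cap on simulated days (default 2000).
#' @return an object of class `life_table`: list with `day` (age axis,
#'   days), `l_x` (surviving fraction of the female cohort), `m_x` (female
#'   eggs per female per day), `eggs` (total eggs laid per day),
#'   `stage_summary` (per-stage entries, completions, realized mortality
#'   and mean duration), `events` (per-individual stage entry days, death
#'   day and sex), `n_initial`, `n_female`, and `viable`.
#' @export
simulate_cohort <- function(model, temps, n_individuals = 100L, seed = NULL,
                            steps_per_day = 24L, max_days = 2000L) {
  stopifnot(inherits(model, "phenology_model"))
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_individuals)
  rates <- .daily_rates(model, temps, steps_per_day)
  nd <- rates$n_days
  slopes <- vapply(model$stages, `[[`, 0, "devtime_slope")

  # constant-temperature short-circuit: a stage with zero development rate
  # can never be completed
  if (nd >= 1 && all(rates$meanT == rates$meanT[1]) &&
      any(rates$dev[1, ] <= 0)) {
    return(.empty_life_table(n, model$female_ratio))
  }

  sex_female <- stats::runif(n) < model$female_ratio
  stage <- rep(1L, n)            # 1 egg, 2 larva, 3 pupa, 4 adult, 0 dead
  p <- rep(0, n)                 # physiological age within current stage
  q <- .stage_threshold(n, slopes[1])
  x <- rep(0, n)                 # adult normalized age
  s_thr <- rep(NA_real_, n)      # adult senescence threshold
  entry <- matrix(NA_integer_, n, 4,
                  dimnames = list(NULL, c("egg", "larva", "pupa", "adult")))
  entry[, 1] <- 0L   # eggs enter at the start of day 1
  death_day <- rep(NA_integer_, n)
  death_stage <- rep(NA_integer_, n)

  eggs_day <- numeric(0)
  females_alive_day <- integer(0)   # female-track individuals alive (any stage)
  alive_day <- integer(0)

  d <- 0L
  while (any(stage > 0L) && d < max_days) {
    d <- d + 1L
    di <- ((d - 1L) %% nd) + 1L
    females_alive_day[d] <- sum(stage > 0L & sex_female)
    alive_day[d] <- sum(stage > 0L)
    eggs_today <- 0

    # immature stages (skip individuals that entered the stage mid-cascade
    # today: their partial-day progress was applied at the transition)
    for (st in 1:3) {
      idx <- which(stage == st & entry[, st] < d)
      if (!length(idx)) next
      da <- rates$dev[di, st]
      m <- rates$mort[di, st]
      frac <- pmin(da, pmax(q[idx] - p[idx], 0)) / q[idx]  # fraction of stage today
      pdie <- 1 - (1 - m)^frac
      dies <- stats::runif(length(idx)) < pdie
      died <- idx[dies]
      death_day[died] <- d
      death_stage[died] <- st
      stage[died] <- 0L
      surv <- idx[!dies]
      if (!length(surv)) next
      p[surv] <- p[surv] + da
      done <- surv[p[surv] >= q[surv]]
      if (length(done)) {
        # fraction of the day left after completing the stage
        left <- if (da > 0) (p[done] - q[done]) / da else rep(0, length(done))
        left <- pmin(pmax(left, 0), 1)
        if (st < 3L) {
          nxt <- st + 1L
          stage[done] <- nxt
          entry[done, nxt] <- d
          q[done] <- .stage_threshold(length(done), slopes[nxt])
          p[done] <- left * rates$dev[di, nxt]
          # mortality for the partial first day in the new stage, so the
          # stage's total exponent still sums to 1
          m2 <- rates$mort[di, nxt]
          pdie2 <- 1 - (1 - m2)^(p[done] / q[done])
          dies2 <- stats::runif(length(done)) < pdie2
          d2 <- done[dies2]
          if (length(d2)) {
            death_day[d2] <- d; death_stage[d2] <- nxt
            stage[d2] <- 0L
          }
        } else {
          stage[done] <- 4L
          entry[done, 4] <- d
          s_thr[done] <- .stage_threshold(length(done), model$adult_slope)
          sen0 <- ifelse(sex_female[done], rates$sen_f[di], rates$sen_m[di])
          x[done] <- left * sen0
          # reproduction for the partial first adult day (females)
          fem <- done[sex_female[done]]
          if (length(fem)) {
            x_end <- pmin(x[fem], s_thr[fem])
            o0 <- eval_oviposition_cdf(model$oviposition, 0)
            eggs_today <- eggs_today +
              sum(rates$fec[di] *
                    (eval_oviposition_cdf(model$oviposition, x_end) - o0))
            dead_ad <- fem[x[fem] >= s_thr[fem]]
            if (length(dead_ad)) {
              death_day[dead_ad] <- d; death_stage[dead_ad] <- 4L
              stage[dead_ad] <- 0L
            }
          }
          dead_m <- done[!sex_female[done] & x[done] >= s_thr[done]]
          if (length(dead_m)) {
            death_day[dead_m] <- d; death_stage[dead_m] <- 4L
            stage[dead_m] <- 0L
          }
        }
      }
    }

    # adults that entered before today
    ad <- which(stage == 4L & entry[, 4] < d)
    if (length(ad)) {
      sen <- ifelse(sex_female[ad], rates$sen_f[di], rates$sen_m[di])
      x_old <- x[ad]
      x_new <- x_old + sen
      fem <- sex_female[ad]
      if (any(fem)) {
        o_new <- eval_oviposition_cdf(model$oviposition,
                                      pmin(x_new[fem], s_thr[ad][fem]))
        o_old <- eval_oviposition_cdf(model$oviposition,
                                      pmin(x_old[fem], s_thr[ad][fem]))
        eggs_today <- eggs_today + sum(rates$fec[di] * (o_new - o_old))
      }
      x[ad] <- x_new
      dead <- ad[x_new >= s_thr[ad]]
      if (length(dead)) {
        death_day[dead] <- d; death_stage[dead] <- 4L
        stage[dead] <- 0L
      }
    }
    eggs_day[d] <- eggs_today
  }

  n_female <- sum(sex_female)
  l_x <- if (n_female > 0) females_alive_day / n_female else rep(0, d)
  m_x <- ifelse(females_alive_day > 0,
                model$female_ratio * eggs_day / females_alive_day, 0)

  stage_names <- c("egg", "larva", "pupa", "adult")
  entered <- c(n, colSums(!is.na(entry[, 2:4, drop = FALSE])))
  exited <- colSums(!is.na(entry[, 2:4, drop = FALSE]))
  completed <- c(exited, sum(death_stage == 4L, na.rm = TRUE))
  durations <- vapply(1:3, function(st) {
    nxt <- entry[, st + 1] - entry[, st]
    mean(nxt, na.rm = TRUE)
  }, 0)
  stage_summary <- data.frame(
    stage = stage_names,
    n_entered = entered,
    n_completed = completed,
    mortality = ifelse(entered > 0, 1 - completed / entered, NA_real_),
    mean_duration = c(durations, mean(death_day[death_stage == 4L] -
                                        entry[death_stage == 4L, 4],
                                      na.rm = TRUE))
  )

  structure(list(
    day = seq_len(d), l_x = l_x, m_x = m_x, eggs = eggs_day,
    stage_summary = stage_summary,
    events = data.frame(entry, death_day = death_day,
                        death_stage = death_stage,
                        female = sex_female),
    n_initial = n, n_female = n_female,
    n_adult_female = sum(sex_female & !is.na(entry[, 4])),
    female_ratio = model$female_ratio,
    viable = sum(eggs_day) > 0
  ), class = "life_table")
}

.empty_life_table <- function(n, female_ratio) {
  structure(list(
    day = integer(0), l_x = numeric(0), m_x = numeric(0), eggs = numeric(0),
    stage_summary = data.frame(stage = c("egg", "larva", "pupa", "adult"),
                               n_entered = c(n, 0, 0, 0),
                               n_completed = 0,
                               mortality = c(1, NA, NA, NA),
                               mean_duration = NA_real_),
    events = NULL, n_initial = n, n_female = NA_integer_,
    n_adult_female = 0L, female_ratio = female_ratio,
    viable = FALSE
  ), class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> %d individuals, %d days, R0 = %.3f%s\n",
              x$n_initial, length(x$day), sum(x$l_x * x$m_x),
              if (x$viable) "" else " (non-viable)"))
  print(x$stage_summary)
  invisible(x)
}

#' Intrinsic rate of increase from a reproduction schedule
#'
#' Solves the discrete Euler-Lotka equation
#' \eqn{\sum_x e^{-r_m a_x} l_x m_x = 1} for \eqn{r_m} by bisection (to a
#' tolerance of 1e-10), where `ages` are the ages (days) at which the
#' `lxmx` mass is placed. The starting bracket is \[-1, 2\] per day,
#' expanded automatically if the root lies outside.
#'
#' @param ages ages in days (e.g. day midpoints `day - 0.5`).
#' @param lxmx products of survivorship and daily female fecundity.
#' @return the intrinsic rate of natural increase per day (0 when the net
#'   reproductive rate is exactly 1; negative when it is below 1).
#' @export
euler_lotka_rm <- function(ages, lxmx) {
  stopifnot(length(ages) == length(lxmx), all(ages >= 0))
  keep <- lxmx > 0
  if (!any(keep)) stop("all-zero reproduction schedule: rm undefined")
  ages <- ages[keep]; lxmx <- lxmx[keep]
  f <- function(r) sum(exp(-r * ages) * lxmx) - 1
  r0 <- sum(lxmx)
  if (r0 == 1) return(0)
  lo <- -1; hi <- 2
  while (f(lo) < 0 && lo > -700) lo <- lo * 2   # R0 << 1, very negative rm
  while (f(hi) > 0 && hi < 700) hi <- hi * 2
  if (f(lo) < 0 || f(hi) > 0) stop("Euler-Lotka root not bracketed")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (hi - lo < 1e-10) break
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Life-table parameters from repeated cohort simulations
#'
#' For each simulated life table computes the net reproductive rate
#' \eqn{R_0 = \sum l_x m_x}, the gross reproductive rate GRR (lifetime
#' female eggs per female ignoring immature mortality, estimated directly
#' as female eggs per adult female: the realized sum of the `m_x`
#' schedule over a small staggered cohort is biased upward because late
#' egg increments are divided by few surviving females), the intrinsic
#' rate of increase \eqn{r_m} solving
#' the Euler-Lotka equation with age midpoints \eqn{x + 0.5}, the finite
#' rate of increase \eqn{\lambda = e^{r_m}}, the mean generation time
#' \eqn{T = \ln R_0 / r_m} and the doubling time \eqn{D_t = \ln 2 / r_m};
#' then reports the mean and standard error of each across repetitions.
#' The identities between the parameters hold exactly for every
#' repetition. Repetitions with \eqn{R_0 \le 1} are reported honestly
#' (\eqn{r_m \le 0}; `Dt` is `Inf` at \eqn{r_m = 0}); life tables with no
#' reproduction at all are flagged non-viable and excluded from the
#' summary.
#'
#' @param life_tables a list of [simulate_cohort()] results (>= 2).
#' @return an object of class `life_table_parameters`: list with `reps`
#'   (per-repetition data frame of rm, R0, GRR, T_gen, lambda, Dt),
#'   `summary` (mean and SE per parameter), `n_reps`, `n_viable`, and
#'   `viable` (TRUE when at least one repetition reproduced).
#' @export
estimate_life_table_parameters <- function(life_tables) {
  if (length(life_tables) < 2L) stop("need >= 2 repetitions")
  stopifnot(all(vapply(life_tables, inherits, TRUE, "life_table")))
  reps <- lapply(life_tables, function(lt) {
    if (!lt$viable || sum(lt$l_x * lt$m_x) <= 0)
      return(data.frame(rm = NA_real_, R0 = 0, GRR = 0, T_gen = NA_real_,
                        lambda = NA_real_, Dt = NA_real_, viable = FALSE))
    lxmx <- lt$l_x * lt$m_x
    r0 <- sum(lxmx)
    rm <- euler_lotka_rm(lt$day - 0.5, lxmx)
    # gross reproduction: female lifetime fecundity ignoring immature
    # mortality, estimated directly as female eggs per adult female (the
    # realized sum of the m_x schedule is survivorship-staggering biased
    # in small cohorts)
    grr <- if (lt$n_adult_female > 0)
      lt$female_ratio * sum(lt$eggs) / lt$n_adult_female else 0
    data.frame(rm = rm, R0 = r0, GRR = grr,
               T_gen = if (rm != 0) log(r0) / rm else NA_real_,
               lambda = exp(rm),
               Dt = if (rm != 0) log(2) / rm else Inf,
               viable = TRUE)
  })
  reps <- do.call(rbind, reps)
  ok <- reps$viable
  pars <- c("rm", "R0", "GRR", "T_gen", "lambda", "Dt")
  summ <- data.frame(
    parameter = pars,
    mean = vapply(pars, function(p) mean(reps[[p]][ok]), 0),
    se = vapply(pars, function(p) {
      v <- reps[[p]][ok]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, 0),
    row.names = NULL
  )
  structure(list(reps = reps, summary = summ,
                 n_reps = nrow(reps), n_viable = sum(ok),
                 viable = any(ok)),
            class = "life_table_parameters")
}

#' @export
print.life_table_parameters <- function(x, ...) {
  cat(sprintf("<life_table_parameters> %d/%d viable repetitions\n",
              x$n_viable, x$n_reps))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Deterministic expected-cohort parameters at constant temperature
#'
#' Closed-form expectations that serve as an independent check on the
#' stochastic simulation. At a constant temperature `T`, whole-stage
#' survival is \eqn{1 - M_s(T)} per immature stage, every female lays
#' \eqn{f(T)\,E[O(s)]} eggs over her life (with `s` her senescence
#' threshold, exactly 1 under the deterministic default), and therefore
#' \deqn{R_0 = \prod_s (1 - M_s(T)) \cdot f(T)\,E[O(s)] \cdot \phi, \qquad
#'       GRR = f(T)\,E[O(s)] \cdot \phi}
#' with \eqn{\phi} the female ratio. Temperatures at which any stage has
#' zero development rate are non-viable (`R0 = 0`).
#'
#' @param model a [phenology_model()].
#' @param temp constant temperature, degrees Celsius.
#' @return list with `R0`, `GRR`, `stage_survival`, `eggs_per_female`,
#'   `viable`.
#' @export
expected_cohort_parameters <- function(model, temp) {
  stopifnot(inherits(model, "phenology_model"), length(temp) == 1L)
  rates <- vapply(model$stages, function(st)
    eval_development_rate(st$dev_rate, temp), 0)
  surv <- vapply(model$stages, function(st)
    1 - eval_mortality(st$mortality, temp), 0)
  if (any(rates <= 0) || any(surv <= 0))
    return(list(R0 = 0, GRR = 0, stage_survival = surv,
                eggs_per_female = 0, viable = FALSE))
  o0 <- eval_oviposition_cdf(model$oviposition, 0)
  e_o <- if (is.finite(model$adult_slope)) {
    u <- (seq_len(4000) - 0.5) / 4000
    s <- exp(stats::qlogis(u) / model$adult_slope)
    mean(eval_oviposition_cdf(model$oviposition, s)) - o0
  } else {
    eval_oviposition_cdf(model$oviposition, 1) - o0
  }
  eggs <- eval_total_fecundity(model$fecundity, temp) * e_o
  list(R0 = prod(surv) * eggs * model$female_ratio,
       GRR = eggs * model$female_ratio,
       stage_survival = surv, eggs_per_female = eggs, viable = TRUE)
}

#' Euclidean distance between observed and simulated summaries
#'
#' The validation statistic for phenology models:
#' \eqn{d = \sqrt{\sum_i (obs_i - sim_i)^2}} over matched data points;
#' zero means perfect agreement.
#'
#' @param observed,simulated equal-length numeric vectors, or named lists
#'   of such vectors (e.g. one element per life stage).
#' @return a single distance, or a data frame with one row per list
#'   element (`stage`, `n_points`, `distance`).
#' @export
validate_against_observed <- function(observed, simulated) {
  if (is.list(observed) && !is.data.frame(observed)) {
    if (!is.list(simulated) || !setequal(names(observed), names(simulated)))
      stop("observed and simulated must have matching element names")
    out <- lapply(names(observed), function(nm) {
      data.frame(stage = nm, n_points = length(observed[[nm]]),
                 distance = validate_against_observed(observed[[nm]],
                                                      simulated[[nm]]))
    })
    return(do.call(rbind, out))
  }
  stopifnot(is.numeric(observed), is.numeric(simulated))
  if (length(observed) != length(simulated))
    stop("observed and simulated vectors must have equal length")
  sqrt(sum((observed - simulated)^2))
}
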