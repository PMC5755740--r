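#!/usr/bin/env Rscript
# Stage 1: synthesize the rearing-study inputs.
#
# The raw constant-temperature rearing data behind the species' published
# thermal response curves are not deposited anywhere, so the analysis
# runs on synthetic data drawn from the packaged "rosa-like" reference
# model: the published mortality/senescence/fecundity/oviposition curves
# plus synthetic development-rate parameters. The design mirrors the
# original study: cohorts of 100 eggs/larvae/pupae, replicated 5 times,
# at 10, 15, 20, 25, 30, 33 and 35 C, and 15 adult pairs per temperature;
# plus an outdoor-like fluctuating year (daily minima 9.14-16.68 C,
# maxima 18.84-37.66 C) and a 12-month synthetic climatology on a small
# latitudinal grid.

library(phenrisk)

seed <- 20260901L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- reference_model("rosa")
cfg <- generator_config(truth, seed = seed)

cohort <- generate_cohort_observations(cfg)
adults <- generate_adult_observations(cfg)
write.csv(cohort, file.path(out, "cohort_observations.csv"), row.names = FALSE)
write.csv(adults$longevity, file.path(out, "adult_longevity.csv"),
          row.names = FALSE)
write.csv(adults$daily_eggs, file.path(out, "adult_daily_eggs.csv"),
          row.names = FALSE)

annual <- generate_annual_temperatures("outdoor_like", seed = seed + 1L)
write.csv(annual, file.path(out, "annual_temperatures.csv"), row.names = FALSE)

clim <- generate_temperature_raster(12, 10, t_north = 10, t_south = 30,
                                    diurnal_range = 10,
                                    seasonal_amplitude = 4, seed = seed + 2L)
for (m in 1:12) {
  write_ascii_grid(clim$tmin[[m]], file.path(out, sprintf("tmin_%02d.asc", m)))
  write_ascii_grid(clim$tmax[[m]], file.path(out, sprintf("tmax_%02d.asc", m)))
}

surv <- aggregate(survived ~ stage + temperature_C, cohort, mean)
cat("pooled stage survival by temperature:\n")
print(reshape(surv, idvar = "temperature_C", timevar = "stage",
              direction = "wide"), row.names = FALSE)
cat(sprintf("\nmean lifetime eggs at 25 C: %.1f (15 pairs)\n",
            mean(adults$longevity$total_eggs[
              adults$longevity$temperature_C == 25])))
cat(sprintf("outdoor-like year: tmin %.2f-%.2f C, tmax %.2f-%.2f C\n",
            min(annual$tmin), max(annual$tmin),
            min(annual$tmax), max(annual$tmax)))
cat("wrote", out, "\n")
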