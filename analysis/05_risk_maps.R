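#!/usr/bin/env Rscript
# Stage 5: risk indices over the annual series and the synthetic
# climatology.
#
# Computes the three generic pest risk indices from the fitted model:
#   ERI -- establishment risk index, the fraction of days in the year on
#          which all immature stages can survive (1 = year-round);
#   GI  -- generation index, mean generations achievable per year over
#          all Julian start days;
#   AI  -- activity index, log10 of the product of daily finite rates of
#          increase (each unit = a 10-fold annual increase).
# Writes the per-cell maps as ESRI ASCII grids plus a binary
# establishment layer at the conventional 0.6 ERI cutoff.

library(phenrisk)

out <- "results/maps"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fitted <- model_from_list(jsonlite::read_json("results/fit/fitted_model.json"))
lambda_fn <- spec_from_list(
  jsonlite::read_json("results/life_tables/lambda_quadratic.json"))
annual <- read_temperature_csv("results/data/annual_temperatures.csv")

cat(sprintf("series-level indices (outdoor-like year): ERI %.3f, GI %.2f, AI %.2f\n",
            compute_eri(fitted, annual),
            compute_gi(fitted, annual),
            compute_ai(lambda_fn, annual)))

clim <- list(
  tmin = lapply(sprintf("results/data/tmin_%02d.asc", 1:12), read_ascii_grid),
  tmax = lapply(sprintf("results/data/tmax_%02d.asc", 1:12), read_ascii_grid))
grids <- compute_indices_for_grid(fitted, lambda_fn, clim$tmin, clim$tmax)

write_ascii_grid(grids$eri, file.path(out, "eri.asc"))
write_ascii_grid(grids$gi, file.path(out, "gi.asc"))
write_ascii_grid(grids$ai, file.path(out, "ai.asc"))
write_ascii_grid(classify_establishment(grids$eri, 0.6),
                 file.path(out, "establishment.asc"))

rng <- function(g) sprintf("%.3f to %.3f", min(g$values, na.rm = TRUE),
                           max(g$values, na.rm = TRUE))
cat("map ranges over the synthetic latitudinal gradient:\n")
cat("  ERI:", rng(grids$eri), "\n")
cat("  GI: ", rng(grids$gi), "\n")
cat("  AI: ", rng(grids$ai), "\n")
cat(sprintf("cells above the 0.6 establishment cutoff: %d of %d\n",
            sum(grids$eri$values > 0.6, na.rm = TRUE),
            sum(!is.na(grids$eri$values))))
cat("wrote", out, "\n")
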