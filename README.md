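# phenrisk

Temperature-driven phenology models and pest risk indices for insect
pests, built for quantitative entomologists and biosecurity analysts who
need to go from constant-temperature rearing data to maps of where a
pest can establish. The motivating system is the Natal fruit fly species
pair — *Ceratitis rosa* (lowland type) and *C. quilicii* (highland
type) — two tephritid pests of African horticulture whose invasion risk
is assessed from their thermal biology, but every component is generic.

The pipeline is the classic process-based (deductive) approach:

1. **Thermal reaction norms.** Fit temperature response functions to
   stage-specific life-table observations: Briere-1 development rate
   r(T) = a·T·(T − T_min)·√(T_max − T) with closed-form optimum
   temperature; logit development-time distributions
   F(x) = 1/(1 + e^−(a_i + b·ln x)) with a common slope across
   temperatures; exponential-quadratic immature mortality
   M(T) = exp(b₁ + b₂T + b₃T²) clipped to [0, 1]; exponential or Stinner
   adult senescence; polynomial-exponential or Gaussian lifetime
   fecundity f(T); and logistic / gamma / cubic-exponential cumulative
   oviposition O(x) over normalized female age. Model choice is by AIC
   (n·ln(RSS/n) + 2k) and R².
2. **Stochastic cohort simulation.** Rate summation over a within-day
   cosine temperature cycle plus cohort updating with individual
   log-logistic stage thresholds; life-table parameters from the
   Euler–Lotka equation Σ e^(−r_m(x+0.5)) l_x m_x = 1 solved by
   bisection, giving r_m, R₀, GRR, mean generation time T, λ = e^(r_m)
   and doubling time ln2/r_m (identities enforced exactly).
3. **Risk indices.** Over an annual temperature series or gridded
   monthly climatologies (ESRI ASCII grids): the establishment risk
   index ERI (fraction of days all immature stages can survive;
   1 = year-round), the generation index GI (mean generations per year
   over all Julian start days), and the activity index
   AI = log₁₀ Π λ_x (each unit a 10-fold annual increase).

A synthetic-data generator reproduces the original study design (seven
constant temperatures, 100 individuals × 5 replicates per stage, 15
adult pairs) so the whole pipeline is testable without the unpublished
raw data. See the vignette (`vignettes/phenology-risk-modelling.Rmd`)
for the model details and the design decisions on ambiguous published
values.

## Worked example

Simulate 50 cohorts of 100 eggs of the packaged lowland-type fixture at
a constant 25 °C and estimate its life-table parameters:

```r
library(phenrisk)

model <- reference_model("rosa")
tabs <- lapply(1:50, function(r)
  simulate_cohort(model, constant_series(25, 365), 100, seed = 25000 + r))
estimate_life_table_parameters(tabs)
#> <life_table_parameters> 50/50 viable repetitions
#>   parameter      mean        se
#> 1        rm   0.09822 5.582e-04
#> 2        R0  77.21372 1.719e+00
#> 3       GRR 171.29492 1.519e-15
#> 4     T_gen  44.13342 1.052e-01
#> 5    lambda   1.10321 6.154e-04
#> 6        Dt   7.06874 4.085e-02
```

At 25 °C the population grows at r_m ≈ 0.098/day (λ ≈ 1.10: 10% per
day), each female egg yields ~77 female eggs in the next generation
(R₀), generations are ~44 days apart and the population doubles every
~7 days — a strongly favourable temperature, consistent with this
species' 25–30 °C optimum.

Risk indices for a synthetic outdoor-like year (tropical-highland
regime, daily minima 9.1–16.7 °C, maxima 18.8–37.7 °C), with λ(T) taken
from the quadratic trend fitted in the analysis workflow:

```r
year <- generate_annual_temperatures("outdoor_like", seed = 42)
lam <- spec_from_list(
  jsonlite::read_json("results/life_tables/lambda_quadratic.json"))
compute_eri(model, year)   # 0.879  -> survivable on 88% of days
compute_gi(model, year)    # 4.23   -> ~4 generations per year
compute_ai(lam, year)      # 9.86   -> ~10^10-fold annual growth potential
```

## The analysis workflow

The `analysis/` scripts run the full study end to end, writing tables
and grids under `results/`:

```sh
Rscript analysis/01_synthesize_data.R     # rearing tables, year, climatology
Rscript analysis/02_fit_thermal_models.R  # fit + select all response curves
Rscript analysis/03_simulate_life_tables.R# 100 x 50 per temperature
Rscript analysis/04_validate_model.R      # fluctuating-year validation
Rscript analysis/05_risk_maps.R           # eri.asc / gi.asc / ai.asc
```

`run_pipeline(run_config(...))` performs the same five stages
programmatically with a reproducibility manifest.

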