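# budcanal

`budcanal` simulates and analyses a minimal model of **competitive auxin-transport
canalization between the two axillary buds of a 2-node stem explant**. Each bud's
auxin efflux `E` (resp. `F`) self-activates through a Hill-type positive feedback
and competes with the other bud through a shared stem sink; bud length grows as a
saturating function of efflux:

```
dE/dt = v0 + v (S E)^n / ((S E)^n + (D (E + F) + K)^n) - mu E     (and symmetrically for F)
dN/dt = E^m / (Q^m + E^m)                                          (bud length)
```

`v0` is the basal efflux rate (lowered by BRC1 activity) and `mu` the efflux
decay rate (PIN1 removal, raised by strigolactone signaling). Depending on
`(v0, mu)` the efflux subsystem is monostable, bistable, tristable or
quadrastable, which maps onto six qualitative branching behaviors — from
*both buds activate* to *neither activates* — with stochasticity (chemical
Langevin noise) selecting the realized outcome in the multistable regimes.

## What the package provides

| Module | Entry points |
|---|---|
| Model core | `bud_params()`, `efflux_rates()`, `efflux_jacobian()`, `growth_rates()` |
| Simulation | `simulate_explant()`, `simulate_ensemble()`, `reference_trajectory()`, `switch_time()` |
| Steady states | `find_steady_states()`, `classify_behavior()`, `nullclines()`, `behavior_table()` |
| Parameter plane | `behavior_map()`, `outcome_fraction_map()`, `metric_heatmaps()`, `repair_pixels()`, `sensitivity_scan()` |
| Trace metrics | `trace_metrics()`, `growth_rate_series()`, `relative_growth_index()`, `outcome_summary()`, `mitchison_series()` |
| Genotype fitting | `genotype_observation()`, `constraint_set()`, `place_genotypes()`, `predict_metrics()`, `sip1_slice()` |
| Synthetic data | `explant_archetype()`, `generate_explants()`, `generate_from_model()` |
| Pipelines / IO | `run_stage()`, `read_run_config()`, `write_grid_map()`, `write_bud_traces()` |

All tabular results are tibbles; fitted/derived objects have `tidy()` /
`glance()` methods and the maps and trajectories have `ggplot2::autoplot()`
methods.

## Quick start

```r
library(budcanal)

p <- bud_params()          # calibrated defaults (v0 = 0.05, mu = 0.4, ...)

# one stochastic explant: top bud wins or loses at random
tr <- simulate_explant(p, t_end = 120, dt = 0.1, seed = 1)
ggplot2::autoplot(tr)

# steady states and qualitative class at this (v0, mu)
ss <- find_steady_states(p)
classify_behavior(ss)
#> <behavior_class> 2: both-or-one (green), 3 stable state(s)

# behavior classes over the (v0, mu) plane
sl  <- default_slice(40, 40)
map <- behavior_map(sl$v0, sl$mu, p)
ggplot2::autoplot(map)

# stochastic outcome fractions, and observed genotypes placed on them
om  <- outcome_fraction_map(sl$v0, sl$mu, p, n_sims = 100)
obs <- rbind(genotype_observation("Col-0",    p_both = 0.20, p_one = 0.80, p_none = 0.00, n = 100),
             genotype_observation("brc1brc2", p_both = 0.39, p_one = 0.61, p_none = 0.00, n = 100))
place_genotypes(obs, constraint_set(
  mu_groups = list(col = c("Col-0", "brc1brc2")),
  v0_groups = list(col = "Col-0", brc1 = "brc1brc2"),
  v0_order  = c("col", "brc1")), om)
```

Synthetic experimental-format data with known ground truth:

```r
arch   <- explant_archetype(p_both = 0.3, p_one = 0.6, p_none = 0.1)
cohort <- generate_explants(arch, n = 50, seed = 1)
m      <- trace_metrics(cohort$traces, mode = "experimental", window = 1)
outcome_summary(m)
```

## File pipelines

Every stage of the analysis is scriptable from a single YAML configuration via
`run_stage()` (trajectories, maps, heatmaps, metrics, fitting, prediction,
synthetic cohorts, sensitivity scans). Outputs are plain TSV/JSON with a
provenance record; identical config + seed gives byte-identical files.

```r
run_stage(list(stage = "map", out_dir = "out", map_kind = "outcome",
               grid = list(n_v0 = 40, n_mu = 40), seed = 1))
```

## Reproducibility notes

- All stochastic simulation is seeded; ensembles and map cells use documented
  per-cell seed formulas, so any single simulation can be replayed in
  isolation.
- `reference_trajectory()` provides an independent high-accuracy deterministic
  integration (`deSolve`) for verifying the stochastic scheme's zero-noise
  limit.
- `scripts/acceptance.R` prints the package's self-contained acceptance
  targets as JSON: `Rscript scripts/acceptance.R --seed 1 --out out.json`.

See the methods vignette (`vignette("budcanal-methods")`) for the model
derivation, the numerical schemes, the behavior taxonomy, and the calibration
procedure behind the defaults.
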