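---
title: "budcanal: model, numerics and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{budcanal: model, numerics and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
```

```{r setup}
library(budcanal)
```

## The model

A 2-node stem explant carries two axillary buds competing to export auxin into
a shared stem sink. The state is `(E, F, N, M)`: the efflux of the top and
bottom bud and their lengths. Efflux follows a canalization-type positive
feedback — a bud's own efflux promotes further efflux through a Hill function —
while the combined efflux of both buds raises the Hill threshold through the
shared sink, producing mutual inhibition:

$$\frac{dE}{dt} = v_0 + v\,\frac{(SE)^n}{(SE)^n + (D(E+F)+K)^n} - \mu E,$$

and symmetrically for $F$. Bud length integrates a saturating function of
efflux, $dN/dt = E^m/(Q^m + E^m)$, so a bud whose efflux never rises
essentially does not grow. `v0` is the basal (non-polar) efflux rate, lowered
by BRC1 activity; `mu` is the efflux decay rate, the model image of PIN1
removal from the membrane, raised by strigolactone signaling. Lengths and
efflux are in model units; time is in integration steps.

```{r}
p <- bud_params()
unlist(p)
```

## Steady states and the six-class taxonomy

The efflux subsystem is closed in `(E, F)`. On the symmetric line $E = F$ the
fixed-point condition is a degree-$(n{+}1)$ polynomial for integer $n$, which
`symmetric_steady_states()` solves exactly by root enumeration; off the line,
`find_steady_states()` runs a vectorized damped Newton iteration from a
lattice of starts, closes the result under the bud-swap symmetry, and labels
stability by the Jacobian eigenvalues.

A *stable configuration* maps to one of six behaviors (`behavior_table()`):
a single active symmetric state (class 1, both buds activate), an active
symmetric state coexisting with an asymmetric pair (class 2, both-or-one), an
asymmetric pair only (class 3, only one), a dormant symmetric state plus an
asymmetric pair (class 4, one-or-neither), two symmetric states plus a pair
(class 5, all four outcomes), and a single dormant symmetric state (class 6,
neither activates). The active/dormant cut-offs (0.4 and 0.24 efflux units)
sit in the gaps of the bimodal distribution of symmetric steady-state values
over the calibrated slice. Any configuration outside the table raises a
`budcanal_unclassifiable` condition rather than being coerced.

```{r}
ss <- find_steady_states(p)
ss
classify_behavior(ss)
```

`behavior_map()` evaluates this classification over a `(v0, mu)` grid.
The calibrated default slice (`default_slice()`) spans
`v0` in [0.005, 0.35] and `mu` in [0.25, 2.0]; the defaults for the remaining
parameters were chosen so this slice exhibits all six classes in a connected
arrangement (the both-activate region at high `v0`/low `mu`, competition
regions in the middle, dormancy at low `v0`/high `mu`).

```{r, eval = FALSE}
sl <- default_slice(60, 60)
ggplot2::autoplot(behavior_map(sl$v0, sl$mu, p))
```

## Stochastic simulation

Multistability only sets the menu; noise selects the outcome. The package
adds chemical-Langevin-style noise to the efflux equations only (growth is a
deterministic readout), with scale `eta` multiplying a state-dependent
diffusion term. Integration uses a drift-implicit Euler–Maruyama scheme in
C++: the Hill feedback term is evaluated explicitly, while the stiff linear
decay `-mu E` is treated implicitly, keeping the update stable and
nonnegative at `dt = 0.1`. Noise increments are pre-generated in R under
`set.seed()`, so every trajectory is a pure function of its seed, and
ensemble member `i` uses `base_seed + i` — any member can be replayed alone.

```{r}
tr <- simulate_explant(p, t_end = 120, dt = 0.1, seed = 1)
ggplot2::autoplot(tr)
```

Two independent checks pin the numerics. First, with `eta = 0` and symmetric
initial conditions the scheme preserves `E = F` to machine precision.
Second, `reference_trajectory()` integrates the deterministic system with
`deSolve::lsoda` at tight tolerances; the zero-noise stochastic scheme
converges to it at first order in `dt` (the measured error is about
`2 * dt` in relative terms near the switch), so `dt = 2e-6` reproduces the
reference to better than `1e-5` relative — the setting used by the package's
acceptance checks of the integrator.

## Outcome maps, metrics and repair

`outcome_fraction_map()` runs an ensemble per grid cell and scores each run
with the final-length outcome rule (`growth_outcome()`): *one* if the longer
bud exceeds three times the shorter, *both* if both exceed an activation
length, *none* otherwise. Cells whose behavior class already fixes the
outcome (classes 1, 3, 6) are filled analytically. Per-cell seeds follow
`base_seed + r + n_sims * ((j-1) + (i-1) * n_mu)`, making every cell
independently replayable. `mark_boundaries()` flags pixels where the number
of stable states changes; `repair_pixels()` heals failed cells from
neighbors (exact copy when neighbors agree, mean for numeric payloads, never
averaging class labels). `metric_heatmaps()` maps mean lag and mean maximum
growth rate over activated buds only, with `NA` (not 0) where nothing ever
activates.

## Trace metrics

A single extractor serves experimental-format and simulated traces:
lengths are smoothed by a centered moving average, differentiated by centered
differences, and a bud is *active* when its rate strictly exceeds a threshold
(2.5 mm/day experimental; 0.02 units/step simulated). Lag is the time of the
first crossing; the maximum growth rate is the peak of the smoothed series;
the relative growth index (RGI) is the longest bud's share of the summed
final lengths, 0.5 for equal growth and 1 for complete dominance, defined
only for active explants. Explants flagged `excluded` are dropped before any
computation.

## Genotype placement under constraints

Observed genotypes enter as outcome-fraction triples
(`genotype_observation()`). Biology supplies equality and order constraints
(`constraint_set()`): labels sharing a PIN1-removal level share a `mu`
column, labels sharing a BRC1 level share a `v0` row, and known hormone
relationships order the bars. `place_genotypes()` minimizes the summed
total-variation distance between each observation and its map cell, exactly:
exhaustive enumeration over ordered column combinations with an exact dynamic
program over ordered rows, ties breaking to the lexicographically smallest
positions. One caution from the package's own calibration: outcome fractions
vary mainly across the region boundaries, so iso-fraction contours are long
and nearly parallel — with independently sampled noisy observations the
optimum can slide several cells along a contour while changing the objective
by less than the sampling noise. Placements should therefore be read as
*contour positions*, sharp across the boundary structure and soft along it.

`predict_metrics()` then runs ensembles at the placed positions and returns
outcome fractions, lag/rate/RGI summaries and Mitchison series;
`sip1_slice()` builds the reduced-`S` slice used for
strigolactone-insensitive PIN1 predictions.

## Synthetic data with known ground truth

`generate_explants()` draws experimental-format cohorts from an
`explant_archetype()`: outcomes from the archetype probabilities, switch days
and maximum rates from clamped normal distributions, activating buds rising
logistically from the baseline to a plateau, inhibited buds creeping
linearly, i.i.d. Gaussian measurement noise on top. The logistic is
constructed so the ground truth is identifiable from daily samples: the
latent curve still equals the baseline exactly at the switch day, and its
maximum slope equals the drawn rate exactly one day later (the steepness `k`
solves `k = (4g/A)(1 - plogis(-k))`). Daily centered differences still
underestimate the true maximum slope by a factor that grows with `4g/A`;
with the default plateau the bias stays within the package's documented
recovery tolerances when `window = 1` is used for such step-like curves.
A `stop_switch` fraction of *both* explants is realized sequentially —
the first bud plateaus at half height before the second activates —
mimicking stop-and-switch competition.

`generate_from_model()` closes the loop on the simulated side: it runs
ensembles at placed `(v0, mu)` positions and emits the same long trace
format, so the whole metrics/fitting pipeline can be exercised against model
ground truth.

## Command-line pipelines

`run_stage()` executes any stage (simulate, map, heatmap, metrics, fit,
predict, synth, sensitivity) from one validated YAML/`list` config, writing
plain TSV/JSON outputs plus a `provenance.json` (config echo, seed, package
version). Identical config and seed give byte-identical outputs. Grid maps
serialize as one matrix TSV per channel plus a JSON sidecar and round-trip
exactly (`write_grid_map()` / `read_grid_map()`).

## Scope and limitations

The model is a two-bud caricature: no explicit auxin pool, no spatial stem,
no delay between efflux and growth. The noise term is a single-scale
Langevin approximation, not a discrete-molecule simulation. The calibrated
defaults are one representative slice chosen for qualitative completeness of
the six-class structure, not a fit to measured bud lengths; quantitative
time units (steps vs days) are not matched to experiments. Placement
recovers contour positions, with the along-contour softness described above.
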