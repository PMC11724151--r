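---
title: "dynrange: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dynrange: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynrange)
```

`dynrange` simulates the range dynamics of one species at a time on a
gridded landscape. This vignette is the package's own account of the
science it implements: the process model and its assumptions, what every
tunable parameter means and why its default was chosen, the numerical
decisions that make the simulator reproducible, what the synthetic-data
generators do and do not emulate, and the known limitations.

## The process chain

One timestep applies, in order, to every grid cell:

1. **Niche → habitat suitability.** Each niche variable is mapped through a
   cardinal (minimum/optimum/maximum) tolerance curve,
   \[
   h = \frac{v_{max}-v_{env}}{v_{max}-v_{opt}}
   \left(\frac{v_{env}-v_{min}}{v_{opt}-v_{min}}\right)
   ^{(v_{opt}-v_{min})/(v_{max}-v_{opt})},
   \]
   which is 1 exactly at the optimum, 0 at both limits, and unimodal in
   between. Multiple variables combine by cell-wise minimum (default:
   Liebig-style limitation) or product (independent filters); restriction
   layers in \[0, 1\] are applied the same way afterwards.

2. **Metabolic theory → demographic rates.** Reproduction rate, mortality
   probability and carrying capacity scale with body mass and local
   temperature, \(Q = b_0\, m^a e^{-E/(kT)}\), with the normalisation
   \(b_0\) anchored so that each rate recovers its reference value at the
   species' optimum temperature. The fields are recomputed each timestep
   from that timestep's temperature grid, so dynamic climate series
   propagate into the demography.

3. **Local dynamics.** The per-cell update is decomposed into *survivors*
   and *seeds*. Under the default Beverton–Holt-with-mortality model the
   seed production is \(N r / (1 + N(r-m)/(K_h m))\) with \(K_h = K h\);
   this is the unique decomposition whose closed-cell composite has its
   positive fixed point exactly at \(K_h\), so habitat suitability
   rescales equilibrium abundance linearly. Ricker and Ricker–Allee maps
   are provided as alternatives, decomposed the same way so the
   reproduce–disperse–recruit order applies uniformly.

4. **Dispersal.** Seeds are redistributed by a truncated
   negative-exponential kernel discretised at cell centres; grid edges are
   absorbing (mass leaving the landscape is lost). The origin cell's
   retained seeds are handled by the kernel's own centre weight — there is
   no separate "stay-at-home" pathway.

5. **Recruitment and integerisation.** Arriving seed mass becomes integer
   recruits: a per-cell Poisson draw when demographic stochasticity is on,
   otherwise deterministically. The new abundance is
   \(N' = \lfloor N(1-m) + \text{recruits}\rfloor\): abundance is rounded
   down once, *after* recruitment. Survivors and seeds are computed from
   the same census \(N_t\) (simultaneous census; the model does not state
   mortality as happening strictly before or after reproduction, and this
   choice keeps the fixed point exact).

Outputs record the state *after* each timestep's update: the abundance
grid plus the habitat suitability, effective carrying capacity,
reproduction rate and mortality fields used in that step.

## Parameters, units, defaults

Configuration (all have the listed default except the required
`temperature` path): `timesteps` 20, `randomseed` 42, `reproduction_model`
`Beverton`, `env_attribute_mode` and `env_restriction_mode` `minimum`,
`initialise_cells` `habitat`, `use_metabolic_theory` true,
`use_stoch_num` false, `input_backup` false.

Species traits (one `key,value` CSV per species):

| key | units | meaning |
|---|---|---|
| `carry` | individuals/cell | carrying capacity at reference conditions |
| `growrate` | per timestep | reference reproduction rate (must exceed `bevmort` under Beverton) |
| `bevmort` | probability | reference mortality, in \[0, 1\] |
| `max_dispersal_dist` | cells (integer ≥ 1) | kernel truncation radius |
| `mean_dispersal_dist` | cells (> 0) | mean displacement; kernel decay length is half of it |
| `mass` | g | body mass driving the allometric scaling |
| `lower/optimum/upper_limit_temperature` | °C or K | cardinal temperature niche |
| `lower/optimum/upper_limit_precipitation` | mm/yr | optional precipitation niche |

Temperature limits may be written in Celsius or Kelvin: values whose mean
exceeds 150 are interpreted as Kelvin (the conversion is therefore
idempotent), and an explicit `temperature_unit` key overrides the
heuristic. The same rule applies to temperature layers.

The metabolic exponents and activation energies are deliberate defaults,
not fitted values: biological *rates* scale as mass^(−1/4) and rise with
temperature (E = +0.65 eV), while *carrying capacity* scales as
mass^(−3/4) and falls with temperature (E = −0.65 eV), the canonical
allometric choices. All six are overridable per species
(`exponent_*`, `activation_energy_*`), and an optional `allee` threshold
(which must stay below `carry`) follows the carrying-capacity scaling.

## Numerical choices

* **Round-down integerisation.** Deterministic recruitment rounds down, and
  the final abundance is floored once per timestep. A floored map stalls
  wherever the continuous per-step gain drops below one individual, so the
  deterministic closed-cell equilibrium sits a few individuals *below*
  \(K_h\) (e.g. 997 for \(r = 1.15, m = 0.44, K_h = 1000\), a 0.3% gap);
  the real-valued composite converges to \(K_h\) exactly. Tests assert
  the fixed point on the real-valued map and a 0.5% band on the
  integerised one. Flooring once (rather than flooring survivors and
  recruits separately) keeps that gap as small as any round-down scheme
  allows.
* **Tolerance-curve clamping.** Values at or beyond the cardinal limits map
  to exactly 0 (no extrapolation; the fractional power never sees a
  negative base); results are clamped into \[0, 1\] against floating-point
  overshoot and suitabilities below 1e−12 are flushed to 0 so "suitable
  cell" predicates are stable.
* **Kernel discretisation.** Weights are evaluated at cell-centre Euclidean
  distances and renormalised over the truncated window, so truncation
  never loses seed mass — only absorbing edges do. For mean distances far
  below one cell the off-centre weights underflow to 0 and the kernel
  degenerates gracefully to the identity.
* **Reproducibility.** One seeded generator (R's global RNG, seeded from
  `randomseed` at initialisation) drives random initialisation and
  Poisson recruitment; Poisson draws are consumed in R's native
  column-major cell order. Same inputs + same seed ⇒ bit-identical
  outputs, which the CLI manifest makes auditable.
* **Degenerate inputs.** `NA` cells in any environment layer are
  permanently uninhabitable (suitability 0, capacity 0, abundance forced
  to 0); `r ≤ m` cells produce zero seeds (decline-only); mortality scaled
  above 1 is clamped to 1 rather than erroring; an extinct grid stays
  extinct.

## Synthetic data: what it does and does not emulate

`neutral_landscape()` generates spatially autocorrelated Gaussian fields
(white noise smoothed by a Gaussian kernel with edge renormalisation) and
then standardises them *exactly* to the target sample mean and standard
deviation — the moments are binding, the autocorrelation algorithm is not.
`demo_input()` uses this for the out-of-the-box experiment: a 20 × 20
landscape, temperature 293.15 ± 2.5 K, precipitation 500 ± 100 mm/yr,
25 timesteps, and a demo species that combines plant-like demographic
references (reproduction 1.15, mortality 0.44, capacity 266 667/cell, mass
23.82 g) with a temperature niche centred on that landscape and dispersal
raised to mean 1 / max 3 cells so dispersal is visible at demo scale.

`climate_trend_series()` implements the burn-in pattern: scenario series
are built as repeated static slices followed by a uniform additive trend
(burn-in is a property of the inputs, not an engine flag). The packaged
example generators (`create_example()`) produce a static experiment and a
warming experiment (40 timesteps, onset at timestep 11, +0.1 K per step)
around the packaged *Orchis militaris* trait file.

Passing tests on these landscapes demonstrates the process chain's
correctness and its qualitative behaviour (equilibrium tracking,
source–sink damping of losses and gains under higher dispersal). It does
*not* validate forecasts for real landscapes: synthetic fields lack
topography, spatially structured trends, land-use patterns and the
spatial covariance of real climate, and the demo problem sizes (hundreds
of cells, tens of timesteps — chosen so the full suite runs in seconds)
are far below application scale.

## Open design points resolved here

* Suitability is always recomputed even when metabolic scaling is
  bypassed — the niche is independent of the metabolic machinery.
* Multiple species files are loaded together but simulated independently,
  one species per run (no biotic interactions).
* Seeds may land in zero-suitability cells; they recruit there and then
  decline (suitability acts only through the carrying capacity, there is
  no settlement filter).
* The output TSV labels the abundance stack `abundance` and is genuinely
  tab-separated; coordinates are 1-based with `x` = column, `y` = row.
* `random` initialisation occupies each suitable cell with probability
  0.5 — an arbitrary, documented constant.
* Recorded outputs are post-update; the initial (pre-step-1) state is not
  a slice of the output stacks.

## Limitations

Single species, no biotic interactions or evolution; absorbing edges only
(use a buffer rim wider than the maximum dispersal distance around any
focal area, or expect depressed boundary abundances for far-dispersing
species); one tolerance-curve shape (no Gaussian alternative); plain-CSV
I/O only (no raster formats); the metabolic defaults are canonical rather
than taxon-calibrated and should be overridden when estimates exist.
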