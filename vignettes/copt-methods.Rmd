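---
title: "Methods: quantifying the rarity of continent-ocean-plate-tectonic planets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the rarity of continent-ocean-plate-tectonic planets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copt)
```

## The problem

The Drake equation estimates the number of active communicative
civilizations (ACCs) in the galaxy as a product of a star-formation rate,
planetary fractions, biological fractions and a broadcast lifetime.  Its
classic parameterizations predict hundreds to tens of millions of ACCs,
in tension with the absence of any observed signal (the Fermi paradox).
This package implements a quantitative resolution built on planetary
tectonics: the factor `f_i` (fraction of life-bearing planets that evolve
intelligent, civilization-building life) is split into

* `f_oc` — the probability that a habitable planet carries *both*
  significant continents and significant oceans over geologic time, and
* `f_pt` — the probability that such a planet has sustained plate
  tectonics for at least 0.5 Gyr,

because early life must evolve in water while technological life must
evolve on land, and because plate tectonics is what accelerates
biological evolution enough to produce a civilization within a planetary
lifetime.  Both factors turn out to be small, and their product is tiny.

## The surface-water window

Topography on rocky planets is isostatically controlled and therefore
nearly independent of planet size: the elevation difference between
continental surfaces and ocean floors is a few kilometres regardless of
radius.  Consequently the *mass* of surface water compatible with
"continents and oceans at the same time" is roughly fixed, and the
permitted *mass fraction* scales inversely with radius.  On Earth the
window is 0.007–0.027% of planetary mass:

* below 0.007% (0.3 Earth oceans) mid-ocean ridges emerge above sea
  level, the oceanic crust stops being hydrated, and one-sided
  subduction — hence plate tectonics — destabilizes;
* above 0.027% (1.2 Earth oceans) nearly all land is flooded, leaving
  less than the 5–10% land coverage needed for terrestrial evolution.

`permitted_window(planet, freeboard_mode)` implements
`fmin = 0.007/R`, `fmax = 0.027/R` (percent, `R` in Earth radii).  The
alternative `"korenaga"` mode anchors the upper bound at 0.067%/R,
following a continental-freeboard analysis under which a water world
with two to three Earth oceans still retains land; we keep
`"conservative"` as the default because it guarantees *significant* land
area rather than marginal emergence.  One Earth ocean is *defined* as
0.0224% of one Earth mass, so all ocean-unit conversions are ratios of
printed constants and no kilogram-scale quantities enter the code.

Two exact scaling laws follow and are asserted in the tests: window
width times radius is constant, and ocean-equivalent bounds grow as
radius squared (mass grows as `R^3`, fraction shrinks as `1/R`).

A deliberate consequence of implementing the *law* rather than printed
instances: for a Mars-size planet (`R = 0.5`) the model returns
0.014–0.054%, whereas rounding each Earth bound to 2 significant figures
before scaling would print 0.015–0.055%.  The water stage emits a
message noting this; the unrounded model values are authoritative.

## Bounds on f_oc

Planet-formation theory predicts delivered water mass fractions from
0.008% up to 3.8% for planetesimal delivery (0–90% impact volatile loss,
5–10% planetesimal water content) and 6–55% for ocean worlds of the
Europa/Callisto type.  Treating the delivered fraction as uniformly
distributed over a variability range `V`, the probability of landing in
a window of width `w` is `w / V`.  `foc_ratio_bounds()` cross-pairs the
extremes — narrowest window (largest planet, width 0.009% at
`R = 2.35`) over widest variability (55%), and widest window (0.04% at
`R = 0.5`) over narrowest variability (3.8%) — giving

```{r}
foc_ratio_bounds(0.009, 0.04, variability_range(3.8, 55))
```

i.e. `f_oc` between about 0.00016 and 0.011.  The uniform-distribution
reading is the only one that reproduces both published endpoints; it is
stated here explicitly because the ratio bound inherits it.

`foc_from_population()` provides the independent, data-driven route:
count the planets of a population whose water fraction falls inside
their radius-dependent window (closed interval; boundary planets count
as inside, a measure-zero choice for continuous generators) and attach
the binomial standard error `sqrt(p(1-p)/n)`.

## The f_pt upper bound

`fpt_estimate()` multiplies independent reduction factors: about 1/3 of
observed stellar compositions can host planets dense enough for
density-driven (plate) tectonics, and roughly half of terrestrial
planets are too small (Mars/Mercury class) to sustain vigorous mantle
convection, giving 0.33 × 0.5 = 0.165, displayed as 0.17.  Further
reductions — super-Earth buoyant crusts, mantles that start too cool for
subduction ever to initiate — are real but unquantified, so the value is
carried strictly as an *upper bound*: the returned value has attribute
`bound = "upper"`, and every quantity derived from it downstream is
flagged `<` in reports.  No lower bound exists in the model; where an
interval is needed downstream the lower end is a configurable floor
defaulting to 0.

## Drake equation forms and uncertainty propagation

`drake_params()` holds the seven terms of the ACC form
`N = R* f_p n_e f_l f_i f_c L` (with `f_i` optionally split into
`f_oc · f_pt`) or the remote-sensing COPT form
`COPTs = R* f_p n_e f_l f_oc f_pt L_COPT`, which drops `f_c` and uses
`L_COPT = 5e8` yr — the characteristic duration of coexisting
continents, oceans and plate tectonics on Earth — in place of the
broadcast lifetime.  Three evaluators:

* `drake_point()` — plain product;
* `drake_interval()` — products of endpoints, exact because all terms
  are non-negative so the product is monotone in each;
* `drake_monte_carlo()` — seeded sampling.  Terms whose interval spans
  more than one decade (`high/low > 10`, e.g. `L` = 1e3–1e8 yr,
  `f_oc`) default to log-uniform sampling, the standard
  non-informative choice for order-of-magnitude parameters; narrower
  terms (`f_p`, `n_e`, `f_c`) default to uniform.  Both are
  overridable per term.  Samples provably lie inside the interval
  bounds, which the tests assert at 1e5 samples.

`scale_acc_range()` reproduces the headline rescaling: the classic
acknowledged range of 200–5e7 ACCs, multiplied by the `f_i` bounds
3e-5–2e-3, collapses to < 0.006 – < 100,000.  Two published ranges are
deliberately *not* asserted anywhere: the lifetime-reduced ACC range
(< 0.0004 – < 20,000) and the COPT count range (500 – ~1,000,000)
cannot be derived from any combination of the printed factors, so the
engine exposes them only as generic scenarios, order-of-magnitude
context rather than test oracles.  (Our COPT interval evaluation gives
2,720 – 2.34e6, qualitatively consistent with the published range.)
Similarly, the classic quoted lower bound of 200 is not the product of
the listed 1961 minima, which give 20; the engine reproduces the scaling
of the quoted range, not its origin.

The galaxy-level statement "the probability of even one ACC can be below
0.04%" corresponds to reading a scaled lower bound `N_low < 1` as a
percentage; the reporting layer does this only when `N_low < 1` and
always alongside the raw count.

## Tectonic timescales

A global plate mosaic must grow from a first subduction-initiation point
by lateral propagation of new convergent margins.  With observed and
modelled trench-lengthening rates of ~100–600 km/Myr and ~55,000 km of
convergent margin to build, `assembly_time_range(55000, 100, 600)` gives
92–550 Myr.  Growth is modelled as linear lengthening at constant rate —
exactly the quotient the estimate implies — with no logistic or
branching dynamics.  `bracket_duration()` computes transition durations
from marker-event ages (Ma before present, larger = older): the
carbon-isotope bracket 811 → 570 Ma gives 241 Myr, the Snowball-Earth
glaciation bracket 720 → 580 Ma gives 140 Myr.  The three estimates
agree to within a factor of a few — hundreds of millions of years.

## The sequential speciation chain

In a constant-rate birth–death model, lineages speciate at rate λ and go
extinct at rate μ, both per lineage per Myr, with estimated rates
typically in 0–1 and rarely above 1 outside crisis intervals.  We track
a *single focal line* — a sequential chain of new species, not a
branching tree.  This is a deliberate design choice: under a full
birth–death tree, rates near 1 over 500–1000 Myr would yield
astronomically many lineages, whereas the "only a few hundred new
complex species in a tectonic era" budget arises exactly from the
single-chain reading.  Extinction of the focal line truncates the chain;
re-seeding from sister lineages is out of scope.

Along the chain, events occur as a Poisson process of rate λ+μ; each
event is a speciation with probability λ/(λ+μ), otherwise the line dies.
By Poisson thinning, speciations accrue at rate λ while the line
survives, and the lifetime is exponential with rate μ, giving the exact
closed form

$$E[N] = \frac{\lambda\,(1 - e^{-\mu T})}{\mu}, \qquad
  E[N] \to \lambda T \ \text{as}\ \mu \to 0 .$$

`expected_chain_length()` evaluates this closed form (no truncated
series is needed).  `simulate_chain()` is the independent cross-check:
an event-driven competing-risks simulation drawing exponential waiting
times and categorical event types, vectorized in blocks sized from the
expected event count for speed but statistically identical to the
one-event-at-a-time loop.  At λ = 1, μ = 0 the count over a horizon T is
exactly Poisson(λT), which the tests use as a distributional oracle
(mean, variance, and exact Poisson median at T = 500).

At the upper typical rate (λ = 1) the chain yields ~500–1000 sequential
speciations over 500–1000 Myr — order a few hundred, the budget that
makes a slow, single-lid tectonic era insufficient for civilization-
building evolution.

## The synthetic population generator

`generate_population()` emulates the statistical footprint of Monte
Carlo planet-formation populations: radii log-uniform over 0.5–2.35
Earth radii (log-uniform because radius is a scale parameter and only
the bounds are specified), and water mass fractions from a three-part
mixture — dry planets (point mass at 0), planetesimal-delivered planets
(uniform over 0.008–3.8%), and ocean worlds (log-uniform over 6–55%).
Water fractions are stored in percent throughout, matching every
constant in the package; the configured maximum defaults to 56% (the
span reported for simulated M-dwarf planet populations; the narrower
"0–55%" phrasing differs only in the ocean-world endpoint, so the
maximum is a config parameter).

The default weights (0.36, 0.19, 0.45) are a *calibration*, chosen once
so that the analytic in-window probability

```{r}
in_window_mass(population_config(10, seed = 1))
```

is of order 1e-3, inside the 0.0006–0.0022 range found by filtering
published planet-formation simulations — not a prediction of this
package.  `in_window_mass()` integrates each component's distribution
function over the radius-dependent window and averages over the radius
law by adaptive quadrature (`stats::integrate`, relative tolerance 1e-9);
the generator and the quadrature are checked against each other at 3
binomial standard errors on populations up to 1e6 planets.

What the generator does *not* emulate: any correlation between radius
and water fraction, radius-dependent mixture weights, or the physics of
migration, snowlines and impact devolatilization.  Passing tests
therefore demonstrate the internal consistency of the estimator chain,
not the realism of any particular exoplanet census; the population
route to `f_oc` is validated against real simulation output only by the
range check above.

## Scenarios, rounding and reproducibility

`run_scenario()` executes stages in dependency order (water →
population → f_oc → f_pt → Drake/COPT; tectonic and speciation
independent), writes CSV and JSON, and reports every rounded value next
to its raw value.  The published headline chain mixes rounding
conventions (1 significant figure for window widths, 2 for `f_oc`, two
decimals for `f_pt`, 1 significant figure for `f_i` and the ACC range),
so `round_display()` centralizes them (round-half-away-from-zero), and
the `paper_headline` scenario feeds each stage the *display-rounded*
output of the previous one — reproducing the published arithmetic —
while raw values are carried alongside.  Science code elsewhere always
returns full precision.

Every stochastic function takes an explicit seed; identical scenario
file plus seed gives byte-identical CSV (fixed column order, 6
significant digits for raw values).  Bundled scenarios:
`paper_headline`, `tectonic`, `drake1961`, `modified_acc`, `copt`,
`population_foc`, `speciation` (see `list_scenarios()`).

Problem sizes used by the test suite and the acceptance script — chosen
as the smallest sizes at which the statistical contracts are sharp:
Monte Carlo Drake containment at 1e5 samples; population recovery at
2e5 (unit) and 1e6 (end-to-end) planets; speciation oracles at 4e3–1e4
replicate chains.  All statistical assertions use 3-standard-error
bands under fixed seeds.

## Known limitations

* The isostatic window is a zeroth-order model: no lithospheric
  flexure, mantle water partitioning, or hypsometric detail — the
  bounds are taken as given constants and only their scaling is
  modelled.
* `f_pt` is an upper bound with no modelled lower end.
* The uniform-delivery assumption behind `foc_ratio_bounds()` is an
  interpretive choice (documented above), not derived from accretion
  physics.
* The speciation chain ignores ecological covariates (trophic
  structure, habitat stability, predation) that the biological argument
  acknowledges as co-determinants.
* External planet-formation datasets are supported only through the
  two-column table loader; no bundled copy is shipped.
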