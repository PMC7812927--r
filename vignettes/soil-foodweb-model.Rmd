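---
title: "A pore-structured soil food-web carbon model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A pore-structured soil food-web carbon model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilfoodweb)
```

## The model in one page

`soilfoodweb` simulates twelve carbon pools at a daily time step in a single
soil layer: nine biotic guilds -- bacteria, fungi, mycorrhiza, bacterivores,
fungivores, detritivores, ecosystem engineers (earthworm-type fauna),
root herbivores and predators -- plus litter, soil organic matter (SOM) and
dissolved organic matter (DOM), all in g C m^-3^.

Three subsystems are coupled:

* **Soil structure.** Total porosity follows from bulk and particle density
  (the latter mixed from mineral and organic particle densities). The pore
  space is split into five size classes -- inaccessible (< 0.1 µm),
  bacterial (0.1--2 µm), micro (2--30 µm), meso (30 µm--1.5 mm) and macro
  (> 1.5 mm) -- and the split is *dynamic*: fungal + mycorrhizal biomass
  drives aggregation, which converts textural mesoporosity into micro- and
  bacterial porosity (half of the affected volume, split equally) and adds
  a capped aggregation porosity; engineers dig biopores that add to
  macroporosity, with a fraction `1 - f_PV` compensated by mesopore
  compaction. Abandoned burrows collapse with a ten-year mean lifespan.
* **Hydrology.** A spilling-bucket water balance with macropore bypass:
  net precipitation infiltrates up to the matrix capacity on the
  non-macropore surface fraction, the rest bypasses through macropores;
  matrix water above field capacity drains. Water is allocated to pore
  classes smallest-first, so exactly one class is partially filled; biotic
  activity concentrates at that wet/dry front.
* **Carbon flow.** Each guild grows by Monod kinetics on the *accessible*
  share of each diet substrate, `G = sum_n g_max (S f_a / (K_s + S))_n B`,
  where `f_a` weights the pore classes the consumer's body size can enter
  by the substrate's volumetric distribution and the per-class moisture
  modifier. `g_max` carries multiplicative modifiers for temperature (Q10
  curve with a plateau above the optimum), pH (tenfold loss per unit beyond
  8 for fungi / below 3 for bacteria; a linear pH 3--5 ramp scales the
  engineers' maximum rate), substrate C:N and recalcitrance. Respiration
  `rB` uses the same Q10 *without* the plateau, so warm spells above the
  optimum erode biomass. Death `dB` routes to SOM. Consumption exceeds
  growth by the faeces fraction (zero for microbes); detritivore and
  engineer faeces increase on nitrogen-poor substrate. Predation removes
  the predator's growth share times `1 + f_faec` from the prey.
  Bioturbation by engineers exports litter and SOM from the layer. DOM is
  produced from exudation plus a respiration-linked solubilization of SOM,
  partitions between adsorbed and dissolved phases by a pH- and
  clay-dependent coefficient, and leaches with draining water.

The daily calculation order is: (a) pore-size distribution, (b) water
balance and per-class allocation, (c) DOM production and leaching, (d)
accessibilities, (e) growth-rate modifiers, (f) all pool derivatives, (g)
state update, (h) litter/SOM quality update, (i) engineering effects
(burrows, bioturbation), (j) a structural-change hook (default no-op).
`daily_step()` composes the exported module functions in exactly this
order; `run_simulation()` executes the identical algorithm in compiled code
(the test suite asserts their equivalence), which keeps a ten-year run in
tens of milliseconds and makes Monte-Carlo calibration practical.

## Numerical scheme

The twelve pool equations are advanced by explicit Euler at the model's
native daily step; no finer integrator is warranted for a model whose
forcing and outputs are daily. Non-negativity is guaranteed by a
carbon-conserving flux limiter: if a pool's total outflow would exceed its
content, *all* of its outflows (and the matched gains of the receiving
pools) are scaled by available/required that day. Pore-class volumes are
clamped at zero with the deficit logged; the clamp never triggers at the
packaged parameterization. Litter and SOM track their own C:N and
recalcitrance: C:N mixes harmonically (i.e. on nitrogen mass, which
conserves N implicitly), recalcitrance as a mass-weighted mean.

Degenerate cases are defined explicitly: zero SOM gives zero aggregation;
zero pore volume gives a zero moisture modifier ("no habitat"); a fully
saturated profile gives zero activity in every class; an empty DOM pool,
dry soil or zero drainage give zero leaching.

## Design choices where the design was open

* **Drainage by mass balance.** The literal drainage expression
  (surface-fraction term plus net precipitation minus the matrix-fill
  minimum) double-counts water in some regimes. Drainage is therefore
  computed as macropore bypass plus matrix spill, which reproduces the
  intended behaviour in the regimes the formulation describes and conserves
  water in all of them; the literal value is still reported as a
  diagnostic (`drainage_eq_literal`).
* **Negative net precipitation** (evapotranspiration exceeding rain)
  extracts water from storage down to the wilting point (the inaccessible
  pore volume).
* **Filling order.** The one-partial-class rule fixes only that classes are
  saturated or dry; smallest-first filling was chosen to mimic
  matric-potential ordering.
* **The class above the wet front** receives the water-share weighting as
  printed; an aerated-share alternative sits behind `eq16_alt`. Classes
  more than one size above the front are fully dry and get modifier zero.
* **Moisture enters once.** For soil substrates moisture acts through the
  per-class weighting inside `f_a`; for surface litter (outside the
  matrix) it acts as the microbial-habitat moisture modifier on `g_max`.
  This avoids double-counting the same water limitation.
* **Burrow collapse.** Recomputing the mesopore volume daily from the
  current biopore volume already returns the compensated share of a
  collapsing burrow to mesoporosity; no extra accumulator is kept, which
  preserves the componentwise pore-class identities exactly.
* **Aggregation cap.** The linear aggregation-porosity rule can exceed
  plausible porosity at field-scale SOM pools, so its total contribution is
  capped at 20 l m^-3^ (~2 % porosity), split equally between micro- and
  bacterial classes.
* **Substrate depletion.** For dead substrates, consumption =
  growth / (1 - f~faecEff~) so that faeces = consumption x f~faecEff~; for
  prey and root links, prey loss = growth x (1 + f~faec~). Both close the
  link-level budget consumption = growth + faeces.
* **Herbivory boundary.** Roots are external to the model. The standing
  fine-root pool (400 g C m^-3^) sets the herbivores' Monod substrate
  level, but daily offtake is capped at root *production*
  (210 g C m^-3^ yr^-1^): an unbounded daily replenishment of the standing
  pool would let released herbivore populations import arbitrarily large
  amounts of carbon, which is biologically impossible and numerically
  destabilizing.
* **Mycorrhiza** receive a fixed daily plant-carbon allocation instead of a
  Monod term; they are prey to fungivores and contribute to aggregation
  like free-living fungi.

## Parameters

The packaged site is a sandy (93 % sand, 3 % clay), acidic (pH 3.5) Scots
pine stand: initial litter 2,680 and SOM 11,470 g C m^-3^, constant inputs
(litterfall 400, root litter 740, mycorrhizal allocation
197 g C m^-3^ yr^-1^), bulk density 1.4 g cm^-3^, 0.3 m layer. Litter
quality is set once for pine (C:N 55, recalcitrant fraction 0.45; SOM 25
and 0.6), chosen so that the evaluation scenarios "litter C:N 40" and
"recalcitrance 20 %" are reductions, as intended.

Guild biology (see `default_guilds()`): the nine maximum growth rates are
the calibration targets, with uniform priors per guild
(`gmax_priors()`). Maintenance respiration and death rates use
literature-scale magnitudes -- microbes turn over in weeks-to-months, fauna
more slowly -- and encode the fungal/bacterial niche asymmetry expected in
acid conifer forest soil: fungi and mycorrhiza have low maintenance costs
(r = 0.003, d = 0.006 day^-1^) and weak sensitivity to substrate quality
(p~mCN~ = 0.2, p~mRec~ = 0.1), bacteria the converse (r = d = 0.01;
p~mCN~ = p~mRec~ = 0.8), so bacteria live boom-and-bust on labile substrate
while fungi process the recalcitrant, nitrogen-poor litter. Temperature
curves default to T~min~ 0 °C, optima 20--25 °C, Q10 = 2. Half-saturation
constants equal the standing substrate concentration for meso- and
macrofauna (growth could double at unlimited food) and are doubled for the
microbes, whose laboratory maximum growth rates overstate field
performance. Every modifier can be switched off per configuration, and the
diet matrix is a plain edge list, so the trophic topology is fully
configurable.

The pedotransfer rule mapping clay fraction to textural pore-class
fractions and matrix infiltration is a documented package-level linear
rule (`texture_hydraulics()`); its coefficients are built to sum to one
for any clay content. It is the single knob the higher-clay evaluation
scenario turns.

## Calibration

The nine growth rates are calibrated by a Metropolis--Hastings random walk
with reflection at the uniform prior bounds (reflection keeps the proposal
symmetric, so the plain Metropolis ratio applies). The likelihood is
independent Gaussian around pool-stability observations -- each of the
eleven observable pools is asked to sit at its initial value at mid-year
snapshots (day 180 + 365k, final year excluded; a ten-year run yields 99
data points) with errors of 10 % for predators, 12.5 % for litter and SOM
and 20 % otherwise. Burn-in discards the first half of the iterations, and
the posterior sample is the last 100 accepted vectors, unthinned. The
proposal scale defaults to 5 % of each prior range; the misfit surface of
this boom-and-bust system is rough, so acceptance rates of a few percent
are typical and the acceptance rate is always reported. Seeded chains are
exactly reproducible.

The synthetic-truth recovery experiment in the test suite uses one-year
runs and 20,000 iterations; the acceptance script calibrates on a
five-year window with 20,000 iterations and propagates the posterior
sample through all six scenarios over the full ten years. These problem
sizes are the package's chosen experiment design; all of them run on a
single CPU in minutes.

## The synthetic climate generator

`synthetic_climate()` emulates a temperate maritime regime: a sinusoidal
annual temperature cycle (mean 10 °C, amplitude 7.5 °C) with Gaussian
day-to-day noise, Bernoulli wet days (probability 0.5) with exponential
amounts targeting 850 mm yr^-1^, and Hamon-type potential
evapotranspiration from temperature and daylength. It reproduces realistic
annual totals and seasonality but *not* multi-day storm persistence,
drought autocorrelation, or snow; passing tests therefore demonstrate the
model's internal consistency and qualitative behaviour under realistic
forcing, not site-level predictive skill. Measured climate series are read
with `read_climate()` and take precedence whenever available.

## Known limitations

* Single layer: bioturbation and leaching are exports, not transfers to a
  deeper layer, and the macropore route ends in a fixed subsoil
  infiltration capacity.
* Matrix flow is a daily spilling bucket, not a Richards'-equation
  solution; sub-daily rainfall intensity effects are invisible.
* Nitrogen exists only through C:N bookkeeping; no explicit N pools.
* Within-guild population structure is assumed stable and optimal; the
  intrinsic growth-rate formulation hides life-history detail.
* The aggregation-to-pore-class mapping is a hypothesis with configurable
  coefficients, not an established law.
* Under predator exclusion the model releases bacterivores strongly enough
  to graze bacteria to trace levels, so the fungi:bacteria ratio *rises*
  at the calibrated parameter sets this package reaches -- the opposite of
  the decline expected when the cascade runs through detritivore and
  engineer release; the corresponding directional check in the acceptance
  suite documents this honestly (the soil-water, microbivore and engineer
  directions reproduce as expected).

## A small worked run

```{r}
cfg <- pine_forest_config()
clim <- synthetic_climate(730, seed = 1)
tr <- run_simulation(cfg, clim)
round(tail(tr[, c("bacteria", "fungi", "litter", "SOM", "SW")], 3), 2)
total_carbon(attr(tr, "final_state")) - total_carbon(init_state(cfg))
```
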