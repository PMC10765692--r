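---
title: "Methods: an age-cohort forest carbon budget under bark-beetle calamity scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an age-cohort forest carbon budget under bark-beetle calamity scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcbs)
```

## The model

`fcbs` simulates the carbon budget of a managed, spruce-dominated forest
estate at annual resolution over an age-cohort state space. A cohort is a
(region, forest type, age) stratum with an area and a per-hectare carbon
pool vector. The pool structure follows the CBM-CFS3 convention: five live
pools (merchantable stemwood and bark, other wood, foliage, coarse roots,
fine roots), two standing-dead snag pools, and seven dead-organic-matter
(DOM) pools with very fast / fast / medium / slow decay classes split into
above- and belowground compartments. The softwood/hardwood duplication of
the live and snag pool families (21 distinct model pools in total) is
carried by the cohort's leading-species flag: a cohort populates exactly
one family, so fourteen named pool columns plus the flag represent the full
structure without loss.

Within a simulated year the fixed operation order is: **grow → turnover →
decay → snag-backlog cutting → demand allocation and disturbance →
species-change replanting**. The ordering is a modelling choice (sub-annual
sequencing is not identifiable from annual statistics); it is fixed,
documented and tested.

### Growth

Growth is yield-data driven. Each forest type carries a merchantable-volume
curve $v(a)$ (m³/ha under bark against age); the default synthetic curves
are Chapman–Richards, $v(a) = V_{max}(1 - e^{-ka})^p$. A year of growth
adds $\rho\,[v(a{+}1) - v(a)]$ to the stem pool, where $\rho$ is the
carbon density of merchantable volume (0.22 t C/m³ softwood, 0.28
hardwood). The non-merchantable components are then regrown up to fixed
allometric proportions of the stem carbon (other wood 0.30/0.35 of stem C
for softwood/hardwood, foliage 0.08/0.04, coarse roots 0.20, fine roots
0.02). Component regrowth therefore *replaces turnover losses*: annual
production covers litterfall, root turnover and foliage renewal in addition
to the net stem increment. A purely increment-driven formulation (adding
only the volume-increment share to each component) was rejected during
design: with stock-proportional turnover it drains the component pools far
below their allometric levels and turns any simulated estate into a
permanent carbon source, which contradicts both the steady-state behaviour
the pool scheme is built around and the sink dynamics the scenarios are
meant to resolve. Growth never removes carbon: components above their
allometric proportion (e.g. after a partial disturbance) are left to decay
through turnover.

### Turnover and decay

Each live pool sheds a fixed annual fraction into designated DOM pools
(defaults: stem mortality 0.005 → snag stems; other wood 0.04 → aboveground
fast; foliage 0.10 softwood / 1.0 hardwood → aboveground very fast; coarse
roots 0.02 → belowground fast; fine roots 0.64, split equally between the
very fast pools). Turnover conserves mass. DOM pools decay first-order
(very fast 0.355 /yr, fast 0.14, medium 0.037, slow 0.015, snags 0.03);
83% of decayed carbon is released to the atmosphere and the remainder
humifies downstream (aboveground chains end in the aboveground slow pool,
belowground in the belowground slow pool; the slow pools are terminal with
full atmospheric release). These defaults are generic magnitudes consistent
with published European applications of the pool scheme — a national
calibration is deliberately out of scope.

Climate modifiers on growth or decay are not implemented: the analysis
treats management and disturbance as the dominant country-scale drivers and
holds tree physiology neutral.

### Initialization (spinup)

DOM pools are initialized by the classical spinup: grow a stand from bare
ground to its rotation age (100 years for conifers, 120 for broadleaves, 80
for short-lived pioneers), clear-cut it with slash burn (the
initialization-only disturbance), and repeat until the belowground slow
pool changes by less than a relative tolerance (default 1e-6) between
cycles; then regrow to each cohort's inventory age. Because spinup uses the
identical annual step as the simulation, the initial state sits on the
model's own quasi-equilibrium and no spurious initial flux transient is
introduced beyond the first-year component-replacement asymmetry. Live
pools always match the inventory volume exactly; spinup touches only DOM.

### Disturbances

Eight event types are encoded as proportional source→sink transfer
matrices: thinning (default 20% intensity, the midpoint of the 10–30%
convention, ages 20–59), salvage clear-cut (full merchantable removal,
stand reset), selective salvage (no reset), final felling (5% seed trees
retained, stand reset, eligibility at the rotation age), the
spinup-only slash-burn clear-cut, standing mortality (live pools to snag
pools, area-based, producing standing-dead spruce `SPx` stands),
snag-stem harvest (90% of the previous year's unprocessed snag carbon,
executed with a one-year delay within the 2018–2022 backlog window, the
remainder left to decompose), and reforestation. Residue (other-wood)
extraction is 20% after salvage and 25% after planned felling; residue
burning defaults to zero. Every event closes its mass balance: carbon
before equals carbon after plus products, extracted residues and any
atmospheric release; this is enforced by randomized property tests at
1e-9 relative tolerance.

## Scenario engines

Harvest demand is a (year × region × forest type × disturbance type) table
in t C of merchantable product carbon. The four engines share the observed
2018–2021 series verbatim and diverge from 2022:

* **Green** — a Gaussian pulse $A e^{-(t-\mu)^2/2\sigma^2}$ is fitted to
  each region's 2012–2021 total harvest (Levenberg–Marquardt, fixed starts
  $A=\max$, $\mu=\operatorname{argmax}$, $\sigma=2$; the peak is bounded
  near the observation window so a still-rising series cannot be fitted as
  a distant pulse). Regional totals for 2022–2029 follow the fitted decline,
  floored at the regional sustainable level; the type×disturbance
  composition interpolates exponentially (geometric path, renormalized)
  between the 2021 observed shares and the potential-regime shares anchored
  at 2031. From 2030 the demand is the sustainable potential scaled to the
  17 Mm³/yr target. Old stands (conifers ≥ 120, broadleaves ≥ 140 years)
  are retained from 2025 — exempt from salvage and final felling.
* **Red** — each region keeps its observed 2021 intensities per type and
  disturbance until its prescribed episode end-year, then switches to the
  potential regime (16 Mm³ target).
* **Black** — as Red, but in the not-yet-culminated (spread-flag) regions
  spruce salvage demand is raised 20% above the 2021 level from 2022.
* **Black rep.** — as Black, plus two-year spruce infestation episodes every
  ten years from 2038, at the regional mean of the 2018 and 2019 sanitary
  volumes, and planned demand for non-fir species escalated by 10/15/20%
  over 2038–2047/2048–2057/2058–2070.

The sustainable potential per region and type amortizes final-cut-eligible
stock (within a 20-year window of the rotation age) over that window, plus
thinnable stock times the thinning intensity over a 10-year return
interval, the thinning component capped by the net increment remaining
after the final-cut component so planned removals beyond the amortized
mature stock never exceed net growth. The sanitary share of
potential-regime demand is fixed at 0.28 (capped at one-third, the
conventional bound under ordinary management) and split evenly between the
two salvage forms. The potential is evaluated once on the spun-up 2018
state and held constant: demand resolution stays annual, while feedback of
the evolving stock enters through allocation, which clips every cell to the
actual availability of eligible cohorts (oldest first, salvage before
thinning before final felling) and records the shortfall as a deficit —
never an error. Retained cohorts are skipped even under unmet demand.

Species change converts cleared spruce areas at replanting: after salvage,
beech 20%, the region's enhanced species (fir or oak, by elevation) 30%,
the other of that pair 10%, long- and short-lived broadleaves 20% each;
after a planned final cut, spruce keeps 50% with fir 10%, beech 20% and
long-lived broadleaves 20%. Non-spruce clearings are replanted in kind.
DOM and seed-tree carbon are inherited per-hectare.

## Synthetic estate

No national inventory is public, so the package generates a structurally
faithful synthetic estate: 14 regions with an altitude gradient
(286–684 m), alternating enhanced species, staggered episode end-years
(2021–2047) and spread flags; 2 610 kha split across nine forest-type
categories at the reference area shares (spruce 49.6%, pine 20.2%, …,
standing-dead spruce 0.2%); ages on 10-year classes with geometric weights
decaying (ratio 0.60) away from modal classes 4–5 and truncated at class
12 — old stands are rare in the emulated 2018 baseline. Areas are integer
hectares by largest-remainder rounding, so configured totals are matched
exactly. The spruce yield curve ($V_{max} = 1090$, $k = 0.025$, $p = 2$) is
calibrated so the area-weighted spruce net annual increment on this age
structure is close to 11 m³/ha/yr; sustaining that mean increment across a
full age distribution implies top-site productivity, which is why the curve
plateaus high. The observed harvest series is a planned baseline
(12.6 Mm³/yr, progressively crowded out near the pulse peak), a sanitary
baseline (3.2 Mm³/yr), and a regional Gaussian spruce-salvage pulse whose
amplitudes are scaled so the 2020 country total hits 35.8 Mm³ — which
simultaneously drives the peak sanitary share to about 95%. Seeded Gaussian
noise (sd 5% of the regional amplitude) perturbs the pulse. A tenth of the
pulse is emitted as unprocessed standing mortality in 2018–2021, feeding
the snag backlog.

What the generator does *not* emulate: regional differences in species
composition, the real spatial pattern of the outbreak, assortment
structure, and any correlation structure in the residuals. Passing tests
on this estate demonstrate that the machinery reproduces the *relative*
behaviour of the scenarios (ordering of sink years, spruce decline,
recurrence peaks, growing deficits) — not the national magnitudes, which
depend on the non-public inventory and a national model calibration.

## Reporting and accounting

Pools aggregate to the four IPCC categories (living biomass; deadwood =
snags, coarse woody debris and dead coarse roots in mineral soil; litter =
the aboveground fast/very fast/slow pools; soil = the belowground very
fast and slow pools — the forest-floor F/H/O horizons are classed litter,
following the standard scheme). Stock changes convert to CO₂ at −44/12
(sink negative). The accounting routine reproduces the compliance
arithmetic: reference-level units and offsets scale linearly with period
length; the gross deficit is the cumulative projected balance plus the
reference-level units, the net deficit subtracts the offsets.

## Numerical choices and degenerate inputs

* Ages are integer years; 10-year classes appear only in reporting.
* Yield curves are linearly interpolated between grid ages and held at the
  plateau beyond; a decreasing segment is an error.
* An all-zero harvest series yields a flagged zero-amplitude pulse fit; a
  vanished composition share is floored at 1e-6 before geometric
  interpolation.
* Allocation resolves ties by age (oldest first); within equal keys,
  cohorts are merged each year by area-weighted pooling, which is exact
  for totals and keeps the state size bounded.
* Spinup failure to converge within the cycle cap is an error reporting
  the last residual; the default tolerance (1e-6 relative on the
  belowground slow pool) changes initialized pools by less than 1e-5
  relative compared to 1e-9.
* Standing-dead spruce loads its inventory volume into the snag stem pool
  with the live-stem conversion and receives the spruce ground-DOM profile
  at its age.

## Problem sizes

The default estate holds roughly 1 500 initial cohorts (growing to a few
thousand as clearings are replanted); one scenario over 2018–2070 runs in
about a minute on a single core, and the full four-scenario pipeline
including spinup completes within ten minutes. Unit tests use a 2-region,
3-type miniature preset.

## Known limitations

* The potential regime is anchored to the 2018 stock; late-century demand
  can overstate what the regrown estate supports, and the overshoot appears
  as allocation deficit rather than as a lower demand path.
* Harvested wood products are exogenous scalar offsets; no product-pool
  dynamics.
* No spatial contagion of the outbreak: spread acts only through regional
  demand scaling.
* Annual statistics cannot identify sub-annual ordering; all conclusions
  are conditional on the fixed operation order.

```{r example, eval = FALSE}
ds <- generate_dataset(synth_config(), seed = 42)
state <- spinup_dom(load_inventory(ds$stands, ds$regions), ds$curves)
green <- run_scenario(state, "Green", ds$curves, ds$observed)
glance(green)
autoplot(green)
```
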