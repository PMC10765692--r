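# fcbs — forest carbon budget scenarios under bark-beetle calamity

`fcbs` is an age-cohort, yield-curve-driven carbon budget simulator for a
managed, spruce-dominated forest estate hit by a drought-induced
bark-beetle outbreak. It is aimed at forest carbon analysts who need to
project ecosystem carbon stock changes, CO₂ emissions, harvest structure
and species composition under contrasting calamity and adaptive-management
narratives, and to translate the projections into LULUCF compliance
arithmetic.

The model tracks each (region × forest type × age) cohort through the
21-pool CBM-CFS3 pool structure: five live pools, two snag pools and seven
dead-organic-matter pools in very fast / fast / medium / slow decay
classes. Growth follows merchantable yield curves $v(a)$ with carbon
density $\rho$ (stem increment $\rho\,[v(a{+}1)-v(a)]$, components held at
allometric proportions); live pools shed fixed annual turnover fractions
into DOM; DOM decays first-order with 83% atmospheric release and
humification of the rest; disturbances are proportional source→sink
transfer matrices (thinning, salvage with/without clear-cut, final felling
with 5% seed trees, standing mortality into snags, delayed 90% snag
harvest, reforestation). Four scenario engines — Green, Red, Black and
Black rep. — build harvest demand from a fitted Gaussian calamity pulse,
frozen 2021 intensities with regional end-years, a 20% sanitary spread
factor, and decadal recurrence episodes, then allocate it with sanitary
priority and explicit deficit tracking. Emissions are $-\Delta C \times
44/12$ (negative = net sink).

Because the national forest-management-plan inventory is not public, the
package ships a seeded synthetic estate generator that reproduces the
*structure* of the study system: 14 regions, 2 610 kha, reference
forest-type shares (spruce 49.6%), a mid-age-heavy age distribution, a
spruce yield curve calibrated to a net annual increment near 11 m³/ha/yr,
and a 2012–2021 harvest series peaking at 35.8 Mm³ in 2020 with a ~95%
sanitary share.

## Worked example

```r
library(fcbs)

ds <- generate_dataset(synth_config(), seed = 42)
state <- load_inventory(ds$stands, ds$regions)
state
#> <fcbs_state> 1203 cohorts, 2610 kha, 14 regions

state <- spinup_dom(state, ds$curves)
green <- run_scenario(state, "Green", ds$curves, ds$observed)
glance(green)
#> # A tibble: 1 × 5
#>   scenario first_sink_year cumulative_emissions_mtco2 spruce_area_share_end deficit_share
#>   <chr>              <int>                      <dbl>                 <dbl>         <dbl>
#> 1 Green               2030                       150.                 0.298         0.177
```

Reading: under the optimistic scenario the sector turns from the
calamity-era emission source into a net CO₂ sink in 2030, and the spruce
area share declines from roughly half of the estate to about 30% by 2070
as salvage-cleared areas are replanted with beech, fir/oak and other
broadleaves. `tidy(green)` returns the per-year, per-IPCC-pool stock
changes, `autoplot(green)` draws the emission trajectory, and
`plot_pool_changes()` / `plot_species_shares()` show the carbon-balance
decomposition and the species transition. The compliance arithmetic is a
plain function call:

```r
acc <- accounting_arithmetic(setNames(green$emissions_mtco2, green$year),
                             frl_annual = -4.739, offsets_annual = -1.75,
                             period = 2021:2025)
acc$frl_units      # 23.695 — reference-level units over the pentad
acc$offset_units   # 8.75   — wood-product and afforestation offsets
```

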