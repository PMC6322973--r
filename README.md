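# evcog

Decision support for scalable manufacture of extracellular vesicles (EVs).

Therapeutic EVs (exosomes and microvesicles) are made in two stages: cells
are expanded in culture while releasing EVs into the media, and the
conditioned media is then processed by a harvest technology
(ultracentrifugation, precipitation, size-exclusion chromatography,
ultrafiltration) that recovers only a fraction of the EVs. Which
combination of expansion vessel and harvest method is cheapest depends
strongly on the lot size (EVs per manufacturing lot) and the annual demand.
`evcog` computes the annual cost of goods (COG) of every technology pair,
applies operational feasibility constraints, and identifies the cheapest
feasible bioprocess — for a single demand point or across a whole
lot-size × demand grid. It is aimed at process developers and
manufacturing strategists choosing technologies early, before committing to
empirical scale-up iterations.

## The model

Cell growth and EV accumulation follow exponential kinetics: a vessel with
growth area *A* (planar area, or microcarrier area × density × volume for a
single-use bioreactor) seeded at density *d*min holds *N*c = *d*·*A* cells,
and accumulates

&nbsp;&nbsp;&nbsp;&nbsp;*N*v^max^ = α (*d*max − *d*min) *A*

EVs by the time it reaches the maximum density *d*max, where α is the EV
output per cell per population doubling (default 11,500, with a 22 h
doubling time). For a lot of *N*v^lot^ EVs harvested with recovery *y*, the
culture must over-produce *N*v^lot^/*y* EVs, which fixes the number of
expansion units *u*E = ⌈*N*v^lot^/(*y·N*v^max^)⌉, the conditioned-media
volume, and hence the number of harvest runs *u*H = ⌈volume/*V*max⌉.
Per-lot costs are consumables (vessels, media, microcarriers; per-run
harvest kits), labor (operators at an hourly rate with an overhead
multiplier, where one operator manages a bounded number of units) and
capital equipment (incubators, biosafety cabinets shared between stages,
ancillary items). Annual COG is affine in the lot rate:

&nbsp;&nbsp;&nbsp;&nbsp;*z* = *N*lot^yr^ (C^cons^ + C^lab^) + C^eq^/*t*dep

Feasibility excludes pairs that violate facility space limits
(*u* ≤ *U*max per technology), cultures that would meet their lot in under
24 h, and lot rates outside a 10–200 lots/year window. The optimizer
enumerates all pairs (both loops are exhaustive, so the returned optimum is
the global one) and reports cost breakdowns, solution grids with
technology-switch annotations, one-at-a-time sensitivity sweeps (media
price, labor rate, harvest consumables), biological-scenario comparisons,
and clinical dose capacity by protein mass.

## Worked example

```r
library(evcog)

cat <- read_catalog(default_catalog_path())
bio <- biology_params()        # t_d = 22 h, alpha = 11,500 EVs/cell/doubling
optimize_cog(demand(n_v_lot = 1e12, n_lot_yr = 100), bio, cat)
```

```
Lot solution: T-175 + SEC2
  demand: 1e+12 EVs/lot x 100 lots/year
  units: 16 expansion (1 operators), 3 harvest (1 operators)
  culture duration: 72.7 h
  per-lot costs (USD):
    expansion: consumables 244.00, labor 120.00, equipment (capital) 22000.00
    harvest:   consumables 360.00, labor 480.00, equipment (capital) 15000.00
  annual COG (USD/yr): expansion 40800.00 + harvest 87000.00 = 127800.00
```

Reading: a 10¹² EVs/lot demand at 100 lots/year is met most cheaply by 16
T-175 flasks feeding 3 size-exclusion (SEC2) runs per lot. Each lot's
culture runs 72.7 h (comfortably above the 24 h minimum lag); consumables
and labor recur per lot while the $37,000 of capital equipment is amortized
over the 5-year depreciation horizon, giving an annual COG of $127,800 —
with harvest, not cell expansion, dominating the total. The shipped catalog
marks its prices and capacities as `placeholder` values; substitute your
own vendor quotes (`read_catalog()` on your file, or `catalog_from_csv()`)
before relying on absolute dollar figures.

A grid over lot sizes and annual demands, with switch annotations:

```r
grid <- solution_grid(c(1e11, 1e12, 1e13), c(1e13, 1e14), bio, cat)
grid
#>    lot\demand      1e+13      1e+14
#>          1e+11 T-175/SEC2          .
#>          1e+12 T-175/SEC2 T-175/SEC2
#>          1e+13          .   L-10/UF2
#> (. = outside lots/year window, x = no feasible pair)
switch_map(grid)
```

The same operations are scriptable from a shell via `inst/cli/evcog`
(`optimize`, `grid`, `sensitivity`, `fit`, `dose`, `validate-catalog`
subcommands driven by one YAML config; see `?read_run_config`).

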