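---
title: "Cost-of-goods modelling for EV manufacturing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-of-goods modelling for EV manufacturing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcog)
```

## The manufacturing model

One *lot* is one cycle of cell expansion followed by a single EV harvest
from the pooled conditioned media. The model deliberately keeps the lot
simple: media is introduced at seeding and removed only at harvest (no
feeding), fresh media contains no EVs, cells are not themselves harvested,
and every technology obeys the same growth and accumulation kinetics.
Demand is specified as a lot size (EVs delivered per lot, after harvest
losses) and a lot rate (lots per year); their product is the annual EV
output.

### Growth and EV accumulation

Cells grow exponentially with doubling time $t_d$ from the seeding density
$d_c^{min}$ to at most the maximum allowable density $d_c^{max}$
(densities per cm^2 of growth surface). The growth surface of one unit is
$A = a^{pln} + a^{mc} d^{mc} V^{sub}$: planar vessels and hollow-fiber
devices contribute a fixed area, microcarrier single-use bioreactors an
area proportional to microcarrier loading and working volume; the two
terms are structurally exclusive, so one expression covers all kinds.
EV accumulation is indexed to cumulative new cells: growing from
$N^{seed}$ to $N$ cells leaves $\alpha\,(N - N^{seed})$ EVs in the media,
with $\alpha$ the EV output per cell per population doubling. Only this
ratio is biologically identifiable from cell-count and particle-count time
courses, which is why the package parameterizes it directly rather than
separate release and growth rate constants. The per-unit maximum is
therefore $\alpha\,(d_c^{max} - d_c^{min})\,A$, attained at full density.
(The accumulation span is written max-minus-min throughout; a
sign-reversed form that sometimes appears in print would give negative EV
counts.)

Inverting the model gives the culture duration needed for an EV load $v$
per unit: $t_d \log_2\!\big(1 + v / (\alpha N^{seed})\big)$. Cultures are
terminated the moment the lot's requirement is met (equivalently: run to
full density and discard the excess — the cost is identical because media
is priced per lot, not per hour), so the duration is evaluated at the
per-unit load actually assigned, `n_v_pre / u_e`.

### From demand to units and costs

For a harvest technology with recovery $y \in (0, 1]$, the culture must
over-produce: $N_v^E = N_v^{lot}/y$. Unit counts are ceilings:
$u_E = \lceil N_v^E / N_v^{max} \rceil$ expansion units, and
$u_H = \lceil u_E\,(v^{pln} a^{pln} + V^{sub}) / V^{max}\rceil$ harvest
runs, because the entire conditioned-media volume must be processed.
Fractional harvest units are topped up with EV-free buffer at negligible
cost, so the ceiling never rounds down. Note the interaction this
creates: a low-recovery technology does not necessarily need more
*vessels* — EVs accumulate exponentially, so the same vessels cultured
longer can cover the over-production — but every extra liter of media does
translate into harvest runs.

Per-lot costs per stage are:

* consumables — vessels, media (priced per liter of conditioned media),
  microcarriers; for harvest, one consumables price per run;
* labor — operators at $p^{lab}$ per hour for the stage's hands-on time
  (seeding + collection for expansion, the protocol's total hands-on time
  for harvest; waiting between steps is free), with one operator managing
  at most $U^m$ units and all wages scaled by $1 + \beta$ for supervision
  and management overhead;
* equipment (capital) — incubators ($\lceil u_E/U^{inc}\rceil$), ancillary
  items ($\lceil u/U^{anc}\rceil$), and biosafety cabinets at one per
  $U^{bsc}$ operators. Cabinets are charged to expansion only for
  technologies that need open handling (`needs_bsc`); harvest operators
  always work in cabinets, but only cabinets *beyond* those the expansion
  stage already bought are charged to harvest.

Annual COG per stage is affine in the lot rate,
$z = N^{yr}_{lot}(C^{cons} + C^{lab}) + C^{eq}/t^{dep}$: equipment is
shared between lots and only depreciates (horizon $t^{dep}$ years, default
5). The pair's total is the sum of the two stages. (The harvest
annualization uses the same additive form as expansion; a product form
would be dimensionally meaningless.)

## Feasibility and optimization

A pair is excluded when

* the lot rate falls outside the lots-per-year window, default
  $[10, 200]$: above the cap consecutive lots would overlap in daily
  operations; below the floor the lot size is needlessly large for the
  demand. Both bounds are configuration (`cog_options()`), since the floor
  in particular is a reporting convention more than a physical limit;
* a stage exceeds its facility space limit, $u > U^{max}$ (inclusive at
  the boundary);
* the culture would meet its lot in under 24 h (`min_culture_h`),
  which would make daily operations impractical for a large-scale device
  serving a small lot.

`optimize_cog()` enumerates every (expansion, harvest) pair — outer loop
over harvest technologies, inner over expansion — and returns the
feasible cost minimizer. Enumeration is exhaustive, so the result is
order-independent; exact cost ties (measure-zero for realistic catalogs,
common in toy ones) are broken deterministically by fewer total units,
then lexicographic id pair. When nothing is feasible the full per-pair
reason table is returned rather than an error, because *why* the space is
empty (space limits vs. the 24 h rule vs. the rate window) is exactly what
a process developer needs next.

Two analysis modes alter the loop. `fixed_recovery` forces $y = 1$ for
all harvest technologies, so every candidate needs the same expansion
train and the comparison isolates the harvest stage. `expansion_only`
treats the lot size as cells per lot and skips the harvest loop entirely
(for benchmarking the expansion module against cell-manufacturing cost
models); its extra infeasibility reason, `seed_exceeds_lot`, flags
technologies whose seeding cell number already reaches the lot size.

`solution_grid()` evaluates the optimizer over a lot-size × annual-demand
grid (the cell's lot rate is demand/lot-size), flags out-of-window and
infeasible cells, and `switch_map()` labels each adjacent cell pair with
whether the optimal expansion technology, harvest technology, or both
switch — the boundaries where a manufacturer's choice flips.

## Sensitivity and scenarios

`sensitivity_sweep()` varies one cost parameter at a time — media price,
labor rate, or all harvest consumables prices — by a signed fraction
(default ±30%) and reports percent change in annual COG for fixed
technology combinations. Unit counts never depend on prices, so each
response is exactly linear in the perturbation with slope equal to that
component's share of annual COG; the sweep is how those shares are made
visible. Re-optimization per perturbation is available behind a flag but
off by default, matching how such tornado-style analyses are usually read.

`compare_scenarios()` contrasts biological parameter sets (donor
variation, starvation-type media conditions) at per-scenario optima,
reporting COG ratios against the first scenario. Convenience multipliers
(`scale_alpha()`) encode the typical effect sizes: a high-producing donor
at about 3× baseline output, starvation culture at about 10×. Note an
asymmetry the tests pin down: comparing two conditions *at one fixed
combination* shows a larger saving than comparing their respective optima,
because the baseline pays more at the boosted scenario's combo than at its
own optimum.

## Dose capacity

`annual_capacity()` converts EV supply to clinical doses by protein mass:
EVs per dose = protein per dose / protein per EV (defaults 247 µg and
0.1 fg). Raw values are always reported; the *rounded* figures propagate
planning precision through the chain — EVs/dose to 2 significant figures,
doses/year to the nearest thousand, and patients/year computed from the
rounded dose figure to the nearest ten — because that is how such
capacity estimates are quoted and combined in practice.

## Catalogs, defaults, and the synthetic generator

Catalogs are plain YAML/JSON documents (or CSV tables) validated on load;
errors name the technology and field. The shipped default catalog lists
the technologies discussed throughout the package (T-175 to 120-layer
planar vessels, a hollow-fiber device, 20/50 L microcarrier bioreactors;
UC, PPT, SEC1, SEC2, UF1, UF2 harvest), but its prices and capacities are
explicitly marked `provenance: placeholder`: they are plausible
order-of-magnitude values for demonstration, to be replaced by vendor
quotes. No test depends on them — the suite pins model *behavior*
(ceilings, affine structure, monotonicities, constraint logic), which is
what survives a catalog swap.

Design choices worth recording:

* Hollow-fiber devices are parameterized planar-style (membrane area +
  media per area); no separate flow model is attempted.
* Seeding and maximum densities are per-technology fields, since
  achievable densities genuinely differ between formats.
* Planar-type technologies must declare `v_pln > 0`: a zero media volume
  would make harvest unit counts degenerate.
* Non-integer lot rates are allowed and read as average rates; the annual
  COG formula is well defined for them.
* Units are fixed: USD, liters, cm², hours (years only for depreciation).

`synthetic_catalog(n_expansion, n_harvest, seed)` generates random valid
catalogs whose technology scales span ≥2 orders of magnitude, so optimizer
tests must exercise scale switching; it is a pure function of its seed.
`synthetic_time_course()` simulates the sampling experiment behind the
biology fit: exponential growth plus cumulative EVs, with optional
multiplicative lognormal noise (unit mean, given CV) on the EV counts at
positive times — the seeding row always records zero EVs because fresh
media is particle-free. Cell counts are left noise-free; the fitter's
growth regression is standard log-linear least squares and its EV
regression a through-origin slope, so EV-side noise is the informative
axis for exercising the fit diagnostics. What passing tests on these
simulations do **not** show: real NTA particle counts include platform
biases, EV uptake/degradation during culture, and donor-level deviations
from clean exponential growth; the generator emulates none of these.

## Numerical choices

* **Ceiling guard.** Unit counts come from chained divisions; values
  within a relative $10^{-9}$ of an integer are snapped before the ceiling
  (`ceil_guard()`), so float residue can never charge a whole extra
  incubator. A genuine overshoot of more than that still rounds up.
* **Tolerance on the culture-time inversion.** The per-unit load
  `n_v_pre/u_e` may exceed the per-unit maximum by the same $10^{-9}$
  after snapping; `culture_duration()` absorbs exactly that and errors on
  anything larger.
* **Tie-breaking** is exact-equality based (fewer units, then id order);
  no epsilon comparison is used for optimality, keeping the optimizer's
  result bit-reproducible.
* **Degenerate inputs** fail loudly at validation (empty catalogs,
  non-positive densities, zero recovery) or in preconditions
  (non-increasing cell counts, <3 time points in the fitter).

## Problem sizes

The test suite and the reference script are sized to run comfortably on a
single CPU: property suites use random catalogs of 2–5 expansion × 2–4
harvest technologies, the optimizer-vs-enumeration cross-check runs 100
random problems, and grids in examples are ≤ 4 × 4 cells. The model is
closed-form throughout (no iterative numerics), so runtime scales linearly
in pairs × grid cells; realistic catalogs of tens of technologies over
dense grids remain sub-second.

## Known limitations

Costs of quality control, fill-finish, storage and shipping are out of
scope, as are cell-harvest technologies, media feeding regimens,
multi-stage seed trains, inter-lot equipment contention, and
continuous-flow industrial equipment. The biology module assumes EVs are
neither degraded nor re-taken up during culture. Absolute COG figures are
only as good as the user's catalog; the package's value is in relative
comparisons and in the structure of the solution space.
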