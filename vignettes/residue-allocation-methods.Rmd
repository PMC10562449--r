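---
title: "Methods: gridded cereal-residue production and usage accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded cereal-residue production and usage accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resalloc)
```

## The accounting scheme

`resalloc` closes a per-cell, per-year mass balance for cereal crop
residues on a regular latitude/longitude grid:

```
residue production = burnt on field + animal usage + other off-field uses
                     + left on field
```

The five layers are computed in a fixed order of claims on production —
burning first, then livestock feed and bedding (with trade between
cells), then other off-field uses, with the remainder left on the field.
That order is forced by the deficit rule the scheme uses: a cell is in
deficit when burning plus animal demand already exceeds the removal cap,
so burning must be settled before animal usage, and other uses can only
take what those two leave behind.

Two global constraints shape every cell's ledger:

* at most 90 % of production may be removed from the field by all uses
  combined (`removal_cap = 0.90`), because complete residue removal is
  impractical; equivalently at least 10 % is always left
  (`min_left_fraction = 1 - removal_cap`);
* in a few regions a *maximum* is also imposed on the fraction left on
  field (China 60 %, Europe 70 %, North America and Oceania 80 %), with
  any excess shifted to other off-field uses. This compensates for the
  lack of global data on domestic fuel, construction and industrial
  usage in regions where those uses are known to be substantial.

### Residue production

Grain production is the primary input. A single gridded base-year
snapshot of per-crop production and harvested area is rescaled, per
country and year, to country annual totals (each cell keeps its
base-year share of the country total). Grain is then converted to
residue by three alternative methods, tracked separately through the
whole pipeline:

1. **constant** — fixed region- and crop-specific residue-to-grain
   ratios applied to production;
2. **exponential** — residue yield `R = a Y exp(-b Y)` for grain yield
   `Y <= 1/b`, with the plateau `a/(b e)` above, applied per cell with
   `Y = production / area`, then multiplied by area;
3. **linear** — `R = Y (c - d Y)`, likewise per cell.

The `a, b, c, d` coefficients are fitted literature values per crop
class, stored in `harvest_index_params()` for the seven classes (barley,
maize, rice, wheat, millet, sorghum, other cereals); `other_cereals`
covers any cereal outside the six named ones. Two numerical choices are
ours: the linear form is clamped at zero for yields beyond `c/d`, where
the fitted parabola would go negative, and cells with harvested area
below 1e-6 ha are treated as zero-yield so division noise cannot
produce absurd yields. We apply the yield formulas at cell level (the
cell is the unit the whole scheme accounts in). The constant-ratio
tables are regional literature compilations that are not part of this
package's sources; we ship a documented single-region default
(`constant_residue_ratios()`, straw:grain between 1.0 and 1.7) and the
correctness tests use synthetic ratio tables, so nothing downstream
depends on the default magnitudes.

### On-field burning

Two fire inputs are supported: a monthly gridded agricultural-burning
field at twice the pipeline resolution (summed over months, then
sum-aggregated to 0.5°) and a point fire inventory (records filtered to
the agricultural vegetation class and the target year, binned to
cells). Burning in each cell is capped at 90 % of cereal residue
production; this cap is also the only correction for non-cereal
residues (e.g. sugar cane) present in agricultural fire data. The point
inventory starts later than the gridded record; for uncovered years the
mean scheme falls back to the gridded dataset alone and
inventory-branch runs simply omit those years — burning is never
fabricated.

### Livestock usage

Country meat and milk production for cattle and small ruminants is
apportioned to cells by each cell's share of the country's animal head
count, then converted to residue feed demand through herd-level feed
conversion ratios (FCR, kg dry-matter feed per kg protein) and crop
residue feed fractions (CRFF), keyed by (region, animal type,
production system, climate, product). Protein contents are 138 g/kg for
bovine meat, 137 g/kg for sheep and goat meat and 33 g/kg for milk. The
dominant production system per 0.5° cell is the modal class of a
fine-resolution system map; ties break by the fixed order grazing <
mixed < intensive < other. The three FCR/CRFF sources use different
system taxonomies (urban/other, feedlot, industrial); we map all of
them onto the canonical set {grazing, mixed, intensive, other} so every
lookup is total, and our shipped tables accept `"any"` wildcards with
most-specific-row matching as the documented fallback. The `mekonnen`
source publishes no CRFFs, so its FCRs are combined with the `herrero`
CRFF table; the loader records this provenance and the tests assert it.
As with the constant ratios, the shipped FCR/CRFF values are plausible
defaults, not the published regional tables, and are meant to be
replaced via YAML for real-world use.

Bedding uses fixed per-head daily straw rates (cattle 0.375, sheep and
goats 0.1, horses 1.5, pigs 0.0625 kg/day) times 365, plus 420 kg/yr
per horse for chewing; poultry bedding is excluded. All straw masses in
the package are on an as-is straw basis — we do not apply a fresh- to
dry-matter conversion anywhere, so the horse total is
`1.5 × 365 + 420 = 967.5` kg/yr exactly. Animal populations are a
single base-year snapshot held fixed across years; only country
production varies.

### Trade, other uses, left on field

A cell is in deficit when burning plus animal demand exceeds 90 % of
production. Deficit cells import from surplus cells by an expanding
Chebyshev-ring search: radius 1 for every deficit cell first, then
radius 2, up to 20 cells (about 1000 km at the equator). "Favouring
local supply" is not further specified by the underlying scheme, so the
mechanism is our design: rings strictly nearest-first, deficit cells
visited in row-major order, and within a ring supply drawn from
exporters in proportion to remaining export capacity — fully
deterministic, no randomness. Traded residues are booked as animal
usage in the *exporting* cell, where the mass actually leaves the
field; this is what keeps every cell's five-layer sum exact. Demand
still unmet after the search is treated as a local overestimate and set
to zero. On global grids the search wraps in longitude; toy grids do
not wrap.

Other off-field uses (domestic fuel, construction, industry, mushroom
cultivation, biogas, losses) are bounded by a piecewise-linear function
of national GDP per capita: 30 % of production below $1046 (2015
prices), 10 % above $12735, linearly interpolated in GDP level (not log
GDP) between. The 30 % anchor is the domestic-fuel share implied by
mid-1990s China: 4 EJ of residue-derived energy at 18 MJ/kg against
roughly 730 Tg/yr of production (`domestic_fuel_share()` ≈ 30 %). The
bound is evaluated against each year's GDP, so countries move between
bands over time. Actual other usage is the smaller of the bound and
what the removal cap leaves after burning and animal usage.

## The synthetic world generator

`make_world()` builds every input the pipeline needs — per-crop
base-year production and area grids, country tables (grain, meat, milk,
GDP), monthly gridded burning at 0.25°, a point fire inventory with
agricultural and non-agricultural classes, per-species livestock grids,
and a fine production-system map — from one seeded configuration, so
the full scheme is testable without any external downloads.

Choices the generator makes (none of them prescribed by the scheme
itself): per-cell grain production is log-normal
(`meanlog = log(1000)`, `sdlog = 0.8` Mg), yields uniform in 0.5–12
Mg/ha — wide enough that both branches of the exponential formula are
exercised; country annual series are the base-year grid totals times a
1 %/yr trend with 5 % noise; countries are rectangular tiles with ~8 %
of cells ocean; GDP trajectories are assigned so the three income bands
are always represented, and the max-return classes china, europe,
north_america_oceania and other always each have a country. Three
derived fixtures fix the study conditions: `standard_world()` (moderate
demand), `deficit_world()` (livestock densities ×8, pushing most
producing cells past the 90 % threshold so trade and the unmet-demand
rule are exercised hard), and `china_surplus_world()` (burning
intensity 1 %, livestock ×0.1, so China-region cells run into the 60 %
return ceiling).

What the generator does *not* emulate: realistic global geography,
SPAM/GFED magnitudes, spatial autocorrelation of yields, seasonality of
burning beyond random month weights, or herd demography. Passing tests
therefore demonstrate the correctness and invariants of the accounting
scheme — mass balance, caps, trade behaviour, determinism — not the
realism of any particular global number.

## Ensemble

Three production methods × three livestock sources × two fire datasets
give 18 combinations, each run through the identical allocation stages.
The mean scheme averages the *stage inputs* (production, burning,
animal demand) and runs the allocation once on the means; averaging the
18 output ledgers instead is available behind
`run_mean(scheme = "outputs")`, since both readings of "mean" are
defensible — input averaging is the default because the allocation
stages are nonlinear, and a mean input should be allocated by the same
single scheme as any other input. Output files follow the
`crop_residue_usage_{production}_{livestock}_{fire}.nc` naming
convention with five layers in Mg/year; files are validated against the
ledger invariants before writing and after reading.

## Numerical conventions

* Grid registration: cell centers, latitude ascending (global 0.5°
  grids run −89.75…89.75, −179.75…179.75), recorded in the netCDF
  attributes. All operations accept rectangular toy extents.
* Missing data: NA for no-country cells in masks and explicit NA in
  country tables; mass rasters stay finite (zero means no production).
* Tolerances: ledger invariants at 1e-6 relative; aggregation and
  country rescaling conserve totals to better than 1e-9 relative;
  exponential-formula continuity at `Y = 1/b` holds to 1e-12.
* Tie-breaks: modal production-system aggregation prefers the earlier
  class in the fixed order; trade visits deficit cells in row-major
  order.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
20 × 20 grids over 25 years (all 18 combinations plus the mean, about
two minutes on one core) and smaller 6–8 cell grids for hand-checkable
and oracle-based cases. The trade oracle comparison enumerates
Chebyshev distances exhaustively on grids up to 6 × 6.

## Known limitations

* The shipped constant-ratio and FCR/CRFF tables are documented
  plausible defaults, not the published regional compilations; real
  applications must supply their own via YAML.
* Below-ground residues and non-cereal crops are out of scope, as is
  emission chemistry of burning.
* Trade ignores transport cost and prices; the radius is the only
  locality mechanism.
* The generator's statistical realism is deliberately minimal (see
  above); no claim about real-world magnitudes follows from it.
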