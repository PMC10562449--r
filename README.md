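# resalloc

Gridded accounting of cereal crop-residue production and usage.

Cereal residues — straw and stover — are burnt on the field, fed to
livestock, used off-field (domestic fuel, construction, industry,
bedding straw trade), or left on the soil, and which of these happens
where matters for greenhouse-gas inventories, soil-carbon modelling and
bioenergy assessments. `resalloc` implements a complete allocation
scheme that closes, for every grid cell and year, the mass balance

```
residue production = burnt + animal usage + other off-field uses + left on field
```

on a regular latitude/longitude grid (0.5° for global work, arbitrary
rectangular extents for testing). It is aimed at agroecosystem and
carbon-cycle modellers who need a residue-management baseline, and at
anyone who wants to study the allocation scheme itself under controlled
synthetic inputs.

## The scheme

* **Production.** Gridded base-year grain production and harvested area
  are rescaled to country annual totals, then converted to residues by
  three alternative harvest-index methods: fixed region×crop ratios;
  the exponential yield form `R = a·Y·e^(−bY)` (`Y ≤ 1/b`, plateau
  `a/(b·e)` above); and the linear form `R = Y(c − dY)`, clamped at
  zero. Coefficients per crop class live in `harvest_index_params()`.
* **Burning.** Annual agricultural burning per cell from either a
  monthly gridded field (summed and aggregated conservatively) or a
  point fire inventory (agricultural records binned to cells), capped
  at 90 % of residue production.
* **Livestock.** Country meat/milk production apportioned by animal
  head counts, converted to residue demand via feed conversion ratios
  and crop-residue feed fractions from three alternative sources, plus
  per-head bedding straw and horse chewing.
* **Trade.** Cells whose burning + animal demand exceed 90 % of
  production import residues from surplus cells within 20 grid cells
  (~1000 km at the equator), nearest Chebyshev ring first,
  proportionally within a ring; remaining deficits are dropped as local
  overestimates.
* **Other uses and left on field.** Other off-field uses are bounded by
  a piecewise-linear function of GDP per capita (30 % below $1046, 10 %
  above $12735, 2015 prices); the remainder stays on the field, with at
  least 10 % always left and regional ceilings (China 60 %, Europe
  70 %, North America/Oceania 80 %) shifting any excess back to other
  uses.

Three production methods × three livestock sources × two fire datasets
give an 18-member ensemble plus a mean scheme; results are written as
netCDF files (`crop_residue_usage_{production}_{livestock}_{fire}.nc`,
five layers, Mg/year).

A seeded synthetic-world generator (`make_world()`, with fixtures
`standard_world()`, `deficit_world()`, `china_surplus_world()`)
produces every input the pipeline needs, so the whole scheme runs and
is tested without any external data.

## Worked example

```r
library(resalloc)

world  <- standard_world(seed = 1, years = 2009:2011)  # synthetic inputs
params <- load_params()
combo  <- method_combo("exponential", "herrero", "GFED4s")

ledgers <- run_combo(world, combo, params)
ledgers[["2010"]]
#> <usage_ledger year 2010, totals (Mg/yr):>
#> production      burnt     animal      other       left
#>  2558648.2   243221.3   619308.2   523326.6  1172792.0

fr <- fractional_usage(ledgers[["2010"]])
round(100 * sapply(fr, mean, na.rm = TRUE), 1)
#>  burnt animal  other   left
#>   10.2   30.2   19.3   40.4
```

The ledger totals say that of the ~2.56 Mt of residues this synthetic
world produced in 2010, 0.24 Mt were burnt on the field, 0.62 Mt fed or
bedded livestock, 0.52 Mt went to other off-field uses and 1.17 Mt
stayed on the soil; the fractional view averages the per-cell shares
over producing cells (here ~40 % left on field). Per cell the five
layers balance exactly and respect the 90 % removal cap.

The ensemble spread across all 18 method combinations:

```r
stages <- pipeline_stages(world, params)   # shared stage cache
runs   <- run_all_combos(world, params, stages = stages)
ensemble_range(runs, world$mask, "global")
#>        layer     min    mean     max
#> 1 production 7680383 8703879 9887858
#> 2      burnt  343110  536666  726749
#> 3     animal 1847105 1940228 1989678
#> 4      other 1516649 1792446 2090526
#> 5       left 3404283 4434538 5601215
```

(totals in Mg summed over 2009–2011; min/mean/max across the 18 runs).
`run_mean()` runs the allocation once on averaged inputs and
`write_usage_netcdf()` / `read_usage_netcdf()` round-trip the results.
A thin command-line driver over the same functions ships at
`inst/cli/resalloc.R` (verbs `synth`, `run`, `summary`).

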