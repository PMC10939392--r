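---
title: "Methods: a full-scale N2O emission inventory with a process-based natural-soil model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a full-scale N2O emission inventory with a process-based natural-soil model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2obudget)
```

# Scope and model structure

`n2obudget` assembles a *full-scale* nitrous oxide budget: four
anthropogenic sectors (agriculture, energy, industry, waste) computed with
emission-factor (EF) accounting in the style of the IPCC 2019 refinement,
plus natural forest and grassland emissions from a reduced-form annual soil
nitrogen-cycle model. The accounting engine is the bilinear form

$$E(y) = \sum_i \sum_j AD_{i,j}(y) \times EF_i,$$

where $AD_{i,j}(y)$ is the activity datum of source $i$ in province $j$ in
year $y$ and $EF_i$ the source's emission factor. Everything downstream —
aggregation, shares, trends, uncertainty — operates on the long table of
per-source, per-province estimates this produces.

Two unit conventions coexist in this field: soil and manure EFs are quoted
per unit nitrogen on the N2O-N basis, while reported budgets use the full
molecule. The package therefore keeps **all internal masses in Gg N2O-N**
and converts to Gg N2O (factor 44/28) only in reporting
(`aggregate_emissions()`, `export_fan()`). Unit composition is explicit:
an EF unit such as `"kg N2O-N/kg N"` must compose with the activity unit,
and a mismatch is an error naming both units rather than a silent
assumption.

# Sector pathways

**Agriculture** is the most structured sector. Direct soil emissions apply
a climate-region- and land-type-stratified EF1 to each nitrogen input
separately (synthetic fertilizer, applied manure, crop residue,
mineralized soil N, deposited N), so each inventory row remains
recoverable. The default EF1 table reflects the regional pattern reported
for China — upland values high in the East (0.0157 kg N2O-N per kg N) and
Northeast (0.0149) and lower elsewhere (0.0065–0.0093), paddy values
spanning 0.0052–0.0161 — and falls back to the IPCC 2019 land-type
defaults (0.01 upland, 0.004 paddy) for strata without a printed value.
Because the exact province-to-climate-region map lives in supplementary
material not reproduced here, it ships as an editable CSV
(`inst/extdata/region_map.csv`), defaulting to standard administrative
groupings with the South merged into the Central climate zone to form six
strata.

Manure nitrogen follows an explicit mass balance: excretion
`headcount x (mass/1000) x rate x 365` (kg N per 1000 kg animal mass per
day; a 365-day year, since the inventory is annual), routed by fractions
to pasture, soil application, and managed systems. Only the managed-system
share is emitted in `manure_management()`; pasture and applied N are
returned for the downstream pathways so nothing is double counted. The
defaults use the IPCC-2019-style parameters (pasture EF3 0.004 for
cows/swine/poultry and 0.003 for sheep/goat/other; goat and sheep
excretion rates 0.34 and 0.32) whose adoption lowers manure emissions
relative to the older 0.02/0.01 EF3 and 1.37/1.17 rates — a direction the
test suite asserts. Indirect pathways use the leaching/runoff EF5 of
0.0065 kg N2O-N per kg N leached with land-type leached fractions, and a
volatilization–redeposition EF4 pathway. The published inventory's
"Nitrogen deposition" row could be computed either via EF1 on deposited N
or via the EF4 pathway; both are supported, and the default
`run_inventory()` assigns the EF1 term plus the volatilization term to
that category.

**Energy** converts fuel activity to TJ (directly, or as mass x net
calorific value) and applies per-TJ EFs for the eleven closed categories;
fugitive emissions stay in native units. **Industry** covers adipic and
nitric acid with `P x EF x (1 - DF x UF)` plant-level abatement; the
registry lists the two plants that installed abatement under the Clean
Development Mechanism, active 2008–2012, with post-2012 continuation a
scenario switch defaulting to off (the continuation is genuinely unknown).
**Waste** uses the protein-based wastewater nitrogen load
(`population x protein x 0.16 x multipliers - sludge N`, floored at zero)
and per-mass EFs for composting and incineration.

# The natural-soil model

The natural module is a hole-in-the-pipe annual model: nitrogen
transformations are first-order in their substrate, modulated by a Q10
temperature factor and a parabolic water-filled-pore-space factor, and N2O
leaks from each flux with a fixed yield fraction. Four microbial pathways
are represented — autotrophic nitrification and nitrifier denitrification
(both riding on the ammonium-oxidation flux), heterotrophic nitrification
(on organic N), and denitrifier denitrification (on nitrate). A
two-pathway variant (autotrophic nitrification + denitrifier
denitrification only) is the same code with the extra yields forced to
zero, and a test asserts bitwise agreement of that reduction.

Numerical choices worth knowing:

* Each depletion uses the exact annual integral of first-order decay,
  `pool x (1 - exp(-k f_T f_W))`, so pools can never go negative and no
  ad-hoc clipping is needed.
* The update order is mineralization, deposition (split evenly NH4/NO3),
  ammonium oxidation, heterotrophic nitrification, denitrification, then
  plant uptake with a litter fraction (default 0.92) returned to soil
  organic N. Nitrogen closes exactly each step:
  `deposition - (N2O + N2 + net uptake) = change in pools`, asserted to
  1e-9 g N m^-2 over 1e4 random step instances.
* CO2 enters only through plant uptake, scaled by
  `1 + beta log(CO2/CO2_ref)` — the fertilization mechanism by which
  rising CO2 stimulates vegetation N uptake, lowers soil inorganic N, and
  suppresses N2O. This gives the expected driver signs (more deposition
  -> more N2O; more CO2 -> less; warming -> more), each verified by
  paired simulations.
* The grid is an abstract equal-area lattice of exact 25 km x 25 km
  cells; no projection handling, so area sums are exact.
* Grid runs spin up on the first year's forcing (default 200 years). The
  slow organic-N pool has a multi-decade time constant because most plant
  uptake returns as litter; shorter spin-ups leave a visible transient
  drift which then appears in the factorial residual.

Default rates and yields were set once so that a China-scale synthetic
grid (3520 forest + 6400 grassland cells) lands in the few-hundred
Gg N2O yr^-1 range with forests carrying roughly 80% of the natural
subtotal — a magnitude-order calibration only; no quantitative claim about
real natural emissions is attached to these defaults.

**Factorial attribution.** Drivers (CO2, N deposition, climate =
temperature + WFPS) are attributed by counterfactual runs holding one
driver at its first-year value per cell. The contribution of driver X is
the trend-integrated difference `slope(S_ALL - S_fix(X)) x 41` for a
1980–2020 window, i.e. the change in annual emission attributable to X
over the window, using the same 41-year multiplier convention as the
accumulated-change statistic. Non-additivity is reported explicitly as a
residual row, never hidden; with converged spin-up the residual is small
relative to the driver terms.

# Uncertainty

Monte Carlo propagation treats activity data as provincial observations
(independent truncated-normal multipliers per record) and EFs as national
parameters (one multiplier per category per draw — perfectly correlated
across provinces within a category, independent across categories). The
lognormal is the EF default (strictly positive, right-skewed, appropriate
for factors with order-of-magnitude literature uncertainty such as the
wastewater EF), parameterized mean-1: `sdlog = sqrt(log(1+cv^2))`,
`meanlog = -sdlog^2/2`. Intervals are empirical 2.5/97.5 percentiles of
the recomputed aggregates; a test checks the one-category case against
closed-form lognormal quantiles at n = 1e4 within 2% relative.

Soil-model calibration uses random-walk Metropolis with diagonal Gaussian
proposals (step sizes chosen for 20–40% acceptance; burn-in half the
chain). The simulate-then-recover experiment fits the denitrifier N2O
yield and the denitrification rate to a 41-year single-cell flux series
with 5% Gaussian noise. Two properties of this design matter and are
deliberate:

* The two parameters are strongly ridge-correlated (their product sets
  the flux level), so marginal quantiles need a well-mixed chain; the
  recovery test uses 16,000 iterations thinned by 4, and `simulate_cell()`
  provides an allocation-free scalar path (regression-tested against
  repeated full steps) to keep 20 repeat fits around a minute.
* True parameters are drawn from the priors in each repeat — the standard
  simulation-based-calibration design under which 95% credible intervals
  have exactly 95% coverage when the machinery is correct. Coverage at one
  fixed parameter point is not guaranteed to be nominal under weak
  identification, and empirically sits a few points lower on this ridge.

# The synthetic-data generator

`generate_activity()` emulates the statistical shape of four decades of
Chinese provincial activity data; it is the package's study condition, not
a tuning knob. National fertilizer N rises roughly threefold from 1980
along a smooth S-curve to a 2016 peak and then declines linearly — the two
printed national anchors (35.4 Tg N in 2016, 30.6 Tg N in 2020; a 13.6%
decline) are matched exactly by construction, and everything else is
shape-only. Adipic-acid production grows steeply after 2005 with the two
CDM-abated provinces held to small fixed shares (so the 2008 abatement
onset cannot reverse the sector's growth); energy use grows fastest in the
2000s (logistic centred on 2006); population increments decelerate from
about 15.5 to about 7.5 million persons per year; provincial splits use
seeded Dirichlet-style weights with multiplicative lognormal noise,
renormalized each year so national anchors hold exactly.
`generate_forcings()` gives monotone CO2 (about 340 to 412 ppm), N
deposition rising to 2000 then plateauing, a warming trend with
interannual anomalies, and stationary WFPS noise.

What the generator does *not* emulate: real provincial statistics, spatial
covariance between neighbouring provinces, sub-annual dynamics,
freeze–thaw pulses, price- or policy-driven discontinuities, and aquatic
N2O sources. Passing tests on synthetic data therefore demonstrate the
correctness and qualitative behaviour of the engines, not agreement with
China's actual inventory beyond the printed worked examples.

# Reporting conventions

Percentages and Gg totals are reported to one decimal; decadal rates are
endpoint ratios, not regression slopes (this is what reproduces the
published 38.2/15.3/31.5/23.1% sequence from the five-snapshot totals).
Accumulated changes multiply the OLS slope by 41 years for the 1980–2020
window, following the published convention even though the window spans 40
intervals. The Mann-Kendall test uses the tie-corrected variance and a
continuity-corrected two-sided normal approximation, without
pre-whitening; the published analysis does not state either choice, and
tie-corrected/non-prewhitened is the conventional default. Printed
aggregates are checked within ±0.2 Gg because the published table rounds
line items to one decimal: its 1980 grand total, for instance, is not
reproducible exactly from either its line items (sum 889.7) or its
subtotals (sum 889.5).

Inventory export writes plain CSV (`fan_inventory.csv`, and
`fan_natural.csv` for the gridded natural fluxes) with shortest
round-trip decimal formatting, so re-reading reproduces the tables
bit-for-bit; re-import uses base R's strtod-backed parser for that
guarantee.

# Problem sizes

The test-suite and acceptance-script runs use: 31 provinces x 41 years
across all sectors (about 28,000 estimate rows); 1000 Monte Carlo draws
for the end-to-end uncertainty run and 10,000 for the closed-form
comparison; a 9920-cell grid (3520 forest, 6400 grassland) with a
200-year spin-up for the natural model and its factorial experiments; and
20 repeat MCMC fits of 16,000 iterations each. These sizes were chosen so
the full pipeline exercises every code path at China-like scale while
remaining comfortable on a single CPU.

# Known limitations

* EFs other than those quoted in the text (fuel-, technology-,
  system-specific values) are IPCC-default-style placeholders shipped as
  configuration, not country-calibrated values.
* The soil model is deliberately minimal: no carbon-cycle closure, no
  vegetation dynamics, no freeze–thaw or rewetting pulses, annual
  resolution only.
* The factorial decomposition is "fix one driver at its first-year
  value"; with interacting drivers the contributions need not sum to the
  total trend, which is why the residual is reported.
* Gridded outputs are CSV, not NetCDF; the long table carries the same
  information (cell, year, flux and pathway split).
* Aquatic and riverine N2O sources are out of scope, as is ingesting the
  comparison inventories (EDGAR, GAINS, FAOSTAT, national inventories).
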