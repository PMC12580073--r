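---
title: "Carbon accounting for wildfire-mitigation treatments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon accounting for wildfire-mitigation treatments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firecarbon)
```

`firecarbon` implements stock-change carbon accounting for a long-term
Before-After-Control-Impact (BACI) fuel-treatment experiment: repeated
plot inventories become per-plot carbon pools, pool changes become a
net-ecosystem ledger with prescribed-fire emission and harvest removal
entries, harvested carbon is followed into wood products, and annual
treatment-minus-control flux differences are discounted into a carbon
cost against the dynamic untreated baseline. This vignette documents the
model, its assumptions, the parameters that matter, and the design
choices made where the design was genuinely open.

## The measurement design the package assumes

Each experimental unit holds permanent 0.04-ha circular plots. Trees and
snags with dbh ≥ 11.4 cm are censused on the full plot; smaller live
stems (1.0–11.4 cm) on nested 0.004-ha subplots, so per-hectare
expansion factors are exactly the area reciprocals (25 and 250). Two
protocol drifts are modelled explicitly rather than normalised away,
because estimation-time decisions about comparability should stay
visible: in 2016 small trees were tallied into 2.54-cm bins (assigned at
the bin midpoint by default; the uniform-draw alternative the field crews
used is a seeded option) and snags were recorded only above 20.5 cm; in
2020 the small-tree census expanded to the whole plot. These travel as
per-year `protocol_flags` on the plot roster (`default_protocol()`), and
`consistently_sampled_plots()` restricts any analysis to plots measured
at every required inventory, since a shifting plot set confounds
treatment and sampling effects. How the 2016 snag floor should be
reconciled in stock change is genuinely underdetermined; the package
keeps the flag and leaves the filter to the analyst.

Downed fuels are sampled on two 11.3-m planar-intercept transects per
plot, with class-specific sampled lengths (1-h and 10-h: 0–2 m, 100-h:
0–3 m, 1000-h: full transect). Litter and duff depths are recorded at
0.3 and 0.9 m on each transect.

## Pool estimation

* **Live trees.** Wood (stem+bark+branch) biomass uses a
  combined-variable power law, `W = a (d²h)^b`, with foliage as a
  species ratio of wood, converted at a carbon fraction of 0.48. The
  shipped coefficient table (`default_allometry()`) carries documented
  defaults for the six study species; regional equation systems are
  drop-in replacements since `AllometryTable` is a plain list of
  tibbles. Tests therefore assert formula structure (monotonicity,
  limits, closed-form evaluation of the shipped curve), never specific
  default values.
* **Snags.** Live-equivalent wood biomass × 0.88 (live-to-dead ratio for
  decay class 2) × 0.51. The class-2 treatment is applied to *all* snags
  deliberately — decay class was not recorded consistently across early
  inventories, and a uniform rule keeps the two endpoint inventories
  comparable, at the cost of overestimating old, degraded snags. Snag
  carbon per unit geometry is always below live-tree carbon
  (0.88 × 0.51 = 0.4488 < 0.48).
* **Understory.** Cover classes are interpreted at midpoints 2.5%, 15%
  and 63%. Shrub cover becomes a count of average-sized individuals via
  mean crown area, then per-individual biomass × 0.49. Herb carbon is
  linear in summed cover with a configurable coefficient (default
  0.5 MgC/ha at 100% cover) — the published herb method is an external
  reference, so the linear-coefficient form keeps the operation explicit
  and replaceable.
* **Downed fuels.** The planar-intercept estimator
  `w = (π²/8) n d̄² s ρ / L` (d in cm, L in m, ρ in g/cm³ gives Mg/ha)
  with composite coefficients formed as basal-area-weighted means over
  the species present; equal weights when a plot has no live trees.
  Transects are assumed horizontal (slope correction 1, configurable);
  the secant-of-lean is a per-class species coefficient.
* **Litter/duff.** Depth × depth-to-biomass coefficient × carbon
  fraction (0.463 litter, 0.362 duff). The depth-to-biomass regression
  behind the published study is not printed there, so the coefficients
  (defaults 5.0 and 8.0 Mg/ha per cm) are exposed in
  `carbon_constants()` for site calibration; the carbon fractions are
  fixed.
* **Soil.** 0–15 cm only: bulk density × thickness × %C, averaged over
  cores. Deeper layers are out of scope.

`estimate_pools()` assembles these per plot-year; the `total` column is
definitionally the sum of the ten pools and the test suite holds that
identity to 1e-12 relative.

## Ledger, wood products, carbon cost

Emissions and removals are stored as **negative** ledger entries so the
published table layout is reproduced literally, and
`nep = necb − fire_emission − wood_removals` is exact by construction.
Annualisation divides by 19 (2001–2020).

The wood-product chain applies merchantability gates (conifer sawlogs
dbh > 22.9 cm to a 15.2-cm top; hardwood fuelwood dbh > 27.9 cm to a
20.3-cm top). Stem volume uses a form factor (default 0.42) on the
cylindrical volume with a merchantable fraction (default 0.90) standing
in for taper-to-top integration — both configurable, and the acceptance
surface depends only on the mill-split invariants: LLP = sawlog carbon ×
0.676 × 0.95, kerf = × 0.224, and LLP + kerf + mill residue = sawlog
carbon.

Carbon cost interpolates inter-inventory changes into constant annual
fluxes (they telescope exactly back to NECB), takes
`control − (treatment + LLP credit)` per year, and discounts by
`(1+r)^−(t−2001)` with r = 0.04/yr. The exponent convention — a 2002
delta carries factor 1/1.04 — is the "start-year equivalent" reading;
since the published worked table is in an appendix we did not reproduce,
the convention is an explicit argument (`rate`, `base_year`) rather than
a constant. LLP is credited in the year of harvest; fall-2001 harvests
are credited in 2002, the first cost year. Tops-and-limbs fate differs
by entry exactly as in the study: left in the forest in 2001 (a
carbon-conserving transfer into the downed-fuel pools), hauled and
burned in 2019 (counted in removals).

## Wildfire scenario

Fire behaviour is *not* simulated. Mortality schedules (species × dbh
class kill fractions) and emissions enter as inputs from external
fire-effects tooling, or from a clearly-labelled stand-in: a logistic
kill curve in dbh (`logistic_mortality()`), so survival rises with stem
size, plus per-pool consumption fractions. `apply_mortality()` uses
deterministic-expectation accounting — each stem contributes its kill
fraction of carbon to the killed pool and survives with the complement
via a `weight` column — so survivor + killed carbon equals pre-fire live
carbon exactly. `scenario_ledger()` conserves carbon strictly: killed
carbon moves live→snag, the emission draws first from combustible
surface pools proportionally to their size and any crown-consumption
excess from the new snag pool, so pre-fire total = post-fire total +
emission.

Two thresholds coexist on purpose: "large tree" is 76.2 cm for the
wildfire-resistant fraction, while "stable carbon" (large resistant
pines) uses 72.6 cm — each metric keeps the threshold its definition is
anchored to, and both are arguments.

## Recovery rates and BACI contrasts

Interval rates are plain difference quotients over the regime-specific
windows (fire: 2003–2009, 2010–2016, 2017–2020; control: 2003–2009,
2009–2016, 2016–2020), summarised at plot level. Annual tree mortality
uses the compound convention `1 − (S/N₀)^(1/t)` by default (the simple
convention is exposed) — the convention is not fixed by the study, so it
is documented and selectable.

The published study's inferential machinery (Gaussian and
Beta-distribution mixed models with zero-inflation selection) is
deliberately replaced by a transparent difference-in-differences with a
seeded percentile bootstrap over plots (`baci_contrast()`). Fitting
mixed models is routine and orthogonal to the accounting this package
contributes; effect directions and magnitudes remain checkable, and the
contrast is translation-invariant by construction. Parameter recovery is
tested: with a known effect δ injected into synthetic plot deltas, the
95% bootstrap CI covers δ in ≥ 90% of seeded replicates.

## What the synthetic generator emulates — and what it does not

`sim_config()` encodes the study conditions as defaults: 12 units × 20
plots, 3 replicates × 4 treatments, inventories in
2001/2003/2009/2010/2016/2017/2020 (comprehensive inventories precede
the year's treatments; the 2010/2017 updates follow them), six-species
composition, thinning to a 31 m²/ha residual (within the prescribed
28–34 band), mastication of 90% of stems < 25 cm, three fire entries for
Fire (2002/2009/2017), the Mech calendar (2001 thin+mastication, 2017
mastication, 2019 whole-tree thin) and the Mech+Fire calendar (2001
mechanical, 2002 burn, 2017 mastication, 2018 burn, 2019 salvage).

The generator simulates the *latent* stand — every stem ≥ 1 cm at
full-plot scale, continuous fuel loads and depths — and derives
measurements by protocol: small stems land on the subplot with
probability 0.1, transect tallies are Poisson draws around the
planar-intercept inversion of the latent load, depths get lognormal
point noise (CV 0.12), CWD pieces are drawn to match the latent load
through E[d²]. This avoids the expansion-factor discontinuity a
subplot-resident sapling would suffer on crossing 11.4 cm, and makes
measurement error honest: estimated pools differ from latent pools by
sampling noise, as in the field.

Demographics are deliberately simple: a Weibull diameter distribution, a
saturating height curve, non-negative normal diameter increments with a
density-dependent multiplier `(BA_ref/BA)^0.5` clamped to [0.7, 1.6]
(release after thinning, suppression in crowded stands), constant
background mortality, snag fall routing 70% of fallen carbon to CWD, and
first-order litter/duff/fuel turnover. One root seed; each unit draws
from a deterministic substream, so adding a unit never perturbs the
others. The default parameterisation was set once, as a realism guard,
so that the simulated Control NECB over 19 years lands near the
magnitude a productive Sierra Nevada mixed-conifer stand can sustain
(~110 MgC/ha ± 50%); it was not fitted to any published cell, and the
treatment-level NECB values the generator produces are *not* expected to
match the study's (its Mech units, for instance, lose more carbon than
the field experiment's did).

Features of real data the generator does not emulate — and which passing
tests therefore say nothing about: recruitment, drought-pulse mortality
(available as an off-by-default event), bark beetles, species-specific
growth differences, spatial structure, crew effects, and lost plots (the
synthetic design is balanced, so `consistently_sampled_plots()` is
exercised by tests with artificial gaps instead).

## Numerical choices and degenerate inputs

Pool totals are exact sums; conservation checks use 1e-9 relative
tolerances where event arithmetic is involved. Plots with no live trees
take equal-weight composite fuel coefficients; fractions of an empty
tree list are `NA`, not 0. Zero-length CWD lists, empty understory
tables and zero-sample soil lists all return exact zeros. Unknown
species codes demote to `OTHER` with a warning; invariant-violating rows
are quarantined into an error report rather than dropped silently.
Bootstrap CIs use `quantile(type = 7)`.

Problem sizes in the test suite were chosen to keep the default run
brief while still exercising the full design: the brute-force
planar-intercept comparison uses 1,000 seeded random transects, BACI
recovery uses 20 replicates of 10+10 plots, cross-seed ordering checks
use 20 seeds of a 4-unit × 3-plot experiment, and one full 12 × 20 × 7
experiment runs end-to-end.

## Known limitations

Belowground live biomass, the 15–30 cm soil layer, decay-class-specific
snag density schedules, fire-behaviour indices (P-torch), post-fire snag
decay and regeneration failure are out of scope. The shipped allometry
and fuel coefficients are placeholders of realistic magnitude, not
fitted regional equations; any absolute pool value derived from them
should be read as illustrative until a user supplies local tables. The
wood-product stem-volume model (form factor × merchantable fraction) is
a first-order stand-in for taper equations. The carbon-cost module
assumes aligned annual series and does not model post-wildfire
trajectories; the cost-with-wildfire convention for a terminal-year
event is configurable and intentionally excluded from the package's
quantitative acceptance surface.
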