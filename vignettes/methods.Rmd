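---
title: "Methods: isotope-probing rate calculations for stratified water columns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-probing rate calculations for stratified water columns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazosip)
```

## The problem

Meromictic lakes develop a permanent chemocline: a thin layer where oxygen
disappears, sulfide appears, and dense blooms of anoxygenic phototrophic
sulfur bacteria sit at the interface. Dual stable-isotope-probing (SIP)
incubations with ^15^N~2~ and ^13^C-labelled dissolved inorganic carbon let
us measure, in the same bottles, how fast this community fixes N~2~ and CO~2~
— in bulk via isotope-ratio mass spectrometry of the particulate pools, and
cell by cell via nanoSIMS. `diazosip` implements the full quantitative chain
from raw measurement tables to population-level budgets, plus a seeded
synthetic-data generator so every stage can be validated by parameter
recovery without any field data.

## Depth alignment

Internal waves shift water masses vertically between the downcast (continuous
profile) and the upcast (stationary bottle sampling). A bottle's *nominal*
depth therefore need not be the depth its water occupied during the downcast.
`align_stations()` matches each station against the downcast row with the
most similar physicochemical fingerprint: all parameters are normalized to a
0–100% scale (`normalize_profile()`), and the corrected depth minimizes the
sum over parameters of absolute percent differences.

Choices made where the procedure is genuinely open:

* **Normalization extremes** span the union of downcast values and station
  means, so a station value can never clamp against a range computed from the
  other cast alone.
* **Ties** resolve to the shallowest candidate depth — deterministic and
  reproducible.
* **Matching parameters** default to conductivity, temperature and pressure;
  turbidity participates only if explicitly requested.
* Rows with missing values are **dropped at ingest**, never imputed; the
  downcast is used at its native resolution, with no interpolation.

A green offset-recovery test establishes that, for profiles that are smooth,
vertically rigid, and observed with homoscedastic sensor noise, the corrected
depth lands within one grid step of truth. Real casts with sensor drift,
non-rigid displacement, or hysteresis are outside what the test establishes.

## Bulk rates

The endpoint incorporation equation converts isotope enrichment of the
particulate pool into a volumetric rate:

$$\mathrm{rate} = \frac{\mathrm{at\%}_{sample} - \mathrm{at\%}_{NA}}
{\mathrm{at\%}_{pool} - \mathrm{at\%}_{NA}} \cdot \frac{[\mathrm{PON}]}{t}$$

with the natural-abundance reference taken from the unincubated control
bottle, the pool enrichment from MIMS (^15^N~2~) or cavity ring-down
spectroscopy (^13^C-DIC), and the identical form for carbon with POC. Note a
deliberate asymmetry kept from the printed equations: the *bulk* denominator
subtracts the PON control's atom%, while the *single-cell* equation uses the
pool's excess over natural abundance; these coincide only when the control is
at true natural abundance. We implement each as printed.

Numerical policies:

* Negative excess (sample below control, possible under noise) **clips to
  zero with a flag** — incorporation cannot be negative, but the flag
  preserves the QC signal.
* **Detection limit**: a rate is censored to zero when the mean endpoint
  excess is below 3× the standard deviation of the control-replicate atom%
  (multiplier configurable); the corresponding rate-scale LOD is reported
  alongside. This policy is the package's own, stated explicitly in output,
  because per-sample detection limits are typically reported only in
  supplementary material.
* Replicates aggregate as **arithmetic mean ± SD**.
* The gas-phase contamination check converts pmol in a gas subsample to ppm
  by moles with a default molar volume of 22.414 L mol^−1^ (0 °C, 1 atm),
  which reproduces the canonical 0.056 ppm for 5 pmol in 2 mL.

The autotrophic N demand is the C fixation rate divided by the bulk biomass
molar C:N (default 8.6, measured per depth in practice), and the fraction of
demand met by fixation is their ratio in percent.

## Diffusive flux and the N-source budget

Ammonium diffuses up into the chemocline along its gradient. With a turbulent
diffusivity D (default 1.6 × 10^−6^ m² s^−1^) and two samples bracketing the
steepest gradient, Fick's first law gives an areal flux

$$J = D \, \frac{\Delta C}{\Delta z},$$

positive when concentration increases downward (upward transport). The
canonical unit is **mmol m^−2^ d^−1^**: with concentrations in µmol L^−1^
(numerically mmol m^−3^) and D converted to m² d^−1^ the quotient is already
on that scale. Texts occasionally render such fluxes in µmol cm^−2^ d^−1^;
that rendering differs by 10^4^ and is dimensionally inconsistent with
spreading the flux over a ~1 m layer to get µmol L^−1^ d^−1^, so
`layer_budget()` reports both renderings with mmol m^−2^ d^−1^ as canonical.
Spreading J uniformly over the mixed layer (`volumetric_rate()`) conserves
mass exactly by construction.

The budget caps the ammonium contribution at the demand left after N~2~
fixation and reports any remainder as unexplained, so fractions never exceed
100% of demand.

## Single-cell rates

Per-plane secondary-ion counts arrive drift-corrected (image processing is
upstream, out of scope). Counts are accumulated over planes, and the working
ratios are ^15^N/(^15^N+^14^N) and ^13^C/(^13^C+^12^C) — while the QC error
is computed on the ^15^N/^14^N and ^13^C/^12^C ratios, mirroring standard
practice. The Poisson relative error of a count ratio is
$\sqrt{1/N_{minor} + 1/N_{major}}$; a cell passes QC only when this error is
**strictly below 5%** on accumulated counts.

The rate equation turns a cell's excess enrichment into absolute uptake:

$$\mathrm{rate} = \frac{\mathrm{at\%excess}_{cell}}
{\mathrm{at\%excess}_{medium}} \cdot \frac{N_{cell}}{t},$$

with cellular nitrogen obtained from biovolume via the prolate-spheroid
formula $BV = (\pi/6)\,w^2 \ell$, the allometric carbon relation
$C_{cell}\,(\mathrm{fmol}) = 0.433\,BV^{0.863} \cdot 1000/12$, and a biomass
C:N of 8.6. The carbon relation is calibrated for comparatively large cells
(µm³-scale biovolumes); applying it to sub-µm³ picoplankton would
extrapolate the power law outside its support.

Further policies: enrichment significance is judged on accumulated counts as
excess > 3× the propagated ratio error (no criterion is standard, so the
multiplier is explicit and configurable); sampling sufficiency uses a
running-mean stability check — the adequate n is the smallest cell count
after which every additional cell changes the cumulative mean by less than
5% (threshold and ordering configurable, bootstrap reshuffles supported by
passing a permuted vector); the FISH-treated vs untreated comparison is a
rank-based Wilcoxon test, robust at nanoSIMS group sizes; no
isotope-dilution correction for FISH treatment is applied by default (the
multiplicative hook `fish_dilution_factor` exists and defaults to 1); ROI-
derived geometries use the minor/major axes of the ROI's equivalent ellipse.

## Population scaling

FISH field-of-view counts convert to abundance with the standard
epifluorescence formula — mean count per field × (filtration area / field
area) / volume filtered — with the SE of the per-field mean scaled
identically. The population rate is abundance × mean single-cell rate
(arithmetic mean over QC-passing cells, inactive zero-rate cells included),
with the unit chain fmol cell^−1^ d^−1^ × cells L^−1^ ÷ 10^9^ → µmol L^−1^
d^−1^ centralized in `unit_conversions`.

**Error propagation** uses the exact variance of a product of independent
errors (Goodman): $SE(R)^2 = (a\,SE_r)^2 + (r\,SE_a)^2 + (SE_a SE_r)^2$.
The familiar first-order relative-quadrature form underestimates the true SE
by ~2% at CVs of 30% — enough to fail a Monte-Carlo calibration check at
that CV — while the exact form stays within sampling noise of a 10^5^-draw
oracle at all tested CVs and needs no special case when the mean rate is
zero. Contribution totals propagate the population SEs in quadrature with
the bulk replicate **SD** (not the SE of the bulk mean), matching how bulk
uncertainty is displayed as replicate-SD error bars; a parameter converts to
the SE of the mean if preferred.

## The synthetic world

`scenario_config()` fixes one seeded stated world; all randomness flows from
the master seed through deterministic per-stage substreams, so any stage can
be regenerated independently and outputs are byte-identical per seed.

Defaults, chosen once: a chemocline at ~14 m on a 0.02 m downcast grid with
sigmoidal conductivity/temperature, linear pressure and a Gaussian turbidity
maximum; an internal-wave offset of 0.3 m; incubations at 13.7/14.0/15.5 m
with true N~2~ fixation 0.27/0.135/0 µmol N L^−1^ d^−1^ (the deepest depth
truly zero, exercising the censoring path), CO~2~ fixation of ~32/36/15
µmol C L^−1^ d^−1^, PON 20 µmol L^−1^, pool enrichments 30 at% ^15^N and
10 at% ^13^C, 5% multiplicative measurement noise, triplicates plus
triplicate controls over 1 d; five phototrophic sulfur bacteria populations
with true shares 80/10/5/3/2% of bulk fixation and mean cell rates
3.29–0.23 fmol N cell^−1^ d^−1^ (one large-celled *Chromatium*-like
population dominating), log-normal cell sizes (CV 10%) and between-cell
rates (CV 30%), one forced inactive cell, 20–70 planes per cell at 8000
(CN^−^) and 20000 (C pair) expected counts per plane, and 38 FISH fields on
a 2 × 10^8^ µm² filter from 10 mL. Magnitudes are anchored to published
chemocline observations where available and otherwise field-typical; they
describe a plausible lake, not any real one.

What the generator does **not** emulate — and hence what green tests do not
establish: sensor drift and hysteresis between casts, non-rigid water-mass
displacement, bottle effects and label equilibration kinetics, nanoSIMS
dead-time/QSA artefacts and drift residuals, spatially clumped cells on FISH
filters (counts are Poisson, i.e. unclumped), and any taxonomic reality of
the population labels.

The incubation forward model is the two-pool mass balance
$at_{end} = (at_{NA}(P - Ft) + at_{pool} F t)/P$; inverting it through
`bulk_rate()` is exact to < 10^−9^ relative without noise, which is the
oracle-equivalence test. The ROI generator inverts the cell-rate equation to
a true fraction and draws independent Poisson counts per plane; a
`target_rel_error` override sets per-cell count totals so the QC filter can
be calibrated at prescribed true ratio errors (essentially all cells pass at
3%, essentially none at 8%).

## Known limitations

* The detection-limit policy is a stand-in where per-sample LODs are not
  supplied externally.
* The steepest-gradient finder scans consecutive sample pairs only; the flux
  window should normally be fixed by the analyst.
* `cell_rate_table()` requires all four ion species per cell; partial pairs
  (N-only measurements) must be padded upstream.
* End-to-end closure is a stochastic criterion: with all error sources
  active its total has roughly 1-SE coverage, so individual seeds can land
  outside; the acceptance suite evaluates it at a fixed seed and the
  propagated SE the pipeline itself reports.
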