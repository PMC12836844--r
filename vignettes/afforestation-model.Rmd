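---
title: "Simulating boreal afforestation with a deciduous-adapted 3-PG"
author: "afforest3PG authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating boreal afforestation with a deciduous-adapted 3-PG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afforest3PG)
```

## What this package models

`afforest3PG` asks a forest-management question with a process model: if
open boreal land (shrubland and grasses that were never forest) is planted
in 2025, how much aboveground biomass accumulates by 2080 under different
warming pathways, and does it matter whether the planted species is a
locally adapted conifer or a fast-growing deciduous broadleaf? The engine
is 3-PG (Physiological Principles Predicting Growth), a light-use-efficiency
stand model driven by monthly climate normals, extended here with a
deciduous phenology scheme. Around the engine sit four landscape stages:
a synthetic study-site generator, site preparation (fertility and soil-water
capacity layers), wetness-stratified planting rules, and nonparametric
post-processing of the resulting biomass and water-stress distributions.

## The growth engine

### Environmental modifiers

Monthly gross production is maximum canopy quantum efficiency
($\alpha_{Cx}$, mol C mol PAR$^{-1}$) down-regulated by dimensionless
modifiers, each in $[0,1]$ (0 = shut-down, 1 = no constraint):

* $f_T$ — a skewed parabola of mean temperature between the growth
  minimum, optimum and maximum ($T_{min}$, $T_{opt}$, $T_{max}$, °C),
* $f_{Frost}$ — linear penalty $1 - k_F \cdot d_{frost}/d_{month}$,
* $f_{VPD} = \exp(-c \cdot D)$ — stomatal closure with day-time vapour
  pressure deficit $D$ (mbar, half the Tetens saturation-pressure spread
  between daily maximum and minimum temperature), coefficient $c$ in
  mbar$^{-1}$,
* $f_{SW} = 1/\left(1+\left(\frac{1-\theta}{c_\theta}\right)^{n_\theta}\right)$
  — the soil-water modifier on relative available water
  $\theta = \mathrm{ASW}/\mathrm{MASW}$, shaped by texture constants,
* $f_{Nutr} = 1-(1-f_{N0})(1-FR)^{f_{Nn}}$ on the fertility rating,
* $f_{Age} = 1/(1+((a/a_{max})/r_a)^{n_a})$,
* $f_{C\alpha}$ — a saturating CO~2~ response equal to 1 at the 350 ppm
  baseline and to the calibration ratio at 700 ppm. We use the canonical
  two-anchor form
  $f_{C\alpha} = f_{x}\,C/(350(f_{x}-1)+C)$ with
  $f_{x} = f_{C\alpha700}/(2-f_{C\alpha700})$, which is the unique member
  of this saturating family passing through both anchors exactly.

The physiological product $\varphi = f_{Age}\min(f_{VPD}, f_{SW})$ takes
the most limiting water-related constraint, after the model's assumption
that the single most limiting factor governs a month.

### Production, allocation, turnover, mortality

Leaf area index is $L = 0.1\,W_f\,\sigma(a)$ with an age-interpolated
specific leaf area $\sigma$. Absorbed PAR follows Beer's law on half the
monthly solar total; GPP converts absorbed molar PAR at
$\alpha_{Cx} f_{C\alpha} f_{Nutr} f_T f_{Frost}\,\varphi$, and NPP is the
fixed fraction $Y$ of GPP. Allocation sends
$p_R = p_{Rx}p_{Rn}/(p_{Rn}+(p_{Rx}-p_{Rn})m\varphi)$ to roots (more under
drought, less on fertile soil) and splits the rest between stem and foliage
by the diameter-dependent ratio anchored at 2 and 20 cm DBH, where DBH
inverts the stem allometry $w_s = a_S\,\mathrm{DBH}^{n_S}$. Foliage and
roots turn over at $\gamma_F(a)$ (sigmoid from juvenile to mature rate) and
$\gamma_R$. Mortality has a background annual fraction plus self-thinning:
mean stem mass may not exceed $w_{Sx1000}(1000/N)^{p_{thin}}$, enforced by a
root-finder on the thinning identity with dying trees carrying 0.2 of the
mean mass (suppressed trees are smaller). The monthly soil-water bucket
gains precipitation minus LAI-saturating interception, loses
Penman–Monteith transpiration through a canopy conductance
$g_C = g_{Cmax}\,\varphi\,\min(1, L/L_{gcx})$ (net radiation 0.8 of solar,
boundary-layer conductance 0.2 m s$^{-1}$), and is clamped to
$[0, \mathrm{MASW}]$ with overflow as runoff; the balance closes exactly by
construction and the test suite asserts it to $10^{-9}$ mm over 660-month
runs.

### Deciduous phenology

3-PG was built for evergreens; its litterfall curve has no annual leaf
drop. The published workarounds (averaged litterfall, spring foliage
resets, monthly SLA, winter nullification) are synthesised here into a
reserve-transfer scheme chosen because it conserves mass and is directly
testable:

* leaf state follows mean monthly temperature against a flushing threshold
  (default 5 °C);
* at leaf-off the whole canopy drops as litter and its mass is banked as a
  foliage reserve; at leaf-on the canopy is re-expressed from the reserve
  (no production is double counted — the reserve only moves mass);
* out of leaf, GPP and NPP are zero and any foliage allocation would bank
  into the reserve;
* while in leaf, the continuous litterfall rate also applies to the
  expressed canopy. This last point matters: without in-season turnover the
  reserve cycle conserves every previous year's foliage and the canopy
  grows without bound (LAI beyond 100 by 2080 in early experiments). With
  it, canopy mass equilibrates where turnover balances allocation, and the
  exact identity *leaf-off litter = next spring's expressed foliage* still
  holds, which is what the conservation tests assert.

An evergreen run and a deciduous parameterisation whose flushing threshold
is never reached are bit-identical, which the suite also checks.

## Synthetic landscape

The generator emulates the *content* of the data products a real analysis
would use, so the pipeline runs self-contained:

* **DEM** — Gaussian-filtered white noise rescaled to the requested relief
  (default 200 m on a 32 × 32 grid of 1-ha cells), giving ridges and
  hollows so the wetness index varies;
* **SOC** — negatively correlated with elevation (valley accumulation),
  spanning both fertility-scaling endpoints, with an exact fraction of
  cells flagged missing (default 5 %) to emulate survey gaps;
* **landcover** — a correlated mosaic of conifer/deciduous forest,
  shrubland, herbs, water and rock, with a forest-history mask equal to
  existing forest plus a configurable 15 % of open vegetated cells
  (burned or harvested former forest);
* **climate** — a sinusoidal annual temperature cycle with
  latitude-dependent mean and amplitude, summer-peaked precipitation,
  top-of-atmosphere solar attenuated by a fixed 0.55 cloudiness factor,
  and frost days as a normal dose on tmin (σ = 4 °C). Scenario warming is
  additive: the 2061–2080 increments default to 1.85 / 2.8 / 3.7 °C for
  the sustainable / middle-of-the-road / pessimistic pathways (the
  midpoints of the published end-of-century ranges) phased in linearly
  across the three 20-year periods. The seed-driven perturbation of the
  monthly curves is shared across scenarios and periods, so warming
  contrasts are exact and the period/scenario orderings hold for every
  seed. CO~2~ per scenario and period is a configuration table
  approximating the published trajectories.

What the generator does **not** emulate: spatial climate gradients within
a site, interannual variability and extremes (normals repeat within each
20-year period), precipitation–temperature covariance, realistic
hydrography or landcover patch geometry, and the 30 m resolution of the
satellite products (cells default to 1 ha). Passing tests therefore show
the pipeline's internal behaviour under controlled conditions, not fidelity
to any particular real landscape.

## Site preparation decisions

* **SOC → fertility**: at or below 40 t C ha$^{-1}$ the fertility rating is
  0.45, at or above 200 it is 1.0, linear between, 0.5 where SOC is
  missing. (The source description of the low anchor reads "> 40" for the
  low-SOC class — an evident typo for "< 40"; the monotone reading is
  implemented.) Missing cells are filled *before* a 3 × 3 uniform mean
  smoothing pass whose edge cells average over available neighbours; the
  window is configurable.
* **DEM → TWI → MASW**: slope by central differences, specific catchment
  area by D8 steepest-descent accumulation times cell size,
  $\mathrm{TWI} = \ln(a/\tan\beta)$ with $\tan\beta$ floored at 0.001 on
  flats. The unspecified "regression" from TWI to maximum available soil
  water is resolved as the monotone linear min–max rescale onto
  [100, 300] mm per site — it honours the stated endpoints and gives
  cross-site consistency; a constant grid maps to the 200 mm midpoint.
* **Eligibility**: shrubland or herbs, never classified as forest;
  water, snow/ice, bryoid and rock are categorically ineligible.
* **Normalized wetness** is min–max over *eligible* cells only (planting
  decisions concern only plantable land); ineligible cells are clamped
  into [0, 1].

## Planting rules and scenario grid

SM1 plants conifer on every eligible cell, SM2 deciduous, SM3 deciduous
below normalized wetness 0.33, conifer above 0.67, and an independent fair
Bernoulli draw per cell in the closed middle band (cells exactly on a
threshold fall in the random band; an exact stratified 50/50 split is a
noted alternative the package does not implement). The planting map for a
rule is drawn once per seed and reused across the three climate scenarios,
so every contrast is paired cell by cell — outside the random band the SM3
biomass is *identical* to the corresponding pure arm, a property the tests
assert cell-wise. Simulation years 2025–2040 use the 2021–2040 normals
(the four-year offset between planting and the first normal period is
accepted as-is), and each stand records its monthly fSW/fVPD trace in 2079,
the year the stands are 55 growing seasons old. Annual biomass is reported
at the August state, so deciduous stands are compared in leaf; whether a
leaf-off "biomass" should include the banked reserve never arises.

## Species parameter files

The three shipped YAML files are configuration, not contract: the source
analysis cites parameterisations rather than printing a table, so values
were assembled once from the 3-PG literature for spruce, pine and
poplar-like species and then frozen. Two choices deserve justification.
First, the generic deciduous file carries a higher quantum efficiency
(0.06 vs 0.05 mol C mol PAR$^{-1}$) but also fast in-season foliage
turnover (0.12 month$^{-1}$), root-heavier allocation bounds, higher
background mortality (2 % yr$^{-1}$) and a lower self-thinning intercept
(140 vs 300 kg at 1000 stems ha$^{-1}$) — a short-lived, fast-cycling
broadleaf against a slow, dense conifer. Second, the deciduous stomatal
parameters (maximum canopy conductance 0.014 m s$^{-1}$, VPD coefficient
0.08 mbar$^{-1}$) encode the isohydric water-use strategy of poplars —
strong stomatal down-regulation under atmospheric drought — against the
more anisohydric spruce (0.02 and 0.05). With these defaults the bundled
synthetic site yields 2080 biomass means of roughly 167–174 (conifer),
282–311 (deciduous) and 266–291 (mixed) tDM ha$^{-1}$ across the three
climate pathways, deciduous advantage growing with warming, and the
conifer arm more soil-water stressed than the deciduous arm over
June–September — the qualitative structure expected of the comparison.
These numbers are recomputed by the acceptance test on the bundled site;
nothing in the package asserts magnitudes beyond that run.

## Numerical choices and degenerate inputs

* Self-thinning solves its identity with `uniroot` at tolerance 1e-10; the
  post-state sits on the frontier to within 1e-6 kg.
* Transpiration is capped at available water plus net precipitation; the
  bucket never goes negative.
* A stand with zero foliage has zero LAI, zero conductance and zero
  transpiration; a deciduous stand out of leaf produces nothing.
* Constant TWI grids map to 200 mm; constant MASW grids to wetness 0.5.
* All randomness flows through per-purpose child seeds derived from one
  user seed (kept below $2^{31}$); regenerating any layer with the same
  seed is bit-identical.
* `runStand` executes a vectorised fast loop that the suite proves equal
  to composing the exported `stepMonth` to machine precision.
* The statistical battery treats cells as independent samples, as the
  source procedure does; per-cell values on a landscape are spatially
  autocorrelated, so the Kruskal–Wallis and Dunn p-values are optimistic
  about effective sample size. The package reproduces the uncorrected
  procedure and leaves spatial corrections out of scope. The "> 5 %"
  stress flag is read as an absolute modifier difference above 0.05 on the
  [0, 1] modifier scale (a relative mode is available), and "X % greater
  stress" is the relative difference of mean $(1-f_{SW})$; both
  definitions are applied to fVPD as well.

## Problem sizes

The routine test suite exercises stands on 8–16 cell-per-side grids and
short spans; the landscape-scale acceptance test runs the full
32 × 32 grid × 9 scenario grid over 2025–2080 (about 500 planted cells ×
672 months × 9, ninety seconds on one core), and the conservation
property runs 256 stands for 660 months. These sizes were chosen as the
smallest at which every wetness band, both species and all three periods
are exercised with comfortable statistical margins.

## Known limitations

Fire, albedo, soil organic carbon and dead-organic-matter pools,
merchantable volume and economics are out of scope by design. Cells are
independent: no seed dispersal, inter-cell competition or disturbance
spread. Climate normals repeat within periods, so droughts and extreme
years — exactly the events that would stress-test a planting strategy —
are absent. The stomatal-VPD description in the source text inverts the
standard relationship ("when VPD is low, stomata close"); the
implementation follows the standard decline of $f_{VPD}$ with *high* VPD.
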