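---
title: "Carbon allocation schemes, turnover diagnostics and synthetic FACE experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon allocation schemes, turnover diagnostics and synthetic FACE experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allocsim)
```

## The model

`allocsim` simulates where a forest stand's net primary production (NPP)
goes. Live biomass is tracked in four pools — foliage, wood (stem, branches
and coarse roots lumped together), fine roots, and cumulative reproduction —
with the simplest dynamics most ecosystem models share:

$$\frac{dB_i}{dt} = a_i\,\mathrm{NPP} - u_i B_i$$

where the allocation coefficients $a_i$ sum to 1 and the turnover rates
$u_i$ (yr⁻¹) send shed carbon to litter. NPP is an exogenous forcing: the
package deliberately contains no photosynthesis, water-balance or nitrogen
cycle. Water and nitrogen enter only as prescribed availability scalars
$W, N \in [0,1]$ that the allocation schemes (and the NPP forcing) read.
Labile/storage pools are out of scope, so annual growth equals annual NPP.

Integration is explicit Euler at a daily step (`dt = 1/365` yr) with a
stability guard `dt * u_i < 1`. The fixed point $B_i^* = a_i\,\mathrm{NPP}/u_i$
is independent of `dt`, and halving `dt` changes 10-year trajectories by
well under 1%, which is the accuracy regime this class of model needs.
Schemes that allocate annually (the allometric and canopy-optimisation
schemes below) bank each year's NPP and partition it on the last day of the
simulated year; turnover still acts daily.

Two derived quantities close the loop between pools and canopy: LAI is
diagnosed as `sla * B_f`, and whole-canopy specific leaf area is recovered
by the diagnostics as peak LAI over peak foliage biomass.

## The four scheme classes

Allocation schemes are interchangeable objects dispatched through
`scheme_allocate()`; each class represents one of the four approaches found
in ecosystem models.

**Fixed coefficients** (`fixed_scheme()`): prescribed fractions, optionally
per phenological phase and optionally overridden per treatment from a start
year (default year 2, matching deciduous parameterisations in which growth
follows the previous year's productivity). A pure fixed scheme cannot
respond to CO2 at all; a *phased* one can, because the relative CO2
enhancement of NPP varies through the season while the phase vectors do
not. `ealco_scheme()` is the prescribed-LAI variant: all growth C to
foliage until the year's maximum LAI is reached, then a fixed 60:40
wood:root split.

**Functional relationships** (`ed2_scheme()`, `lpj_scheme()`,
`ocn_scheme()`): constraints among *biomass stocks*. The deficit-filling
scheme drives leaf and root pools toward targets set by a leaf:sapwood
proportionality per unit height (`q_sw * h`) and a root:peak-leaf ratio `q`
that rises with water or N limitation, then splits the remaining "reserve"
C 70:30 between wood and reproduction. The allometric scheme sends 10% of
NPP to reproduction and divides the rest so that, after growth, (i) LAI is
proportional to sapwood area (pipe model), (ii) height follows the
diameter allometry `H = k2 D^k3`, and (iii) the leaf:root mass ratio equals
`lr_max * min(N, W)`. Wood is a cylinder of density `wood_density`; a stem
density `stems` (default 0.05 m⁻²) converts stand sapwood area to a
representative-tree diameter so the geometry is tree-sized rather than
sapling-sized. How N and W combine is not uniquely determined by the class
description; `min(N, W)` is the default and a multiplicative variant is
selectable (`stress_combine = "product"`). `ocn_scheme()` approaches the
same targets with each day's carbon.

**Resource limitations** (`isam_scheme()`, `teco_scheme()`,
`daycent_scheme()`): rules among *allocation coefficients*. The light/water
scheme uses the Arora–Boer closed form with light availability
`L = exp(-k_ext * LAI)`; wood allocation rises with shading, root
allocation with drought, foliage takes the residual, and in deciduous mode
three phases override the formula (all-foliage during expansion, none from
senescence on). The capped demand scheme fills foliage demand toward a
fixed maximum LAI subject to a 40% cap and root demand rising with
`1 - W` to a 30% cap (from a `root_base` of 0.12 at no stress — a strictly
zero unstressed root share would contradict roots being a prioritised
sink); wood takes the rest. The strict-priority scheme gives roots first
claim (5–18% of NPP with the *stronger* of the water and N limitations),
then foliage up to a wood-biomass-dependent maximum LAI, then wood.

**Canopy optimisation** (`sdgvm_scheme()`): LAI is chosen so the lowest
canopy layer breaks even under Beer-law light decay — the largest LAI (in
`layer_dlai` steps) with `a0 * co2_scalar * exp(-k_ext * LAI) >= leaf_cost`.
Foliage allocation realises the *previous* year's optimum (a mandatory
one-year lag; the first year uses `initial_lai`); the remainder is split
wood:root at a fixed 70:30. The CO2 response of canopy gain is
`co2_scalar = 1 + beta_canopy * ln(co2/co2_ref)` with `beta_canopy = 0.4`:
a raw CO2 ratio would inflate the LAI target as fast as NPP itself and
suppress the scheme's characteristic foliage-fraction decline, whereas
photosynthetic gain saturates with CO2.

## Phenology

The deciduous clock (`phenology_params()`, `advance_phenology()`) visits
DORMANT → LEAF_EXPANSION → STEADY_GROWTH → SENESCENCE cyclically. Budburst
requires the degree-day sum to pass `budburst_gdd` *and* the date to be
before midseason (otherwise the autumn degree-day sum would trigger a
second spring). Expansion ends at `steady_frac * lai_max`; the senescence
trigger — LAI below `senescence_frac * lai_max` (default 95%) — is armed
only after `midseason_doy`, which stands in for "after the annual LAI
peak" without requiring the clock to remember the peak. During senescence
an extra shedding flux (`shed_rate`, 30 yr⁻¹) empties the canopy, down to
an optional `winter_lai` floor (off by default) for parameterisations that
keep an overwintering canopy. Evergreen runs stay in STEADY_GROWTH.

## Diagnostics

`diagnose_records()` and its pieces compute the assumption-centred metrics
on annual observation-style tables, identically for simulated and external
data: allocation fractions as component NPP over total NPP (years with
zero total NPP are flagged and dropped from means); turnover rate as
annual litter-plus-mortality over the annual biomass maximum, lifespan as
its inverse, multi-year lifespan as the *mean of annual lifespans*
(zero-litter years report an infinite lifespan, flagged, never a crash);
canopy SLA as peak LAI over peak foliage biomass; CO2 response ratios as
the mean of elevated annual values over the mean of ambient ones, with
biomass and LAI entering as within-year maxima; and the NPP retention rate
`100 * (ΔB_e - ΔB_a) / (cumNPP_e - cumNPP_a)`, which may legitimately leave
[0, 100]. Biomass increment uses end-minus-start totals of annual-maximum
biomass. Wood litter includes any exogenous mortality events injected via
`mortality_events` (branch shedding and suppressed-tree loss are not
separated). No significance testing is done anywhere: the package's
evaluation style is qualitative, mechanism-by-mechanism.

Note one scale subtlety: the bmax-based turnover diagnostic equals the
generating `u` only at quasi-equilibrium; in a growing or seasonal stand
the annual maximum exceeds the mean biomass, so diagnosed lifespans run a
little long. The recovery machinery therefore records ledger truth on the
diagnostic's own scale, and the `u`-recovery claim is tested separately at
quasi-equilibrium (within 5%).

## The synthetic FACE generator

`face_scenario()` plus `generate_forcing()`/`generate_observations()`
emulate a paired ambient/elevated CO2 enrichment experiment: a step CO2
increase with logarithmic NPP fertilisation `1 + beta ln(co2/co2_a)`
(default `beta = 0.6`, which puts the NPP response ratio near 1.2 for
either site preset — a calibration choice, not a measured value);
progressive nitrogen limitation as a linear `Nfac` decline under the
elevated treatment only; optional midseason drought years, with a fraction
of the stress relieved under elevated CO2 (stomatal water savings — this
is what lets the CO2 effect on NPP amplify during drought, the mechanism
behind the phased-scheme wood shift); an optional SLA reduction under
elevated CO2 (defaults 6.4% / 5.3% in the two site presets) that both
feeds back on simulated LAI and appears in the observations; and
multiplicative lognormal mean-1 noise. Stress scalars enter NPP as
`x^0.5`. Seasonality confines deciduous NPP to days 90–300 with a sine
hump; evergreen NPP has a mild year-round cycle.

All randomness derives from per-treatment, per-purpose substreams of one
scenario seed, so ambient/elevated comparisons are paired and every table
is bit-reproducible. Observation noise is independent per year and
component, except that peak foliage biomass and peak LAI share a
multiplier (leaf area and leaf mass come from the same canopy sample), so
canopy SLA — a ratio — is recovered cleanly at any noise level.

What the generator does *not* emulate: real meteorology, storms and ice
damage, understorey vegetation, rhizodeposition, soil carbon, demography.
Passing tests show the pipeline recovers what this generator encodes;
they say nothing about processes it omits.

## Signature presets

`signature_preset()` packages six study conditions under which each scheme
class shows its characteristic elevated-CO2 response (zero response for
pure fixed coefficients; a drought-year wood shift for phased ones;
wood-then-root for functional balance under progressive N limitation; a
foliage increase via delayed senescence for the deciduous resource scheme;
a root decrease for the capped-demand scheme under water savings; a
foliage decrease for canopy optimisation). These are assertions about
*this package's* schemes, mirroring qualitative behaviours of the model
families they represent. The preset parameters were chosen so the
documented mechanism actually operates. The delayed-senescence preset is
the delicate one: the biome maximum LAI (2.0) sits between the two
treatments' midseason canopies, so the ambient stand drops below the
95%-of-maximum threshold around midseason while the larger elevated canopy
holds above it for weeks longer, during which foliage allocation
continues; its foliage turnover (3.5 yr⁻¹) makes the autumn decline fast
enough that both canopies do eventually senesce within the season.

## Numerical choices

* Allometric solver: bisection on the leaf increment (the residual is
  monotone), interval tolerance 1e-10 kg C m⁻², 200 iterations max; the
  terminal remainder is absorbed into wood so allocation sums exactly.
  Infeasible (off-allometry) states — e.g. after a mortality event — fill
  the wood/root deficits pro rata, never disinvest, and are flagged
  `off_allometry`.
* Zero-NPP steps skip allocation entirely; scheme-level calls with zero
  growth C return a `no_growth` flag rather than dividing by zero.
* Allocation vectors are validated on construction (each fraction in
  [0, 1], sum to 1 within 1e-9); the light/water scheme clips a negative
  residual foliage share to zero with a warning and renormalises.
* Mass balance is exact by construction (litter is computed from the same
  pools the step drains) and checked to 1e-6 relative in the tests.

## Problem sizes

The test-suite study conditions are desk-scale by design: 4–11 simulated
years at a daily step, ~100 random configurations for the conservation
property, 100 seeds for the noise-bias property, 20 random instances for
the solver-vs-scan oracle. These sizes give Monte-Carlo standard errors
comfortably inside the asserted tolerances while keeping the whole suite
in the low minutes.

## Limitations

Single representative stand, no demography or competition; mortality only
as prescribed events; reproduction is a terminal sink; NPP is prescribed,
so schemes cannot feed back on productivity through LAI (except through
the schemes' own allocation rules); stress scalars are forcings, not
states. The calendar has no leap days; years are indexed from treatment
start. These match the package's purpose — isolating allocation and
turnover assumptions — rather than limiting it.
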