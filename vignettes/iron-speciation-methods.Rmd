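---
title: "Thermodynamic iron speciation in subsurface seawater: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic iron speciation in subsurface seawater: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fespec)
```

## The problem

Dissolved iron (DFe) in the deep ocean is held in solution almost entirely by
organic complexation: the free, inorganic fraction (Fe', the sum of Fe3+ and
its hydroxo complexes) is orders of magnitude smaller than DFe, yet it is
Fe' that controls precipitation of authigenic ferric oxyhydroxide (authFeOH)
and abiotic exchange with particles. `fespec` partitions the total labile
iron pool of a subsurface seawater sample across four thermodynamically
defined pathways that all communicate through Fe':

1. reversible binding to heterogeneous **dissolved organic matter** (DOM),
2. complexation by discrete **siderophores** (a ferrioxamine-B-like proxy),
3. precipitation of **authFeOH** when Fe' exceeds the ferrihydrite
   solubility cap, and
4. reversible binding to heterogeneous **particulate organic matter** (POM).

Pools 1-3 constitute the predicted dissolved iron (DFe_pred); pools 3-4 the
predicted labile particulate iron (LPFe_pred, with authFeOH allocated to the
particulate phase). When the POM pathway is active, the boundary condition
is the total labile pool TLFe = DFe + LPFe and no prior assumption is made
about the dissolved/particulate split.

## Models

### Inorganic speciation and the solubility cap

Fe3+ hydrolysis is evaluated by mass action with constants stored at
298.15 K and corrected by the van't Hoff relation
(`vant_hoff_logk()`); activities follow the Davies equation with a
temperature-dependent coefficient, so constants calibrated in simple
electrolytes can be applied at seawater ionic strength (conditional-constant
mode with unit activity coefficients is a configuration switch). Fe' is
strictly linear in free Fe3+ at fixed pH, temperature and salinity. pH
enters as an imposed condition on the free scale; total-scale input is
converted through the Dickson HSO4- constant.

Authigenic precipitation follows the dissolution convention
Fe(OH)3(s) + 3H+ = Fe3+ + 3H2O: the Fe3+ activity may not exceed
Ks(T){H+}^3. Precipitation is handled as a complementarity branch, not a
kinetic rate: the engine solves, checks saturation, caps Fe3+ and re-solves,
assigning the remainder to authFeOH. The bundled enthalpies make the overall
solid-to-Fe' dissolution exothermic, so Fe' solubility increases as
temperature and pH decrease and the solubility minimum sits near pH 8.2 —
the qualitative behaviour expected for ferrihydrite in cold deep water.

### NICA-Donnan organic phases

DOM and POM are bimodal NICA phases: two site groups (carboxylic-type and
phenolic-type), each with a site density `qmax` (mol kg-1), median
affinities `logk` and non-idealities `n` per ion (H, Mg, Ca, Fe), and a
generic heterogeneity `p`. Competition by the major cations and protons is
explicit. Electrostatics use the Donnan gel model: a salinity-dependent gel
volume `log10 V_D = b(1 - log10 I) - 1` (clipped at 5e-4 L kg-1 for
numerical safety far outside the seawater regime) and a Boltzmann factor
chi solved from gel charge neutrality. NICA inputs are free ion
concentrations in the gel, matching the calibration convention of typical
parameter sets.

The default POM phase fixes the total site density at 1 mol kg-1 split 3:1
between the low- and high-affinity groups, the value estimated for marine
particulate material; every other POM parameter is hypothetical and exposed
in the configuration file.

### The siderophore ligand

Siderophores are a discrete dissolved ligand with protonation and Mg/Ca/Fe
formation constants at the ferrioxamine-B order of magnitude
(log K(FeL) near 30.6). At seawater pH the conditional affinity is so high
that iron binding is near-stoichiometric in ligand concentration, which is
why the patch-confined siderophore field simply subtracts from the iron
available to DOM. Its bound iron counts toward DFe_pred; the ligand charge
is excluded from Donnan balances (it is not a gel phase). Below-detection
siderophore entries are treated as zero.

### The equilibrium engine

Unknowns are log-transformed ([Fe3+], chi_DOM, chi_POM) to enforce
positivity. The default solver is a damped Newton iteration (step halving,
up to 50 halvings; finite-difference Jacobian with step 1e-7 — parameter
sets are configuration-driven, so no analytic Jacobian is attempted) on the
Fe mass balance and the two gel charge balances; convergence requires a
maximum scaled residual below 1e-10, stricter than any reported
concentration precision. Initial guesses come from an inorganic-only
pre-bracketing with chi = 1, or from the previous sample in transect sweeps
(warm start). A structurally independent nested bracketing solver
(`bisect_equilibrium()` — outer level on chi_DOM, middle on chi_POM, inner
on [Fe3+]; each residual is monotone in its own unknown) serves as the
verification oracle and as an automatic fallback when Newton fails, flagged
in the result.

### Effective affinities of occupied sites

Site heterogeneity means iron occupies sites in decreasing order of
affinity. At fixed competing-ion composition the trace-metal conditional
isotherm of a NICA group is Sips-shaped with width h = n_Fe, whose
underlying affinity density is the Sips kernel; its median is the group's
Fe affinity shifted by the ambient competition. `occupied_affinity()`
weights that density by the local Langmuir occupancy and integrates by
quadrature (2048 nodes over median +/- 8/h log units, capturing essentially
all of the distribution mass), aggregating the two groups by their occupied
amounts. The homogeneous limit (n = p = 1) collapses exactly to the
conditional affinity; a published closed form of the conditional spectrum
exists and could be slotted in as an alternative backend, but the package
deliberately ships the quadrature route only and validates it by
self-convergence rather than guessing the closed form.

## The transect pipeline

`run_transect()` applies the analysis-domain filter (depth > 250 m, where
biological uptake/remineralisation terms are weakest), derives DOM mass
from DOC (0.0408 kg DOM per mol DOC), derives POM mass from total
particulate phosphorus (C:P = 80, carbon 50 % of POM mass, with the
station-22-style override of 2e-9 kg/L between 2050 and 2380 m for
suspected non-organic particulate phosphorus), solves every sample, and
classifies predicted-minus-observed residuals:

* **enhanced** residuals beyond the fixed thresholds (negative:
  DFe < -0.44 or LPFe < -0.315 nmol/L; positive: DFe > 0.453 or
  LPFe > 0.437 nmol/L) mark samples out of equilibrium, typically near
  hydrothermal, volcanic or shelf sources;
* **equilibrium inliers** have LPFe residuals inside the inlier band. The
  default band is the interquartile range of the dataset's LPFe residuals
  (type-7 quantiles — a convention that must be fixed for reproducibility);
  two fixed presets (`"text"`: -0.034 to 0.135; `"figure"`: -0.032 to
  0.157 nmol/L) are shipped because published analyses quote slightly
  different bands, and the discrepancy is surfaced rather than resolved
  silently;
* the remainder is **intermediate**.

A data-derived IQR band contains ~50 % of any sample by construction, so
closure checks on synthetic data use a fixed preset band instead. Deep
(> 3000 m) enhanced-negative samples whose labile Fe:Mn mole ratio falls
within 1.1 +/- 3 x 0.35 are flagged as ferromanganese-like benthic inputs.

Scattered fields (pH, DOC, siderophores) can be gridded by two-stage
piecewise-linear interpolation — vertically along each station profile to a
1 m grid, then horizontally along the great-circle track to a 10 km grid —
with no extrapolation outside the sampled envelope. The two-stage scheme
was chosen over scattered-point triangulation because transect data live on
station profiles; it reproduces support values exactly and keeps the method
fully deterministic.

Equation-style diagnostics include the Fe:C ratios of the organic pools and
the scavenging residence-time ratio tau_LPFe/tau_Part = 1 + cDFe/cLPFe;
because published discussions do not state whether such a figure is a ratio
of medians or a median of ratios, `glance()` on a transect reports both.

## Water-mass analysis (eOMPA)

`solve_mixing()` decomposes each sample into non-negative fractions of six
endmember water masses plus a remineralisation extent acting through the
Redfield vector (0, 0, -170, 1, 16, 40) for (T, S, O2, PO4, NO3+NO2,
SiO4). Parameter rows are standardised by the endmember-matrix spread (the
common eOMPA convention; configurable), the mass-conservation row is
weighted 100x the tracer rows (configurable), and the non-negative least
squares core is `pracma::lsqnonneg` with the sign-free extent split into
positive and negative parts. Noiseless convex combinations are recovered to
machine precision. The bundled endmember table is a synthetic placeholder
at hydrographically plausible values for STW, ESSW, AAIW, UCDW, PDW and
LCDW; study-specific endmembers should be supplied as a CSV.

## The synthetic transect generator

`synth_transect()` emulates a zonal section (about 72 degW to 179 degE,
250-5000 m, default 34 stations x 15 depths = 510 samples): smooth
exponential/Gaussian background fields for temperature (1.6-16 C),
salinity, total-scale pH (7.5-7.9), oxygen/AOU, DOC (39-54 umol/L,
declining with depth) and particulate phosphorus (POC staying below the
0.68 umol/L small-particle ceiling); a mesopelagic siderophore patch (up to
425 pmol/L, 400-1500 m, centred near 117 degW); and three planted iron
sources (hydrothermal ridge at 117 degW and ~2500 m, volcano at 177 degE
and ~1200 m, continental shelf at the eastern edge near the seafloor) that
carry total labile iron from a ~0.35-1.6 nmol/L background up to the
12.6 nmol/L ceiling. All randomness flows from a single integer seed, and
the global RNG stream is left untouched.

"Observations" are constructed by running the forward pathway model on the
generated conditions and emitting the predicted partition with
multiplicative lognormal noise (default sigma 5 % for the iron fields,
consistent with reported analytical precision of a few percent;
concentrations are positive and span decades, hence multiplicative).
Anomaly samples are then displaced from equilibrium by twice the enhanced
residual thresholds: dissolved excesses at saturated plume cores (where the
model must precipitate the excess, so the displacement survives in the
residual), particulate excesses with ferromanganese-like Fe:Mn in clearly
undersaturated bottom waters, and dissolved deficits at capped high-iron
samples. A parallel truth table records the generating pools and class per
sample.

What passing the closure tests does and does not show: with zero noise the
pipeline reproduces its own forward model to solver tolerance and flags
every planted anomaly — that validates the numerics and the classification
logic, not the geochemical realism of the parameter values. The generator
makes no claim of plume physics, water-mass structure, or covariances
between fields beyond the documented ranges.

## Parameter provenance and limitations

The numeric values bundled in `inst/extdata` (hydrolysis constants and
enthalpies, the ferrihydrite solubility product, NICA-Donnan Fe parameters
for marine DOM and POM, siderophore stability constants, eOMPA endmembers)
are **synthetic placeholders**: shaped like the literature sets a
practitioner would use and tuned once so that open-ocean conditions
(DFe ~ 0.2-2 nmol/L, DOC ~ 40 umol/L, pH_tot 7.5-8.0, T 1.6-16 C) yield a
field-realistic partition — most dissolved iron DOM-bound, Fe' of order
0.05-1 nmol/L capping near 1 nmol/L in cold water, occupied-site effective
affinities in the log K' ~ 17-24 range with POM about 1.6 log units above
DOM, and labile particulate iron a few percent of the dissolved pool.
They are not a critically reviewed compilation and should be replaced via
`load_thermo()` / `load_phases()` / `wm_endmembers()` with calibrated decks
for quantitative work against real data. Known limitations, by design: no
redox (Fe(II)) chemistry, no precipitation kinetics or colloid dynamics, no
surface-complexation phases for lithogenic or biogenic minerals, no
Pitzer-class activity model, no carbonate-system solving (pH is consumed,
not computed), and no more than two site groups per NICA phase.

## Problem sizes used in validation

The shipped checks run, on one CPU in a few minutes: mass-balance
conservation on 10^4 random problems across the full condition ranges;
Newton-versus-bisection agreement on 200 problems; a 510-sample zero-noise
closure transect; and 20 seeded 120-sample transects for anomaly
detectability. These sizes were chosen to exercise every solver branch
(both Donnan phases present/absent, capped and uncapped) while keeping the
default validation run quick enough to be part of routine development.
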