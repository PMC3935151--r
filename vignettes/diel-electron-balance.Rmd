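---
title: "Methods: the diel electron mass balance and its companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the diel electron mass balance and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielmat)
```

## The scientific problem

Phototrophic microbial mats alternate between an oxic daytime state, in
which cyanobacteria fix CO₂ and store it as glycogen, and an anoxic
nighttime state, in which that photosynthate is fermented to H₂ and
organic acids. Those products are the currency that couples the
cyanobacteria to accessory populations — sulfate-reducing bacteria and
filamentous anoxygenic phototrophs — living pressed against them in the
mat fabric. `dielmat` quantifies this coupling from three kinds of
measurements: concentration time series from sealed microcosms and flux
chambers, NanoSIMS isotope ratios from labeling experiments, and paired
DNA/cDNA 16S amplicon tables.

## From concentrations to area fluxes

A microcosm is an 11 mm mat core in a 14 mL serum vial with 4 mL site
water (the `mat_geometry()` defaults); a flux-chamber incubation is a
1.5 L chamber enclosing a mat area that must be configured because it is
site-specific. For each analyte the net flux over a window is computed
by **endpoint differencing**, not regression: net accumulation between
two sampling times is the quantity reported by this experimental design,
and differencing is exact for it (it is also additive over adjacent
windows and antisymmetric under window reversal, two properties the test
suite checks). The amount conversion depends on the compartment:

* headspace gases: ideal-gas conversion of ppm-by-volume at the
  configured temperature and pressure (defaults 298.15 K, 1 atm — the
  incubation conditions are not part of the data files, so they live in
  the geometry);
* liquid analytes: concentration × liquid volume;
* chamber water: concentration × chamber volume, normalized by chamber
  area rather than core area.

The sign convention throughout: **negative flux = uptake into the mat**,
so daytime DIC fluxes are negative. Dissolved H₂ in the 4 mL liquid
phase is neglected in the headspace conversion; at these vial geometries
the partitioning correction is far below replicate noise, but it is a
known, one-sided bias.

Replicate aggregation reports the mean and the *sample* SD (n − 1): with
typical n = 6, the small-sample correction matters. Treatment effects
are tested with the unpaired two-tailed Student's t-test
(pooled variance) at α = 0.05; Welch is available via `var_equal =
FALSE`.

## The electron balance

All flux/storage terms are placed on a common basis of **electron
equivalents**, moles × electrons transferable per mole. The default
("paper") coefficients follow total-charge-state bookkeeping:

| species | e⁻ per mole |
|---|---|
| fixed inorganic C | 4 per C |
| glycogen | 24 per glucosyl |
| acetate | 8 |
| formate | 1 |
| propionate | 13 |
| H₂ | 2 |

Strict redox bookkeeping for full oxidation to CO₂ would give formate 2
and propionate 14; `electron_coefficients("redox")` provides that
preset, and individual values can be overridden. The default preset is
the one under which the benchmark table's printed electron column is
internally consistent.

The diel flux of a day/night pair is the mean of magnitudes,
(|day| + |night|)/2 — the day's fixation and the night's release are two
sides of the same diel budget. Nighttime-only products enter with their
night flux directly. With net fluxes from intact (control) mats and
total fluxes from homogenized (disrupted) mats:

* **% fixed e⁻ fermented** = 100 · Σ total-product e⁻ / fixed-C e⁻;
* **% fixed e⁻ to accessory microbes** = 100 · (Σ total e⁻ − Σ net e⁻) /
  fixed-C e⁻.

Two denominators were possible for these percentages: the DIC-derived
fixed-carbon electron flux or the glycogen-storage electron flux. The
package uses the DIC route — glycogen storage measurements carry an SD
larger than their mean in this design — and reports the glycogen row
informationally, excluded from both percentages. Since disruption cannot
be assumed to eliminate consumption entirely, the total fluxes are lower
bounds and so are both percentages.

### Uncertainty propagation

Three rules are offered because the propagation behind reported balance
tables of this kind is rarely stated exactly:

* `mean_sd` (default): the diel SD is the arithmetic mean of the phase
  SDs, and all propagation is linear with fully correlated errors
  (row e⁻ SD = coefficient × diel SD; ratio SD = ratio × sum of relative
  SDs). This is the conservative choice for replicate spreads that share
  systematic structure between day and night, and it is the rule under
  which the benchmark table's combined SDs reproduce exactly.
* `quadrature`: independent-error propagation,
  √(sd_d² + sd_n²)/2 for diel SDs and root-sum-square relative errors
  for ratios.
* `monte_carlo`: a parametric bootstrap — phase fluxes drawn from
  normal distributions with the stated means and SDs, the table
  recomputed per draw (default 10⁴ draws, deterministic given the
  seed). This is the reference when the ratio statistics are too
  nonlinear for either closed form.

Internal computation is at full precision; only the report layer rounds,
half away from zero, to 1 decimal (base R's `round()` rounds half to
even, which does not match how such tables are conventionally printed).

## NanoSIMS isotope enrichment

Carbon is measured as C₂⁻ dimers. With atom fraction
f = ¹³C/(¹²C + ¹³C) and binomial pairing, P(¹³C¹²C)/P(¹²C¹²C) =
2f/(1 − f) = 2r, so the measured count ratio m recovers the atom ratio
**exactly** as r = m/2 — the dimer correction is an identity, not an
approximation, as long as only these two channels are used (¹³C₂ counts
are second order in f and are not part of the measurement model).
δ¹³C = (r/R_VPDB − 1)·1000 with R_VPDB = 0.0112372; δ ≤ −1000 ‰ is
rejected as it would imply a non-positive atom fraction.

Group comparisons use a **normality-gated test**: Shapiro–Wilk on each
group, and if either p < 0.05 the two-sample Wilcoxon rank-sum test is
used, otherwise Student's t. Zero-variance groups, on which Shapiro–Wilk
is undefined, are routed to the Wilcoxon path; with heavy ties the
Wilcoxon p-value uses the normal approximation so integer-valued data
cannot error. Outliers are flagged by the 1.5×IQR rule with quartiles by
linear interpolation (R type 7; Tukey hinges differ slightly and the
convention behind any given box plot is usually unstated) and are
**never removed** — the flag exists for plotting.

## Community profiles

Richness is computed per sample with repeated rarefaction to a common
depth (multivariate hypergeometric subsampling via `vegan::rrarefy`),
reporting the mean and SD over iterations of observed richness, Chao1,
and ACE. Chao1 uses the classic form S_obs + F1²/(2 F2) when doubletons
exist and the bias-corrected form S_obs + F1(F1 − 1)/(2(F2 + 1)) only
when F2 = 0 — legacy amplicon pipelines of the relevant era report the
classic form, and which variant a given published table used is
generally unknowable, so the choice is fixed and documented rather than
guessed per dataset. ACE uses the standard coverage estimator with rare
threshold 10 (configurable), falling back to Chao1 with a warning when
every rare individual is a singleton (coverage zero).

Expression ratios (cDNA:DNA relative abundance per taxon, genus level by
default) are computed on **full, unrarefied** libraries: the ratio of
relative abundances is scale-free, so rarefaction would only add noise.
Taxa at ≤ 1 % DNA relative abundance are excluded from ratios (retained
in the output, flagged `included = FALSE`) because their denominators
are too poorly sampled to interpret; this also automatically excludes
taxa seen only in cDNA. Taxonomy strings are opaque ordered labels
(domain-first, semicolon-separated); truncated strings pool into
`unclassified`.

## What the synthetic generator does and does not emulate

`scenario_config()` fixes the ground truth of a simulated experiment.
The defaults are the measured flux scale of an intertidal *Lyngbya*-mat
study: net nighttime fluxes (mmol m⁻²) acetate 14.9, formate 8.3,
propionate 2.4, H₂ 0.83; total (disrupted) fluxes 28.0, 10.0, 6.6, 1.77;
daytime DIC flux −121.4 and nighttime +77.5; glycogen +21.2 by day and
−31.6 by night. Treatments: `disruption` *is* the total-flux condition;
`molybdate` doubles H₂ (sulfate-reducer inhibition); `dcmu` suppresses
H₂ (×0.3) and raises net acetate (×1.5), the observed signature of
photosystem-II shutdown; `nh4cl` changes nothing (N-fixation suppression
does not affect constitutive fermentation). Defaults chosen once from
the qualitative behavior of the corresponding manipulation experiments.

Replicate noise is multiplicative log-normal on per-replicate production
rates, parameterized by a CV (default 0.1, the scale of replicate error
bars in such experiments), with the mean-one parameterization
σ² = log(1 + cv²), μ = −σ²/2 so the expected flux is unchanged.
Concentrations are therefore positive by construction. The photoperiod
defaults to 12 h/12 h with time in hours since dawn; sampling defaults
to every 6 h. The chamber area (0.005 m²) and dawn DIC baseline
(5 mmol L⁻¹) are generator conveniences chosen so chamber
concentrations stay positive at the default flux scale.

The generator emulates *measurement structure*, not mat physiology: no
reaction network, light field, or diffusion; product accumulation is
linear within the night; destructive liquid sampling is idealized as a
continuous series; day/night transitions are sharp. A pipeline that
passes round-trip tests against this generator is verified as an
*analysis*, i.e. it recovers the fluxes that generated the data — that
says nothing about whether a real mat's fluxes are linear or its noise
log-normal.

OTU tables are drawn multinomially from a log-normal rank-abundance
profile (σ_log = 1.5, a few dominant taxa), with cDNA mass concentrated
on the dominant OTUs by a configurable dominance factor; NanoSIMS spots
are Poisson counts with the ¹³C¹²C channel mean set to 2r × the ¹²C¹²C
mean.

## Numerical choices and degenerate inputs

* Every stochastic operation takes an explicit seed and restores the
  global RNG state (`withr::with_seed`); identical seeds give
  byte-identical pipeline outputs.
* Net-flux windows interpolate endpoint concentrations linearly when
  they fall between samples; windows need ≥ 2 samples and must lie
  within the series range.
* A single replicate reports SD 0 with n = 1 recorded, rather than NA,
  so downstream propagation stays defined.
* `total < net` for a species is a warning, not an error: with real
  replicate noise the inequality can invert, and the balance should
  still be computable; the generator's configuration, by contrast,
  enforces total ≥ net strictly.
* Monte-Carlo propagation requires ≥ 1000 draws; below that the SD of
  an SD is too large to report.

## Problem sizes in the test suite

The suite verifies parameter recovery through the full
simulate → flux → balance pipeline noise-free (exact recovery of the
configured percent-fermented at ground truths 20, 50, and 81.2 %) and at
CV 0.1 with 6 replicates over 100 seeds (the mean estimate centres on
the truth within 2 empirical SDs). Isotope unbiasedness is checked with
50 binomial simulations of 10⁷ ions at f = 0.0111, 0.02, and 0.1 (1 ‰
tolerance on the mean recovered δ); rarefaction is checked against the
hypergeometric mean over 10⁴ draws at 3σ; Chao1 and ACE are checked
against independently coded formula oracles on 50 random tables and
against `vegan::estimateR` where the variants coincide. These sizes make
the statistical assertions sharp while keeping the default test run
fast.

## Known limitations

* The electron balance attributes the net/total gap entirely to
  accessory consumption; incomplete disruption makes both percentages
  lower bounds.
* Headspace fluxes ignore dissolved-gas partitioning into the small
  liquid phase.
* The percentage SDs depend strongly on the propagation rule (correlated
  linear vs quadrature vs Monte Carlo can differ by ~50 % on realistic
  inputs); all three are reported precisely because the choice is a
  modelling decision, not a computation.
* Richness estimates from clustered, denoised amplicon data are
  pipeline-dependent; Chao1/ACE here are estimator implementations, not
  a re-creation of any particular vendor pipeline's numbers.
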