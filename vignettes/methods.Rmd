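---
title: "Quantifying C and N transfer from diazotrophs to epibionts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying C and N transfer from diazotrophs to epibionts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simsTransfer)
```

# The problem

Filamentous, heterocystous cyanobacteria such as *Aphanizomenon* and
*Nodularia* fix N₂ and CO₂ during summer blooms, and part of that freshly
fixed material is released and taken up by bacteria attached to the
filaments (epibionts). Quantifying that transfer at the single-cell level
requires a chain of measurements and models: dual stable-isotope labelling
(¹³C-bicarbonate and ¹⁵N₂) of hand-picked colonies, nanoSIMS ion imaging of
individual cells, conversion of per-cell isotope enrichment into element
uptake, and a partition model apportioning the total fixed C and N of a
cyanobacterial cell between the cell itself and its attached epibionts.
This vignette describes each model in the chain, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

# Imaging model

A nanoSIMS acquisition rasters a Cs⁺ beam over a 15 µm × 15 µm area and
records, simultaneously and repeatedly, secondary-ion count images of
¹²C⁻, ¹³C⁻, ¹²C¹⁴N⁻, ¹²C¹⁵N⁻, ³¹P⁻ and ³²S⁻ — typically 40+ planes of
256 × 256 px. Counts are small integers per pixel per plane and are treated
as independent Poisson draws; the stage drifts slowly during the tens of
minutes of acquisition.

**Drift correction.** Each plane of the reference channel (¹²C¹⁴N⁻ by
default — the strongest biomass signal) is registered against plane 1 by
maximizing the integer-shift cross-correlation within a ±10 px window
(computed via FFT), and all channels of that plane are shifted by the
negated offset with zero fill. Design choices, made for bit-exact
reproducibility: integer shifts only (no interpolation, so Poisson counts
stay integer), plane 1 as the fixed registration target, zero-fill at the
border. A flat (degenerate) reference plane registers as offset (0, 0) with
a flag, and an optimum sitting on the window edge is flagged as possible
unbounded drift. Ties in the correlation are broken toward the smallest
offset magnitude.

**Ratios.** Per cell (ROI), ratios are computed as ratio-of-sums
(Σminor/Σmajor over the accumulated ROI), not as means of per-pixel ratios:
for Poisson counts the ratio of sums is the lower-variance, less biased
estimator, and per-pixel ratios are undefined wherever the major isotope
count is zero. The counting-statistics standard error is
SE = r·√(1/N_minor + 1/N_major). Cell length and width come from the
eigenvalues of the ROI pixel-coordinate covariance (4√λ × pixel size), i.e.
the moment-equivalent ellipse.

**Detection limits.** Ratios must be *strictly above* 0.0117 (¹³C/¹²C) and
0.0043 (¹⁵N/¹⁴N) to count as enriched; these instrument-calibration limits
are configuration inputs, not derived quantities. The ¹⁵N/¹⁴N ratio is
reported directly as the ¹²C¹⁵N⁻/¹²C¹⁴N⁻ ion ratio, with no molecular-ion
correction factor.

**Segmentation** (`segmentEpibionts`) is advisory only: Otsu threshold on
the CN⁻ (or S⁻) channel, connected components, size filter. Masks drawn by
the analyst (mirroring SEM-correlated manual ROIs) are always
authoritative; touching cells may merge and the function makes no attempt
to split them.

# From enrichment to rates

All isotope algebra is in atom fractions, A = r/(1+r). The relative
activity

a = (A_cell − A_na) / (X_I − A_na)

uses atom-fraction excesses (APE form). Whether the original calculation
used ratio excess or atom-fraction excess differs by < 1 % at the labelling
levels involved (≤ 12 atom%); the APE form is declared as this package's
contract. Negative excess — measurement noise below natural abundance — is
clipped to 0 and flagged, never discarded, so below-detection cells remain
countable.

Defaults: natural abundances A_na(¹³C) = 0.0111, A_na(¹⁵N) = 0.00366
(standard terrestrial values; overridable by a measured control), source
pools X_I(C) = 0.119, X_I(N) = 0.018 (the incubation-water labelling of the
single-cell experiments), incubation t = 1 day.

The growth-rate model assumes isotopes distribute evenly between daughter
cells at division, giving µ = a·2/t (day⁻¹) — exactly a factor 2 over the
naive turnover rate. Cellular element contents use the prolate-spheroid
biovolume V = (π/6)·L·W² and a biovolume→C conversion. The conversion is a
configuration input: the default is a constant 250 fg C µm⁻³ (a mid-range
literature value for small heterotrophic bacteria), with a power-law hook
`a·V^b` because no specific numeric factor is universal. N content follows
from the molar C:N ratio via atomic masses (12.011, 14.007); the epibiont
default C:N of 5.0 reflects the SEM-EDS observation that epibionts sit
slightly below Redfield (6.625), while cyanobacteria use Redfield.

# Partition model

The epibiont share of total fixed C (or N) per cyanobacterial cell is

share = Ē·n̄ / (Ē·n̄ + C̄) × 100

computed from *medians*: the median per-epibiont assimilation, the median
epibionts-per-cell count, and the median per-cyanobacterium assimilation.
Means are reported alongside but never drive the share — single-cell rate
distributions are right-skewed and a few hot cells would otherwise dominate.
The share's uncertainty is a seeded nonparametric bootstrap over both cell
cohorts (resample cells, recompute medians and the share; SE = SD of the
bootstrap shares; 2000 resamples by default). A one-cell cohort cannot be
resampled and yields SE = NA with a warning. This bootstrap is this
package's choice; "median ± SE" can be propagated in several ways and no
single recipe is canonical.

The **older-biomass scenario** assumes the material released by the
cyanobacteria is not freshly fixed (at source-pool labelling) but carries
the isotopic composition of the cyanobacterial biomass at the end of the
incubation. Implementation: the cyanobacterial end-point atom fraction
replaces X_I in the activity formula. Since the end point is always less
enriched than the source pool, this always raises the inferred epibiont
activity — the freshly-fixed reading is the conservative lower bound. The
identity a_alt / a = (X_I − A_na)/(A_end − A_na) holds exactly and is
tested to 1e-12.

# Bulk-rate models

**Isotope mass balance.** rate = (A_end − A_na)/(A_source − A_na) × pool /
t. Linear in the excess and in the pool; the generator implements exactly
the inverse map, and the noiseless round trip is tested to 1e-10.

**³³P radiotracer uptake.** The fraction of added tracer incorporated is
f(t) = (filter counts − mean control counts)/total counts, all
decay-corrected (counts × 2^(elapsed/t½), t½ = 25.4 d) to a common
reference date — the result is invariant to that date, and detector
efficiency cancels in the counts ratio. The uptake rate is the per-replicate
OLS slope of f(t) over the linear window times the ambient DIP
concentration, summarised as mean ± SD over replicates. Design choices
where the protocol leaves room: the two controls (filtered, heat-killed)
are averaged per time point; per-replicate slopes are fitted rather than
pooling all points into one regression; the ~0.02 nmol L⁻¹ of DIP carried
by the tracer itself is ignored (≤ 0.1 % of ambient). The advisory
`linearWindow` extends the fitted prefix point by point while R² stays
≥ 0.98 and the next residual stays within 3 RMSE; an explicit user window
always overrides it.

# The synthetic-data generator

The generator exists so that every stage has inputs with known ground
truth. It emulates:

* **Ion stacks**: per-cell elemental ion yields split between
  isotopologues by the cell's true atom fraction (major: yield × (1 − A),
  minor: yield × A), independent Poisson counts per pixel/plane/channel,
  integer-pixel random-walk drift applied *after* the draws (so the same
  seed with zero drift yields the exact drift-free counterpart — this is
  what makes the drift-correction oracle bit-exact), and a low off-cell
  background (1 % of cell yields, the residue of gold-sputtered filters).
* **Colony scenes**: one cyanobacterial cell crossing the field plus
  epibionts packed without overlap in lanes along the filament, long axis
  parallel to it. Non-overlap is deliberate: the analysis attributes pixels
  to single cells, mirroring the restriction to single/double epibiont
  layers; a field asked to hold more cells than fit is an error rather
  than a silent overlap. Epibiont volumes are log-normal with median
  0.84 µm³ (the observed median cell size), SD 0.5 µm³, truncated to
  0.2–3 µm³.
* **Radiotracer series**: linear tracer incorporation at rate/DIP per hour
  until the DIP pool is exhausted (t* = DIP/rate), then a plateau;
  controls carry only an unspecific-binding fraction; Poisson counting
  noise; decay by the counting-day delay.
* **Bulk incubations**: end-point atom fractions from the exact inverse of
  the mass balance plus Gaussian measurement noise.

**Scenario presets.** The four `colonyScenario` presets encode the study
conditions. Epibiont relative-activity medians and SDs are the reported
single-cell values (C/N: *Aphanizomenon* in situ 0.03/0.03, +DIP 0.03/0.07;
*Nodularia* in situ 0.08/0.08, +DIP 0.05/0.05), drawn from a log-normal
centred on the median with dispersion matched to the SD (activities are
positive and right-skewed). Epibionts-per-cell medians are 2
(*Aphanizomenon*) and 20 (*Nodularia*). *Aphanizomenon* cyanobacterial
activities follow from the reported growth rates (a = µ·t/2: C 0.255→0.19,
N 0.11→0.145 across in situ→+DIP) with 8 × 5 µm cells. The *Nodularia*
cyanobacterial parameters are not printed anywhere and were calibrated
once, jointly, so the emergent behaviour matches the reported outcomes: in
situ activities C 0.162 / N 0.154 and +DIP 0.331/0.213 with 7.4 × 4.6 µm
cells (V ≈ 82 µm³), which reproduce in-situ epibiont shares near 8–14 %,
+DIP shares near 3–6 %, an older-biomass N share near 50 %, and the roughly
doubled growth under +DIP. These are generator settings, not measurements;
they define the simulation's study conditions and are not tuned per run.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: instrument dead time and quasi-simultaneous
arrival, mass interferences, within-incubation enrichment kinetics
(end-point atom fractions are specified directly), epibionts embedded in
multi-layer mucilage, spatial clustering of epibionts (cells are packed in
lanes, not clustered near heterocysts), and SEM correlation (masks are
taken as given).

# Numerical choices and degenerate inputs

* Pixel coordinates are 0-based in concept, row-major; masks are integer
  label images with 0 = background, stored as 16-bit TIFF (lossless for
  labels and counts ≤ 65535).
* Cross-correlation registration uses circular FFT correlation restricted
  to the search window; within-window integer drifts of signals away from
  the border behave identically to linear correlation.
* An ROI with zero major-isotope counts is invalid (excluded downstream);
  zero minor counts give ratio 0 with a low-count flag and no SE.
* Mann-Whitney comparisons (two-sided throughout, α = 0.05, no
  multiple-testing correction — comparisons are reported one at a time) use
  the exact permutation distribution when both groups have ≤ 8
  observations and no ties, else the normal approximation with tie and
  continuity corrections; the implementation wraps `stats::wilcox.test`
  and is cross-checked in the tests against exhaustive enumeration.
* All stochastic components (generators, bootstraps) take explicit seeds;
  identical configuration and seeds give byte-identical pipeline outputs.

# Problem sizes

The test suite exercises the chain at reduced sizes chosen to keep the
statistics meaningful: ratio-recovery cohorts at ≥ 10⁴ major-isotope counts
per cell over 200 seeded runs; the drift oracle over every integer offset
in [−5, 5]²; end-to-end scenario runs at 128 × 128 px, 12 planes and 36
epibionts; radiotracer recovery over 100 seeded five-replicate designs. The
acceptance script runs the scenarios at the full 256 × 256 px and 40
planes with 44 epibionts per field.

# Known limitations

* The partition is not a mass balance: C and N lost to the medium or taken
  up by non-attached, mucilage-embedded microorganisms are invisible to
  it, so shares are conservative lower bounds on release.
* Rates are not corrected for isotope loss during sample preparation.
* The biovolume→C conversion and the cyanobacterial cell contents dominate
  the absolute assimilation scale; both are configuration inputs, and the
  shares are invariant only to *common* rescaling of epibiont and
  cyanobacterial assimilation.
* With a single cyanobacterial cell per field, the share SE reflects only
  epibiont-cohort resampling and is reported as NA; pooling fields is the
  intended route to a defensible uncertainty.
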