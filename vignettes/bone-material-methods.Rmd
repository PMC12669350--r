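---
title: "Bone material methods: qBEI calibration, BMDD, OLS morphometry and Raman metrics"
author: "bonemat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone material methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonemat)
```

## Scope

`bonemat` implements a tissue-level bone material analysis pipeline: the
calibration of quantitative backscattered electron (qBEI) images to local
calcium concentrations, the bone mineralization density distribution (BMDD)
and its five derived parameters, osteocyte lacunae section (OLS)
morphometry, Raman band-ratio bone-quality metrics, and the assumption-gated
statistical workflow used to compare patient cohorts against healthy
reference data. Because real biopsy images and spectra are not
distributable, the package ships a synthetic generator that produces
phantoms and spectra with analytic ground truth; every method is validated
against that truth in the test suite.

## qBEI calibration

Backscattered electron intensity grows with the local mean atomic number
$\bar Z$ of the imaged surface, and in mineralized bone $\bar Z$ is
dominated by calcium. The calibration is a composition of two affine maps:
grey level $\to \bar Z$, anchored by the measured grey values of carbon
($Z = 6$) and aluminum ($Z = 13$) standards, and $\bar Z \to$ wt% Ca,
anchored at the osteoid composition ($\bar Z_{ost} = 7.0$, 0 wt% Ca) and
stoichiometric hydroxyapatite ($\bar Z_{HA} = 14.06$, 39.86 wt% Ca). The
second pair of anchors is a convention of the method rather than a measured
quantity; both are arguments of `fit_calibration()` so a laboratory using
different constants loses nothing. The composed map is affine with positive
slope; greys that map below 0 wt% (embedding resin, background) are clamped
to zero, so the full map is non-decreasing and strictly increasing above the
osteoid anchor. With the default anchors one 8-bit grey step corresponds to
about 0.198 wt% Ca, and any representable calcium value survives the
Ca $\to$ grey $\to$ Ca round trip within half of that step.

The mineralization threshold separating matrix from voids and osteoid
defaults to 5.2 wt% Ca everywhere — the same boundary the OLS segmentation
uses — so "mineralized bone area" means one thing across the package.

## BMDD

`compute_bmdd()` histograms all mineralized pixels of a compartment
(cancellous or cortical) on a fixed grid of 0.17 wt% Ca bins over
[0, 45] wt% and normalizes to 100% of mineralized bone area. The five
parameters from `derive_params()`:

* **CaMean** — frequency-weighted mean of the bin centers; agrees with the
  raw pixel mean within half a bin by construction.
* **CaPeak** — center of the maximum-frequency bin; ties resolve to the
  lowest-calcium bin for determinism.
* **CaWidth** — full width at half the global maximum, with the crossing
  points interpolated linearly between bin centers; on multimodal curves the
  *outermost* crossings are used, so the value describes the whole
  distribution's spread at half height.
* **CaLow / CaHigh** — percent of mineralized area below/above the 5th/95th
  percentile of a pooled healthy reference distribution.

`pool_reference()` pools per-subject curves with equal weights — each
subject is one statistical unit, regardless of sectioned area — and computes
the percentile cutoffs on the pooled cumulative distribution with linear
interpolation inside bins. `derive_params()` integrates partial bins with
the same interpolation, which makes the definition self-consistent: CaLow of
the pooled reference against its own cutoffs is exactly 5%. Whether the
original reference cutoffs were derived from pooled pixels or pooled
per-subject curves is not decidable from the published descriptions; equal
subject weighting was chosen because it matches how the cohort statistics
treat subjects, and the choice only matters when sectioned areas differ
grossly.

No smoothing is applied to the histogram before parameter extraction.

## OLS morphometry

`segment_ols()` thresholds the calibrated image (void: Ca strictly below
5.2 wt%), groups void pixels into 8-connected components (8-connectivity
preserves thin, diagonally stepping sections), fills internal holes (a
lacuna section is simply connected; rare bright specks inside a void are
artifacts), and applies three filters, each configurable:

* components touching the image border or the compartment-mask border are
  discarded — they cannot be told apart from marrow space or resin;
* area outside [5, 200] µm² is discarded (vascular channels and cracks
  above, noise below);
* fitted-ellipse aspect ratio above 10 is discarded (cracks).

The aspect ratio is the square root of the eigenvalue ratio of the pixel
coordinates' central second-moment matrix — the equivalent-ellipse
convention of ImageJ and `regionprops`. It is exact for the pixel set but
inherits that set's pixelation: a center-rasterized ellipse with a 4 px
minor half-axis has a *discrete* moment ratio about 8% above the continuous
one (exact enumeration gives 3.242 for half-axes 12 and 4 versus the
continuous 3), and the bias decays roughly with the inverse minor-axis
length (24×8: +3%, 36×12: +1%). Tests therefore pin the estimator to the
exact discrete oracle at coarse scales and to the continuous ratio via
multigrid convergence. Additive eigenvalue corrections (pixel-square +1/12,
half-pixel dilation) were evaluated and rejected: any constant large enough
to cancel the coarse-scale bias also drags genuinely degenerate thin
objects below the aspect-ratio filter.

The perimeter is measured on the traced 8-connected outer contour (Moore
neighborhood) with step weights 1 and $\sqrt2$, plus half the signed
exterior angle at every turn of at least 90° that sits between straight runs
of length ≥ 2 pixels. The correction gives sharp polygon corners the
half-pixel offset between boundary pixel centers and the true outline, while
staircase caps of smooth curves — where the chain's inherent excess already
compensates that offset — are left alone. On test shapes this lands
digitized circles at +4–5%, pixel rectangles at −3% and ellipses within 5%
of their analytic perimeters. Degenerate contours (fewer than three traced
points) fall back to the exposed-edge perimeter, so a single pixel reports
$4s$ for pixel size $s$.

`summarize_ols()` computes the five per-sample parameters with the
denominator (mineralized matrix area + total OLS area) of the published
definitions: OLS-density (1/mm²), OLS-porosity (%), and the per-sample
medians of area, perimeter and aspect ratio.

## Raman metrics

Spectra are trimmed to 350–1800 cm⁻¹ and corrected with a rubber-band
baseline: the piecewise-linear interpolation of the lower convex hull of the
spectrum graph. Two implementation details matter:

* **Iterations.** The published protocols quote "five iterations" of the
  rubber band. With a convex-hull residual the loop is a fixed point after
  the first pass — the residual is non-negative with zeros at the hull
  support points, so the next hull is the zero line. The `iterations`
  argument exists for protocol compatibility and is documented as inert
  beyond the first pass.
* **Noise.** The hull of a *noisy* graph threads the lowest noise
  excursions and sits 2–3 noise SD below the true background, which inflates
  narrow band areas by tens of percent. The hull is therefore computed on a
  running-mean-smoothed copy (default width 31 grid points, chosen by
  scanning 11–41 on synthetic grids: wide enough to suppress anchor noise,
  narrow enough not to leak band intensity into the inter-band valleys) and
  subtracted from the raw spectrum. With `smooth = 0` the exact raw-graph
  hull is available.

The five metrics of `compute_params()` use trapezoidal band areas with
linear edge interpolation: mineral/matrix = area(ν₂PO₄ 410–460) /
area(amide III 1215–1300); GAG = area(CH₃/proteoglycan 1365–1390) /
area(amide III); nanoporosity = area(embedding 494–509) / area(amide III);
Pyd = height at 1660 cm⁻¹ / area(amide I 1620–1700); MMC = 1 / FWHM(ν₁PO₄
930–980) with linearly interpolated half-maximum crossings. The Pyd height
is taken from the baseline-corrected spectrum, consistent with the area
denominators (published descriptions do not say whether raw or corrected
height was used). All five are invariant under global intensity scaling.

`aggregate_statistical_units()` drops ROIs flagged `single-label` or
`overlapping-label` and averages the rest per (subject, compartment,
position); each average is one statistical unit downstream.

## Statistics

Every comparison is gated at α = 0.05 by Shapiro–Wilk normality per group
and Brown–Forsythe (median-centered Levene) homogeneity across groups — the
convention of the classical biomedical statistics packages, which do not
publish their gate level. Two groups: pooled t-test if both gates pass,
otherwise two-sided Mann–Whitney. Three or more: one-way ANOVA with
Holm–Šidák-adjusted pairwise t-tests on the pooled error, otherwise
Kruskal–Wallis with Dunn's rank comparisons (tie-corrected,
Holm–Šidák-adjusted); post-hoc tests run only after a significant omnibus
test. Zero-variance groups route to the rank test with a warning instead of
crashing. Raman outcomes use a two-way ANOVA (group × position) with type-II
sums of squares — main effects are then not distorted by imbalance — and
within-position pairwise contrasts on the cell-mean model, Holm–Šidák
adjusted within each position family. With a single observation per cell the
interaction is dropped and only main effects are reported. Simulated type-I
error of the gated two- and three-group procedures at n = 16 per group stays
within [0.035, 0.065] over 2000 replicates in the test suite. No
multiplicity correction is applied across outcome families, matching the
published analysis style.

## Synthetic generator

Phantoms are Gaussian calcium fields (default mean 21 wt%, SD 1.5 wt% —
normally mineralized adult matrix; the reference cohort uses mean
22.2 wt%, between-subject SD 0.55, within-subject SD 1.5) with voids carved
as center-rasterized ellipses; ground truth stores the analytic area πab and
axis ratio a/b. Cohorts draw per-subject latent cancellous/cortical means
from a bivariate normal with correlation 0.9, emulating the tight
within-subject coupling of compartments, and the affected-subgroup default
shifts latent means down by 1.5 wt% (a strong mineralization defect at the
scale of reference variability). Spectra are sums of Gaussian/Lorentzian
bands over a convex fluorescence polynomial plus white noise, with
closed-form (erf/arctan) metric truths.

What the generator does *not* emulate — and what passing tests therefore do
not certify on real data: spatially correlated mineralization (bone packets,
cement lines; a low-calcium cement-line mode exists but is off by default),
partial-volume grey levels at void boundaries, perilacunar hypomineralized
halos, detector noise and drift, cosmic spikes (the optional despike filter
defaults off because remeasurement is the standard remedy), and overlapping
Raman bands requiring deconvolution.

Problem sizes in the tests and acceptance script — 500–600 px phantoms,
10,000–20,000 pixels per simulated subject, 25-subject references, 2000
statistical replicates, 60-cohort correlation runs — were chosen so the
whole suite validates every claim in a couple of minutes on one CPU while
keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

2D section morphometry only (no stereological 3D recovery of lacunar
volume); no canalicular analysis; histogram-based BMDD parameters inherit
the 0.17 wt% bin resolution; the perimeter and aspect-ratio estimators carry
the documented pixelation biases at very small object sizes; the rubber-band
baseline assumes a background that is convex on the scale of the inter-band
valleys.
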