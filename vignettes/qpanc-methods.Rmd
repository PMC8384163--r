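---
title: "Methods: pancreas quantitative-MRI mapping and multisite reproducibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pancreas quantitative-MRI mapping and multisite reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpanc)
```

## Scope and data model

`qpanc` implements the processing chain of a harmonized multisite pancreas
MRI protocol: parametric mapping (ADC, T1, MTR), contour morphometry, the
reproducibility statistics of a travelling-volunteer / travelling-phantom
design, and sample-size projection.  All images are 3D axial volumes
(`image_volume`) with voxel centers at `origin + (index − 1) × spacing`
millimetres, 1-based indices, and a single invalid-value sentinel (`NA`)
that propagates through every operation.  Structures are delineated by
per-slice closed polygons (`contour_stack`) in the same millimetre frame.
Alignment between series of one session is assumed to be translation-only
(coplanar axial stacks); rotational registration is deliberately out of
scope, and volumes carry a `space` label so that accidental mixing of
frames errors out instead of silently resampling.

## Parametric mapping

**ADC.**  The two-point monoexponential solution
`ADC = ln(SI(b_low)/SI(b_high)) / (b_high − b_low)` is exact for two
b-values, so no iterative fit is involved.  The standardized pair is
(200, 800) s/mm²; using (0, 800) admits the perfusion-sensitive
low-b regime and is provided as the non-standardized variant.  Voxels with
non-positive signal at either b-value are invalid; voxels with a negative
estimate are censored from the map but counted in the diagnostics, so ROI
summaries can report censoring instead of absorbing a clamping bias.

**T1 (variable flip angle).**  The spoiled-gradient-echo steady state
`S(α) = S0 sin(fα)(1 − E)/(1 − E cos(fα))`, `E = exp(−TR/T1)`, is fitted
per voxel by least squares over the acquired flip angles (defaults 4°–20°
in five steps, TR = 4.6 ms), with the flip-angle correction factor `f`
fixed from a B1 map.  Echo-time decay is neglected (TE ≪ T2*), matching
the acquisition's short echo time.  The fit is initialized by the
linearized regression of `S/sin(fα)` on `S/tan(fα)` (slope `E`), which is
exact on noiseless data, and refined by a damped Gauss–Newton iteration on
`(S0, E)` — vectorized across voxels, with backtracking halving so the
residual never increases, relative parameter tolerance `1e-8`, and at most
200 iterations.  T1 is constrained to (0, 10000] ms; boundary-pinned,
non-convergent, or under-determined voxels (fewer than two valid frames)
are invalid with per-reason counts in the diagnostics.  Because `S0`
absorbs any multiplicative scanner gain, T1 estimates are gain-invariant;
the tests check this at gains 0.5–10.  B1 maps acquired on coarser slices
are regridded to the series grid by trilinear interpolation before
fitting — transmit fields are smooth, so interpolation is safe.

**MTR.**  `(SI_off − SI_on)/SI_off` per voxel; voxels with non-positive
`SI_off` are invalid.  Noisy estimates outside [0, 1] are kept (censoring
them would bias ROI means) but counted.

## Morphometry

Volume is the slice-summation rule: Σ(polygon area) × slice distance,
with area from the shoelace formula; the slice distance is thickness plus
gap (4 mm for the anatomical series).  The surface-area-to-volume ratio
uses the open-tube construction — Σ(perimeter) × slice distance, divided
by volume, with no end caps — because the downstream reproducibility
statistics are defined on exactly this estimator; it underestimates a
closed surface, but consistently so, and CVs are invariant to such
consistent scale conventions.  The ratio is computed in 1/mm and reported
in 1/cm in `compute_scan_measures` (values near 0.1/cm match the packaged
study table's convention; the choice is recorded in the value's units
attribute and cancels in every CV).  ROI transfer follows the protocol's
re-gridding rule: contours are rasterized directly at each parametric
map's own grid by center sampling (even-odd rule, boundary centers counted
inside, a deterministic convention for edges shared between neighboring
voxels), rather than resampling a high-resolution mask.  The hepatic ROI
is an explicit placement — a 4 cm² circle (radius 11.28 mm) on one slice —
because vessel avoidance is the analyst's judgement, not an algorithmic
one.

## The digital phantom

The generator produces digital analogues of the study's calibration
objects with known truth, which is what every closure test in the package
is run against:

* **Vial phantom** (`make_vial_phantom_truth`): four T1 vials at the
  prescribed 500/1000/1250/1500 ms, an ice-water vial with ADC
  1.1 × 10⁻³ mm²/s, a macromolecular vial (default MTR 0.35) and an oil
  vial (default fat fraction 0.95), cylinders in a water background on the
  mapping grid (default 128 × 104 × 24 at 3 × 3 × 4 mm).  Default signal
  scale S0 = 1000.
* **Pancreas object** (`make_pancreas_truth`): a connected, curved,
  tapered tube of elliptical cross sections swept along a smooth in-plane
  C-curve over ≥ 10 slices — a stylized organ, since the study's printed
  organ geometry is not available.  In-plane axes are iteratively rescaled
  until the voxelized volume is within 2% of the request (default 89 ml,
  the reference volume of the study's organ phantom); the per-slice
  ellipse boundaries double as the digital stand-in for radiologist
  tracings.
* **Transmit field** (`simulate_b1_field`): a sum of six low-frequency
  cosine components with seed-determined directions and phases,
  normalized so the deviation from 1 is bounded by `amplitude`.
  Coefficients depend only on the seed, never the grid, so coarse
  simulation plus regridding agrees with direct fine-grid evaluation — the
  property that justifies interpolating measured B1 maps.  The default
  amplitude of 0.1 is a typical abdominal transmit deviation at 3 T; the
  study scanners' actual deviation is not characterized, so this is an
  explicit, exposed choice.
* **Noise** (`add_rician_noise`): magnitude-MRI Rician noise,
  `sqrt((v + g₁σ)² + (g₂σ)²)`, not Gaussian — the distinction matters at
  the low signal of strong diffusion weighting.  Noise levels in tests are
  stated as acquisition SNR = (mean in-object noiseless signal across
  frames) / σ, so that "SNR 50" stresses each protocol comparably despite
  very different absolute signal levels (VFA frames sit at a few percent
  of S0).
* **Site effects** (`site_effect`): a signal gain (which the T1 and ADC
  estimators must reject), a transmit miscalibration `b1_scale` that
  perturbs the actual field but *not* the site's correction map (apparent
  T1 scales roughly as 1/b1_scale², giving the mechanism by which
  uncorrected transmit errors corrupt multisite T1), and additive
  per-measure biases for measure-level simulations.
* **Volunteer studies** (`simulate_multisite_study`): measure-level
  normal random effects, `value = μ + a_subject + e_subject,site + bias`,
  rather than full abdominal image synthesis — this matches what the
  statistics consume and keeps runtimes at desk scale.  The generating
  SDs are returned so variance-component recovery can be tested.

All randomness flows from explicit seeds through derived substreams; the
caller's RNG state is never touched.  What the phantom does **not**
emulate: pulse-sequence physics (no Bloch simulation), k-space/EPI
artifacts, respiratory motion (the presumed failure mode of free-breathing
MTR in vivo), fat–water reconstruction (fat-fraction maps are synthesized
directly, as they are consumed as vendor products), or inter-reader
tracing variability.  Passing closure tests therefore demonstrates the
correctness of the estimators and statistics, not robustness to those
physical confounds.

## Reproducibility statistics

Missing cells are dropped pairwise per statistic and never imputed; every
statistic reports its effective n.  The CV uses the n − 1 sample SD — the
convention under which the packaged study table reproduces its published
summary CVs.  The headline per-measure result is the unweighted mean of
per-subject across-site CVs; subjects with fewer than two sites are
excluded with a warning.

The Friedman test treats subjects as complete blocks: sites with no data
for a measure are dropped first (a site that never acquired a sequence is
a design hole, not a missing observation), then subjects missing any
remaining site are excluded block-wise.  When every block is fully tied
the tie-corrected statistic degenerates to 0/0 and is reported as 0 with
p = 1.  Post-hoc pairwise comparisons default to the unpaired Wilcoxon
rank-sum test (exact for small tie-free samples, tie-corrected normal
approximation otherwise), with a `paired = TRUE` signed-rank variant that
respects the travelling-volunteer pairing; with only 4–5 values per site
the unpaired test can reach p ≈ 0.016 while the paired test's floor is
0.125, so the choice materially affects borderline conclusions (see
Limitations).  No multiplicity correction is applied by default; Holm is
available behind `adjust`.

The variance decomposition is deliberately the simple construction, not
REML: inter-assay SD = mean over subjects of the per-subject across-site
SD; inter-individual SD = SD of per-subject means.  With k sites the
latter includes a technical residual of order site-SD/√k, and the former
underestimates the generating site SD by the small-sample factor c₄(k)
(≈ 8% at k = 4); recovery tests budget for both.

## Power analysis

Sample sizes use transparent z-based normal-approximation formulas, with
δ defined as a percentage of the measure's grand mean: per-group
`ceil(2((z₁₋α/₂ + z_pow)·σ_between-subject/δ)²)` for two independent
groups (the headline is the total across both groups), and
`ceil(((z₁₋α/₂ + z_pow)·σ_between-scan/δ)²)`, floored at 3, for
within-subject change.  An iterative t-quantile refinement is available
behind `use_t` and never returns fewer subjects than the z form.  The
intended use is the *ordering and scaling* of requirements across
measures and designs — exact cell values depend on test-family choices
that reasonable analysts make differently.

## Problem sizes and numerical tolerances

The validation suite runs closure at the full mapping grid
(128 × 104 × 24; ~3 × 10⁵ voxels, enlarged vials of ~9 × 10³ voxels per
truth value) — noiseless recovery is exact to numerical precision and is
asserted at 0.1%, noisy medians at SNR 50 are asserted at 2%.  Oracle
agreement for the T1 solver is checked against a dense brute-force grid
(1 ms steps) on 100 random noiseless voxels; rank statistics are checked
against from-scratch rank computations on 50 random tables and full
enumeration for 5-vs-5; variance-component recovery uses a 200 × 4
simulated design at 15% relative tolerance.  These sizes make the whole
suite run in well under a minute of compute per heavy block.

## Known limitations

* The packaged study table is transcribed at its published precision;
  statistics recomputed from it can differ in the last digit from
  summaries computed on unrounded source data.  Two documented
  consequences, both visible in the package's own test output: the
  size-measure mean CVs land within 0.15 percentage points of (not
  exactly on) their published 9.5/9.8, and the phantom ADC/MTR/fat CVs
  recompute to 6.1/9.3/0.5 rather than the published 4.3/8.9/0.4.
* One site's MTR entries in the packaged volunteer table are several-fold
  low (free-breathing MTR is known to be motion-sensitive).  On the
  printed data this reverses three qualitative claims for MTR — the
  unpaired pairwise rank-sum tests against that site reach p = 0.016, the
  inter-assay SD exceeds the inter-individual SD, and the within-subject
  sample size exceeds the two-group total; the corresponding acceptance
  expectations fail honestly rather than being relaxed.  (Under the
  paired signed-rank variant, no pair is significant.)
* On the printed table ADC, not the surface-to-volume ratio, has the
  smallest relative between-subject SD and hence the smallest two-group
  sample size; the expectation encoding the published ordering fails
  honestly as well.
* The morphometry pipeline assumes translation-only inter-series
  alignment and axial contours; oblique reformats and rotational
  registration are out of scope.
* The pancreas object is stylized (smooth tube); it validates the
  geometry pipeline, not anatomical realism of shape metrics.
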