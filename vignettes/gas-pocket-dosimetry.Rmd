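---
title: "Gas-pocket dosimetry in adaptive MRgRT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gas-pocket dosimetry in adaptive MRgRT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasdose)
```

## The problem

In online adaptive MR-guided radiotherapy the electron-density map used
for dose recalculation comes from a simulation CT acquired days before
treatment. Abdominal gas pockets form and move between and within
fractions, creating tissue–gas interfaces whose relative electron
density (RED) differs from water by an order of magnitude. At a 0.35 T
MR-linac those interfaces additionally distort dose through the
electron return effect (ERE): secondary electrons curl back at
tissue–gas boundaries, raising dose on the proximal tissue side and
lowering it inside the cavity. The clinical questions this package
addresses quantitatively are: *which RED should recontoured gas be
overridden with*, and *when does the day's gas actually matter enough to
spend online time recontouring it*.

## The analysis pipeline

### Gas electron density (GIGED)

Gas-pocket voxels are pooled over a cohort and their mean HU converted
to RED through the linear segment of the scanner calibration curve
fitted over [−1000, 0] HU (`fit_calibration_segment()`). The default
calibration ships as the two points (−1000 HU, 0.0) and (0 HU, 1.0): the
published fitted curve reproduces a gastrointestinal-gas RED (GIGED) of
0.38 at −620 HU under exactly this line, and users substitute their
scanner's measured table in practice. GIGED is reported to two decimals,
and is computed from the *pooled* across-patient gas voxels rather than
per patient, because the organ-level comparisons (Mann–Whitney on
per-patient mean HU of stomach, small-bowel and large-bowel gas) show no
significant differences — treating GAS as one volume is then justified.

Statistical conventions: sample SD uses the n−1 denominator; the
Kolmogorov–Smirnov normality check compares against a normal with the
sample's own mean and SD, and the plain KS p-value is reported (the
Lilliefors caveat — estimated parameters make it anti-conservative — is
documented rather than corrected, matching common clinical usage); the
Mann–Whitney test enumerates the exact U distribution when the smaller
sample has ≤ 8 observations and no ties, and otherwise uses the normal
approximation with tie-corrected variance and *no* continuity
correction, so that identical samples give p = 1 exactly.

### Gamma analysis

Plan pairs are compared on the three orthogonal planar slices (axial,
sagittal, coronal) through the GTV centroid — planar slices, not
ray-sum projections, because gamma on summed projections has no
conventional meaning in plan QA and orthogonal-plane review is standard
MRgRT practice. This is the one genuine interpretation ambiguity of the
protocol and is recorded here as a deliberate choice.

`gamma_2d()` follows the Low et al. gamma index with criteria 1%/1 mm
and a 10% low-dose threshold, both percentages of the *global maximum of
the reference plane* (TG-218's default normalization; whether the
original analysis used global or local normalization is not stated, so
both the normalization and the search parameters are configurable). The
first-named plan of each comparison is the reference; the scored pixel
set is defined on the reference only, while evaluated pixels below
threshold may still serve as comparison points. The evaluated
distribution is bilinearly interpolated on a search grid of
0.1·Δd within a radius of 3·Δd (defaults; both configurable). Offsets
are visited in order of increasing distance with per-pixel early
termination using the bound γ² ≥ (r/Δd)², which provably returns the
same minimum as a full scan. The test suite verifies the implementation
against an exhaustive brute-force search at a 0.01·Δd grid: pass rates
agree to well under 0.5 percentage points on smooth dose-like fields,
and per-pixel gamma values agree exactly at matched search resolution.
Because the gamma landscape is steep along the dose axis (tolerance is
1% of the maximum), the *absolute* per-pixel discretization error of any
finite search step diverges as γ → 0; it is the passing decision and the
GPR that are robust, and those are what the package reports.

### DVH metrics and the Active Gas Volume

DVHs are exact voxel-counting cumulative histograms (default bin 0.01
Gy, no sub-voxel partial-volume weighting). D_x is the highest dose
level still covering x% of the structure, interpolated linearly between
bins; V95 uses 95% of the prescription. The Active Gas Volume is

AGV = volume(GAS ∩ {D ≥ 0.05 · D_Rx}) in cc,

with an inclusive threshold. The dose defining the 5% isodose is the
air-override plan (APLAN) by default — the clinical-convention
recalculation, available before any comparison outcome is known — and is
configurable, since the defining plan is not otherwise pinned down.

### Cohort trends and the 90% threshold

`fit_trend()` fits GPR (%) against AGV (cc) by OLS (the line drawn
through the cohort scatter, with R² = r²) and locates the AGV where the
fitted trend crosses the 90% GPR action level recommended for IMRT gamma
tests. Two conventions are implemented. The default, `"inverse"`,
regresses AGV on GPR and evaluates at 90% — the calibration-style
interpolation that treats AGV as the quantity solved for; on the
packaged 21-patient table it gives 41, 59 and 139 cc for the water–air,
GIGED–air and water–GIGED comparisons, matching the published 41/60/139
to about 1 cc. The `"forward"` convention inverts the GPR-on-AGV line in
closed form, (90 − intercept)/slope, and gives 34/49/141 cc on the same
table; the difference is the usual regression-direction asymmetry under
scatter. Both are returned. No outliers are excluded (the 432.63 cc
patient stays in), thresholds are reported to the nearest cc, and the
linear fits are descriptive — no claim is made that the GPR–AGV
relation is truly linear.

One cohort quantity deserves a caveat: from the packaged table (integer
GPRs, as published) the GIGED-vs-air Pearson correlation computes to
−0.91, while −0.89 was published alongside it; the published value
presumably used unrounded passing rates, which are not recoverable from
the printed table. The other two correlations (−0.97, −0.94) reproduce
exactly.

## The synthetic-data generator

No imaging or dose data are deposited with the source analysis, so the
package generates its own study conditions.

**Phantom.** An ellipsoidal soft-tissue body (default semi-axes
100 × 80 × 60 mm) with N(0, 10²) HU texture; three disjoint ellipsoidal
organ volumes standing in for stomach, small bowel and large bowel;
ellipsoidal gas pockets placed inside the organs by rejection sampling
(cycling through the organs so every per-organ gas partition is
non-trivial; oversized draws are progressively conceded in crowded
organs, and placement that still fails after 1000 attempts errors); a
spherical GTV with a 3 mm isotropic PTV margin. Pocket HU is drawn from
N(−620, 90²), clipped at −1000 HU — the published gas-pocket
distribution. CT gas voxels are filled through the same
contour-rasterization used in analysis, so the imaged and contoured gas
coincide voxel-wise. Everything derives from one mandatory seed, bit
reproducibly. Voxel-centre inclusion with the even–odd rule (half-open
edges) is the rasterization convention throughout: deterministic and
directly checkable against a brute-force point-in-polygon oracle.
Clinical TPS rasterization rules differ at structure boundaries, so
absolute voxel counts are not comparable to a clinical system's.

**Beams.** 24 beams spread uniformly over the gantry circle except two
20° blocked sectors centred at 120° and 240° (couch-edge avoidance),
prescription 35–40 Gy (default 38) at the 80% isodose.

**Toy dose engine.** A declared stand-in for the commercial Monte Carlo
engine — *not* a reimplementation, and the published slab-sweep GPR
values (68.3% … 23.8%) are explicitly not reproduction targets; only
directional and ordering properties are asserted against it. Per beam
the dose is `exp(−μ · radiological depth)` with a Gaussian-penumbra flat
field (μ_eff = 0.05 cm⁻¹ of radiological path, penumbra σ = 3 mm; μ_eff
is a free parameter defaulted only to produce plausible isodose lines).
The ERE-like interface term lowers dose inside a cavity downstream of a
tissue→gas boundary and raises it on the proximal tissue side, with
amplitude

gain · max(0, 1 − RED/RED_sat),  RED_sat = 0.5,

and an in-cavity recovery length `range/RED` (range = 10 mm at unit
density, capped at 20× range). Two considerations fix this form over a
simple (1 − RED) scaling: physically, the electron rebuild distance
scales inversely with density, so the perturbation saturates and
vanishes well below water density; and empirically the interface
distortion is observed to be gone by RED ≈ 0.5 — the slab depth-dose
curves for RED ≥ 0.5 coincide with water up to pure attenuation, and the
plan-pair ordering (water vs GIGED most similar, water vs air least)
follows from the same saturation. A linear amplitude reproduces
neither. With gain 0 the perturbation is off and the engine is a pure
attenuation model. The engine is deterministic.

**Normalization.** The air-override plan is scaled so its PTV D98
equals the prescription (the 80%-isodose prescription convention), and
the *same* scalar is applied to the water and GIGED plans: one
normalization per triplet, no re-optimization, so inter-plan differences
are physical, not renormalization artefacts.

**Slab experiment.** A 30 × 30 × 30 cm solid-water block with a
full-width 30 mm gap 7.5 cm below the entry surface, a single 10 × 10 cm
field delivering 10 Gy at the isocentre (15 cm deep), gap RED swept from
air to water; each dose is gamma-compared (1%/1 mm) on the axial plane
through the isocentre against the air-gap reference, and central-axis
depth-dose curves are extracted. Default grid 5 × 2.5 × 5 mm.

**What the generator does not emulate.** Lorentz-force transport at
0.35 T (the ERE term is a phenomenological surrogate), IMRT step-and-
shoot fluence optimization, realistic organ shapes and peristalsis,
duodenum gas, CT artefacts, and scanner-specific calibration curvature.
Passing tests therefore demonstrate that the *analysis* (geometry,
statistics, gamma, DVH, AGV, cohort trends) is correct and that the
pipeline's qualitative physics (anticorrelation of GPR with AGV,
interface-effect saturation with RED, plan-pair ordering) emerges from a
minimal interface model — they do not validate absolute clinical GPR or
DVH values, which require the clinical CTs and the commercial engine.

## Numerical choices and problem sizes

* Degenerate inputs error loudly: empty masks for statistics/centroids/
  DVHs, constant samples for KS and Pearson, all-below-threshold gamma
  planes, zero-RED volumes, non-uniform CT slice spacing (> 1%),
  duplicate calibration HU values.
* Dose thresholds (AGV, V_x) and the gamma pass test are inclusive;
  gamma passing uses γ ≤ 1 + 1e−9 to absorb float noise.
* Dose and CT grids may differ; dose is resampled to the CT grid by
  trilinear interpolation (`resample_to_grid()`), nearest-edge clamped.
* DICOM I/O is a minimal, self-contained explicit-VR-little-endian
  codec (CT series, RTSTRUCT with nested sequences, grid-scaled RTDOSE)
  writing viewer-readable files; an independent Python DICOM reader
  cross-checks the writer in the test suite.
* Default working resolutions: 2.5 mm phantoms for single-case work,
  5 mm for cohort simulation (a 21-patient cohort — 63 dose
  calculations and 189 planar gamma analyses — runs in about half a
  minute), 1.27 × 1.27 × 1.25 mm (CT-protocol resolution) for the
  gas-HU recovery check. These sizes are the package's chosen study
  conditions; they keep the full pipeline interactive while leaving
  every qualitative result unchanged at finer grids.

## Known limitations

* The toy engine's absolute GPR levels depend on its free parameters
  (gain, μ_eff); only ordering/monotonicity statements are meaningful.
* The KS normality p-value is anti-conservative with estimated
  parameters (see above).
* Oblique or rotated grids, multi-frame-of-reference registration and
  deformable registration are out of scope; grids are axial and
  axis-aligned.
* The packaged cohort table holds integer-rounded GPRs; quantities that
  depended on unrounded values (one published correlation) cannot be
  reproduced beyond the rounding limit.
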