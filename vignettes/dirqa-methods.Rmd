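---
title: "Methods: ground-truth-based QA of deformable registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ground-truth-based QA of deformable registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dirqa` evaluates a deformable image registration (DIR) against a
deformation that is known exactly, and propagates the registration's
geometric error into the dose-accumulation error it would cause. This
vignette records the model behind each stage, the parameters that matter,
the numerical choices, and what the synthetic test bed can and cannot say
about clinical data.

## Conventions

All lattices share one anatomical axis convention: array axis 1 is
left–right (LR), axis 2 anterior–posterior (AP, increasing index =
posterior), axis 3 inferior–superior (SI, increasing index = superior);
physical coordinates are `origin + (index − 1) · spacing` in mm.
Displacement fields are stored **push-forward**: a material point at
planning position `p` lies at `p + u(p)` in the deformed anatomy. This is
the convention point-correspondence analysis needs; resampling (image
warping) uses the inverse displacement, computed by fixed-point iteration
(`invert_dvf()`). Fields supplied in pull-back form are converted on
import; the JSON sidecar written next to every exported field records
convention, units and component order so a reader never guesses.

## The phantom as study condition

`generate_phantom()` builds a stylised abdomen on a 96³ lattice at 2 mm
isotropic spacing (192 mm cube): an elliptic-cylinder body of soft tissue
(≈40 HU), lungs (≈−700 HU) whose inferior surface defines the diaphragm,
a dense spine (vertebral bodies alternating with discs along SI,
450–700 HU), a GTV abutting the spine (the pancreatic-target geometry),
a stomach+duodenum and a small-bowel region. The anatomy is deliberately
geometric — the QA mathematics depends only on masks, intensities and
geometry — but two texture choices matter for registration realism:

* additive Gaussian noise, σ = 20 HU (default), applied everywhere;
* a smooth soft-tissue texture (40 HU amplitude, 8 mm correlation
  length), standing in for the vessels and fat planes that give
  intensity-based DIR something to lock onto inside otherwise uniform
  organs. Without it, any intensity-driven algorithm reverts to pure
  regularisation inside large uniform regions, and recovery there
  becomes untestable.

Organ dimensions scale with the grid extent, so coarse test phantoms keep
full-size anatomy. The generator is bit-deterministic in `(config, seed)`
and validates its own invariants (organs inside the body, target/organ
disjointness, GTV within 30 mm of the spine, stomach volume plausibility).

## Ground-truth deformation

The respiratory component is a separable parametric field: SI
displacement only,

`u_SI(y, z) = −A · exp(−(z − z_d)² / 2σ_z²) · logistic((y_c − y)/w)`,

with amplitude `A` from the named presets (low 10, medium 20, high
38 mm), `z_d` the diaphragm plane (inferior lung extent), `σ_z = 30` mm
the SI decay length and `w = 12` mm the AP decay width, centred 40 mm
anterior of the spine so the spine stays nearly static (mean residual
motion < 2 % of the peak in practice). The negative sign displaces tissue
inferiorly, as exhale-to-inhale motion does. A biomechanical simulation
would produce a richer field; this stand-in reproduces the features the
QA needs — SI dominance, a diaphragm-anchored peak, smooth decay, a
quiet spine — while staying analytically controllable. The construction
keeps every displacement gradient below 1 (checked numerically, enforced
analytically via `A·e^{−1/2}/σ_z < 1` and `A/4w < 1`), which guarantees
the smooth part of the field is invertible; amplitudes that would fold
the field are rejected.

Digestive motion is a hard, uniform in-mask translation: exactly
`shift_AP = shift_LR = 5` mm at every stomach+duodenum and small-bowel
voxel, exactly zero outside. The resulting field discontinuity at the
organ boundary is intentional (it models organ sliding and is the stated
motion model); its consequences are handled explicitly: inversion
residuals near the discontinuity are reported rather than fatal, and the
dose analysis uses the forward field directly, never the inverse, at
those voxels. An optional cosine feather exists but defaults to off.

`combine_fields()` adds components voxelwise; `warp_image()` deforms the
planning CT with trilinear interpolation (nearest-neighbour for masks,
fill −1000 HU / 0 outside the field of view).

## Candidate registration

The built-in candidate is a classical multi-resolution demons: rigid
spine pre-alignment (exhaustive integer-voxel normalised
cross-correlation search over the spine mask, quadratic sub-voxel
refinement, translation-only — adequate for same-patient scans), then
coarse-to-fine (3 levels, 100/60/30 iterations) intensity-driven updates
`Δs = −(m_w − f) ∇I / (|∇I|² + (m_w − f)²/⟨h⟩²)` with Gaussian smoothing
of the update (fluid-like, σ = 2 mm) and of the accumulated field
(diffusion-like, σ = 4 mm). Both images are pre-smoothed with σ = 2 mm at
each level: without this, noise-driven forces in texture-free regions
accumulate as a random walk and the field drifts. The algorithm is fully
deterministic. It estimates the pull-back field and converts to
push-forward via `invert_dvf()` before QA. No attempt is made to mimic
any commercial engine's error pattern; the demons exists to exercise the
pipeline, and external DVFs are first-class inputs.

## Geometric QA

All field comparisons happen on a 1 mm isotropic **analysis grid** whose
origin is aligned across inputs. The grid covers the intersection of the
source extents, snapped to whole millimetres *inside* the intersection,
so every analysis voxel is interpolable from every source and no
fill-value voxels enter the statistics. Displacement components are
resampled trilinearly (values are mm along fixed anatomical axes, so no
re-orientation is involved); masks move by nearest-neighbour, and ROI
statistics are computed on planning-space ROIs, consistent with indexing
by the planning voxel. The magnitude error is the Euclidean norm of the
component differences; percentiles use linear interpolation between order
statistics (R `quantile` type 7) — fixed here because reasonable software
disagrees on percentile definitions.

## Dosimetric QA

The planned dose is an analytic **static dose cloud**: a function of
physical position only, independent of anatomy. The default model sums a
2 % bath and one flat-topped super-Gaussian kernel per prescription
level, centred on the GTV, calibrated so the cumulative centre dose
reaches 1.05× each level (a simultaneous-integrated-boost structure, e.g.
4500/7500 cGy). Modelling "recalculate the plan on the deformed CT" as
the same cloud sampled at corresponding points is a deliberate
simplification: it removes density effects (a documented limitation) but
makes the dose error *exactly* the registration error seen through the
dose gradient, which is the quantity this QA isolates. A perfect
candidate gives identically zero dose error; a flat dose hides all
geometric error; and `|e(A)| ≤ L·‖u_truth(A) − u_cand(A)‖` with `L` the
cloud's Lipschitz constant — all three properties are tested.

Signed errors are kept signed throughout (`truth-side − candidate-side`).
Dmax/Dmin panel entries are metric-level differences, distinct from the
voxelwise maximum error; both are reported. "Top 1 cc" — not defined
precisely in common usage — is fixed as the mean signed error over the
⌈1 cm³ / voxel volume⌉ ROI voxels of largest absolute error, and the ROI
Dmax/Dmin reference uses the ground-truth correspondence by default. All
conventions are embedded in the report metadata.

## Binned correlation analysis

Voxels are grouped into 75 equal-width bins (configurable; the useful
range is roughly 50–100, giving sub-millimetre bin resolution over
typical motion ranges) by ground-truth magnitude or by DIR magnitude
error; each bin contributes its centre (nominal magnitude), mean, and
25th–75th-percentile range of the tracked statistic. Bins with fewer
than 10 voxels are flagged and excluded from correlation — binning exists
to stabilise the voxelwise scatter, and near-empty bins defeat that.
The coefficient is Pearson's, computed on the binned summaries: the
analysis asks for a linear trend measure, and degenerate cases
(zero-variance statistic, fewer than 3 usable bins, a single-valued key)
are reported as flagged nulls, never numbers.

## Problem sizes and numerical choices

The package's own test bed runs the full pipeline on the 96³/2 mm
phantom (≈3 × 10⁶ analysis-grid body voxels) for the null and identity
checks, a 48³/4 mm phantom (same physical extent) for unit-level
registration checks, and ~10⁵-voxel constructed fields for correlation
properties — sizes chosen so the whole suite exercises every path at
clinical extents while remaining routine to run. Fixed-point inversion
uses 50 iterations / 0.01 mm tolerance; its composition residual is
~10⁻⁴ mm for smooth fields and is reported (not suppressed) near
digestive discontinuities. Trilinear sampling snaps continuous indices
within 10⁻⁹ voxel of an integer, so aligned resampling and identity
warps are bit-exact. Gaussian smoothing uses FFT circular convolution;
wrap-around is acceptable because every smoothed quantity is small near
the volume boundary.

## What passing tests do and do not show

The phantom establishes that the *pipeline* measures what it claims:
exact construction parameters, exact nulls, closed-form dose errors,
recovery of smooth fields. It does not certify any registration for
clinical use: real CTs have density heterogeneity, sliding interfaces,
contrast differences and artefacts the phantom lacks; the dose cloud
ignores tissue density; digestive motion is richer than a rigid 5 mm
shift; and a demons stand-in says nothing about a specific commercial
engine. For clinical QA, the intended use is to import the engine's own
DVF (`import_dvf()`) computed on this package's exported ground-truth
deformation of the patient's planning CT.
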