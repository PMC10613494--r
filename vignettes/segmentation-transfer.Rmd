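---
title: "Transferring left-atrial segmentations from CE-MRA to 4D-flow MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transferring left-atrial segmentations from CE-MRA to 4D-flow MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Quantifying left-atrial (LA) hemodynamics — mean velocity and stasis — from
4D-flow MRI requires a segmentation of the atrium on the 4D-flow voxel grid.
The 4D-flow acquisition itself offers poor anatomy: ~3 mm voxels, washed-out
contrast, and motion-averaged borders. Contrast-enhanced MR angiography
(CE-MRA), acquired in the same session at ~1.2 mm, shows the chambers and
veins crisply but lives on a different grid, at a slightly different patient
pose. `atrialign` implements the transfer: segment on CE-MRA, rigidly
register the CE-MRA onto an angiogram derived from the 4D-flow data, and
carry the segmentation across.

The workflow is, in order:

1. **PC-MRA derivation.** The phase-contrast MR angiogram is the time
   average of magnitude times speed,
   $$\mathrm{PCMRA}(\vec r) = \frac{1}{N}\sum_{i=1}^{N}
   I_i^{\mathrm{Mag}}(\vec r)\,
   \sqrt{v_{x,i}^2(\vec r) + v_{y,i}^2(\vec r) + v_{z,i}^2(\vec r)},$$
   which highlights voxels that are both signal-rich and moving.
   `compute_pcmra()` implements exactly this sum — no rescaling, clipping or
   masking — so that it can serve as a registration target and as the
   counterpart of reference segmentations. The PC-MRA is bias-corrected
   (below) before registration.
2. **Segmentation** of the CE-MRA by seeded region growing inside an
   explicit intensity window, followed by median/closing refinement, and
   optional plane cuts separating the appendage at its orifice and trimming
   pulmonary veins at their ostia.
3. **Rigid mutual-information registration** of the CE-MRA (moving) onto
   the PC-MRA (fixed), with a global first round and an ROI-restricted
   second round.
4. **Resampling** of the segmentation into the 4D-flow grid by
   nearest-neighbor pull-back.
5. **Quantification**: volume, Dice overlap and average symmetric surface
   distance against a reference mask; mean velocity and stasis inside the
   transferred mask.

## Conventions that everything else depends on

* **Coordinates.** Every volume carries a 4×4 index→world affine in mm
  (NIfTI s-form, used verbatim — no axis flipping); voxel indices are
  0-based and may be fractional. Registration is meaningless without
  affines, so both inputs must carry them.
* **Transform direction.** A `rigid_transform` always maps *fixed/target*
  world coordinates to *moving/source* world coordinates (a pull-back).
  Registration estimates the transform in this direction and resampling
  consumes it unchanged — the classic source of silent left/right flips is
  removed by having exactly one convention.
* **Euler order.** Rotations are stored as intrinsic Z–Y–X Euler angles.
  Transforms are *compared* on their rotation matrices
  (`transform_difference()`), never on raw angles, to avoid gimbal
  ambiguity.
* **Rotation center.** The world center of the fixed grid (index
  `(shape−1)/2`); a documented default rather than a guess at any external
  tool's convention.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `scale_mm` (bias correction) | 25 mm | SD of the Gaussian bias estimate; well above wall thickness, well below the field of view |
| region-growing connectivity | 6 | face adjacency; conservative against leaks through diagonal voxel corners |
| `kernel_mm` (refinement) | 3 mm | world radius of the ellipsoidal median/closing element; per-axis voxel radius `max(1, round(kernel_mm/spacing))` |
| `sample_fraction` | 0.2 / 1.0 | fraction of fixed voxel centers used as metric samples (global round / ROI round) |
| `histogram_bins` | 32 | joint-histogram bins per intensity axis |
| `max_iterations` | 1500 | cap on objective evaluations per registration call |
| ROI margin | 20 mm | padding around the chamber segments for the second round |
| stasis threshold | 0.1 m/s | speed below which a voxel-frame counts as stagnant (strict `<`) |

## The registration objective and optimizer

The similarity metric is plain joint-histogram mutual information in nats,
$MI = H(F) + H(M) - H(F,M)$, over a set of fixed-image sample points:
fixed intensity at the sample, moving intensity at the transform-mapped
point by trilinear interpolation; samples mapping outside the moving volume
are dropped (fewer than two survivors is an overlap failure). Intensities
are binned linearly between each image's 0.5th–99.5th percentiles, computed
once per round — the clipping tames contrast-agent hot spots that would
otherwise crush the histogram into a few bins. This is the simplest
well-defined MI estimator; it is invariant to any intensity remap that
preserves bin order, which is what lets one metric serve two modalities
with unrelated contrast.

Samples are drawn once per round (uniformly, without replacement, from the
voxel centers inside the grid∩ROI) under the configuration seed and held
fixed across iterations. The objective is therefore a deterministic
function of the six parameters, and the whole registration is
bit-reproducible.

Optimization is derivative-free Nelder–Mead over
(translation mm, rotations·50 mm): scaling the angles by a 50 mm
characteristic lever makes a unit step mean roughly 50 mm of arc for every
parameter, so the simplex is well-conditioned. Two details matter in
practice and are deliberate design choices:

* **A two-level pyramid.** The first simplex runs operate on copies of both
  images smoothed with a Gaussian of one fixed-voxel SD; the final runs use
  the full-resolution images. Hard binning makes the raw metric piecewise
  flat at sub-sample scales, and a simplex started from zero can stall on
  those plateaus; smoothing widens the capture basin and irons the
  plateaus out, while the full-resolution level restores the sharp
  optimum.
* **Coarse-to-fine restarts.** Nelder–Mead is restarted with initial
  simplex extents of roughly 5, 5, 2 mm (smoothed level) and 1, 1, 0.5,
  0.2 mm (full level), stopping early once an already-converged restart no
  longer improves the metric; restarting guards against premature simplex
  collapse. The total evaluation count is capped by `max_iterations`.

The result is never worse than its starting point: if the search fails, the
initial transform is returned with its metric value. A quality record
replaces the visual accept/reject step of an interactive workflow: a result
is flagged when the metric gain is below 10⁻³ nats or the recovered
displacement exceeds half the fixed field of view. The flag is advisory —
final acceptance stays with the user, as it does in clinical practice.

**Two rounds.** A time-averaged PC-MRA and a single-phase CE-MRA disagree
slightly on where the aorta sits relative to the chambers, so a global
registration can latch onto the aorta. The second round therefore restarts
from the round-1 pose with samples restricted to an axis-aligned box around
the LA and PV segments (mapped into the fixed frame through the round-1
transform, padded by 20 mm) and samples every voxel in the box
(`sample_fraction = 1.0`). The box deliberately stays a simple cube: precise
ROI contouring would add interaction for little gain.

## Resampling

Masks are carried between grids by nearest-neighbor pull-back: for each
target voxel center $p$, look up the source voxel at index of $T(p)$,
rounding fractional indices half away from zero (stated explicitly because
voxel-boundary ties otherwise differ across platforms); out-of-bounds reads
are background. Nearest-neighbor keeps masks strictly binary. Scalar
volumes use trilinear interpolation with zero fill, for overlays and
alignment checks.

## Metrics

* `volume_ml`: foreground count × |det| of the affine's 3×3 block / 1000.
* `dice`: $2|A\cap B| / (|A|+|B|)$. Two empty masks raise an error rather
  than returning a degenerate 1 — a silent "perfect" score would hide
  upstream failures.
* `surface_voxels`: foreground voxels with a background or out-of-volume
  neighbor, under 6- or 26-connectivity (the 26-surface contains the
  6-surface; the surface-to-total ratio gauges how much boundary
  disagreement can move volume-derived quantities).
* `assd`: average symmetric surface distance over the two 6-connected
  surfaces, voxel-center to voxel-center in world mm. Voxel centers (not
  meshes) are a documented choice; with them the metric is exactly
  symmetric and zero iff the surfaces coincide.
* `bland_altman`: mean difference, mean ± 1.96·SD limits of agreement
  (sample SD), and Pearson r, for method-agreement studies.

## Hemodynamics

Mean velocity is the pooled mean of speed over all (voxel ∈ mask, frame)
pairs, in cm/s — identical to a per-frame mean of means for a fixed mask,
pooled form stated to remove the ambiguity. Stasis is, per voxel, the
fraction of frames with speed *strictly* below the threshold (default
0.1 m/s), averaged over the mask and expressed in percent; `stasis_map()`
exposes the per-voxel fractions and its mask-mean reproduces the scalar
exactly. Averaging the time-fraction over space (rather than thresholding
a time-averaged speed) is the convention adopted here and documented so
alternatives can be layered later.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds a paired dataset with known ground truth:

* **Geometry** (flow frame, mm): an LA ellipsoid with semiaxes 30/25/20
  (≈63 ml, a plausible atrium) centered at the origin; a small appendage
  lobe; four pulmonary-vein tubes (radius 6 mm) entering the posterior
  wall; an aortic arch (half-torus, major radius 30 mm, tube 9 mm); a left
  ventricle ellipsoid; myocardium shells around LA and LV.
* **Grids**: 1.2 mm isotropic angiography over a 132 mm field of view and
  3.0 mm isotropic, 25-phase flow over 144 mm — the clinical resolution
  ratio at a desk-scale field of view that keeps a phantom generation in
  seconds. These sizes are the package's stated study conditions.
* **Pose**: the angiography scene is placed at a known rigid transform
  (default 6/−4/8 mm, 5/−3/2°) relative to the flow scene. The truth
  record stores it in the same pull-back convention the pipeline
  estimates. With `decoy_offset_mm`, the aorta is additionally displaced
  in the angiography scene only — reproducing the real-world failure mode
  that motivates the two-round scheme.
* **Intensities**: piecewise tissue classes with a gamma remap on the
  angiography side, a multiplicative bias ramp (amplitude 0.2), and
  additive Gaussian noise. The class mapping across modalities is
  deliberately **non-monotone** (contrast-enhanced blood is the brightest
  angiography class but, emulating contrast wash-out, *not* the brightest
  flow-magnitude class), so correlation-like metrics would fail where
  mutual information succeeds — the phantom exercises the reason MI was
  chosen. Gaussian rather than Rician noise is a documented
  simplification; at the phantom's SNR the distinction is immaterial.
* **Velocities**: inside the LA a rigid-body-like swirl
  $v = \omega \times (r - r_c)$, modulated per frame by
  $|\sin(2\pi t/T)|$, with a low-speed boundary layer: full speed in the
  ellipsoidal core (ρ ≤ 0.85), linear decay to a 0.2 residual at the wall,
  and a slow sub-threshold tail across the myocardium shell. The tail
  models tissue-adjacent partial-volume blood — the voxels a slightly
  oversized segmentation picks up. Its peak speed stays below the 0.1 m/s
  stasis threshold by construction, which is what makes stasis (a
  binarizing metric) more boundary-sensitive than mean velocity (a
  diluting one). Pulmonary veins get plug flow, the aorta tangential arch
  flow, the ventricle its own swirl; background velocities are pure noise.
  Because the stored LA velocities are evaluated from the same closed
  form, stasis and mean velocity over the truth mask have analytic values
  carried in the truth record.
* **Truth masks**: fine-grid masks are the discretized geometry; the
  flow-grid LA truth mask is produced by `resample_mask()` through the
  true transform — the same operation the pipeline uses — so comparisons
  are free of a second discretization convention.

What the phantom does **not** emulate: physiologic atrial flow (vortices,
PV jets), k-space/acquisition artifacts, deformable cardiac or respiratory
motion, Rician noise statistics, and partial-volume intensity blending.
Passing tests on the phantom therefore validate the machinery —
formulas, conventions, convergence, determinism — not clinical accuracy on
patient data.

## Numerical choices, degenerate inputs, tie-breaks

* Bias correction divides by a Gaussian-smoothed copy (edge-renormalized
  separable kernels, so a flat field is exactly preserved), floors the
  denominator at 10⁻⁶ of its maximum, and rescales to preserve the mean;
  an all-zero volume is returned unchanged with a warning.
* Region growing requires every seed's intensity inside the window and
  names the offending seed otherwise.
* The binary median filter acts as discrete mean-curvature flow: each pass
  moves a curved boundary inward by ~r²/(4R). Exact idempotence is
  therefore impossible on curved shapes; at chamber scale (kernel 3 mm,
  curvature radii ≥ 20 mm) a second application changes well under 1% of
  voxels, which is the regime the refinement targets.
* Plane cuts keep voxels whose signed distance has the `keep_point`'s
  sign, with on-plane voxels kept; `kept`/`removed` partition the input
  exactly, and `kept` is restricted to the 6-connected component of the
  keep point.
* Nearest-neighbor index rounding is half-away-from-zero, chosen once and
  shared.
* Dice of two empty masks, ASSD with an empty side, empty-mask
  hemodynamics, zero-variance correlation: all structured errors, never
  silent defaults.
* All randomness (sampling, phantom noise, perturbation) flows through
  explicitly passed integer seeds; RNG state is saved and restored around
  each draw, so library calls never perturb a caller's stream.

## Problem sizes used in validation

The test-suite and acceptance experiments run on the default phantom
(110³ angiography voxels, 48³ × 25 flow voxels), ten-seed registration
recovery sweeps with misalignments up to 10 mm / 10°, brute-force oracle
comparisons on 12³ masks, and one end-to-end pipeline run on the decoy
phantom. These sizes were chosen as the smallest that keep every geometric
feature (tube radii, shell thicknesses, misalignments) several voxels wide
on both grids.

## Known limitations

* Rigid alignment only: atrial deformation between the CE-MRA and 4D-flow
  acquisitions (different cardiac phases, contraction states) becomes
  residual overlap error, visible as Dice < 1 even for perfect rigid
  recovery.
* The mutual-information estimator uses hard binning; partial-volume or
  Parzen estimators would be smoother but are not needed at these sample
  counts.
* I/O is NIfTI-only; DICOM series must be converted upstream.
* Single-window region growing merges connected blood pools (LA, appendage,
  veins); separation is by explicit plane cuts, not automatic ostium
  detection.
* The registration quality flag is a heuristic surrogate for visual
  inspection, not a guarantee; flagged results should be reviewed.
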