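# atrialign

Semi-automated transfer of left-atrium (LA) segmentations from
contrast-enhanced MR angiography (CE-MRA) into 4D-flow MRI coordinates, for
hemodynamic analysis in atrial fibrillation and related conditions.

## Why

4D-flow MRI measures time-resolved, three-directional blood velocity, from
which atrial **mean velocity** and **stasis** — markers linked to thrombus
formation — are computed inside an LA segmentation. But the 4D-flow data
itself (≈3 mm voxels, contrast washed out by the time it is acquired) is a
poor basis for segmenting the atrium, and manual slice-by-slice contouring
of a derived angiogram takes tens of minutes per case. A same-session
CE-MRA shows the chambers at ≈1.2 mm with strong contrast. `atrialign`
segments the CE-MRA, registers it onto the 4D-flow data, and carries the
segmentation across:

1. **PC-MRA derivation** — the phase-contrast MR angiogram
   `PCMRA(r) = (1/N) Σᵢ Iᵢᴹᵃᵍ(r) · √(v²ₓᵢ + v²ᵧᵢ + v²𝓏ᵢ)`,
   a time average of magnitude × speed that highlights moving blood.
2. **Segmentation** — seeded region growing within an intensity window on
   the (optionally bias-corrected) CE-MRA, median + closing refinement with
   a 3 mm ellipsoidal kernel, and plane cuts separating the appendage and
   trimming pulmonary veins.
3. **Rigid mutual-information registration** of CE-MRA (moving) onto the
   bias-corrected PC-MRA (fixed): joint-histogram MI (32 bins,
   0.5–99.5 percentile clipping), fixed sample sets (fraction 0.2),
   derivative-free optimization; a second round restricted to a cube ROI
   around the chambers (sample fraction 1.0) recovers cases where the
   global round latches onto the aorta.
4. **Resampling** — nearest-neighbor pull-back of the mask into the
   4D-flow grid.
5. **Quantification** — volume (ml), Dice coefficient
   `DSC = 2|A∩B|/(|A|+|B|)`, average symmetric surface distance
   `ASSD = (Σ_{a∈S(A)} min_b‖a−b‖ + Σ_{b∈S(B)} min_a‖a−b‖) / (|S(A)|+|S(B)|)`,
   Bland–Altman agreement, and hemodynamics: mean velocity (cm/s) and
   stasis (% of the cycle below 0.1 m/s).

A synthetic cardiac phantom (`generate_phantom()`) provides paired
CE-MRA / 4D-flow datasets with a known rigid misalignment, a decoy aorta,
non-monotone inter-modality intensity mapping, and closed-form atrial
hemodynamics, so every stage can be validated against ground truth.

## Worked example

Generate a misaligned phantom pair, register with the two-round scheme, and
evaluate the transferred segmentation against the generator's truth:

```r
library(atrialign)

ph    <- generate_phantom(phantom_spec(seed = 42, decoy_offset_mm = 12))
pcmra <- bias_correct(compute_pcmra(ph$flow))

res <- two_round_register(
  pcmra, ph$ce,
  segments = list(ph$truth$la_mask_ce, ph$truth$pv_mask_ce),
  cfg1 = registration_config(sample_fraction = 0.2, seed = 42),
  cfg2 = registration_config(sample_fraction = 1.0, seed = 42))
print(res)
#> registration_result (round 2): MI 0.3170 -> 0.3350 in 1262 evaluations
#> rigid_transform: angles (4.569, -3.185, 2.382) deg, translation (6.573, -3.961, 8.144) mm, center (0, 0, 0) mm

la_flow <- resample_mask(ph$truth$la_mask_ce, res$transform, ph$flow$grid)
dice(la_flow, ph$truth$la_mask_flow)   # 0.979
assd(la_flow, ph$truth$la_mask_flow)   # 0.36 mm
volume_ml(la_flow)                     # 62.6 ml (truth: 62.8 ml)
mean_velocity(ph$flow, la_flow)        # 11.5 cm/s
stasis(ph$flow, la_flow)               # 48.6 %  (analytic truth: 48.5 %)
```

The recovered transform sits within a fraction of a flow voxel of the true
pose (6, −4, 8 mm / 5, −3, 2°); the transferred mask overlaps the truth
mask at Dice 0.979 with sub-voxel surface distance, and the hemodynamic
quantities reproduce the phantom's closed-form values.

File-based workflows use `run_pipeline()` (YAML/JSON config → JSON report
plus intermediate NIfTI volumes) or the equivalent CLI
(`inst/cli/atrialign.R`) with subcommands `phantom`, `pcmra`, `segment`,
`register`, `resample`, `evaluate`, `hemo`, `pipeline`.

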