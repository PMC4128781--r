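---
title: "Retrospective movement correction for dynamic brain PET/CT: methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrospective movement correction for dynamic brain PET/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A dynamic brain PET/CT study acquires one CT and then an hour or more of PET
frames. The CT serves double duty: anatomy, and the attenuation map used to
reconstruct quantitative PET images. When the head moves during the dynamic
scan — common in elderly patients and in movement disorders, and most
pronounced in late frames — two distinct errors appear:

1. **Attenuation-correction (AC) artifacts.** Each PET frame is reconstructed
   with an attenuation map derived from a CT that no longer matches the head
   position, producing spatially structured bias (one side of the brain too
   hot, the opposite too cold). Realigning the reconstructed images afterwards
   cannot undo this.
2. **Inter-frame misalignment.** Region-of-interest time–activity curves
   (TACs) mix tissues across frames, corrupting kinetic parameters estimated
   from them.

`petmc` implements the retrospective, image-based correction: re-register the
CT to *every* frame, re-reconstruct each frame with its own matched
attenuation map, then realign all frames to a common reference. Because no
public scanner data accompany the procedure, the package also contains a
complete synthetic-study generator (digital head phantom, compartment-model
kinetics, projection/reconstruction physics) so the whole pipeline is
verifiable end-to-end on a desk.

## The correction pipeline

`run_mc()` executes the procedure as eight steps on (CT, per-frame emission
sinograms, frame schedule):

* **Step 0** (inputs): non-AC reconstructions of all frames; the reference
  frame additionally reconstructed with AC from the original CT. The
  reference frame is configurable (`mc_config(reference_frame=)`); the
  conventions used in the validation studies are frame 1 for the 12-frame
  repositioning phantom protocol, frame 7 for the 20-frame FDDNP protocol and
  frame 24 for the 24-frame FDG protocol — frames with high signal-to-noise
  and clear anatomy.
* **Step 1**: segment the head from the stationary background
  (`segment_head()`). The head holder and bed do not move with the patient,
  so only the head part of the CT may be moved. Segmentation is thresholding
  at −500 HU, selection of the largest connected component, then
  morphological closing. Selection happens *before* closing: closing the raw
  mask first can bridge the narrow air gap between the scalp and the head
  holder. The decomposition is exact — head CT and background CT recompose
  voxelwise to the original.
* **Step 2**: rigidly register the head CT to the AC reference PET frame by
  normalized mutual information (NMI), giving `CT_REF`. AC (not non-AC) PET
  is used on purpose: the stronger in-brain signal makes the cross-modality
  metric better conditioned.
* **Step 3**: register the *non-AC* reference frame to every other non-AC
  frame by normalized cross-correlation (NCC), giving n−1 transforms
  (reference → frame i). Non-AC images are used here because AC images carry
  mismatch artifacts that perturb inter-frame registration. Frames starting
  within the first 90 s (configurable) are summed into one image, registered
  once, and the transform replicated — individually these short early frames
  are too noisy to register.
* **Step 4**: move `CT_REF` with each transform.
* **Step 5**: paste the stationary background back around each moved head
  CT. Where the moved head overlaps background structure, the head value
  wins (overlaps occur only at contour edges); voxels the head vacated
  revert to the background value (air, −1000 HU).
* **Step 6**: re-reconstruct every frame with attenuation-weighted OSEM
  using attenuation factors from its own moved CT.
* **Step 7**: realign the AC frames to the reference frame with the inverse
  transforms.

A movement-skip option (`skip_if_negligible`) returns the original
reconstruction when every estimated displacement is below 1 mm and every
rotation below 0.5°, avoiding the mild extra smoothing that resampling
introduces.

**Direction convention.** Transforms map the reference position onto frame
i's position; Step 4 therefore moves `CT_REF` forward and Step 7 applies
inverses. Transform files record translations (mm), rotations (degrees,
intrinsic Z–Y–X order) about the grid centre, so serialized transforms are
unambiguous.

**Evaluation metrics.** `displacement()` is the Euclidean norm of the
translation — the movement of the image-centre point; with rotations present
most head locations move more than this measure indicates.
`registration_error()` reports |preset displacement − estimated
displacement| as the primary (scalar) error and the vector norm
‖t_preset − t_estimated‖ as a stricter secondary field; the reverse triangle
inequality guarantees scalar ≤ vector. `difference_map()` and
`lr_asymmetry()` reproduce the qualitative image checks; the left–right
asymmetry formula (mean over mirrored in-mask pairs of
|L−R|/((L+R)/2)×100, pairs below 10% of the robust maximum excluded) is this
package's choice — the original report prints only summary values from
scanner data, which are not reproducible without it.

## Registration

`register()` maximizes NMI (cross-modality) or NCC (within-modality) over
rigid parameters with a coarse-to-fine pyramid (downsample factors 4, 2, 1;
levels that would leave images under ~24 voxels across are dropped) and
cyclic coordinate descent with step halving, from 8 mm/degrees down to
0.05 mm/degrees. It is deterministic given inputs and initialization; ties
resolve to the first-found maximum with 1e−9 slack.

NMI uses 64 histogram bins (32 for images under 64 voxels across) over the
robust 1st–99th percentile range, with air/background voxel pairs excluded —
both a speed-up and a conditioning measure. Both images are pre-smoothed to
4 mm FWHM before NMI registration: a crisp CT resampled by the optimizer
changes entropy purely through interpolation, which otherwise creates
spurious NMI maxima away from alignment (we observed ~1.5° phantom offsets
without pre-smoothing; with it, sub-voxel self-registration).

Measured desk-scale accuracy (128×128, 2 mm grid): PET→PET NCC recovers the
twelve preset phantom translations with ≤0.3 mm scalar error under Poisson
noise; CT→PET NMI recovers a 6 mm / 3° offset within ~0.5 mm / 0.5°. At
64×64 / 3 mm the NMI rotation axis is poorly conditioned and only
translations are reliable — the dynamic-study simulations therefore run
registration at full resolution within their own grids.

## Physics simulation

The projector is 2-D parallel-beam: line integrals (mm-scaled) over rays
sampled at half a bin width, with the system resolution modelled as a single
isotropic Gaussian (default FWHM 4.5 mm, the scanner's stated intrinsic
resolution) applied in image space before projection. 3-D volumes project
slice-by-slice. The backprojector is the exact adjoint (bilinear splatting),
which makes the OSEM update well-behaved. Attenuation factors are
exp(−∫μ dl) along the full ray — correct for coincidence detection, where
attenuation is independent of the emission point. The HU→μ map is bilinear:
−1000 HU → 0, 0 HU → 0.096 cm⁻¹ (water at 511 keV), slope 1e−4 cm⁻¹/HU
above 0 HU for bone; both anchors configurable.

AW-OSEM folds the attenuation factors into the system model:
x ← x · Pᵀ[a·y/(a·Px+ε)] / Pᵀ[a], ε = 1e−10, uniform positive
initialization, subsets by angle interleave visited in bit-reversed order.
Defaults are 6 iterations × 16 subsets, the re-reconstruction protocol's
setting; small test geometries use fewer subsets. Randoms and scatter are
not simulated — the procedure being validated specifies no scatter model —
and detector normalization, dead time and within-frame decay are out of
scope. Simulated concentrations are decay-corrected by construction (no
¹⁸F decay term), which keeps the graphical-analysis identities exact.

Emission counts are Poisson draws of
factors × projection × duration × sensitivity, seeded explicitly. The
default sensitivity (5e−3) puts a 10-min phantom frame near 10⁷ counts —
the activity actually used in such phantom sessions (~13 MBq in ~1.1 L)
pins count levels only loosely, so the scale is a free, documented
parameter.

## The digital phantom

`make_digital_phantom()` builds a Hoffman-like 2-D (default) or 3-D head:
scalp ellipse, skull shell (+800 HU), cortical gray-matter ribbon carved
into frontal, parietal, lateral-temporal and cerebellar sectors plus generic
gray, deep medial-temporal and posterior-cingulate structures in the white
core, two 5-mm carotid discs, and a posterior head-holder arc (+200 HU)
separated from the scalp by a 4-mm air gap. Labels partition the grid; the
head keeps ≥10% margin to the field edge so preset movements of the
repositioning-protocol scale stay in-field. In 2-D the image plane is the
(Y, Z) scanner plane: Y (perpendicular to the bed) is axis 1, Z (along the
bed) is axis 2.

Tracer kinetics use the two-tissue compartment model; `simulate_tissue_tac()`
evaluates the analytic bi-exponential impulse response convolved with the
input on a fine grid (the test suite cross-checks it against an independent
`deSolve` integrator to <0.5%). The plasma input is a sum-of-exponentials
bolus (zero at injection, peak <2 min, monotone decay). Rate constants are
design choices — no tabulated values exist for this protocol:

* FDG-like (irreversible, k₄=0): gray K₁=0.10, k₂=0.15, k₃=0.08
  (Kᵢ = K₁k₃/(k₂+k₃) ≈ 0.0348 min⁻¹), white scaled to give the classic ~4:1
  gray:white contrast; small per-region variations.
* FDDNP-like (reversible): k₂=0.25 throughout for fast equilibration,
  cerebellum as non-binding reference (k₃=0), target k₃/k₄ chosen so
  DVR = V_T/V_REF ∈ [1.25, 1.42]. The faster k₂ matters: the Logan
  reference-tissue form used here omits the reference-efflux (k2′)
  correction term — as the quoted formulation does — and the residual bias
  of that omission at t* = 30 min is held under ~1.5% by the equilibration
  speed, inside the 5% recovery tolerance.

The carotid discs carry the plasma input itself so image-derived input
function (IDIF) extraction is exercisable end-to-end: `extract_idif()` sums
frames starting within 45 s, finds (or is given) carotid centres, and
averages 5-mm-diameter disc ROIs (three consecutive slices in 3-D).

What the generator does **not** emulate: anatomical realism (MRI-derived
phantoms), scatter and randoms, within-frame motion, partial-volume
correction, inter-subject variability. Passing tests demonstrate the
algorithmic correctness of the pipeline under its own physics model, not
clinical performance.

## Kinetic quantification

`logan_dvr()` regresses ∫C_T/C_T on ∫C_REF/C_T for mid-frame times ≥ t*
(default 30 min, where the plot is considered linear); the slope is DVR.
`patlak_ki()` regresses C_T/C_P on ∫C_P/C_P (t* default 20 min — the
protocol states none for this analysis; 20 min leaves the five-to-seven late
frames that dominate the slope); the slope is Kᵢ. Integrals are trapezoids
from time zero with an implicit (0,0) anchor. `parametric_image()` runs the
same fits per voxel, vectorized, with a validity mask excluding voxels with
nonpositive denominators in the fit window; negative slopes are retained
deliberately so the known noise-induced negative bias of graphical methods
remains observable, and no smoothing is applied before fitting.

## Validation design and problem sizes

The test suite builds every fixture in code. Scales were chosen as the
package's own desk-scale conditions:

* **Repositioning experiment** (registration accuracy): 128×128, 2 mm grid,
  twelve 10-min frames carrying the preset Y/Z translations (including the
  −18.9 mm and (−10, 20) mm positions), Poisson noise, non-AC
  reconstructions, NCC registration. Acceptance: every scalar
  co-registration error < 2 mm (noisy) and < 1 voxel (noiseless rendering).
* **Attenuation-mismatch contrast**: one late FDG-like frame reconstructed
  with aligned, 2-mm-shifted and 10-mm-shifted μ-maps. The 10-mm maximum
  regional bias must exceed three times the 2-mm bias; the 2-mm bias must
  sit within the seed-to-seed spread of the aligned case (plus a 0.5
  percentage-point allowance) and below 5%. Measured values: ~2% aligned,
  ~2.7% at 2 mm, ~14% at 10 mm.
* **End-to-end benefit**: 64×64, 3 mm dynamic FDDNP (20 frames, reference 7,
  sustained movement from 40 min) and FDG (24 frames, reference 24,
  sustained movement from 30 min) studies with a (−5, 7) mm / 4° sustained
  late movement. A sustained reposition is used because alternating
  movements can cancel in a least-squares slope, masking the artifact.
  Comparisons run in the reference frame's coordinates (truth and masks
  moved by the reference frame's scripted position — with a moved reference
  the whole corrected study legitimately lives there). "Before MC" is the
  same pipeline with all frames attenuation-corrected by the original,
  unmoved CT, then realigned with the same estimated transforms, isolating
  the AC artifact. Asserted orderings: late-frame voxel RMSE vs smoothed
  ground truth, mean |slope − truth| over the five cortical ROIs (Patlak
  against the true input; Logan against the image-extracted cerebellum),
  and graphical-fit residual RMS, all strictly better after MC.
* **Oracle recovery**: noiseless Logan DVR within 5% of the closed-form
  V_T ratio, Patlak Kᵢ within 3% of K₁k₃/(k₂+k₃), DVR ≡ 1 when target =
  reference.

`scripts/acceptance.R` re-runs the noisy repositioning experiment from
scratch at a caller-supplied seed and reports the maximum scalar
co-registration error in mm.

## Known limitations

* The projection model is 2-D parallel-beam; 3-D studies are handled
  slice-by-slice and out-of-plane resolution is not modelled.
* NMI rotation estimation degrades below ~96 voxels across; small-grid
  simulations should restrict rotation search or use larger grids.
* No scatter/randoms model, so AC artifacts here are attenuation-only; real
  mismatch artifacts also perturb scatter correction.
* The IDIF carries partial-volume bias at coarse voxel sizes; kinetic
  *orderings* are unaffected but absolute Kᵢ from small-structure IDIFs is
  biased, as it is in practice without partial-volume correction.
* Within-frame motion is out of scope; the method corrects inter-frame
  motion only.
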