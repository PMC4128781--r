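# petmc

Retrospective, image-based movement correction for dynamic brain PET/CT,
with downstream kinetic quantification — plus a complete synthetic-study
generator (digital head phantom, compartment-model kinetics,
projection/reconstruction physics) so everything is verifiable end-to-end
without scanner data.

## The problem

Dynamic brain PET/CT studies last an hour or more. When the head moves, the
single CT acquired at the start no longer matches the late PET frames, and
CT-based attenuation correction (AC) then stamps structured bias into the
reconstructed images — bias that realigning the images afterwards cannot
remove. Inter-frame misalignment additionally corrupts region time–activity
curves (TACs) and everything estimated from them: Logan distribution volume
ratios (DVR) for reversible tracers, Patlak uptake constants
(K_i = slope of C_T(t)/C_P(t) vs ∫C_P dτ/C_P(t)) for irreversible ones.

`petmc` implements the retrospective fix as a pipeline (`run_mc()`):

1. segment the head from the stationary background in the CT;
2. register the head CT to the AC reference PET frame (normalized mutual
   information);
3. register the non-AC reference frame to every other non-AC frame
   (normalized cross-correlation) — n−1 rigid transforms, with sub-90-s
   early frames summed and sharing one transform;
4. move the reference CT with each transform;
5. restore the stationary background (head holder, bed) around each moved CT;
6. re-reconstruct every frame with attenuation-weighted OSEM (default
   6 iterations × 16 subsets) using its own moved CT;
7. realign all AC frames to the reference frame.

Quantification tools: `extract_tac()`, `extract_idif()` (image-derived input
function from 5-mm carotid ROIs on the first-45-s summed image),
`logan_dvr()`, `patlak_ki()`, `parametric_image()`, `auc()`; evaluation
tools: `displacement()`, `registration_error()`, `difference_map()`,
`lr_asymmetry()`.

## Worked example

Simulate the phantom repositioning experiment — twelve 10-min frames with
preset translations up to 18.9 mm and (−10, 20) mm — then estimate the
movements from the noisy reconstructions:

```r
library(petmc)

sch    <- phantom_schedule()                       # 12 x 10-min frames
script <- make_phantom_repositioning_script(sch, "2d")   # preset Y/Z positions
sim    <- simulate_study(c(128, 128), 2, tracer = "fdg",
                         schedule = sch, script = script, seed = 1)

res <- run_mc(sim$phantom$ct, sim$sinograms, sch,
              mc_config(reference_frame = 1),
              recon_scale = sim$recon_scale)
res
#> <mc_result> 12 frames (reference FR1)
#>   displacement: mean 7.11 mm, max 22.44 mm (frame 9)

err <- vapply(2:12, function(f)
  registration_error(script$transforms[[f]],
                     res$transforms$transforms[[f]])$scalar_mm, numeric(1))
max(err)
#> [1] 0.1675198
```

The largest preset displacement is frame 9 at √(10² + 20²) ≈ 22.36 mm; the
pipeline recovers every frame's movement with a scalar co-registration error
(|preset displacement − estimated displacement|) well under the 2-mm level
at which AC artifacts would be reintroduced, and under the 2-mm voxel size.

For a dynamic study with late head movement, `make_late_movement_script()`
injects a sustained ≥5 mm / 4° reposition, and the corrected series improves
late-frame RMSE, Logan/Patlak residual scatter, and |DVR/K_i − truth| over
the uncorrected one (see `tests/testthat/test-acceptance.R`).

## Layout

* `R/phantom.R`, `R/kinetics_sim.R` — digital phantom, tracer kinetics,
  movement scripts, study simulator (`simulate_study()`)
* `R/projection.R`, `src/projector.cpp` — forward/back projection, HU→μ,
  attenuation factors, Poisson emission simulation, AW-OSEM
* `R/registration.R`, `R/transforms.R` — rigid transform algebra, NMI/NCC,
  multi-resolution registration
* `R/mc.R` — the movement-correction pipeline and evaluation metrics
* `R/kinetics.R` — TACs, IDIF, Logan/Patlak, parametric images
* `R/io.R` — NIfTI volumes/series, timing sidecars, transform files,
  study bundles; `inst/cli/petmc.R` — command-line wrapper
* `vignettes/movement-correction.Rmd` — methods, parameter choices,
  validation design, limitations
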