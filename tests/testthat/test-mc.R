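test_that("head/background decomposition recomposes the CT exactly", {
  ph <- phantom128()
  seg <- segment_head(ph$ct)
  expect_identical(pmax(as.numeric(seg$head_ct), as.numeric(seg$background_ct)),
                   as.numeric(ph$ct))
  # inside the mask the background is air
  m <- as.numeric(seg$head_mask) > 0.5
  expect_true(all(as.numeric(seg$background_ct)[m] == -1000))
  expect_true(all(as.numeric(seg$head_ct)[!m] == -1000))
})

test_that("the head mask covers the head and excludes the holder (label oracle)", {
  ph <- phantom128()
  seg <- segment_head(ph$ct)
  head_v <- role_idx(ph, head_roles(ph))
  cover <- sum(seg$head_mask[head_v]) / sum(head_v)
  expect_gte(cover, 0.99)
  expect_equal(sum(seg$head_mask[role_idx(ph, "head_holder")]), 0)
  expect_error(segment_head(image_volume(matrix(-1000, 32, 32), 2, "CT-HU")),
               "no above-air")
})

test_that("displacement is the Euclidean norm of the centre translation", {
  expect_equal(displacement(rigid_transform()), 0)
  expect_equal(displacement(rigid_transform(ty = -10, tz = 20)), sqrt(500))
  expect_equal(displacement(rigid_transform(ty = -18.9)), 18.9)
  # rotations contribute nothing at the image centre
  expect_equal(displacement(rigid_transform(rx = 30, rz = 45)), 0)
})

test_that("registration error: scalar definition and scalar <= vector bound", {
  e <- registration_error(rigid_transform(tz = 10), rigid_transform(tz = 9.2))
  expect_equal(e$scalar_mm, 0.8, tolerance = 1e-12)
  expect_equal(registration_error(rigid_transform(tx = 3),
                                  rigid_transform(tx = 3))$scalar_mm, 0)
  set.seed(5)
  for (i in 1:50) {
    A <- rigid_transform(rnorm(1, 0, 10), rnorm(1, 0, 10), rnorm(1, 0, 10))
    B <- rigid_transform(rnorm(1, 0, 10), rnorm(1, 0, 10), rnorm(1, 0, 10))
    e <- registration_error(A, B)
    expect_lte(e$scalar_mm, e$vector_mm + 1e-12)
  }
})

test_that("difference maps are antisymmetric and zero-centred", {
  a <- phantom_activity(phantom64())
  b <- vol_like(as.numeric(a) + rnorm(length(a), 0, 0.1), a)
  expect_true(all(difference_map(a, a) == 0))
  expect_equal(as.numeric(difference_map(a, b)),
               -as.numeric(difference_map(b, a)))
  dr <- attr(difference_map(a, b), "display_range")
  expect_equal(dr[1], -dr[2])
  expect_error(difference_map(a, image_volume(matrix(0, 2, 2), 1)),
               "congruent")
})

test_that("left-right asymmetry: symmetric volume 0%, one side doubled 66.7%", {
  v <- image_volume(matrix(3, 32, 32), 2)
  mask <- image_volume(matrix(1, 32, 32), 2)
  expect_equal(lr_asymmetry(v, mask), 0)
  doubled <- matrix(3, 32, 32)
  doubled[, 17:32] <- 6
  expect_equal(lr_asymmetry(image_volume(doubled, 2), mask),
               abs(6 - 3) / 4.5 * 100, tolerance = 1e-9)
  expect_error(lr_asymmetry(v, image_volume(matrix(0, 32, 32), 2)), "empty")
  expect_error(lr_asymmetry(v, mask, midline = 40), "midline")
})

test_that("run_mc bookkeeping: n-1 transforms, identity reference, displacement 0", {
  sch <- phantom_schedule(4, 300)
  sim <- simulate_study(c(64, 64), 3, tracer = "fdg", schedule = sch,
                        script = NULL, geom = tiny_geom(n_rad = 56, n_ang = 32),
                        sensitivity = 2e-3, seed = 3)
  cfg <- mc_config(reference_frame = 1, early_window_s = 0,
                   n_iter = 4, n_subsets = 8)
  res <- run_mc(sim$phantom$ct, sim$sinograms, sch, cfg,
                recon_scale = sim$recon_scale, keep_uncorrected = TRUE)
  .fixture_env$mc_still <- res
  .fixture_env$mc_still_sim <- sim
  expect_length(res$transforms$transforms, 4)
  non_ref <- res$transforms$transforms[-1]
  expect_length(non_ref, 3)                       # n - 1 transforms
  expect_true(is_identity_transform(res$transforms$transforms[[1]]))
  expect_equal(res$displacement_mm[1], 0)
})

test_that("zero-movement MC is a no-op: sub-mm estimates, series matches no-MC recon", {
  res <- .fixture_env$mc_still
  sim <- .fixture_env$mc_still_sim
  expect_true(all(res$displacement_mm < 1))
  # corrected equals the standard (original-CT) reconstruction within noise
  ph <- sim$phantom
  for (f in c(2, 4)) {
    a <- as.numeric(res$corrected$frames[[f]])
    b <- as.numeric(res$uncorrected$frames[[f]])
    gray <- role_idx(ph, c("gray", "frontal", "cerebellum"))
    expect_equal(mean(a[gray]), mean(b[gray]), tolerance = 0.05)
  }
})

test_that("moved CT composites leave no voxel undefined and keep the holder fixed", {
  res <- .fixture_env$mc_still
  sim <- .fixture_env$mc_still_sim
  holder <- role_idx(sim$phantom, "head_holder")
  for (f in 1:4) {
    ctf <- res$moved_ct[[f]]
    expect_true(all(is.finite(as.numeric(ctf))))
    expect_true(all(as.numeric(ctf) >= -1000))
    expect_equal(as.numeric(ctf)[holder], as.numeric(sim$phantom$ct)[holder])
  }
})

test_that("negligible-movement skip returns the original reconstruction", {
  sim <- .fixture_env$mc_still_sim
  sch <- phantom_schedule(4, 300)
  cfg <- mc_config(reference_frame = 1, early_window_s = 0, n_iter = 4,
                   n_subsets = 8, skip_if_negligible = TRUE,
                   reg_rotation = FALSE)
  res <- run_mc(sim$phantom$ct, sim$sinograms, sch, cfg,
                recon_scale = sim$recon_scale)
  expect_true(res$skipped)
  expect_identical(as.numeric(res$moved_ct[[2]]), as.numeric(sim$phantom$ct))
})

test_that("MC on an already-corrected series estimates near-identity transforms", {
  res <- .fixture_env$mc_still
  sim <- .fixture_env$mc_still_sim
  sch <- phantom_schedule(4, 300)
  # feed the corrected frames back in as the non-AC series
  cfg <- mc_config(reference_frame = 1, early_window_s = 0, n_iter = 4,
                   n_subsets = 8)
  res2 <- run_mc(sim$phantom$ct, sim$sinograms, sch, cfg,
                 recon_scale = sim$recon_scale, dynamic_nonac = res$corrected)
  voxel <- max(vol_spacing(sim$phantom$ct))
  expect_true(all(res2$displacement_mm < voxel))
})

test_that("missing sinograms are rejected", {
  sim <- .fixture_env$mc_still_sim
  sch <- phantom_schedule(4, 300)
  expect_error(run_mc(sim$phantom$ct, sim$sinograms[1:3], sch, mc_config()),
               "missing sinogram")
})
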