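make_dyn <- function(frames_vals, sch, template) {
  dynamic_series(lapply(frames_vals, function(v)
    vol_like(array(v, dim(template)), template, "PET-activity")), sch)
}

test_that("extract_tac averages over the mask at mid-frame times", {
  ph <- phantom64()
  sch <- frame_schedule(c(0, 60, 120), c(60, 60, 60))
  dyn <- make_dyn(list(1, 2, 3), sch, ph$ct)
  m <- region_mask(ph$labels, "gray")
  tt <- extract_tac(dyn, m)
  expect_equal(tt$conc, c(1, 2, 3))
  expect_equal(tt$time_min, sch$mid_min)
  # single-voxel mask returns that voxel's series
  sv <- array(0, dim(ph$ct)); sv[30, 30] <- 1
  frames <- lapply(1:3, function(f) {
    a <- array(f, dim(ph$ct)); a[30, 30] <- 10 * f
    vol_like(a, ph$ct, "PET-activity")
  })
  tt2 <- extract_tac(dynamic_series(frames, sch), vol_like(sv, ph$ct))
  expect_equal(tt2$conc, c(10, 20, 30))
  expect_error(extract_tac(dyn, vol_like(array(0, dim(ph$ct)), ph$ct)),
               "empty mask")
})

test_that("region TACs of a noiseless rendered phantom match the simulated kinetics", {
  ph <- phantom64()
  sch <- fdg_schedule()
  tacs <- simulate_region_tacs(ph$labels, default_kinetics("fdg"), 60)
  dyn <- render_dynamic_pet(ph$labels, tacs, sch)
  for (role in c("gray", "cerebellum", "frontal")) {
    got <- extract_tac(dyn, region_mask(ph$labels, role))
    want <- vapply(seq_len(nrow(sch)), function(f)
      auc(tacs[[role]], sch$start_s[f] / 60,
          (sch$start_s[f] + sch$dur_s[f]) / 60) / (sch$dur_s[f] / 60),
      numeric(1))
    expect_equal(got$conc, want, tolerance = 0.01)
  }
})

test_that("IDIF recovery: 45-s summation window, 5-mm discs, input shape", {
  ph <- phantom64()
  sch <- fdg_schedule()
  tacs <- simulate_region_tacs(ph$labels, default_kinetics("fdg"), 60)
  dyn <- render_dynamic_pet(ph$labels, tacs, sch)
  idif <- extract_idif(dyn, roi_diameter_mm = 5)
  cp <- attr(tacs, "input")
  # peak frame within one frame of the true input's peak
  pk_true <- cp$time_min[which.max(cp$conc)]
  pk_frames <- which(sch$mid_min >= pk_true)[1] + c(-1, 0, 1)
  expect_true(which.max(idif$conc) %in% pk_frames)
  # late tail close to the true input (no noise, direct rendering)
  late <- sch$mid_min > 30
  cp_late <- stats::approx(cp$time_min, cp$conc, sch$mid_min[late])$y
  expect_equal(idif$conc[late], cp_late, tolerance = 0.15)
  # ROI discs have the prescribed 5-mm scale (within one voxel ring)
  roi <- attr(idif, "roi_mask")
  area_per_disc <- sum(roi) / length(attr(idif, "centres"))
  r_vox <- vol_spacing(dyn$frames[[1]])[1]
  expect_lte(area_per_disc, ceiling(pi * (2.5 + r_vox)^2 / r_vox^2))
  expect_error(extract_idif(dynamic_series(dyn$frames[1], frame_schedule(0, 30))),
               "shorter")
})

test_that("Logan DVR identities: unit slope for target = reference, closed-form recovery", {
  tg <- seq(0.02, 65, by = 0.02)
  cp <- simulate_input_function(tg)
  mid <- fddnp_schedule()$mid_min
  kin <- default_kinetics("fddnp")
  cer <- kin[kin$region == "cerebellum", ]
  cref <- simulate_tissue_tac(cer$K1, cer$k2, cer$k3, cer$k4, cp, mid)
  fit_same <- logan_dvr(cref, cref, 30)
  expect_equal(fit_same$slope, 1, tolerance = 1e-6)
  for (role in c("medial_temporal", "frontal")) {
    row <- kin[kin$region == role, ]
    ctt <- simulate_tissue_tac(row$K1, row$k2, row$k3, row$k4, cp, mid)
    fit <- logan_dvr(ctt, cref, 30)
    truth <- vt_macro(row$K1, row$k2, row$k3, row$k4) /
      vt_macro(cer$K1, cer$k2, cer$k3, cer$k4)
    expect_equal(fit$slope, truth, tolerance = 0.05)
  }
  expect_error(logan_dvr(cref, simulate_tissue_tac(0.1, 0.2, 0, 0, cp, mid[-1]),
                         30), "time grid")
})

test_that("noise in C_T biases Logan DVR downward (median over replicates)", {
  tg <- seq(0.02, 65, by = 0.02)
  cp <- simulate_input_function(tg)
  mid <- fddnp_schedule()$mid_min
  kin <- default_kinetics("fddnp")
  row <- kin[kin$region == "lateral_temporal", ]
  cer <- kin[kin$region == "cerebellum", ]
  ctt <- simulate_tissue_tac(row$K1, row$k2, row$k3, row$k4, cp, mid)
  cref <- simulate_tissue_tac(cer$K1, cer$k2, cer$k3, cer$k4, cp, mid)
  dvr0 <- logan_dvr(ctt, cref, 30)$slope
  set.seed(99)
  reps <- replicate(200, {
    noisy <- tac(mid, pmax(ctt$conc * (1 + rnorm(length(mid), 0, 0.2)), 1e-3))
    logan_dvr(noisy, cref, 30)$slope
  })
  expect_lte(stats::median(reps), dvr0)
})

test_that("Patlak identities: flat plot without trapping, closed form, homogeneity", {
  tg <- seq(0.02, 60, by = 0.02)
  cp <- simulate_input_function(tg)
  mid <- fdg_schedule()$mid_min
  cpt <- tac(mid, stats::approx(c(0, tg), c(0, cp$conc), mid)$y)
  # k3 = 0: no trapping, slope ~ 0
  ct0 <- simulate_tissue_tac(0.1, 0.15, 0, 0, cp, mid)
  expect_lt(abs(patlak_ki(ct0, cpt, 20)$slope), 0.002)
  ct1 <- simulate_tissue_tac(0.1, 0.15, 0.08, 0, cp, mid)
  fit <- patlak_ki(ct1, cpt, 20)
  expect_equal(fit$slope, 0.1 * 0.08 / (0.15 + 0.08), tolerance = 0.03)
  # doubling C_P halves the slope
  cpt2 <- tac(mid, 2 * cpt$conc)
  expect_equal(patlak_ki(ct1, cpt2, 20)$slope, fit$slope / 2,
               tolerance = 1e-9)
  expect_error(patlak_ki(ct1, tac(mid, rep(0, length(mid))), 20), "positive")
})

test_that("DVR and Ki are invariant under global intensity rescaling", {
  tg <- seq(0.02, 60, by = 0.02)
  cp <- simulate_input_function(tg)
  mid <- fdg_schedule()$mid_min
  cpt <- tac(mid, stats::approx(c(0, tg), c(0, cp$conc), mid)$y)
  ct1 <- simulate_tissue_tac(0.1, 0.15, 0.08, 0, cp, mid)
  f1 <- patlak_ki(ct1, cpt, 20)$slope
  f2 <- patlak_ki(tac(mid, 3.7 * ct1$conc), tac(mid, 3.7 * cpt$conc), 20)$slope
  expect_equal(f1, f2, tolerance = 1e-9)
  ctr <- simulate_tissue_tac(0.12, 0.25, 0.02, 0.06, cp, mid)
  crf <- simulate_tissue_tac(0.12, 0.25, 0, 0, cp, mid)
  expect_equal(logan_dvr(ctr, crf, 30)$slope,
               logan_dvr(tac(mid, 5 * ctr$conc), tac(mid, 5 * crf$conc),
                         30)$slope,
               tolerance = 1e-9)
})

test_that("graphical fits reject too-few points past t*", {
  mid <- fdg_schedule()$mid_min
  ct <- tac(mid, seq_along(mid))
  expect_error(patlak_ki(ct, tac(mid, rep(1, length(mid))), 58), "3 points")
})

test_that("parametric images reproduce ROI fits on region-wise constant data", {
  ph <- phantom64()
  sch <- fddnp_schedule()
  tacs <- simulate_region_tacs(ph$labels, default_kinetics("fddnp"), 65)
  dyn <- render_dynamic_pet(ph$labels, tacs, sch)
  cref <- extract_tac(dyn, region_mask(ph$labels, "cerebellum"))
  pim <- parametric_image(dyn, cref, "logan", 30)
  valid <- attr(pim, "valid")
  # background voxels are excluded by the validity mask
  expect_true(all(valid[role_idx(ph, "background")] == 0))
  kin <- default_kinetics("fddnp")
  cer <- kin[kin$region == "cerebellum", ]
  for (role in c("frontal", "lateral_temporal")) {
    m <- role_idx(ph, role) & as.numeric(valid) > 0.5
    roi_fit <- logan_dvr(extract_tac(dyn, region_mask(ph$labels, role)),
                         cref, 30)$slope
    # voxelwise fit equals the ROI fit on noiseless region-constant data
    expect_equal(stats::median(pim[m]), roi_fit, tolerance = 1e-6)
    row <- kin[kin$region == role, ]
    truth <- vt_macro(row$K1, row$k2, row$k3, row$k4) /
      vt_macro(cer$K1, cer$k2, cer$k3, cer$k4)
    expect_equal(stats::median(pim[m]), truth, tolerance = 0.07)
  }
})
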