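test_that("phantom CT has air background and all named regions populated", {
  ph <- phantom128()
  dict <- ph$labels$dict
  expect_equal(unique(ph$ct[as.integer(ph$labels$vol) == dict[["background"]]]),
               -1000)
  for (role in names(dict))
    expect_gt(sum(as.integer(ph$labels$vol) == dict[[role]]), 0)
  expect_true(all(ph$ct >= -1000))
})

test_that("labels partition the grid and head regions are disjoint from the holder", {
  ph <- phantom128()
  lab <- as.integer(ph$labels$vol)
  # every voxel carries exactly one dictionary label
  expect_true(all(lab %in% ph$labels$dict))
  head_n <- sum(lab %in% ph$labels$dict[head_roles(ph)])
  per_region <- sum(vapply(head_roles(ph), function(r)
    sum(lab == ph$labels$dict[[r]]), numeric(1)))
  expect_equal(head_n, per_region)
  expect_equal(sum(lab %in% ph$labels$dict[head_roles(ph)] &
                     lab == ph$labels$dict[["head_holder"]]), 0)
})

test_that("head sits inside the field of view with >= 10% margin", {
  ph <- phantom128()
  idx <- which(array(role_idx(ph, head_roles(ph)), dim(ph$ct)), arr.ind = TRUE)
  d <- dim(ph$ct)
  for (ax in 1:2) {
    margin <- min(min(idx[, ax]) - 1, d[ax] - max(idx[, ax]))
    expect_gte(margin, 0.1 * d[ax])
  }
})

test_that("a grid too small for the anatomy is rejected", {
  expect_error(make_digital_phantom(c(16, 16), 2), "32")
  expect_error(make_digital_phantom(c(32, 32), 0.5), "too small")
})

test_that("the preset movement script reproduces the printed phantom positions", {
  sc <- make_phantom_repositioning_script(phantom_schedule(), "2d")
  df <- as.data.frame(sc)
  expect_true(is_identity_transform(sc$transforms[[1]]))
  expect_equal(df$tx[10], -18.9)   # frame 10 Y translation
  expect_equal(unname(c(df$tx[9], df$ty[9])), c(-10, 20))
  expect_equal(unname(c(df$tx[8], df$ty[8])), c(5, 10))
  expect_true(all(df$rx == 0 & df$ry == 0 & df$rz == 0))
  # 3-D mode maps Y/Z onto ty/tz
  sc3 <- make_phantom_repositioning_script(phantom_schedule(), "3d")
  df3 <- as.data.frame(sc3)
  expect_equal(df3$ty, df$tx)
  expect_equal(df3$tz, df$ty)
  expect_true(all(df3$tx == 0))
})

test_that("rendered frames average the TAC over each frame interval", {
  ph <- phantom64()
  sch <- frame_schedule(c(0, 120, 300), c(120, 180, 300))
  tg <- seq(0.01, 12, by = 0.01)
  tacs <- stats::setNames(
    lapply(head_roles(ph), function(r) tac(tg, 10 * (1 - exp(-0.5 * tg)))),
    head_roles(ph))
  dyn <- render_dynamic_pet(ph$labels, tacs, sch)
  gray_idx <- role_idx(ph, "gray")
  for (f in 1:3) {
    t0 <- sch$start_s[f] / 60; t1 <- (sch$start_s[f] + sch$dur_s[f]) / 60
    tq <- seq(t0, t1, length.out = 1000)          # fine-quadrature oracle
    expected <- mean(10 * (1 - exp(-0.5 * tq)))
    got <- unique(round(dyn$frames[[f]][gray_idx], 9))
    expect_equal(got, expected, tolerance = 1e-3)
  }
})

test_that("identity script with constant TACs renders identical frames", {
  ph <- phantom64()
  sch <- frame_schedule(c(0, 60), c(60, 60))
  tg <- seq(0, 3, by = 0.01)
  tacs <- stats::setNames(
    lapply(head_roles(ph), function(r) tac(tg, rep(5, length(tg)))),
    head_roles(ph))
  dyn <- render_dynamic_pet(ph$labels, tacs, sch,
                            movement_script(rep(list(rigid_transform()), 2)))
  expect_identical(as.numeric(dyn$frames[[1]]), as.numeric(dyn$frames[[2]]))
  expect_equal(unique(as.numeric(dyn$frames[[1]][role_idx(ph, "background")])), 0)
})

test_that("a missing region TAC is rejected", {
  ph <- phantom64()
  sch <- frame_schedule(0, 60)
  expect_error(render_dynamic_pet(ph$labels, list(gray = tac(1:3, 1:3)), sch),
               "missing region TAC")
})

test_that("rendered moved frames shift the centroid by the scripted translation", {
  ph <- phantom64()
  sch <- phantom_schedule(12, 600)
  sc <- make_phantom_repositioning_script(sch, "2d")
  tg <- seq(0, 121, by = 0.05)
  tacs <- stats::setNames(
    lapply(head_roles(ph), function(r) tac(tg, rep(3, length(tg)))),
    head_roles(ph))
  dyn <- render_dynamic_pet(ph$labels, tacs, sch, sc)
  c1 <- centroid_mm(dyn$frames[[1]])
  c8 <- centroid_mm(dyn$frames[[8]])        # preset (Y, Z) = (5, 10) mm
  half_voxel <- max(vol_spacing(ph$ct)) / 2
  expect_lt(max(abs((c8 - c1) - c(5, 10))), half_voxel)
  c9 <- centroid_mm(dyn$frames[[9]])        # preset (Y, Z) = (-10, 20) mm
  expect_lt(max(abs((c9 - c1) - c(-10, 20))), half_voxel)
})

test_that("kinetic defaults give irreversible FDG-like and reversible FDDNP-like sets", {
  fdg <- default_kinetics("fdg")
  expect_true(all(fdg$k4 == 0))
  expect_true(all(fdg[, c("K1", "k2", "k3")] >= 0))
  fddnp <- default_kinetics("fddnp")
  cer <- fddnp[fddnp$region == "cerebellum", ]
  expect_equal(cer$k3, 0)                   # non-binding reference region
  targets <- fddnp[!fddnp$region %in% c("cerebellum", "white"), ]
  dvr <- apply(targets, 1, function(r)
    vt_macro(as.numeric(r["K1"]), as.numeric(r["k2"]), as.numeric(r["k3"]),
             as.numeric(r["k4"])) / vt_macro(cer$K1, cer$k2, cer$k3, cer$k4))
  expect_true(all(dvr >= 1 & dvr <= 1.5))
})
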