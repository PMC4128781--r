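#' Region label map of the digital brain phantom
#'
#' @param vol an [image_volume] of integer labels (modality `"label"`).
#' @param dict named integer vector: role name -> label value.  Roles include
#'   background, head_holder, scalp, skull, gray, white, cerebellum, frontal,
#'   parietal, lateral_temporal, medial_temporal, posterior_cingulate,
#'   carotid.
#' @export
region_label_map <- function(vol, dict) {
  if (anyDuplicated(names(dict)) || anyDuplicated(dict))
    stop("label dictionary must be one-to-one")
  if (!all(as.integer(vol) %in% dict))
    stop("volume contains labels absent from the dictionary")
  structure(list(vol = vol, dict = dict), class = "region_label_map")
}

#' @export
print.region_label_map <- function(x, ...) {
  cat(sprintf("<region_label_map> %s voxels, %d roles\n",
              paste(dim(x$vol), collapse = "x"), length(x$dict)))
  counts <- table(factor(as.integer(x$vol), levels = x$dict,
                         labels = names(x$dict)))
  print(counts)
  invisible(x)
}

#' Binary mask of one or more labelled roles
#' @param labels a [region_label_map].
#' @param roles character vector of role names.
#' @return an [image_volume] of 0/1 values.
#' @export
region_mask <- function(labels, roles) {
  miss <- setdiff(roles, names(labels$dict))
  if (length(miss)) stop("unknown roles: ", paste(miss, collapse = ", "))
  m <- array(as.numeric(as.integer(labels$vol) %in% labels$dict[roles]),
             dim(labels$vol))
  vol_like(m, labels$vol, modality = "generic")
}

# roles carrying tracer activity (everything inside the head contour)
head_region_roles <- function(labels) {
  setdiff(names(labels$dict), c("background", "head_holder"))
}

#' Digital brain phantom: label map and CT
#'
#' Constructs a Hoffman-like digital head phantom on a regular grid: scalp
#' ellipse, skull shell, cortical gray-matter ribbon carved into named
#' anatomical regions (frontal, parietal, lateral temporal, cerebellum, plus
#' generic gray), deep structures (medial temporal, posterior cingulate)
#' inside the white-matter core, two small carotid-artery discs, and a
#' posterior head-holder arc that is part of the stationary background.  The
#' CT assigns air -1000 HU, soft tissue 35-50 HU, skull +800 HU and the
#' head holder +200 HU.  The head is placed with at least 10% margin to the
#' field-of-view edge so preset movements of the repositioning-protocol scale keep it
#' in-field.
#'
#' In 2-D mode the image plane is the (Y, Z) plane of the scanner (Y
#' perpendicular to the bed, axis 1; Z along the bed, axis 2).
#'
#' @param grid_shape integer vector: 2 (2-D) or 3 (3-D) voxel counts, each
#'   >= 32.
#' @param spacing_mm voxel spacing, mm (recycled).
#' @return list with elements `labels` (a [region_label_map]) and `ct`
#'   (an [image_volume], CT-HU).
#' @export
make_digital_phantom <- function(grid_shape = c(128, 128), spacing_mm = 2) {
  nd <- length(grid_shape)
  if (!nd %in% c(2L, 3L)) stop("grid_shape must have 2 or 3 elements")
  if (any(grid_shape < 32)) stop("grid too small to contain all labelled regions (need >= 32 per axis)")
  sp <- rep_len(as.numeric(spacing_mm), nd)
  ext <- grid_shape * sp
  # head must fit with >= 10% margin per side
  ay <- 0.30 * ext[1]; az <- 0.36 * ext[2]      # scalp semi-axes, mm
  if (nd == 3L) ax3 <- 0.32 * ext[3] else ax3 <- Inf
  x <- axis_coords(grid_shape[1], sp[1])
  y <- axis_coords(grid_shape[2], sp[2])
  if (nd == 2L) {
    X <- matrix(x, grid_shape[1], grid_shape[2])
    Y <- matrix(y, grid_shape[1], grid_shape[2], byrow = TRUE)
    Z <- array(0, grid_shape)
  } else {
    z <- axis_coords(grid_shape[3], sp[3])
    X <- array(rep(x, times = prod(grid_shape[2:3])), grid_shape)
    Y <- array(rep(rep(y, each = grid_shape[1]), grid_shape[3]), grid_shape)
    Z <- array(rep(z, each = prod(grid_shape[1:2])), grid_shape)
  }
  inside <- function(a, b, c3, cx = 0, cy = 0)
    ((X - cx) / a)^2 + ((Y - cy) / b)^2 +
      (if (is.finite(c3)) (Z / c3)^2 else 0) < 1
  s <- min(ay, az) / 78            # scale all interior structures together
  scalp  <- inside(ay, az, ax3)
  skull  <- inside(ay - 4 * s, az - 4 * s, ax3 - 4 * s)
  brain  <- inside(ay - 10 * s, az - 10 * s, ax3 - 10 * s)
  white  <- inside(0.52 * ay, 0.55 * az, 0.55 * ax3, 0, 4 * s)
  ribbon <- brain & !white
  th <- atan2(Y, X) * 180 / pi     # 0 deg = +Y(axis1), 90 = +Z(axis2)
  lab <- array(0L, grid_shape)
  dict <- c(background = 0L, head_holder = 1L, scalp = 2L, skull = 3L,
            gray = 4L, white = 5L, cerebellum = 6L, frontal = 7L,
            parietal = 8L, lateral_temporal = 9L, medial_temporal = 10L,
            posterior_cingulate = 11L, carotid = 12L)
  lab[scalp] <- dict[["scalp"]]
  lab[skull] <- dict[["skull"]]
  lab[brain] <- dict[["gray"]]
  lab[white] <- dict[["white"]]
  sector <- function(lo, hi) ribbon & ((th - lo) %% 360) < ((hi - lo) %% 360)
  lab[sector(60, 120)]  <- dict[["frontal"]]
  lab[sector(120, 170)] <- dict[["parietal"]]
  lab[sector(170, 230)] <- dict[["lateral_temporal"]]
  lab[sector(230, 310)] <- dict[["cerebellum"]]
  disc <- function(cx, cy, r) (X - cx)^2 + (Y - cy)^2 < r^2 &
    (if (nd == 3L) abs(Z) < max(3 * sp[3], 0.25 * ax3) else TRUE)
  lab[white & disc(-14 * s, -18 * s, 9 * s)] <- dict[["medial_temporal"]]
  lab[white & disc(14 * s, -18 * s, 9 * s)] <- dict[["medial_temporal"]]
  lab[white & disc(-6 * s, 14 * s, 7 * s)] <- dict[["posterior_cingulate"]]
  lab[brain & (disc(-52 * s, -12 * s, 2.6) | disc(-52 * s, 12 * s, 2.6))] <-
    dict[["carotid"]]
  # posterior head-holder arc: stationary, below the head, 4 mm air gap
  hold <- !inside(ay + 4, az + 4, ax3 + 4) &
    inside(ay + 12, az + 12, if (is.finite(ax3)) ax3 + 12 else Inf) &
    X < -0.45 * ay
  lab[hold] <- dict[["head_holder"]]
  for (role in c("cerebellum", "frontal", "parietal", "lateral_temporal",
                 "medial_temporal", "posterior_cingulate", "carotid",
                 "gray", "white", "skull", "scalp", "head_holder"))
    if (!any(lab == dict[[role]]))
      stop("grid too small to contain all labelled regions (", role, " empty)")
  hu <- c(background = -1000, head_holder = 200, scalp = 40, skull = 800,
          gray = 45, white = 35, cerebellum = 45, frontal = 45,
          parietal = 45, lateral_temporal = 45, medial_temporal = 45,
          posterior_cingulate = 45, carotid = 50)
  ct <- array(hu[match(lab, dict[names(hu)])], grid_shape)
  labels <- region_label_map(image_volume(lab, sp, "label"), dict)
  list(labels = labels, ct = image_volume(ct, sp, "CT-HU"))
}

#' Default kinetic rate constants per phantom region
#'
#' FDG-like parameters are irreversible (`k4 = 0`); FDDNP-like parameters are
#' reversible with cerebellum as the non-binding reference region and target
#' DVRs between 1.25 and 1.42.  No tabulated rate constants exist for these
#' protocols; the defaults are chosen to give physiologic gray:white
#' activity contrast (about 4:1 for FDG) and reference-tissue behaviour
#' suitable for Logan/Patlak analysis.  The carotid region carries the plasma
#' input function itself; skull and scalp carry no activity.
#'
#' @param tracer `"fdg"` or `"fddnp"`.
#' @return data.frame with columns region, K1, k2, k3, k4.
#' @export
default_kinetics <- function(tracer = c("fdg", "fddnp")) {
  tracer <- match.arg(tracer)
  if (tracer == "fdg") {
    df <- data.frame(
      region = c("gray", "white", "cerebellum", "frontal", "parietal",
                 "lateral_temporal", "medial_temporal", "posterior_cingulate"),
      K1 = c(0.100, 0.035, 0.100, 0.110, 0.105, 0.100, 0.095, 0.115),
      k2 = c(0.150, 0.140, 0.150, 0.160, 0.150, 0.150, 0.150, 0.160),
      k3 = c(0.080, 0.055, 0.080, 0.085, 0.080, 0.075, 0.070, 0.090),
      k4 = 0)
  } else {
    df <- data.frame(
      region = c("gray", "white", "cerebellum", "frontal", "parietal",
                 "lateral_temporal", "medial_temporal", "posterior_cingulate"),
      K1 = c(0.120, 0.050, 0.120, 0.120, 0.120, 0.120, 0.120, 0.120),
      k2 = c(0.250, 0.250, 0.250, 0.250, 0.250, 0.250, 0.250, 0.250),
      k3 = c(0.020, 0.010, 0.000, 0.015, 0.018, 0.020, 0.025, 0.022),
      k4 = c(0.060, 0.060, 0.000, 0.060, 0.060, 0.060, 0.060, 0.060))
  }
  df
}

#' Macro-parameters implied by two-tissue rate constants
#'
#' `ki_macro` is the irreversible net uptake constant
#' \eqn{K_1 k_3/(k_2+k_3)}; `vt_macro` the reversible total distribution
#' volume \eqn{(K_1/k_2)(1 + k_3/k_4)}.
#' @param K1,k2,k3,k4 rate constants.
#' @export
ki_macro <- function(K1, k2, k3, k4 = 0) K1 * k3 / (k2 + k3)

#' @rdname ki_macro
#' @export
vt_macro <- function(K1, k2, k3, k4) {
  if (k4 == 0 && k3 > 0) return(Inf)
  K1 / k2 * (1 + if (k4 > 0) k3 / k4 else 0)
}

#' Simulate region TACs for every head region of the phantom
#'
#' Evaluates the plasma input on a fine grid and runs the
#' two-tissue-compartment model per region; the carotid region carries the
#' input function and skull/scalp carry zero activity.
#'
#' @param labels a [region_label_map].
#' @param kinetics data.frame as from [default_kinetics()].
#' @param t_end_min end of simulation, minutes.
#' @param dt fine-grid step, minutes.
#' @param input_scale multiplies the default input function (count-level
#'   control).
#' @return named list of [tac] objects on the fine grid, one per head region,
#'   plus attribute `input` (the plasma TAC).
#' @export
simulate_region_tacs <- function(labels, kinetics, t_end_min, dt = 0.02,
                                 input_scale = 1) {
  tg <- seq(dt, t_end_min + 2 * dt, by = dt)
  cp <- simulate_input_function(tg)
  cp$conc <- cp$conc * input_scale
  out <- list()
  for (role in head_region_roles(labels)) {
    if (role == "carotid") { out[[role]] <- cp; next }
    row <- kinetics[kinetics$region == role, ]
    if (nrow(row) == 0) {
      out[[role]] <- tac(tg, rep(0, length(tg)))   # skull, scalp
    } else {
      out[[role]] <- simulate_tissue_tac(row$K1, row$k2, row$k3, row$k4,
                                         cp, tg, dt = dt)
    }
  }
  attr(out, "input") <- cp
  out
}

#' Render a moved dynamic PET series from region TACs
#'
#' Frame f of the output equals the label map painted with the time-average
#' of each region's TAC over frame f's interval, then rigidly moved by the
#' movement script's transform for that frame.  Background activity is zero.
#'
#' @param labels a [region_label_map].
#' @param region_tacs named list of [tac] (one per head region), e.g. from
#'   [simulate_region_tacs()].
#' @param schedule a [frame_schedule].
#' @param script a [movement_script] (NULL for no movement).
#' @return a [dynamic_series] of PET-activity volumes (kBq/mL).
#' @export
render_dynamic_pet <- function(labels, region_tacs, schedule, script = NULL) {
  roles <- head_region_roles(labels)
  miss <- setdiff(roles, names(region_tacs))
  if (length(miss))
    stop("missing region TAC for: ", paste(miss, collapse = ", "))
  if (!is.null(script) && length(script$transforms) != nrow(schedule))
    stop("movement script length != frame count")
  lab <- as.integer(labels$vol)
  frames <- vector("list", nrow(schedule))
  for (f in seq_len(nrow(schedule))) {
    t0 <- schedule$start_s[f] / 60
    t1 <- (schedule$start_s[f] + schedule$dur_s[f]) / 60
    vals <- numeric(max(labels$dict) + 1L)       # by label value + 1
    for (role in roles)
      vals[labels$dict[[role]] + 1L] <- frame_average(region_tacs[[role]], t0, t1)
    img <- vol_like(array(vals[lab + 1L], dim(labels$vol)), labels$vol,
                    modality = "PET-activity")
    if (!is.null(script) && !is_identity_transform(script$transforms[[f]]))
      img <- apply_transform(img, script$transforms[[f]], fill_value = 0)
    frames[[f]] <- img
  }
  dynamic_series(frames, schedule)
}

#' Preset phantom movement script (repositioning experiment)
#'
#' The twelve relative phantom positions used in the repositioning
#' experiment, as translations in the Y direction (perpendicular to the bed)
#' and Z direction (along the bed axis), in mm, relative to frame 1:
#' Y = (0, 0, -1, 0, 2, 0, 5, 5, -10, -18.9, -2, 10),
#' Z = (0, 1, 0, -2, 0, -5, 0, 10, 20, 0, 2, -10).  X translations and all
#' rotations are zero.
#'
#' In `"2d"` mode (image plane = (Y, Z)), Y maps to axis-1 translation `tx`
#' and Z to axis-2 translation `ty`; in `"3d"` mode they map to `ty` and `tz`.
#' If the schedule has fewer than 12 frames the script is truncated; extra
#' frames hold the last position.
#'
#' @param schedule a [frame_schedule].
#' @param mode `"2d"` or `"3d"`.
#' @return a [movement_script] with frame 1 as reference.
#' @export
make_phantom_repositioning_script <- function(schedule = phantom_schedule(),
                                        mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  Yv <- c(0, 0, -1, 0, 2, 0, 5, 5, -10, -18.9, -2, 10)
  Zv <- c(0, 1, 0, -2, 0, -5, 0, 10, 20, 0, 2, -10)
  n <- nrow(schedule)
  idx <- pmin(seq_len(n), length(Yv))
  trs <- lapply(idx, function(i) {
    if (mode == "2d") rigid_transform(tx = Yv[i], ty = Zv[i])
    else rigid_transform(ty = Yv[i], tz = Zv[i])
  })
  movement_script(trs, reference = 1L)
}

#' Late-frame head-movement script
#'
#' Emulates the common pattern in dynamic patient studies: the head is still
#' early on and moves in late frames, from `onset_min` onwards, at or above
#' the visually-noticeable level (5 mm displacement / 4 degrees).  With
#' `pattern = "sustained"` (default) the head moves once and stays in the
#' new position; with `pattern = "blocks"` the affected frames split into
#' three blocks — a pure translation, a pure rotation, and a combined
#' translation + rotation.
#'
#' @param schedule a [frame_schedule].
#' @param onset_min first moved time, minutes (40).
#' @param mode `"2d"` (in-plane tx/ty/rz) or `"3d"` (ty/tz and rx).
#' @param pattern `"sustained"` or `"blocks"`.
#' @return a [movement_script] with frame 1 as reference.
#' @export
make_late_movement_script <- function(schedule, onset_min = 40,
                                      mode = c("2d", "3d"),
                                      pattern = c("sustained", "blocks")) {
  mode <- match.arg(mode)
  pattern <- match.arg(pattern)
  n <- nrow(schedule)
  moved <- which(schedule$start_s >= onset_min * 60)
  trs <- rep(list(rigid_transform()), n)
  mk <- function(tx, ty, rot) {
    if (mode == "2d") rigid_transform(tx = tx, ty = ty, rz = rot)
    else rigid_transform(ty = tx, tz = ty, rx = rot)
  }
  if (length(moved)) {
    if (pattern == "sustained") {
      for (f in moved) trs[[f]] <- mk(-5, 7, 4)
    } else {
      blocks <- split(moved, cut(seq_along(moved), 3, labels = FALSE))
      presets <- list(mk(6, 0, 0), mk(0, 0, 5), mk(-5, 7, 4))
      for (b in seq_along(blocks))
        for (f in blocks[[b]]) trs[[f]] <- presets[[b]]
    }
  }
  movement_script(trs, reference = 1L)
}

#' Activity-weighted centroid of a volume, mm (world coordinates)
#' @param vol an [image_volume].
#' @export
centroid_mm <- function(vol) {
  d <- dim(vol); sp <- vol_spacing(vol)
  w <- as.numeric(vol)
  w[w < 0] <- 0
  tot <- sum(w)
  if (tot <= 0) return(rep(NA_real_, length(d)))
  vapply(seq_along(d), function(ax) {
    co <- axis_coords(d[ax], sp[ax])
    idx <- slice.index(array(0, d), ax)
    sum(w * co[idx]) / tot
  }, numeric(1))
}
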