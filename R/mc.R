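#' Movement-correction configuration
#'
#' @param reference_frame 1-based reference frame index (in the repositioning
#'   phantom protocol frame 1; 7 for the 20-frame FDDNP protocol; 24 for the
#'   24-frame FDG protocol).
#' @param early_window_s frames starting before this time are summed for a
#'   single co-registration whose transform is replicated to each of them
#'   (90 s, matching the short-early-frame handling); 0 disables summing.
#' @param n_iter,n_subsets AW-OSEM settings for re-reconstruction.
#' @param reg_levels pyramid downsampling factors for registration.
#' @param reg_rotation search rotations as well as translations.
#' @param skip_threshold_mm,skip_threshold_deg if every estimated movement is
#'   below both thresholds and `skip_if_negligible` is TRUE, the original
#'   (uncorrected) reconstruction is returned to avoid the extra resampling
#'   smoothing.
#' @param skip_if_negligible see above (default FALSE).
#' @export
mc_config <- function(reference_frame = 1L, early_window_s = 90,
                      n_iter = 6, n_subsets = 16,
                      reg_levels = c(4, 2, 1), reg_rotation = TRUE,
                      skip_threshold_mm = 1, skip_threshold_deg = 0.5,
                      skip_if_negligible = FALSE) {
  stopifnot(reference_frame >= 1, early_window_s >= 0)
  structure(list(reference_frame = as.integer(reference_frame),
                 early_window_s = early_window_s, n_iter = n_iter,
                 n_subsets = n_subsets, reg_levels = reg_levels,
                 reg_rotation = reg_rotation,
                 skip_threshold_mm = skip_threshold_mm,
                 skip_threshold_deg = skip_threshold_deg,
                 skip_if_negligible = skip_if_negligible),
            class = "mc_config")
}

#' Segment the head from the stationary background in a CT volume
#'
#' Thresholds the CT above `threshold_hu`, closes small gaps morphologically,
#' and keeps the largest connected component as the head; smaller
#' above-threshold structures (head holder, bed) stay in the background.
#' The decomposition is exact: `head_ct` equals the CT inside the mask and
#' -1000 HU (air) outside; `background_ct` is the complement; taking the
#' voxelwise maximum of the two restores the original CT.
#'
#' @param ct an [image_volume] in CT-HU.
#' @param threshold_hu above-air threshold (-500 HU).
#' @param close_iter morphological closing radius in voxels.
#' @return list with `head_ct`, `background_ct` (both CT-HU volumes) and
#'   `head_mask` (0/1 volume).
#' @export
segment_head <- function(ct, threshold_hu = -500, close_iter = 2L) {
  above <- as_plain_array(ct) > threshold_hu
  if (!any(above)) stop("no above-air component found in CT")
  # select first, close after: closing the raw mask can bridge the narrow
  # air gap between the head and the head holder
  comp <- morph_close(largest_component(above), close_iter)
  head <- as_plain_array(ct)
  head[!comp] <- -1000
  bg <- as_plain_array(ct)
  bg[comp] <- -1000
  list(head_ct = vol_like(head, ct, "CT-HU"),
       background_ct = vol_like(bg, ct, "CT-HU"),
       head_mask = vol_like(comp * 1, ct, "generic"))
}

#' Centre-of-image displacement of a rigid transform
#'
#' Euclidean norm of the translation components, in mm.  This is the
#' movement of the grid-centre point: rotations about the centre contribute
#' nothing there, and with rotations present most head locations move more
#' than this measure indicates.
#'
#' @param T a [rigid_transform].
#' @export
displacement <- function(T) sqrt(sum(T$t^2))

#' Co-registration error between preset and estimated movements
#'
#' The primary error is the absolute difference of the two centre-of-image
#' displacements, `|displacement(preset) - displacement(estimated)|`; the
#' stricter vector error `||t_preset - t_estimated||` is reported alongside
#' (it bounds the primary error from above by the reverse triangle
#' inequality).
#'
#' @param preset,estimated [rigid_transform]s in the same convention.
#' @return list with `scalar_mm` and `vector_mm`.
#' @export
registration_error <- function(preset, estimated) {
  list(scalar_mm = abs(displacement(preset) - displacement(estimated)),
       vector_mm = sqrt(sum((preset$t - estimated$t)^2)))
}

#' Voxelwise difference map
#'
#' `a - b` with zero-centred symmetric display range metadata, used to
#' compare reconstructions before/after movement correction.
#'
#' @param a,b congruent [image_volume]s.
#' @return an [image_volume] with attribute `display_range` = c(-m, m).
#' @export
difference_map <- function(a, b) {
  stopifnot_congruent(a, b)
  d <- vol_like(as_plain_array(a) - as_plain_array(b), a, "generic")
  m <- max(abs(d))
  attr(d, "display_range") <- c(-m, m)
  d
}

#' Left-right asymmetry of a volume, percent
#'
#' Mean over mirrored in-mask voxel pairs of `|L - R| / ((L + R)/2) * 100`,
#' mirroring across the midline of `axis`; pairs whose mean is below 10% of
#' the robust (99th percentile) maximum are excluded so air and background
#' do not dominate.  A mirror-symmetric volume scores 0%.
#'
#' @param vol an [image_volume].
#' @param head_mask 0/1 volume; only pairs with both voxels in the mask
#'   count.
#' @param axis mirror axis (default 2, the in-plane left-right axis of the
#'   rendered views).
#' @param midline mirror centre in voxel coordinates (default the grid
#'   midline `(n+1)/2`).
#' @export
lr_asymmetry <- function(vol, head_mask, axis = 2L, midline = NULL) {
  d <- dim(vol)
  if (sum(head_mask) == 0) stop("empty mask")
  n <- d[axis]
  if (is.null(midline)) midline <- (n + 1) / 2
  if (midline < 1 || midline > n) stop("midline outside grid")
  j <- seq_len(n)
  jm <- round(2 * midline - j)
  ok <- jm >= 1 & jm <= n & j < jm          # each pair once
  idx <- rep(list(quote(expr = )), length(d))
  idxm <- idx
  idx[[axis]] <- j[ok]
  idxm[[axis]] <- jm[ok]
  L <- do.call(`[`, c(list(as_plain_array(vol)), idx, list(drop = FALSE)))
  R <- do.call(`[`, c(list(as_plain_array(vol)), idxm, list(drop = FALSE)))
  mL <- do.call(`[`, c(list(as_plain_array(head_mask)), idx, list(drop = FALSE))) > 0.5
  mR <- do.call(`[`, c(list(as_plain_array(head_mask)), idxm, list(drop = FALSE))) > 0.5
  mean_lr <- (L + R) / 2
  floor_v <- 0.1 * stats::quantile(as.numeric(vol)[as.numeric(head_mask) > 0.5],
                                   0.99, names = FALSE)
  keep <- mL & mR & mean_lr > floor_v
  if (!any(keep)) return(0)
  mean(abs(L - R)[keep] / mean_lr[keep]) * 100
}

#' Run the retrospective movement-correction pipeline
#'
#' Executes the eight-step procedure on a dynamic PET/CT study:
#' \enumerate{
#'   \item segment the head from the stationary background in the CT;
#'   \item rigidly register the head CT to the attenuation-corrected
#'     reference PET frame (normalized mutual information), giving CT_REF;
#'   \item register the non-AC reference frame to every other non-AC frame
#'     (normalized cross-correlation), giving n-1 transforms; frames starting
#'     inside the early window are summed first and share one transform;
#'   \item move CT_REF with each transform;
#'   \item add the stationary background back to each moved head CT;
#'   \item re-reconstruct every frame with AW-OSEM using attenuation factors
#'     from its own moved CT;
#'   \item realign the AC frames to the reference frame with the inverse
#'     transforms.
#' }
#'
#' @param ct original CT [image_volume] (head + holder, CT-HU), acquired at
#'   the reference position.
#' @param sinograms list of observed-count [sinogram]s, one per frame.
#' @param schedule a [frame_schedule].
#' @param config an [mc_config].
#' @param recon_shape,recon_spacing reconstruction grid (defaults to the CT
#'   grid).
#' @param recon_scale per-frame multiplicative factors restoring
#'   concentration units, `1/(duration * sensitivity)`; scalar sensitivity
#'   is accepted and expanded using the schedule.
#' @param dynamic_nonac optional precomputed non-AC [dynamic_series]
#'   (reconstructed internally if NULL).
#' @param keep_uncorrected also reconstruct the no-MC comparison series
#'   (all frames attenuation-corrected with the original, unmoved CT, then
#'   realigned with the same transforms).
#' @return an object of class `mc_result`; see [print.mc_result()].
#' @export
run_mc <- function(ct, sinograms, schedule, config = mc_config(),
                   recon_shape = dim(ct), recon_spacing = vol_spacing(ct),
                   recon_scale = NULL, dynamic_nonac = NULL,
                   keep_uncorrected = FALSE) {
  n <- nrow(schedule)
  if (length(sinograms) != n) stop("missing sinogram: need one per frame")
  ref <- config$reference_frame
  if (ref < 1 || ref > n) stop("reference frame outside frame count")
  if (is.null(recon_scale)) recon_scale <- rep(1, n)
  if (length(recon_scale) == 1L) recon_scale <- rep(recon_scale, n)
  geom <- sinograms[[1]]$geom
  warnings <- character()
  recon <- function(sino, factors, scale)
    awosem_reconstruct(sino, factors, recon_shape, recon_spacing,
                       n_iter = config$n_iter, n_subsets = config$n_subsets,
                       scale = scale)
  # Step 0 products: non-AC frames and the AC reference (original CT)
  if (is.null(dynamic_nonac)) {
    nonac <- lapply(seq_len(n), function(f)
      recon(sinograms[[f]], NULL, recon_scale[f]))
    dynamic_nonac <- dynamic_series(nonac, schedule)
  }
  nonac <- dynamic_nonac$frames
  mu0 <- hu_to_mu(ct)
  fac0 <- attenuation_factors(mu0, geom)
  ac_ref <- recon(sinograms[[ref]], fac0, recon_scale[ref])
  # Step 1
  seg <- segment_head(ct)
  # Step 2: head CT -> AC reference PET (NMI)
  T_ct <- register(ac_ref, seg$head_ct, metric = "nmi",
                   levels = config$reg_levels, rotation = config$reg_rotation)
  if (!is.null(attr(T_ct, "warning")))
    warnings <- c(warnings, paste("CT-to-PET:", attr(T_ct, "warning")))
  ct_ref <- apply_transform(seg$head_ct, T_ct, fill_value = -1000)
  mask_ref <- apply_transform(seg$head_mask, T_ct, fill_value = 0)
  # Step 3: reference -> frame transforms on non-AC images (NCC)
  transforms <- vector("list", n)
  transforms[[ref]] <- rigid_transform()
  early <- which(schedule$start_s < config$early_window_s)
  early <- setdiff(early, ref)
  T_early <- NULL
  if (length(early) > 1 && config$early_window_s > 0) {
    w <- schedule$dur_s[early] / sum(schedule$dur_s[early])
    summed <- Reduce(`+`, Map(function(fr, wi) as_plain_array(fr) * wi,
                              nonac[early], w))
    summed <- vol_like(summed, nonac[[1]], "PET-activity")
    if (stats::sd(as.numeric(summed)) < 1e-12) {
      warnings <- c(warnings, "early-frame sum is empty; using identity")
      T_early <- rigid_transform()
    } else {
      T_early <- register(summed, nonac[[ref]], metric = "ncc",
                          levels = config$reg_levels,
                          rotation = config$reg_rotation)
      if (!is.null(attr(T_early, "warning")))
        warnings <- c(warnings, paste("early frames:", attr(T_early, "warning")))
    }
  }
  for (f in setdiff(seq_len(n), ref)) {
    if (f %in% early && !is.null(T_early)) {
      transforms[[f]] <- T_early
      next
    }
    Tf <- register(nonac[[f]], nonac[[ref]], metric = "ncc",
                   levels = config$reg_levels, rotation = config$reg_rotation)
    if (!is.null(attr(Tf, "warning")))
      warnings <- c(warnings, sprintf("frame %d: %s", f, attr(Tf, "warning")))
    attr(Tf, "warning") <- NULL
    transforms[[f]] <- Tf
  }
  disp <- vapply(transforms, displacement, numeric(1))
  rots <- vapply(transforms, function(T) max(abs(T$r)), numeric(1))
  skipped <- FALSE
  moved_ct <- vector("list", n)
  corrected <- vector("list", n)
  uncorrected <- NULL
  if (config$skip_if_negligible && all(disp < config$skip_threshold_mm) &&
      all(rots < config$skip_threshold_deg)) {
    skipped <- TRUE
    for (f in seq_len(n)) {
      moved_ct[[f]] <- ct
      corrected[[f]] <- recon(sinograms[[f]], fac0, recon_scale[f])
    }
  } else {
    for (f in seq_len(n)) {
      Tf <- transforms[[f]]
      # Steps 4-5: move CT_REF, restore stationary background
      if (is_identity_transform(Tf, tol = 1e-7)) {
        head_f <- ct_ref
        mask_f <- mask_ref
      } else {
        head_f <- apply_transform(ct_ref, Tf, fill_value = -1000)
        mask_f <- apply_transform(mask_ref, Tf, fill_value = 0)
      }
      comp <- as_plain_array(seg$background_ct)
      sel <- as_plain_array(mask_f) > 0.5     # head value wins at overlaps
      comp[sel] <- as_plain_array(head_f)[sel]
      moved_ct[[f]] <- vol_like(comp, ct, "CT-HU")
      # Step 6: AW-OSEM with the frame's own moved CT
      fac_f <- attenuation_factors(hu_to_mu(moved_ct[[f]]), geom)
      ac_f <- recon(sinograms[[f]], fac_f, recon_scale[f])
      # Step 7: realign to the reference frame
      corrected[[f]] <- if (is_identity_transform(Tf, tol = 1e-7)) ac_f else
        apply_transform(ac_f, invert_transform(Tf), fill_value = 0)
    }
  }
  if (keep_uncorrected) {
    uncorrected <- lapply(seq_len(n), function(f) {
      acu <- recon(sinograms[[f]], fac0, recon_scale[f])
      Tf <- transforms[[f]]
      if (is_identity_transform(Tf, tol = 1e-7)) acu else
        apply_transform(acu, invert_transform(Tf), fill_value = 0)
    })
    uncorrected <- dynamic_series(uncorrected, schedule)
  }
  structure(list(
    transforms = movement_script(transforms, reference = ref),
    ct_to_pet = T_ct,
    displacement_mm = disp,
    moved_ct = moved_ct,
    corrected = dynamic_series(corrected, schedule),
    uncorrected = uncorrected,
    nonac = dynamic_nonac,
    head_mask = seg$head_mask,
    skipped = skipped,
    config = config,
    warnings = warnings), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  n <- n_frames(x$corrected)
  cat(sprintf("<mc_result> %d frames (reference FR%d)%s\n", n,
              x$config$reference_frame,
              if (x$skipped) " [negligible movement: MC skipped]" else ""))
  cat(sprintf("  displacement: mean %.2f mm, max %.2f mm (frame %d)\n",
              mean(x$displacement_mm), max(x$displacement_mm),
              which.max(x$displacement_mm)))
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' @export
summary.mc_result <- function(object, ...) {
  df <- as.data.frame(object$transforms)
  df$displacement_mm <- object$displacement_mm
  df
}
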