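#' Normalized mutual information between two congruent images
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` computed from a joint intensity histogram
#' with linear binning over the robust 1st-99th percentile range of each
#' image.  Voxel pairs where both images are at or below background
#' (`exclude_below`) are left out of the histogram, which both speeds the
#' metric up and stops the large air region from dominating it.  NMI is
#' >= 1, with equality for independent images; a constant image is a
#' degenerate case returning 1.
#'
#' @param a,b congruent [image_volume]s.
#' @param n_bins histogram bins per axis (64; use 32 for small images).
#' @param exclude_below named or plain numeric length-2 vector: pairs with
#'   `a <= exclude_below[1]` and `b <= exclude_below[2]` are excluded (NULL
#'   keeps everything).
#' @return scalar NMI score.
#' @export
nmi <- function(a, b, n_bins = 64, exclude_below = NULL) {
  stopifnot_congruent(a, b)
  av <- as.numeric(a); bv <- as.numeric(b)
  if (!is.null(exclude_below)) {
    keep <- !(av <= exclude_below[1] & bv <= exclude_below[2])
    av <- av[keep]; bv <- bv[keep]
  }
  if (length(av) < 4) return(1)
  bins <- function(v) {
    q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
    if (q[2] - q[1] < 1e-12) return(NULL)           # constant image
    pmin(pmax(floor((v - q[1]) / (q[2] - q[1]) * (n_bins - 1L)), 0), n_bins - 1L)
  }
  ia <- bins(av); ib <- bins(bv)
  if (is.null(ia) || is.null(ib)) return(1)
  joint <- tabulate(ia * n_bins + ib + 1L, nbins = n_bins * n_bins)
  p <- joint[joint > 0] / length(av)
  hab <- -sum(p * log(p))
  pa <- tabulate(ia + 1L, nbins = n_bins); pa <- pa[pa > 0] / length(av)
  pb <- tabulate(ib + 1L, nbins = n_bins); pb <- pb[pb > 0] / length(bv)
  ha <- -sum(pa * log(pa)); hb <- -sum(pb * log(pb))
  if (hab < 1e-12) return(1)
  (ha + hb) / hab
}

#' Normalized cross-correlation between two congruent images
#'
#' Pearson correlation over voxels, in [-1, 1]; invariant to affine
#' rescaling of either image.
#'
#' @param a,b congruent [image_volume]s (nonconstant).
#' @return scalar correlation.
#' @export
ncc <- function(a, b) {
  stopifnot_congruent(a, b)
  av <- as.numeric(a); bv <- as.numeric(b)
  if (stats::sd(av) < 1e-12 || stats::sd(bv) < 1e-12)
    stop("ncc undefined for a constant image")
  stats::cor(av, bv)
}

# average-pool an image by integer factor (multi-resolution pyramid level)
downsample_vol <- function(vol, factor) {
  if (factor <= 1L) return(vol)
  d <- dim(vol)
  nd <- length(d)
  keep <- (d %/% factor) * factor
  idx <- lapply(keep, seq_len)
  arr <- do.call(`[`, c(list(as_plain_array(vol)), idx, list(drop = FALSE)))
  newd <- keep %/% factor
  if (nd == 2L) {
    dim(arr) <- c(factor, newd[1], factor, newd[2])
    out <- apply(arr, c(2, 4), mean)
  } else {
    dim(arr) <- c(factor, newd[1], factor, newd[2], factor, newd[3])
    out <- apply(arr, c(2, 4, 6), mean)
  }
  image_volume(out, vol_spacing(vol) * factor, vol_modality(vol))
}

active_params <- function(nd) {
  if (nd == 2L) c("tx", "ty", "rz") else c("tx", "ty", "tz", "rx", "ry", "rz")
}

params_to_transform <- function(p) {
  full <- c(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0)
  full[names(p)] <- p
  rigid_transform(full["tx"], full["ty"], full["tz"],
                  full["rx"], full["ry"], full["rz"])
}

transform_to_params <- function(T, nd) {
  c(T$t, T$r)[active_params(nd)]
}

#' Rigid registration by metric maximization
#'
#' Estimates the rigid transform `T` maximizing
#' `metric(fixed, apply_transform(moving, T))` with a coarse-to-fine
#' multi-resolution pyramid and a derivative-free cyclic coordinate descent
#' (Powell-style) at each level: each parameter in turn is probed with an
#' adaptive step that is halved until below `tol`.  Deterministic given the
#' inputs and `init`.  Translations are in mm and rotations in degrees about
#' the grid centre; in 2-D the parameters are (tx, ty, rz).
#'
#' @param fixed,moving [image_volume]s on congruent grids.
#' @param metric `"nmi"` (cross-modality, CT to PET) or `"ncc"`
#'   (PET to PET).
#' @param levels integer downsampling factors, coarse to fine.
#' @param init initial [rigid_transform].
#' @param max_step initial search step (mm and degrees) at the coarsest
#'   level.
#' @param tol convergence step size, mm/degrees.
#' @param rotation search rotation parameters as well as translations.
#' @param fill_value out-of-field fill for the moving image.
#' @param pre_smooth_mm Gaussian FWHM applied to both images before
#'   registration (default 4 mm for NMI, 0 for NCC).  Matching the
#'   smoothness of a crisp CT to the PET stabilizes the joint histogram:
#'   without it, the resampling interpolation itself changes the moving
#'   image's entropy and can create spurious NMI maxima away from
#'   alignment.
#' @return the estimated [rigid_transform], with attribute `warning` set to
#'   a message if the optimizer failed to improve at the coarsest level.
#' @export
register <- function(fixed, moving, metric = c("ncc", "nmi"),
                     levels = c(4, 2, 1), init = rigid_transform(),
                     max_step = 8, tol = 0.05, rotation = TRUE,
                     fill_value = NULL, pre_smooth_mm = NULL) {
  metric <- match.arg(metric)
  stopifnot_congruent(fixed, moving)
  nd <- length(dim(fixed))
  if (is.null(pre_smooth_mm)) pre_smooth_mm <- if (metric == "nmi") 4 else 0
  if (pre_smooth_mm > 0) {
    fixed <- gaussian_smooth(fixed, pre_smooth_mm)
    moving <- gaussian_smooth(moving, pre_smooth_mm)
  }
  score_fun <- function(f, m) {
    if (metric == "ncc") ncc(f, m)
    else nmi(f, m, n_bins = if (min(dim(f)) < 64) 32 else 64,
             exclude_below = c(bg_level(f), bg_level(m)))
  }
  # drop pyramid levels that would leave too few voxels to drive the metric
  ok_lv <- min(dim(fixed)) / levels >= 24
  levels <- if (any(ok_lv)) levels[ok_lv] else min(levels)
  pnames <- active_params(nd)
  if (!rotation) pnames <- grep("^t", pnames, value = TRUE)
  p <- transform_to_params(init, nd)[pnames]
  improved_any <- FALSE
  for (li in seq_along(levels)) {
    fac <- levels[li]
    f <- downsample_vol(fixed, fac)
    m <- downsample_vol(moving, fac)
    fv <- if (is.null(fill_value)) {
      if (identical(vol_modality(moving), "CT-HU")) -1000 else 0
    } else fill_value
    eval_p <- function(pp) {
      Tm <- params_to_transform(pp)
      score_fun(f, apply_transform(m, Tm, fill_value = fv))
    }
    best <- eval_p(p)
    step <- stats::setNames(rep(max_step * fac / levels[1], length(pnames)),
                            pnames)
    while (max(step) > tol) {
      moved <- FALSE
      for (k in pnames) {
        repeat {
          cand <- p
          cand[k] <- p[k] + step[k]
          s_plus <- eval_p(cand)
          cand[k] <- p[k] - step[k]
          s_minus <- eval_p(cand)
          if (s_plus > best + 1e-9 && s_plus >= s_minus) {
            p[k] <- p[k] + step[k]; best <- s_plus; moved <- TRUE
          } else if (s_minus > best + 1e-9) {
            p[k] <- p[k] - step[k]; best <- s_minus; moved <- TRUE
          } else break
        }
      }
      if (moved) improved_any <- TRUE
      step <- step / 2
    }
  }
  out <- params_to_transform(p)
  if (!improved_any)
    attr(out, "warning") <- "optimizer made no improvement; returning init"
  out
}

# background intensity level used to exclude air from NMI histograms
bg_level <- function(vol) {
  if (identical(vol_modality(vol), "CT-HU")) -900 else {
    mx <- stats::quantile(as.numeric(vol), 0.99, names = FALSE)
    0.05 * max(mx, 0)
  }
}
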