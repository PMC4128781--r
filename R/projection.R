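#' Parallel-beam scan geometry
#'
#' @param n_rad number of radial bins (>= 8).
#' @param dr_mm radial bin width, mm.
#' @param n_ang number of projection angles over 180 degrees (>= 8).
#' @param fwhm_mm in-plane Gaussian resolution of the system, mm (default
#'   4.5 mm, the scanner's intrinsic resolution).
#' @param step_mm ray-marching step for line integrals, mm.
#' @export
scan_geometry <- function(n_rad = 96, dr_mm = 2, n_ang = 96, fwhm_mm = 4.5,
                          step_mm = dr_mm / 2) {
  if (n_rad < 8 || n_ang < 8) stop("need >= 8 radial bins and angles")
  if (fwhm_mm < 0) stop("FWHM must be >= 0")
  structure(list(n_rad = as.integer(n_rad), dr_mm = dr_mm,
                 n_ang = as.integer(n_ang), fwhm_mm = fwhm_mm,
                 step_mm = step_mm,
                 angles = seq(0, pi, length.out = n_ang + 1)[seq_len(n_ang)]),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %d radial bins x %.3g mm, %d angles/180deg, FWHM %.2g mm\n",
              x$n_rad, x$dr_mm, x$n_ang, x$fwhm_mm))
  invisible(x)
}

#' Sinogram container
#' @param data matrix n_rad x n_ang (or n_rad x n_ang x n_frames array).
#' @param geom a [scan_geometry].
#' @param kind `"expected"`, `"observed"` or `"factors"`.
#' @export
sinogram <- function(data, geom, kind = c("expected", "observed", "factors")) {
  kind <- match.arg(kind)
  if (nrow(data) != geom$n_rad || ncol(data) != geom$n_ang)
    stop("sinogram shape does not match geometry")
  if (kind == "observed" && any(data < 0))
    stop("observed counts must be nonnegative")
  if (kind == "factors" && (any(data <= 0) || any(data > 1 + 1e-12)))
    stop("attenuation factors must lie in (0, 1]")
  structure(list(data = data, geom = geom, kind = kind), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram:%s> %d x %d, total %.4g\n", x$kind,
              nrow(x$data), ncol(x$data), sum(x$data)))
  invisible(x)
}

#' CT Hounsfield units to 511 keV linear attenuation coefficients
#'
#' Bilinear (piecewise-linear) scaling: -1000 HU (air) maps to 0, 0 HU
#' (water) to `mu_water` 1/cm, and above 0 HU a shallower bone slope applies,
#' reflecting the smaller energy dependence of cortical bone attenuation at
#' 511 keV.  Values below -1000 HU clamp to 0; the map is monotone
#' nondecreasing.
#'
#' @param ct an [image_volume] in CT-HU.
#' @param mu_water water attenuation at 511 keV, 1/cm.
#' @param bone_slope slope above 0 HU, (1/cm)/HU.
#' @return an [image_volume] of class mu-map, units 1/cm.
#' @export
hu_to_mu <- function(ct, mu_water = 0.096, bone_slope = 1e-4) {
  hu <- as.numeric(ct)
  mu <- ifelse(hu <= 0, mu_water * (1 + hu / 1000), mu_water + bone_slope * hu)
  mu[mu < 0] <- 0
  vol_like(mu, ct, modality = "mu-map")
}

#' Forward projection (2-D parallel beam)
#'
#' Line integrals of the volume along each (angle, radial-bin) ray, in
#' mm-scaled units, after smoothing the volume to the geometry's resolution
#' FWHM.  3-D volumes are projected slice-by-slice along the third axis and
#' the result summed (a single 2-D sinogram), matching the package's 2-D
#' reconstruction model.
#'
#' @param vol an [image_volume] (activity or mu).
#' @param geom a [scan_geometry].
#' @param smooth apply the geometry FWHM before projecting (TRUE for
#'   emission; attenuation integrals use FALSE).
#' @return a [sinogram] of kind `"expected"`.
#' @export
forward_project <- function(vol, geom, smooth = TRUE) {
  sp <- vol_spacing(vol)
  d <- dim(vol)
  if (geom$n_rad * geom$dr_mm / 2 < max(d[1:2] * sp[1:2]) / 2)
    warning("detector smaller than object: projections are truncated")
  if (smooth && geom$fwhm_mm > 0) vol <- gaussian_smooth(vol, geom$fwhm_mm)
  proj_one <- function(m)
    .fp2d(m, sp[1], sp[2], geom$angles, geom$n_rad, geom$dr_mm, geom$step_mm)
  if (length(d) == 2L) {
    s <- proj_one(as_plain_array(vol))
  } else {
    s <- 0
    for (k in seq_len(d[3])) s <- s + proj_one(as_plain_array(vol)[, , k])
  }
  sinogram(s, geom, "expected")
}

#' Attenuation survival factors from a mu-map
#'
#' For PET coincidences the photon pair traverses the full ray, so the
#' survival probability of a bin is `exp(-integral of mu dl)` along the whole
#' line, independent of the emission point.  `mu` is in 1/cm; path lengths in
#' mm are converted accordingly.
#'
#' @param mu an [image_volume] mu-map (1/cm).
#' @param geom a [scan_geometry].
#' @return a [sinogram] of kind `"factors"` with values in (0, 1].
#' @export
attenuation_factors <- function(mu, geom) {
  path <- forward_project(mu, geom, smooth = FALSE)   # mm * 1/cm
  f <- exp(-path$data / 10)
  f[f <= 0] <- .Machine$double.xmin
  sinogram(f, geom, "factors")
}

#' Simulate a Poisson emission scan
#'
#' Expected counts per bin are
#' `factors * forward_project(activity) * duration * sensitivity`; observed
#' counts are Poisson draws, reproducible given `seed`.
#'
#' @param activity an [image_volume] of activity concentration (kBq/mL).
#' @param mu a mu-map [image_volume] (NULL for no attenuation).
#' @param geom a [scan_geometry].
#' @param duration_s frame duration, s.
#' @param sensitivity detection sensitivity scale (counts per kBq/mL per mm
#'   per s); controls the count level.
#' @param seed integer RNG seed; NULL draws from the current RNG state.
#' @param noiseless if TRUE return the expected sinogram without noise.
#' @return a [sinogram] (kind `"observed"`, or `"expected"` if noiseless).
#' @export
simulate_emission_scan <- function(activity, mu, geom, duration_s,
                                   sensitivity = 1e-3, seed = NULL,
                                   noiseless = FALSE) {
  if (duration_s <= 0) stop("duration must be positive")
  if (any(as.numeric(activity) < 0)) stop("negative activity")
  lam <- forward_project(activity, geom)$data * duration_s * sensitivity
  if (!is.null(mu)) lam <- lam * attenuation_factors(mu, geom)$data
  if (noiseless) return(sinogram(lam, geom, "expected"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  obs <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
  sinogram(obs, geom, "observed")
}

# bit-reversed ordering of subsets for balanced angular coverage
bit_reverse_order <- function(n) {
  if (n == 1L) return(1L)
  ord <- 0L
  m <- n
  while (m > 1L) { ord <- ord + 1L; m <- m %/% 2L }
  if (2L^ord == n) {
    idx <- 0:(n - 1L)
    rev_bits <- vapply(idx, function(i) {
      r <- 0L
      for (b in seq_len(ord)) { r <- bitwOr(bitwShiftL(r, 1L), bitwAnd(i, 1L)); i <- bitwShiftR(i, 1L) }
      r
    }, integer(1))
    order(order(rev_bits))      # permutation applying bit-reversed visit order
    rev_bits + 1L
  } else {
    # non power of two: interleave by largest stride
    ((seq_len(n) - 1L) * max(1L, n %/% 2L + 1L)) %% n + 1L
  }
}

#' Attenuation-weighted OSEM reconstruction (2-D)
#'
#' Ordered-subsets expectation maximization with the attenuation survival
#' factors folded into the system model (AW-OSEM).  The update for subset S is
#' \deqn{x \leftarrow x \cdot \frac{P^T[a\, y/(a\,Px + \epsilon)]_S}{P^T[a]_S}}
#' starting from a uniform positive image.  Subsets partition the angles by a
#' bit-reversed interleave.  Defaults follow the re-reconstruction protocol
#' (6 iterations, 16 subsets); smaller subset counts are appropriate for
#' small test geometries.
#'
#' @param sino observed-count [sinogram].
#' @param factors attenuation-factor [sinogram] (NULL for non-AC
#'   reconstruction, i.e. factors = 1).
#' @param shape output grid c(nx, ny).
#' @param spacing_mm output voxel spacing.
#' @param n_iter full iterations (default 6).
#' @param n_subsets number of angle subsets (default 16; must divide the
#'   angle count).
#' @param scale multiplies the raw reconstruction back to concentration
#'   units (1 / (duration * sensitivity)); default 1 leaves count units.
#' @param eps division guard.
#' @return an [image_volume] of nonnegative PET activity.
#' @export
awosem_reconstruct <- function(sino, factors = NULL, shape, spacing_mm,
                               n_iter = 6, n_subsets = 16, scale = 1,
                               eps = 1e-10) {
  geom <- sino$geom
  if (!is.null(factors)) {
    if (!identical(dim(factors$data), dim(sino$data)))
      stop("factor/sinogram shape mismatch")
    a <- factors$data
  } else a <- matrix(1, geom$n_rad, geom$n_ang)
  if (geom$n_ang %% n_subsets != 0)
    stop("n_subsets must divide the angle count")
  sp <- rep_len(as.numeric(spacing_mm), 2L)
  y <- sino$data
  nx <- shape[1]; ny <- shape[2]
  x <- matrix(1, nx, ny)
  # assign angle i to subset ((i-1) mod n_subsets), visited in bit-reversed order
  sub_id <- ((seq_len(geom$n_ang) - 1L) %% n_subsets) + 1L
  visit <- bit_reverse_order(n_subsets)
  fp <- function(img, ang) .fp2d(img, sp[1], sp[2], ang, geom$n_rad,
                                 geom$dr_mm, geom$step_mm)
  bp <- function(s, ang) .bp2d(s, sp[1], sp[2], ang, nx, ny,
                               geom$dr_mm, geom$step_mm)
  sens <- lapply(seq_len(n_subsets), function(s) {
    ang <- geom$angles[sub_id == s]
    bp(a[, sub_id == s, drop = FALSE], ang)
  })
  for (it in seq_len(n_iter)) {
    for (s in visit) {
      sel <- sub_id == s
      ang <- geom$angles[sel]
      proj <- a[, sel, drop = FALSE] * fp(x, ang)
      ratio <- a[, sel, drop = FALSE] * y[, sel, drop = FALSE] / (proj + eps)
      upd <- bp(ratio, ang) / (sens[[s]] + eps)
      x <- x * upd
    }
  }
  image_volume(x * scale, sp, "PET-activity")
}
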