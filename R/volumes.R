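#' Image volume on a regular grid
#'
#' Lightweight container for a scalar 2-D or 3-D field sampled on a regular
#' grid with millimetre spacing.  The grid centre is the world origin and all
#' rigid motion in the package is defined about it.
#'
#' @param data numeric matrix (2-D) or 3-D array.
#' @param spacing numeric vector of voxel spacings in mm, one per axis
#'   (recycled if scalar).
#' @param modality one of `"CT-HU"`, `"PET-activity"`, `"mu-map"`, `"label"`,
#'   `"generic"`.
#' @return An object of class `image_volume`: the array with `spacing` and
#'   `modality` attributes.
#' @export
image_volume <- function(data, spacing = 1, modality = "generic") {
  if (!is.numeric(data) && !is.integer(data))
    stop("'data' must be numeric")
  nd <- length(dim(data))
  if (is.null(dim(data)) || nd < 2L || nd > 3L)
    stop("'data' must be a 2-D matrix or 3-D array")
  modality <- match.arg(modality,
                        c("CT-HU", "PET-activity", "mu-map", "label", "generic"))
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(data, spacing = spacing, modality = modality,
            class = c("image_volume", class(data)))
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              vol_modality(x), paste(dim(x), collapse = "x"),
              paste(format(vol_spacing(x), trim = TRUE), collapse = "x"),
              min(x), max(x)))
  invisible(x)
}

#' Spacing and modality accessors
#' @param x an `image_volume`.
#' @return `vol_spacing`: numeric vector of mm spacings; `vol_modality`: string.
#' @export
vol_spacing <- function(x) attr(x, "spacing")

#' @rdname vol_spacing
#' @export
vol_modality <- function(x) attr(x, "modality")

#' Rebuild an image_volume with the grid metadata of a template
#' @param data array congruent with `template`.
#' @param template an `image_volume` supplying spacing.
#' @param modality modality tag of the result (default: template's).
#' @export
vol_like <- function(data, template, modality = vol_modality(template)) {
  dim(data) <- dim(template)
  image_volume(data, vol_spacing(template), modality)
}

as_plain_array <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

stopifnot_congruent <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("image grids are not congruent: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

#' World coordinates of voxel centres along one axis
#'
#' Axis k with n voxels and spacing s places voxel i at `(i - (n+1)/2) * s`
#' (1-based), so the grid centre is 0 mm.
#' @param n number of voxels.
#' @param s spacing in mm.
#' @export
axis_coords <- function(n, s) (seq_len(n) - (n + 1) / 2) * s

#' Frame schedule of a dynamic acquisition
#'
#' @param start_s frame start times in seconds (contiguous, nonoverlapping).
#' @param dur_s frame durations in seconds (> 0).
#' @return data.frame of class `frame_schedule` with columns `start_s`,
#'   `dur_s`, and `mid_min` (mid-frame time in minutes).
#' @export
frame_schedule <- function(start_s, dur_s) {
  start_s <- as.numeric(start_s); dur_s <- as.numeric(dur_s)
  if (length(start_s) != length(dur_s)) stop("lengths differ")
  if (any(dur_s <= 0)) stop("durations must be positive")
  if (length(start_s) > 1 &&
      any(abs(start_s[-1] - (start_s + dur_s)[-length(start_s)]) > 1e-9))
    stop("frames must be contiguous and non-overlapping")
  structure(data.frame(start_s = start_s, dur_s = dur_s,
                       mid_min = (start_s + dur_s / 2) / 60),
            class = c("frame_schedule", "data.frame"))
}

schedule_from_durations <- function(dur_s) {
  frame_schedule(cumsum(c(0, dur_s[-length(dur_s)])), dur_s)
}

#' Built-in acquisition schedules
#'
#' `fddnp_schedule()`: 65-min dynamic FDDNP protocol
#' (6x30 s, 4x3 min, 10x5 min; 20 frames).
#' `fdg_schedule()`: 60-min dynamic FDG protocol
#' (9x5 s, 3x15 s, 3x30 s, 1x2 min, 5x5 min, 3x10 min; 24 frames).
#' `phantom_schedule()`: 12 static 10-min frames as in the phantom
#' repositioning experiment.
#' @return a [frame_schedule].
#' @export
fddnp_schedule <- function() {
  schedule_from_durations(c(rep(30, 6), rep(180, 4), rep(300, 10)))
}

#' @rdname fddnp_schedule
#' @export
fdg_schedule <- function() {
  schedule_from_durations(c(rep(5, 9), rep(15, 3), rep(30, 3), 120,
                            rep(300, 5), rep(600, 3)))
}

#' @rdname fddnp_schedule
#' @export
phantom_schedule <- function(n_frames = 12, frame_s = 600) {
  schedule_from_durations(rep(frame_s, n_frames))
}

#' Dynamic series: ordered frames on a shared grid plus a schedule
#'
#' @param frames list of congruent [image_volume] objects.
#' @param schedule a [frame_schedule] with one row per frame.
#' @export
dynamic_series <- function(frames, schedule) {
  if (!inherits(schedule, "frame_schedule")) stop("need a frame_schedule")
  if (length(frames) != nrow(schedule))
    stop("frame count (", length(frames), ") != schedule rows (",
         nrow(schedule), ")")
  d1 <- dim(frames[[1]])
  for (f in frames) if (!identical(dim(f), d1)) stop("frames not congruent")
  structure(list(frames = frames, schedule = schedule),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("<dynamic_series> %d frames of %s, %.1f min total\n",
              n_frames(x), paste(dim(x$frames[[1]]), collapse = "x"),
              sum(x$schedule$dur_s) / 60))
  invisible(x)
}

#' @rdname dynamic_series
#' @param x a `dynamic_series`.
#' @export
n_frames <- function(x) length(x$frames)

#' Isotropic Gaussian smoothing of an image volume
#'
#' Separable convolution with a Gaussian of the given full width at half
#' maximum; used to model scanner resolution (4.5 mm FWHM by default
#' elsewhere in the package).
#'
#' @param vol an [image_volume].
#' @param fwhm_mm full width at half maximum in mm; 0 returns `vol`.
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  if (fwhm_mm <= 0) return(vol)
  sp <- vol_spacing(vol)
  sig <- fwhm_mm / 2.354820045
  out <- as_plain_array(vol)
  nd <- length(dim(out))
  for (ax in seq_len(nd)) {
    s <- sig / sp[ax]
    if (s < 1e-6) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-half:half) / s)^2)
    k <- k / sum(k)
    out <- conv_axis(out, k, ax)
  }
  vol_like(out, vol)
}

# replicate-padded 1-D convolution along axis `ax` of a 2-D/3-D array
conv_axis <- function(arr, k, ax) {
  d <- dim(arr)
  half <- (length(k) - 1L) / 2L
  n <- d[ax]
  idx <- pmin(pmax(seq_len(n + 2L * half) - half, 1L), n)
  perm <- c(ax, setdiff(seq_along(d), ax))
  m <- aperm(arr, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1])
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (t in seq_along(k))
    out <- out + k[t] * mp[seq_len(n) + (t - 1L), , drop = FALSE]
  dim(out) <- dm
  aperm(out, order(perm))
}
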