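#' Extract a region time-activity curve from a dynamic series
#'
#' Per-frame mean concentration over the mask, at mid-frame times.
#'
#' @param dyn a [dynamic_series].
#' @param mask 0/1 [image_volume] (or logical array) congruent with the
#'   frames; must be nonempty.
#' @return a [tac] with frame durations attached.
#' @export
extract_tac <- function(dyn, mask) {
  m <- as.numeric(mask) > 0.5
  if (!any(m)) stop("empty mask")
  stopifnot_congruent(dyn$frames[[1]], mask)
  conc <- vapply(dyn$frames, function(f) mean(as.numeric(f)[m]), numeric(1))
  tac(dyn$schedule$mid_min, conc, dyn$schedule$dur_s / 60)
}

#' Image-derived input function from carotid-artery ROIs
#'
#' Sums the frames that start within the first `window_s` seconds into a
#' localization image, places circular ROIs of `roi_diameter_mm` at the
#' carotid centres (supplied, or auto-detected as the brightest local maxima
#' in the lower part of the head), and returns the mean TAC over the combined
#' ROI.  In 3-D the discs are replicated on `n_slices` consecutive slices.
#'
#' @param dyn a [dynamic_series] covering at least `window_s` seconds.
#' @param centres optional list/matrix of world-mm centres (rows = (x, y) or
#'   (x, y, z)); NULL auto-detects `n_vessels` maxima.
#' @param roi_diameter_mm ROI diameter (5 mm).
#' @param window_s early summation window (45 s).
#' @param n_vessels number of carotid centres to auto-detect.
#' @param n_slices consecutive slices carrying discs in 3-D (3).
#' @param min_separation_mm minimum distance between auto-detected centres.
#' @return a [tac]; attribute `roi_mask` holds the combined ROI volume.
#' @export
extract_idif <- function(dyn, centres = NULL, roi_diameter_mm = 5,
                         window_s = 45, n_vessels = 2, n_slices = 3,
                         min_separation_mm = 10) {
  sch <- dyn$schedule
  if (sum(sch$dur_s) < window_s) stop("dynamic series shorter than the summation window")
  sel <- which(sch$start_s < window_s)
  loc <- Reduce(`+`, Map(function(f, d) as_plain_array(f) * d,
                         dyn$frames[sel], sch$dur_s[sel]))
  loc <- loc / sum(sch$dur_s[sel])
  d <- dim(loc)
  sp <- vol_spacing(dyn$frames[[1]])
  co <- lapply(seq_along(d), function(ax) axis_coords(d[ax], sp[ax]))
  if (is.null(centres)) {
    cand <- order(loc, decreasing = TRUE)
    centres <- list()
    if (max(loc) <= 0) stop("no carotid signal found in early summed image; supply centres")
    for (ix in cand) {
      pos <- arrayInd(ix, d)
      w <- vapply(seq_along(d), function(ax) co[[ax]][pos[ax]], numeric(1))
      if (all(vapply(centres, function(c0)
        sqrt(sum((w[1:2] - c0[1:2])^2)) >= min_separation_mm, TRUE))) {
        centres[[length(centres) + 1L]] <- w
      }
      if (length(centres) >= n_vessels) break
    }
    if (length(centres) < n_vessels)
      stop("could not find ", n_vessels, " separated carotid maxima; supply centres")
  } else if (is.matrix(centres)) {
    centres <- lapply(seq_len(nrow(centres)), function(i) centres[i, ])
  }
  r <- roi_diameter_mm / 2
  mask <- array(FALSE, d)
  if (length(d) == 2L) {
    X <- matrix(co[[1]], d[1], d[2])
    Y <- matrix(co[[2]], d[1], d[2], byrow = TRUE)
    for (c0 in centres)
      mask <- mask | ((X - c0[1])^2 + (Y - c0[2])^2 <= r^2)
  } else {
    X <- array(rep(co[[1]], prod(d[2:3])), d)
    Y <- array(rep(rep(co[[2]], each = d[1]), d[3]), d)
    for (c0 in centres) {
      k0 <- which.min(abs(co[[3]] - if (length(c0) >= 3) c0[3] else 0))
      ks <- intersect(k0 + seq_len(n_slices) - ((n_slices + 1) %/% 2), seq_len(d[3]))
      disc <- (X[, , 1] - c0[1])^2 + (Y[, , 1] - c0[2])^2 <= r^2
      for (k in ks) mask[, , k] <- mask[, , k] | disc
    }
  }
  if (!any(mask)) stop("carotid ROI is empty; supply centres on the grid")
  out <- extract_tac(dyn, vol_like(mask * 1, dyn$frames[[1]], "generic"))
  attr(out, "roi_mask") <- vol_like(mask * 1, dyn$frames[[1]], "generic")
  attr(out, "centres") <- centres
  out
}

# cumulative trapezoid integral from time 0 (implicit (0,0) anchor)
cumtrapz0 <- function(t, y) {
  tt <- c(0, t); yy <- c(0, y)
  if (t[1] == 0) { tt <- t; yy <- y }
  ci <- cumsum(c(0, diff(tt) * (yy[-1] + yy[-length(yy)]) / 2))
  if (t[1] == 0) ci else ci[-1]
}

graphical_fit <- function(x, y, t, t_star, method) {
  use <- t >= t_star - 1e-9
  if (sum(use) < 3) stop("fewer than 3 points at or after t*")
  fit <- stats::lm.fit(cbind(1, x[use]), y[use])
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 t_star_min = t_star, n_points = sum(use),
                 residual_rms = sqrt(mean(fit$residuals^2)),
                 x = x, y = y, t = t, used = use, method = method),
            class = "graphical_fit")
}

#' @export
print.graphical_fit <- function(x, ...) {
  lab <- if (x$method == "logan") "DVR" else "Ki (1/min)"
  cat(sprintf("<graphical_fit:%s> slope (%s) = %.4f, intercept = %.4f\n",
              x$method, lab, x$slope, x$intercept))
  cat(sprintf("  t* = %g min, %d points, residual RMS = %.4g\n",
              x$t_star_min, x$n_points, x$residual_rms))
  invisible(x)
}

#' @export
coef.graphical_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
residuals.graphical_fit <- function(object, ...) {
  (object$y - object$intercept - object$slope * object$x)[object$used]
}

#' @export
plot.graphical_fit <- function(x, ...) {
  lab <- if (x$method == "logan")
    c(expression(integral(C[REF] * d * tau, 0, t) / C[T](t)),
      expression(integral(C[T] * d * tau, 0, t) / C[T](t)))
  else
    c(expression(integral(C[P] * d * tau, 0, t) / C[P](t)),
      expression(C[T](t) / C[P](t)))
  graphics::plot(x$x, x$y, pch = ifelse(x$used, 19, 1),
                 xlab = lab[1], ylab = lab[2], ...)
  graphics::abline(x$intercept, x$slope, col = 2)
  invisible(x)
}

#' Logan graphical analysis with a reference region
#'
#' Ordinary least squares of
#' \eqn{\int_0^t C_T d\tau / C_T(t)} against
#' \eqn{\int_0^t C_{REF} d\tau / C_T(t)} over mid-frame times at or after
#' `t_star_min`; the slope estimates the distribution volume ratio
#' \eqn{DVR = V_T / V_{REF}}.  The plot is treated as linear from 30 min
#' after scan start (the default `t_star_min`); no reference-region efflux
#' (k2') correction term is applied.  Integrals are trapezoids from time 0.
#'
#' @param ct_tac target-tissue [tac].
#' @param cref_tac reference-tissue (cerebellum) [tac] on the same time grid.
#' @param t_star_min start of the linear fit window, minutes.
#' @return a `graphical_fit` object (slope = DVR).
#' @export
logan_dvr <- function(ct_tac, cref_tac, t_star_min = 30) {
  if (!isTRUE(all.equal(ct_tac$time_min, cref_tac$time_min)))
    stop("TACs must share a time grid")
  t <- ct_tac$time_min
  use <- t >= t_star_min - 1e-9
  if (any(ct_tac$conc[use] <= 0))
    stop("C_T must be positive on the fit window")
  x <- cumtrapz0(t, cref_tac$conc) / ct_tac$conc
  y <- cumtrapz0(t, ct_tac$conc) / ct_tac$conc
  graphical_fit(x, y, t, t_star_min, "logan")
}

#' Patlak graphical analysis with a plasma input function
#'
#' Ordinary least squares of \eqn{C_T(t)/C_P(t)} against
#' \eqn{\int_0^t C_P d\tau / C_P(t)} over mid-frame times at or after
#' `t_star_min`; the slope estimates the irreversible uptake constant
#' \eqn{K_i} (1/min).
#'
#' @param ct_tac target-tissue [tac].
#' @param cp_tac plasma input [tac] (e.g. from [extract_idif()]) on the same
#'   time grid.
#' @param t_star_min start of the linear fit window, minutes (default
#'   20).
#' @return a `graphical_fit` object (slope = Ki, 1/min).
#' @export
patlak_ki <- function(ct_tac, cp_tac, t_star_min = 20) {
  if (!isTRUE(all.equal(ct_tac$time_min, cp_tac$time_min)))
    stop("TACs must share a time grid")
  t <- ct_tac$time_min
  use <- t >= t_star_min - 1e-9
  if (any(cp_tac$conc[use] <= 0))
    stop("C_P must be positive on the fit window")
  x <- cumtrapz0(t, cp_tac$conc) / cp_tac$conc
  y <- ct_tac$conc / cp_tac$conc
  graphical_fit(x, y, t, t_star_min, "patlak")
}

#' Voxelwise parametric image by graphical analysis
#'
#' Fits the Logan or Patlak model at every voxel (vectorized least squares)
#' against a common reference/input TAC.  Voxels failing the preconditions
#' (nonpositive denominator anywhere in the fit window) are set to 0 and
#' flagged in the validity mask; negative slopes are retained.
#'
#' @param dyn a [dynamic_series].
#' @param ref_tac reference-region TAC (`method = "logan"`) or plasma input
#'   TAC (`method = "patlak"`), on the series' mid-frame grid.
#' @param method `"logan"` or `"patlak"`.
#' @param t_star_min fit window start (30 for Logan, 20 for Patlak by
#'   default).
#' @return an [image_volume] of slopes with attribute `valid` (0/1 volume).
#' @export
parametric_image <- function(dyn, ref_tac, method = c("logan", "patlak"),
                             t_star_min = NULL) {
  method <- match.arg(method)
  if (is.null(t_star_min)) t_star_min <- if (method == "logan") 30 else 20
  t <- dyn$schedule$mid_min
  if (!isTRUE(all.equal(t, ref_tac$time_min)))
    stop("reference TAC must be on the series' mid-frame time grid")
  use <- t >= t_star_min - 1e-9
  if (sum(use) < 3) stop("fewer than 3 frames at or after t*")
  d <- dim(dyn$frames[[1]])
  nvox <- prod(d)
  V <- vapply(dyn$frames, as.numeric, numeric(nvox))    # nvox x nt
  iref <- cumtrapz0(t, ref_tac$conc)
  if (method == "logan") {
    Icum <- t(apply(V, 1, function(v) cumtrapz0(t, v)))
    den <- V[, use, drop = FALSE]
    valid <- rowSums(den <= 0) == 0
    x <- sweep(1 / den, 2, iref[use], `*`)
    y <- Icum[, use, drop = FALSE] / den
  } else {
    cp <- ref_tac$conc[use]
    if (any(cp <= 0)) stop("C_P must be positive on the fit window")
    x <- matrix(iref[use] / cp, nvox, sum(use), byrow = TRUE)
    y <- sweep(V[, use, drop = FALSE], 2, cp, `/`)
    valid <- rep(TRUE, nvox)
  }
  x[!valid, ] <- 0; y[!valid, ] <- 0
  mx <- rowMeans(x); my <- rowMeans(y)
  sxx <- rowMeans(x * x) - mx^2
  sxy <- rowMeans(x * y) - mx * my
  slope <- ifelse(valid & sxx > 1e-12, sxy / pmax(sxx, 1e-300), 0)
  out <- vol_like(array(slope, d), dyn$frames[[1]], "generic")
  attr(out, "valid") <- vol_like(array((valid & sxx > 1e-12) * 1, d),
                                 dyn$frames[[1]], "generic")
  out
}
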