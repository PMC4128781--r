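#' Rigid-body transform (6-DOF; 3-DOF in 2-D)
#'
#' Translations in mm and rotations in degrees about the grid centre, with
#' intrinsic ZYX rotation order: the rotation matrix is
#' `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)`.  A world point `p` maps to
#' `R (p - c) + c + t` where `c` is the grid centre (the world origin under
#' this package's coordinate convention).  In 2-D mode only `tx`, `ty`
#' and the in-plane rotation `rz` act.
#'
#' @param tx,ty,tz translations, mm.
#' @param rx,ry,rz rotations, degrees.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  structure(list(t = c(tx = tx, ty = ty, tz = tz),
                 r = c(rx = rx, ry = ry, rz = rz)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg\n",
              x$t[1], x$t[2], x$t[3], x$r[1], x$r[2], x$r[3]))
  invisible(x)
}

#' @rdname rigid_transform
#' @param T a `rigid_transform`.
#' @export
is_identity_transform <- function(T, tol = 1e-9) {
  all(abs(T$t) < tol) && all(abs(T$r) < tol)
}

rot_matrix <- function(r_deg) {
  a <- r_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

euler_from_rot <- function(R) {
  # inverse of rot_matrix for the ZYX convention (non-degenerate case)
  ry <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {                      # gimbal lock: fold everything into rx
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(T2, T1)` is "apply `T1` first, then `T2`"; because all
#' rotations share the grid-centre pivot the composition is again a
#' centre-pivot rigid transform.
#'
#' @param T2,T1,T `rigid_transform` objects.
#' @export
compose_transform <- function(T2, T1) {
  R2 <- rot_matrix(T2$r); R1 <- rot_matrix(T1$r)
  R <- R2 %*% R1
  t <- as.numeric(R2 %*% T1$t + T2$t)
  e <- euler_from_rot(R)
  rigid_transform(t[1], t[2], t[3], e[1], e[2], e[3])
}

#' @rdname compose_transform
#' @export
invert_transform <- function(T) {
  R <- rot_matrix(T$r)
  t <- as.numeric(-t(R) %*% T$t)
  e <- euler_from_rot(t(R))
  rigid_transform(t[1], t[2], t[3], e[1], e[2], e[3])
}

#' Resample a volume under a rigid transform
#'
#' Moves the image content by `T` (a voxel at world `p` ends up at
#' `R(p - c) + c + t`) using bilinear (2-D) or trilinear (3-D)
#' interpolation; voxels mapped from outside the field of view are set to
#' `fill_value`.
#'
#' @param vol an [image_volume].
#' @param T a [rigid_transform].
#' @param fill_value out-of-field value; default -1000 for CT-HU, else 0.
#' @return an [image_volume] on the same grid.
#' @export
apply_transform <- function(vol, T, fill_value = NULL) {
  if (is.null(fill_value))
    fill_value <- if (identical(vol_modality(vol), "CT-HU")) -1000 else 0
  sp <- vol_spacing(vol)
  d <- dim(vol)
  if (length(d) == 2L) {
    if (any(abs(T$t[3]) > 1e-12) || any(abs(T$r[1:2]) > 1e-12))
      stop("2-D volume: only tx, ty and rz may be nonzero")
    out <- .resample_rigid2d(as_plain_array(vol), sp[1], sp[2],
                             T$t[1], T$t[2], T$r[3], fill_value)
  } else {
    out <- .resample_rigid3d(as.numeric(vol), as.integer(d), sp,
                             rot_matrix(T$r), as.numeric(T$t), fill_value)
  }
  vol_like(out, vol)
}

#' Movement script: one rigid transform per frame
#'
#' @param transforms list of [rigid_transform], one per frame; the reference
#'   frame's entry must be the identity.
#' @param reference 1-based reference frame index.
#' @export
movement_script <- function(transforms, reference = 1L) {
  stopifnot(reference >= 1, reference <= length(transforms))
  if (!is_identity_transform(transforms[[reference]], tol = 1e-7))
    stop("reference frame transform must be the identity")
  structure(list(transforms = transforms, reference = as.integer(reference)),
            class = "movement_script")
}

#' @export
print.movement_script <- function(x, ...) {
  cat(sprintf("<movement_script> %d frames (reference FR%d)\n",
              length(x$transforms), x$reference))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.movement_script <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$transforms), function(i) {
    T <- x$transforms[[i]]
    data.frame(frame = i, tx = T$t[1], ty = T$t[2], tz = T$t[3],
               rx = T$r[1], ry = T$r[2], rz = T$r[3], row.names = NULL)
  }))
}

#' Serialize transforms as delimited text
#'
#' Tab-separated table with one row per frame (columns frame, tx, ty, tz,
#' rx, ry, rz), preceded by comment lines recording the convention
#' (mm / degrees, centre-pivot, intrinsic ZYX).
#'
#' @param x a [movement_script] or single [rigid_transform].
#' @param path output file.
#' @export
write_transforms <- function(x, path) {
  if (inherits(x, "rigid_transform")) x <- movement_script(list(x), 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# rigid transforms: translations mm, rotations deg",
               "# pivot: grid centre; rotation order: intrinsic ZYX",
               sprintf("# reference_frame: %d", x$reference)), con)
  utils::write.table(format(as.data.frame(x), digits = 10, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  lines <- readLines(path)
  ref <- 1L
  hdr <- grep("^# reference_frame:", lines, value = TRUE)
  if (length(hdr)) ref <- as.integer(sub(".*: *", "", hdr[1]))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t")
  movement_script(lapply(seq_len(nrow(df)), function(i)
    rigid_transform(df$tx[i], df$ty[i], df$tz[i],
                    df$rx[i], df$ry[i], df$rz[i])), ref)
}
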