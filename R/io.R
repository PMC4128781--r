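#' Write / read an image volume as NIfTI
#'
#' Voxel spacing is stored in the NIfTI pixdim; the modality tag in the
#' intent_name field (restored on read when recognised).
#'
#' @param vol an [image_volume] (or a [dynamic_series] for the 4-D writer).
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(as_plain_array(vol), reference = NULL)
  RNifti::pixdim(img) <- vol_spacing(vol)
  img$intent_name <- vol_modality(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  nd <- hdr$dim[1]
  modality <- hdr$intent_name
  if (!modality %in% c("CT-HU", "PET-activity", "mu-map", "label"))
    modality <- "generic"
  image_volume(array(as.numeric(img), dim(img)[seq_len(nd)]),
               hdr$pixdim[1 + seq_len(nd)], modality)
}

#' Write / read a dynamic series (4-D NIfTI + frame-timing sidecar)
#'
#' The 4-D NIfTI carries the frames along the 4th dimension; NIfTI has no
#' per-frame duration field, so timing goes to a tab-separated sidecar
#' `<path>.timing.tsv` with columns `frame`, `start_s`, `dur_s` (1-based
#' frame numbering).
#'
#' @param dyn a [dynamic_series].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_dynamic <- function(dyn, path) {
  d <- dim(dyn$frames[[1]])
  arr <- array(unlist(lapply(dyn$frames, as.numeric)), c(d, n_frames(dyn)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vol_spacing(dyn$frames[[1]]), 1)
  RNifti::writeNifti(img, path)
  write_timing_sidecar(dyn$schedule, sidecar_path(path))
  invisible(path)
}

#' @rdname write_dynamic
#' @export
read_dynamic <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  nd <- hdr$dim[1]
  if (nd < 3) stop("expected a 3-D or 4-D NIfTI with time as the last axis")
  d <- dim(img)[seq_len(nd)]
  sp <- hdr$pixdim[1 + seq_len(nd - 1)]
  sch <- read_timing_sidecar(sidecar_path(path))
  nt <- d[nd]
  if (nt != nrow(sch))
    stop("frame count mismatch: volume has ", nt, " frames, sidecar ",
         nrow(sch))
  arr <- array(as.numeric(img), d)
  frames <- lapply(seq_len(nt), function(f) {
    sl <- if (nd == 3L) arr[, , f] else arr[, , , f]
    image_volume(array(sl, d[seq_len(nd - 1)]), sp, "PET-activity")
  })
  dynamic_series(frames, sch)
}

#' Path of the frame-timing sidecar belonging to a dynamic NIfTI
#' @param path the `.nii` / `.nii.gz` path.
#' @export
sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".timing.tsv")
}

#' Frame-timing sidecar (tab-separated start/duration in seconds)
#' @param schedule a [frame_schedule].
#' @param path sidecar path.
#' @export
write_timing_sidecar <- function(schedule, path) {
  utils::write.table(
    data.frame(frame = seq_len(nrow(schedule)),
               start_s = schedule$start_s, dur_s = schedule$dur_s),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timing_sidecar
#' @export
read_timing_sidecar <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  frame_schedule(df$start_s, df$dur_s)
}

#' Write / read a TAC as delimited text with header metadata
#' @param x a [tac]; metadata lines (key: value) are written as `#` comments.
#' @param path file path.
#' @param meta named list of metadata values.
#' @export
write_tac <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac
#' @export
read_tac <- function(path) {
  lines <- readLines(path)
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t")
  tac(df$time_min, df$conc, df$dur_min)
}

#' Study bundle: file-backed dynamic PET/CT study
#'
#' `write_study` lays out a directory with `ct.nii.gz`, `dynamic.nii.gz` (+
#' timing sidecar), and optionally `labels.nii.gz`, `movement.tsv` and
#' per-frame sinogram arrays; `read_study` loads it back, checking frame
#' counts across the series, sidecar and sinograms.  Round trips preserve
#' arrays bit-exactly (data are stored as float64).
#'
#' @param bundle list with elements `ct` ([image_volume]), `dynamic`
#'   ([dynamic_series]), and optional `labels` ([region_label_map]),
#'   `script` ([movement_script]), `seed` (integer).
#' @param path directory to create.
#' @export
write_study <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_volume(bundle$ct, file.path(path, "ct.nii.gz"))
  write_dynamic(bundle$dynamic, file.path(path, "dynamic.nii.gz"))
  if (!is.null(bundle$labels)) {
    write_volume(bundle$labels$vol, file.path(path, "labels.nii.gz"))
    utils::write.table(
      data.frame(role = names(bundle$labels$dict),
                 label = as.integer(bundle$labels$dict)),
      file.path(path, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (!is.null(bundle$script))
    write_transforms(bundle$script, file.path(path, "movement.tsv"))
  manifest <- c(
    sprintf("seed: %s", if (is.null(bundle$seed)) "NA" else bundle$seed),
    sprintf("frames: %d", n_frames(bundle$dynamic)),
    sprintf("ct_md5: %s", tools::md5sum(file.path(path, "ct.nii.gz"))[[1]]),
    sprintf("dynamic_md5: %s",
            tools::md5sum(file.path(path, "dynamic.nii.gz"))[[1]]))
  writeLines(manifest, file.path(path, "manifest.txt"))
  invisible(path)
}

#' @rdname write_study
#' @export
read_study <- function(path) {
  ct <- read_volume(file.path(path, "ct.nii.gz"))
  dyn <- read_dynamic(file.path(path, "dynamic.nii.gz"))
  out <- list(ct = ct, dynamic = dyn)
  lp <- file.path(path, "labels.nii.gz")
  if (file.exists(lp)) {
    lv <- read_volume(lp)
    ld <- utils::read.table(file.path(path, "labels.tsv"), header = TRUE,
                            sep = "\t")
    out$labels <- region_label_map(
      image_volume(array(as.integer(lv), dim(lv)), vol_spacing(lv), "label"),
      stats::setNames(as.integer(ld$label), ld$role))
  }
  mp <- file.path(path, "movement.tsv")
  if (file.exists(mp)) {
    out$script <- read_transforms(mp)
    if (length(out$script$transforms) != n_frames(dyn))
      stop("inconsistent frame counts: movement script has ",
           length(out$script$transforms), ", dynamic series ", n_frames(dyn))
  }
  man <- file.path(path, "manifest.txt")
  if (file.exists(man)) {
    sd <- grep("^seed:", readLines(man), value = TRUE)
    if (length(sd) && !grepl("NA", sd))
      out$seed <- as.integer(sub("seed: *", "", sd))
  }
  out
}
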