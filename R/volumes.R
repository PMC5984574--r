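#' Construct a volume grid
#'
#' The universal carrier for images, likelihood maps, masks and probability
#' maps: a 3-D array of finite real intensities plus the voxel spacing in mm.
#' All cross-volume operations in the package require identical shape and
#' spacing; nothing is ever resampled implicitly.
#'
#' @param data numeric 3-D array of finite values.
#' @param spacing positive numeric voxel size per axis in mm (length 1 or 3).
#' @return an object of class `"volume_grid"` with elements `data`, `spacing`.
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3-D array")
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at voxel (%d, %d, %d)",
                 bad[1L], bad[2L], bad[3L]))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  structure(list(data = data, spacing = spacing), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm, range [%g, %g]\n",
              d[1L], d[2L], d[3L],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
as.array.volume_grid <- function(x, ...) x$data

vg_like <- function(template, data) volume_grid(data, template$spacing)

same_lattice <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < 1e-6)
}

stopifnot_lattice <- function(..., what = "volumes") {
  vols <- list(...)
  ref <- vols[[1L]]
  for (v in vols[-1L])
    if (!same_lattice(ref, v))
      stop(sprintf("%s do not share a voxel lattice (shape/spacing mismatch)", what))
  invisible(TRUE)
}

#' Read a 3-D NIfTI volume
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`) with a 3-D scalar
#'   payload.
#' @return a [volume_grid()] with spacing taken from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such volume file: '%s'", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) {
    img <- array(as.numeric(img), dim = d[1:3])
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop(sprintf("'%s' does not hold a 3-D scalar payload", path))
  arr <- array(as.numeric(img), dim = d)
  if (!all(is.finite(arr))) {
    bad <- which(!is.finite(arr), arr.ind = TRUE)[1L, ]
    stop(sprintf("'%s' contains a non-finite value at voxel (%d, %d, %d)",
                 path, bad[1L], bad[2L], bad[3L]))
  }
  spacing <- RNifti::pixdim(img)[seq_len(3L)]
  volume_grid(arr, spacing)
}

#' Write a volume grid as NIfTI-1
#'
#' Data are stored as 64-bit floats so that [read_volume()] round-trips
#' bit-exactly.
#'
#' @param volume a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Bundle the per-subject input volumes
#'
#' @param t1,flair [volume_grid()] intensity volumes.
#' @param wm_prob,gm_prob tissue probability maps in `[0, 1]`.
#' @param ventricle_mask binary (0/1) ventricle mask.
#' @param atlas lesion-probability atlas in `[0, 1]`.
#' @param lesion_truth optional binary reference lesion mask.
#' @return an object of class `"subject_bundle"`; validated by
#'   [check_bundle()].
#' @export
subject_bundle <- function(t1, flair, wm_prob, gm_prob, ventricle_mask,
                           atlas, lesion_truth = NULL) {
  b <- structure(list(t1 = t1, flair = flair, wm_prob = wm_prob,
                      gm_prob = gm_prob, ventricle_mask = ventricle_mask,
                      atlas = atlas, lesion_truth = lesion_truth),
                 class = "subject_bundle")
  check_bundle(b)
}

#' Validate a subject bundle
#'
#' Checks that every member volume shares one lattice, probability volumes lie
#' in `[0, 1]` and masks are strictly 0/1.
#'
#' @param bundle a [subject_bundle()].
#' @return the bundle, unchanged, if valid; otherwise an error naming the
#'   offending member.
#' @export
check_bundle <- function(bundle) {
  members <- c("t1", "flair", "wm_prob", "gm_prob", "ventricle_mask", "atlas")
  ref <- bundle$t1
  for (m in members) {
    v <- bundle[[m]]
    if (!inherits(v, "volume_grid"))
      stop(sprintf("bundle member '%s' is not a volume_grid", m))
    if (!identical(dim(v$data), dim(ref$data)))
      stop(sprintf("bundle member '%s' has mismatched shape", m))
    if (any(abs(v$spacing - ref$spacing) >= 1e-6))
      stop(sprintf("bundle member '%s' has mismatched spacing", m))
  }
  for (m in c("wm_prob", "gm_prob", "atlas")) {
    v <- bundle[[m]]$data
    if (min(v) < 0 || max(v) > 1)
      stop(sprintf("bundle member '%s' has values outside [0, 1]", m))
  }
  for (m in "ventricle_mask") {
    v <- bundle[[m]]$data
    if (!all(v %in% c(0, 1)))
      stop(sprintf("bundle member '%s' is not a 0/1 mask", m))
  }
  if (!is.null(bundle$lesion_truth)) {
    v <- bundle$lesion_truth
    if (!identical(dim(v$data), dim(ref$data)))
      stop("bundle member 'lesion_truth' has mismatched shape")
    if (!all(v$data %in% c(0, 1)))
      stop("bundle member 'lesion_truth' is not a 0/1 mask")
  }
  bundle
}

#' @export
print.subject_bundle <- function(x, ...) {
  d <- dim(x$t1$data)
  cat(sprintf("<subject_bundle> %d x %d x %d voxels%s\n", d[1L], d[2L], d[3L],
              if (is.null(x$lesion_truth)) "" else
                sprintf(", lesion volume %g voxels", sum(x$lesion_truth$data))))
  invisible(x)
}

#' Write every volume of a bundle under a common prefix
#'
#' @param bundle a [subject_bundle()].
#' @param prefix path prefix; member names and `.nii.gz` are appended.
#' @return named character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, prefix) {
  members <- c("t1", "flair", "wm_prob", "gm_prob", "ventricle_mask", "atlas")
  if (!is.null(bundle$lesion_truth)) members <- c(members, "lesion_truth")
  paths <- vapply(members, function(m) {
    p <- paste0(prefix, "_", m, ".nii.gz")
    write_volume(bundle[[m]], p)
    p
  }, character(1L))
  invisible(paths)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param prefix the prefix used when writing.
#' @return a [subject_bundle()].
#' @export
read_bundle <- function(prefix) {
  rd <- function(m) read_volume(paste0(prefix, "_", m, ".nii.gz"))
  truth_path <- paste0(prefix, "_lesion_truth.nii.gz")
  subject_bundle(rd("t1"), rd("flair"), rd("wm_prob"), rd("gm_prob"),
                 rd("ventricle_mask"), rd("atlas"),
                 lesion_truth = if (file.exists(truth_path)) rd("lesion_truth"))
}
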