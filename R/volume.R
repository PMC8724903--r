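#' 3D scalar volume with voxel geometry
#'
#' `VolumeImage` is the common currency of all maps in the pipeline: a 3D
#' numeric array plus voxel spacing in mm and an axis-orientation code
#' identifying, in particular, the left-right axis used for contralateral
#' mirroring.
#'
#' @param voxels 3D numeric array.
#' @param spacing Numeric length-3, voxel size in mm per axis; all > 0.
#' @param orientation Three-letter axis code (one letter per array axis) drawn
#'   from R/L, A/P, S/I, naming the anatomical direction of increasing index.
#'   Default `"RAS"`: axis 1 runs left-to-right.
#' @param units Free-text value tag, e.g. `"SUV g/mL"`, `"rCBV ratio"`.
#' @return A `VolumeImage` object.
#' @export
volume_image <- function(voxels, spacing, orientation = "RAS", units = "a.u.") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("expected 3D volume, got ", length(dim(voxels)), "D")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 finite positive values (mm)")
  check_orientation(orientation)
  structure(
    list(voxels = voxels, spacing = spacing,
         orientation = toupper(orientation), units = units),
    class = "VolumeImage")
}

#' 3D binary mask sharing the VolumeImage geometry contract
#'
#' @param voxels 3D logical (or 0/1 numeric) array.
#' @inheritParams volume_image
#' @return A `BinaryMask` object.
#' @export
binary_mask <- function(voxels, spacing, orientation = "RAS") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("expected 3D mask, got ", length(dim(voxels)), "D")
  if (is.numeric(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      stop("numeric mask voxels must be 0/1")
    voxels <- array(voxels != 0, dim = dim(voxels))
  }
  if (!is.logical(voxels)) stop("mask voxels must be logical or 0/1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 finite positive values (mm)")
  check_orientation(orientation)
  structure(
    list(voxels = voxels, spacing = spacing, orientation = toupper(orientation)),
    class = "BinaryMask")
}

#' 4D dynamic susceptibility contrast (DSC) acquisition
#'
#' Frames are stored x-y-z-t. `injection_delay_s` is the pre-bolus baseline
#' duration; at least one frame must be acquired entirely before it.
#'
#' @param frames 4D numeric array (x, y, z, t).
#' @param tr_s Repetition time in seconds (frame spacing).
#' @param te_ms Echo time in milliseconds.
#' @param injection_delay_s Pre-bolus baseline duration in seconds.
#' @param spacing,orientation Voxel geometry, as in [volume_image()].
#' @return A `DynamicSeries` object. Frame `k` is taken at `(k-1)*tr_s` s.
#' @export
dynamic_series <- function(frames, tr_s, te_ms, injection_delay_s,
                           spacing, orientation = "RAS") {
  frames <- as.array(frames)
  if (length(dim(frames)) != 4L)
    stop("expected 4D series, got ", length(dim(frames)), "D")
  if (dim(frames)[4] < 2L) stop("series needs at least 2 time points")
  if (!is.finite(tr_s) || tr_s <= 0) stop("tr_s must be > 0")
  if (!is.finite(te_ms) || te_ms <= 0) stop("te_ms must be > 0")
  if (!is.finite(injection_delay_s) || injection_delay_s < 0)
    stop("injection_delay_s must be >= 0")
  if (injection_delay_s < tr_s)
    stop("need at least one fully pre-bolus frame (injection_delay_s >= tr_s)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("invalid spacing")
  check_orientation(orientation)
  structure(
    list(frames = frames, tr_s = tr_s, te_ms = te_ms,
         injection_delay_s = injection_delay_s,
         spacing = spacing, orientation = toupper(orientation)),
    class = "DynamicSeries")
}

check_orientation <- function(orientation) {
  o <- strsplit(toupper(orientation), "")[[1]]
  if (length(o) != 3L || !all(o %in% c("R", "L", "A", "P", "S", "I")))
    stop("orientation must be 3 letters from R/L, A/P, S/I")
  invisible(TRUE)
}

#' Index of the left-right axis of a volume or mask
#' @param x A `VolumeImage`, `BinaryMask` or `DynamicSeries`.
#' @return Integer axis index (1-3).
#' @export
lr_axis <- function(x) {
  o <- strsplit(x$orientation, "")[[1]]
  ax <- which(o %in% c("R", "L"))
  if (length(ax) != 1L) stop("unknown left-right axis in orientation '",
                             x$orientation, "'")
  ax
}

#' Test two objects for identical voxel geometry
#'
#' Same dimensions and spacing within 1e-6 mm. Geometry mismatch is always a
#' hard error downstream; silent resampling is never performed.
#'
#' @param a,b Volumes or masks.
#' @return `TRUE`/`FALSE`.
#' @export
same_geometry <- function(a, b) {
  da <- dim(a$voxels %||% a$frames)[1:3]
  db <- dim(b$voxels %||% b$frames)[1:3]
  identical(da, db) && all(abs(a$spacing - b$spacing) <= 1e-6)
}

stopifnot_same_geometry <- function(a, b) {
  if (!same_geometry(a, b))
    stop("geometry mismatch: dims/spacing differ; resample explicitly first")
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.VolumeImage <- function(x, ...) {
  cat(sprintf("<VolumeImage %s, %.4gx%.4gx%.4g mm, %s, units: %s>\n",
              paste(dim(x$voxels), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$orientation, x$units))
  invisible(x)
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("<BinaryMask %s, %.4gx%.4gx%.4g mm, %s, %d true voxels>\n",
              paste(dim(x$voxels), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$orientation, sum(x$voxels)))
  invisible(x)
}

#' @export
print.DynamicSeries <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<DynamicSeries %dx%dx%d x %d frames, TR %.3g s, TE %.3g ms, delay %.3g s>\n",
    d[1], d[2], d[3], d[4], x$tr_s, x$te_ms, x$injection_delay_s))
  invisible(x)
}
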