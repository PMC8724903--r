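#' Read a 3D NIfTI volume
#'
#' Spacing is taken from the header pixel dimensions and the axis orientation
#' from the sform/qform; files without an xform are assumed RAS.
#'
#' @param path Path to a NIfTI-1/2 file containing a 3D image.
#' @param units Units tag to attach (caller hint; NIfTI stores none).
#' @return A [volume_image()].
#' @export
read_volume <- function(path, units = "a.u.") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), "D: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-finite or non-positive voxel spacing in header: ", path)
  volume_image(nifti_array(img), spacing = sp,
               orientation = nifti_orientation(img), units = units)
}

#' Read a binary mask from a NIfTI file
#'
#' Masks are serialized as uint8 NIfTI with 0/1 values; any nonzero voxel is
#' treated as true.
#'
#' @param path Path to a NIfTI file containing a 3D 0/1 image.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$voxels != 0, spacing = v$spacing, orientation = v$orientation)
}

#' Write a volume or mask to NIfTI
#'
#' Masks are written as uint8 (0/1), float maps as float64, so integer masks
#' round-trip bit-exactly.
#'
#' @param x A `VolumeImage` or `BinaryMask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  is_mask <- inherits(x, "BinaryMask")
  arr <- if (is_mask) array(as.integer(x$voxels), dim = dim(x$voxels))
         else x$voxels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  RNifti::sform(img) <- orientation_affine(x$orientation, x$spacing)
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}

#' Read a 4D DSC series with its JSON sidecar
#'
#' TR is taken from the header time-step field; echo time and injection delay
#' from a sidecar JSON (keys `"EchoTimeMs"`, `"InjectionDelayS"`) found at
#' `<path without extension>.json` unless given explicitly.
#'
#' @param path Path to a 4D NIfTI file.
#' @param sidecar Optional explicit sidecar JSON path.
#' @return A [dynamic_series()].
#' @export
read_series <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected 4D series, got ", length(d), "D: ", path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 4L || pd[4] <= 0)
    stop("header time step (TR) missing or non-positive: ", path)
  if (is.null(sidecar))
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  if (!file.exists(sidecar)) stop("sidecar JSON not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar)
  if (is.null(meta$EchoTimeMs) || is.null(meta$InjectionDelayS))
    stop("sidecar must provide EchoTimeMs and InjectionDelayS")
  dynamic_series(nifti_array(img), tr_s = pd[4], te_ms = meta$EchoTimeMs,
                 injection_delay_s = meta$InjectionDelayS,
                 spacing = pd[1:3], orientation = nifti_orientation(img))
}

#' Write a 4D DSC series plus JSON sidecar
#'
#' @param x A `DynamicSeries`.
#' @param path Output NIfTI path; the sidecar goes to the same stem `.json`.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  img <- RNifti::asNifti(x$frames)
  RNifti::pixdim(img) <- c(x$spacing, x$tr_s)
  RNifti::sform(img) <- orientation_affine(x$orientation, x$spacing)
  RNifti::writeNifti(img, path, datatype = "double")
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  jsonlite::write_json(
    list(EchoTimeMs = x$te_ms, InjectionDelayS = x$injection_delay_s),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# plain array stripped of RNifti header attributes
nifti_array <- function(img) {
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  a
}

nifti_orientation <- function(img) {
  o <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (is.na(o) || nchar(o) != 3L) "RAS" else o
}

orientation_affine <- function(orientation, spacing) {
  dirs <- list(R = c(1, 0, 0),  L = c(-1, 0, 0),
               A = c(0, 1, 0),  P = c(0, -1, 0),
               S = c(0, 0, 1),  I = c(0, 0, -1))
  o <- strsplit(toupper(orientation), "")[[1]]
  m <- diag(4)
  for (j in 1:3) m[1:3, j] <- dirs[[o[j]]] * spacing[j]
  attr(m, "code") <- 2L
  m
}
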