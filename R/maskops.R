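#' Voxelwise Boolean algebra on binary masks
#'
#' The peripheral-volume and hot-spot statistics are defined by Boolean
#' operations between modality ROIs and the contrast-enhancement ROI; this is
#' the primitive they use. `NOT` is set difference (`a AND !b`).
#'
#' @param a,b `BinaryMask`s with identical geometry.
#' @param op One of `"AND"`, `"OR"`, `"NOT"`, `"XOR"`.
#' @return A `BinaryMask`.
#' @export
mask_ops <- function(a, b, op = c("AND", "OR", "NOT", "XOR")) {
  op <- match.arg(op)
  stopifnot_same_geometry(a, b)
  v <- switch(op,
    AND = a$voxels & b$voxels,
    OR  = a$voxels | b$voxels,
    NOT = a$voxels & !b$voxels,
    XOR = xor(a$voxels, b$voxels))
  binary_mask(v, spacing = a$spacing, orientation = a$orientation)
}

#' Mirror a mask across the mid-sagittal plane
#'
#' Realizes the "normal-appearing contralateral side" as the reflection along
#' the left-right axis: voxel index i maps to N-1-i (0-based) along that axis.
#'
#' @param mask A `BinaryMask` whose orientation identifies the L-R axis.
#' @return The mirrored `BinaryMask`.
#' @export
mirror_mask <- function(mask) {
  ax <- lr_axis(mask)
  n <- dim(mask$voxels)[ax]
  idx <- list(TRUE, TRUE, TRUE)
  idx[[ax]] <- n:1
  v <- do.call(`[`, c(list(mask$voxels), idx, list(drop = FALSE)))
  binary_mask(v, spacing = mask$spacing, orientation = mask$orientation)
}

#' Mirror a scalar volume across the mid-sagittal plane
#'
#' @param vol A `VolumeImage`.
#' @return The mirrored `VolumeImage`.
#' @export
mirror_volume <- function(vol) {
  ax <- lr_axis(vol)
  n <- dim(vol$voxels)[ax]
  idx <- list(TRUE, TRUE, TRUE)
  idx[[ax]] <- n:1
  v <- do.call(`[`, c(list(vol$voxels), idx, list(drop = FALSE)))
  volume_image(v, spacing = vol$spacing, orientation = vol$orientation,
               units = vol$units)
}
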