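#' Resample a volume or mask onto a reference grid
#'
#' Inputs are assumed co-registered (identity spatial transform); only grid
#' resampling is performed, using the voxel-center convention (the center of
#' voxel i, 0-based, sits at (i + 0.5) * spacing along each axis, with both
#' grids sharing their corner origin). Values outside the moving extent are 0.
#' Masks must use nearest-neighbour interpolation.
#'
#' @param moving `VolumeImage` or `BinaryMask` to resample.
#' @param reference `VolumeImage` or `BinaryMask` defining the target grid.
#' @param mode `"trilinear"` or `"nearest"`. Trilinear on a mask is an error.
#' @return Object of the same class as `moving`, on the reference grid.
#' @export
resample_to_reference <- function(moving, reference,
                                  mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  is_mask <- inherits(moving, "BinaryMask")
  if (is_mask && mode == "trilinear")
    stop("trilinear interpolation is not valid for a binary mask; use nearest")
  if (same_geometry(moving, reference)) return(moving)

  src <- if (is_mask) array(as.numeric(moving$voxels), dim = dim(moving$voxels))
         else moving$voxels
  dm <- dim(src)
  dr <- dim(reference$voxels %||% reference$frames)[1:3]

  # continuous 1-based moving-grid coordinate of each reference voxel center
  cc <- lapply(1:3, function(ax)
    ((seq_len(dr[ax]) - 0.5) * reference$spacing[ax]) / moving$spacing[ax] + 0.5)

  out <- if (mode == "nearest") {
    ix <- lapply(1:3, function(ax) as.integer(round(cc[[ax]])))
    IX <- array(ix[[1]], dim = dr)
    IY <- array(rep(ix[[2]], each = dr[1]), dim = dr)
    IZ <- array(rep(ix[[3]], each = dr[1] * dr[2]), dim = dr)
    ok <- IX >= 1L & IX <= dm[1] & IY >= 1L & IY <= dm[2] & IZ >= 1L & IZ <= dm[3]
    v <- array(0, dim = dr)
    lin <- IX[ok] + (IY[ok] - 1L) * dm[1] + (IZ[ok] - 1L) * dm[1] * dm[2]
    v[ok] <- src[lin]
    v
  } else {
    fl <- lapply(cc, floor)
    wt <- lapply(1:3, function(ax) cc[[ax]] - fl[[ax]])
    FX <- array(as.integer(fl[[1]]), dim = dr)
    FY <- array(rep(as.integer(fl[[2]]), each = dr[1]), dim = dr)
    FZ <- array(rep(as.integer(fl[[3]]), each = dr[1] * dr[2]), dim = dr)
    WX <- array(wt[[1]], dim = dr)
    WY <- array(rep(wt[[2]], each = dr[1]), dim = dr)
    WZ <- array(rep(wt[[3]], each = dr[1] * dr[2]), dim = dr)
    v <- array(0, dim = dr)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      IX <- FX + dx; IY <- FY + dy; IZ <- FZ + dz
      w <- (if (dx) WX else 1 - WX) * (if (dy) WY else 1 - WY) *
           (if (dz) WZ else 1 - WZ)
      ok <- IX >= 1L & IX <= dm[1] & IY >= 1L & IY <= dm[2] &
            IZ >= 1L & IZ <= dm[3] & w > 0
      if (any(ok)) {
        lin <- IX[ok] + (IY[ok] - 1L) * dm[1] + (IZ[ok] - 1L) * dm[1] * dm[2]
        v[ok] <- v[ok] + w[ok] * src[lin]
      }
    }
    v
  }

  if (is_mask)
    binary_mask(out != 0, spacing = reference$spacing,
                orientation = moving$orientation)
  else
    volume_image(out, spacing = reference$spacing,
                 orientation = moving$orientation, units = moving$units)
}
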