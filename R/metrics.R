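#' Volume of a binary mask in mL
#'
#' True-voxel count times voxel volume (mm^3) / 1000.
#'
#' @param mask A `BinaryMask`.
#' @return Volume in mL.
#' @export
volume_ml <- function(mask) {
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' Peripheral volume percentage of a modality ROI outside the CE region
#'
#' The fraction of a modality's segmented volume lying outside the
#' contrast-enhancement (CE) region, expressed relative to the CE volume:
#' \deqn{100 \cdot |ROI_{mod} \setminus ROI_{CE}| / |ROI_{CE}|.}
#' The denominator is the CE volume, so values above 100% are possible (and
#' observed) when the modality volume extends far beyond CE.
#'
#' @param modality,ce `BinaryMask`s with identical geometry; `ce` non-empty.
#' @return Percentage (>= 0, unbounded above).
#' @export
peripheral_volume_pct <- function(modality, ce) {
  stopifnot_same_geometry(modality, ce)
  n_ce <- sum(ce$voxels)
  if (n_ce == 0L) stop("CE mask is empty: peripheral percentage undefined")
  100 * sum(modality$voxels & !ce$voxels) / n_ce
}

#' Peripheral hot-spot percentage outside the CE region
#'
#' Same Boolean statistic as [peripheral_volume_pct()], applied to the
#' hot-spot subvolume mask.
#'
#' @param hotspot,ce `BinaryMask`s with identical geometry; `ce` non-empty.
#' @return Percentage.
#' @export
peripheral_hotspot_pct <- function(hotspot, ce) {
  peripheral_volume_pct(hotspot, ce)
}

#' Dice similarity coefficient between two masks
#'
#' @param a,b `BinaryMask`s with identical geometry.
#' @return 2|A AND B| / (|A| + |B|); 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot_same_geometry(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L) return(1)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Per-modality overlap and peripheral summary against the CE mask
#'
#' One row per labelled modality mask (and optional hot-spot mask): ROI
#' volume, CE volume, overlap volume, peripheral volume % and peripheral
#' hot-spot %.
#'
#' @param masks Named list of modality `BinaryMask`s.
#' @param ce CE `BinaryMask`.
#' @param hotspots Optional named list of hot-spot `BinaryMask`s (names a
#'   subset of `names(masks)`).
#' @return A data.frame with columns `modality`, `volume_ml`, `ce_volume_ml`,
#'   `overlap_ml`, `peripheral_volume_pct`, `peripheral_hotspot_pct`.
#' @export
overlap_summary <- function(masks, ce, hotspots = NULL) {
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("masks must be a named list")
  rows <- lapply(names(masks), function(lab) {
    m <- masks[[lab]]
    stopifnot_same_geometry(m, ce)
    hs_pct <- NA_real_
    if (!is.null(hotspots) && lab %in% names(hotspots))
      hs_pct <- peripheral_hotspot_pct(hotspots[[lab]], ce)
    data.frame(
      modality = lab,
      volume_ml = volume_ml(m),
      ce_volume_ml = volume_ml(ce),
      overlap_ml = volume_ml(mask_ops(m, ce, "AND")),
      peripheral_volume_pct = peripheral_volume_pct(m, ce),
      peripheral_hotspot_pct = hs_pct,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
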