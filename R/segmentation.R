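#' Mean and SD of a map over a contralateral mask
#'
#' The "Mean Contra" statistics underlying the statistical thresholds: the
#' tumor-volume cutoffs are mean + 3.3 SDs on FMISO SUV maps and mean + 1.96
#' SDs on rCBV maps, computed over normal-appearing contralateral tissue.
#' Non-finite voxels are excluded.
#'
#' @param map `VolumeImage`.
#' @param contra Non-empty `BinaryMask` (>= 2 finite voxels).
#' @param source Provenance label stored with the result.
#' @return A `ContralateralStats`: list with `mean`, `sd` (sample SD),
#'   `n_voxels`, `source`.
#' @export
contralateral_stats <- function(map, contra, source = "contralateral") {
  stopifnot_same_geometry(map, contra)
  v <- map$voxels[contra$voxels]
  v <- v[is.finite(v)]
  if (length(v) < 2L)
    stop("contralateral mask must contain at least 2 finite voxels")
  structure(list(mean = mean(v), sd = stats::sd(v), n_voxels = length(v),
                 source = source),
            class = "ContralateralStats")
}

new_segmentation_result <- function(mask, method, threshold_value, params) {
  structure(list(mask = mask, method = method,
                 threshold_value = threshold_value, params = params),
            class = "SegmentationResult")
}

#' @export
print.SegmentationResult <- function(x, ...) {
  cat(sprintf("<SegmentationResult method=%s threshold=%s, %d voxels>\n",
              x$method,
              if (is.null(x$threshold_value)) "-"
              else format(x$threshold_value, digits = 5),
              sum(x$mask$voxels)))
  invisible(x)
}

#' Statistical contralateral threshold segmentation
#'
#' Selects voxels with value strictly greater than mean + k * SD of the
#' contralateral statistics (k = 3.3 for FMISO SUV, 1.96 for rCBV), optionally
#' intersected with a restriction mask (the FLAIR hypersignal for rCBV and
#' FMISO). Non-finite voxels are never selected.
#'
#' @param map `VolumeImage`.
#' @param stats A `ContralateralStats` from [contralateral_stats()].
#' @param k SD multiplier, > 0.
#' @param restrict Optional `BinaryMask` intersected with the result.
#' @return A `SegmentationResult` with method `"stat_threshold"` and the
#'   realized cutoff in `threshold_value`.
#' @export
stat_threshold_seg <- function(map, stats, k, restrict = NULL) {
  if (!is.finite(k) || k <= 0) stop("k must be > 0")
  thr <- stats$mean + k * stats$sd
  sel <- is.finite(map$voxels) & map$voxels > thr
  if (!is.null(restrict)) {
    stopifnot_same_geometry(map, restrict)
    sel <- sel & restrict$voxels
  }
  mask <- binary_mask(sel, spacing = map$spacing,
                      orientation = map$orientation)
  new_segmentation_result(mask, "stat_threshold", thr,
                          list(k = k, mean = stats$mean, sd = stats$sd,
                               restricted = !is.null(restrict)))
}

#' Percent-of-maximum segmentation
#'
#' Threshold at `fraction` of the map maximum over the search region (the
#' classical 40%-of-SUVmax PET delineation); selection uses `>=` so a
#' constant region is fully selected.
#'
#' @param map `VolumeImage`.
#' @param fraction Fraction of the maximum, in (0, 1).
#' @param search Non-empty `BinaryMask` defining both the max and the
#'   candidate voxels.
#' @return A `SegmentationResult` with method `"percent_max"`.
#' @export
percent_max_seg <- function(map, fraction, search) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  stopifnot_same_geometry(map, search)
  vals <- map$voxels[search$voxels]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("search region is empty")
  thr <- fraction * max(vals)
  sel <- search$voxels & is.finite(map$voxels) & map$voxels >= thr
  mask <- binary_mask(sel, spacing = map$spacing,
                      orientation = map$orientation)
  new_segmentation_result(mask, "percent_max", thr,
                          list(fraction = fraction, max = max(vals)))
}

#' Reference-ratio segmentation
#'
#' Threshold at `factor` times a reference value: the 1.2 tissue-to-blood
#' cutoff for FMISO (reference = blood activity) or 2-3 times the
#' normal-appearing white-matter signal for CBV maps.
#'
#' @param map `VolumeImage`.
#' @param reference_value Positive reference in map units.
#' @param factor Multiplier, > 0.
#' @param restrict Optional `BinaryMask` intersected with the result.
#' @return A `SegmentationResult` with method `"ratio"`.
#' @export
ratio_seg <- function(map, reference_value, factor, restrict = NULL) {
  if (!is.finite(reference_value) || reference_value <= 0)
    stop("reference_value must be > 0")
  if (!is.finite(factor) || factor <= 0) stop("factor must be > 0")
  thr <- factor * reference_value
  sel <- is.finite(map$voxels) & map$voxels > thr
  if (!is.null(restrict)) {
    stopifnot_same_geometry(map, restrict)
    sel <- sel & restrict$voxels
  }
  mask <- binary_mask(sel, spacing = map$spacing,
                      orientation = map$orientation)
  new_segmentation_result(mask, "ratio", thr,
                          list(reference_value = reference_value,
                               factor = factor,
                               restricted = !is.null(restrict)))
}

#' Hot-spot segmentation at a histogram percentile
#'
#' The hot spot is the subvolume at or above the stated percentile (default
#' 95th) of the map's value distribution within the FLAIR-hypersignal ROI.
#' The percentile uses linear interpolation between order statistics;
#' selection uses `>=`, so a constant ROI yields a full hot spot. The result
#' is always a subset of the FLAIR mask.
#'
#' @param map `VolumeImage`.
#' @param flair Non-empty FLAIR-hypersignal `BinaryMask`.
#' @param percentile Percentile in (0, 100), default 95.
#' @return A `SegmentationResult` with method `"hotspot"`.
#' @export
hotspot_seg <- function(map, flair, percentile = 95) {
  if (!is.finite(percentile) || percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  stopifnot_same_geometry(map, flair)
  vals <- map$voxels[flair$voxels]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("FLAIR region is empty")
  thr <- unname(stats::quantile(vals, percentile / 100, type = 7))
  sel <- flair$voxels & is.finite(map$voxels) & map$voxels >= thr
  mask <- binary_mask(sel, spacing = map$spacing,
                      orientation = map$orientation)
  new_segmentation_result(mask, "hotspot", thr,
                          list(percentile = percentile))
}

#' Standardized uptake value map from an activity-concentration map
#'
#' SUV (g/mL) = tissue activity concentration (kBq/mL) divided by injected
#' activity per gram of body weight (kBq/g).
#'
#' @param activity `VolumeImage` in kBq/mL.
#' @param injected_activity_kbq Injected activity in kBq, > 0.
#' @param body_weight_g Body weight in g, > 0.
#' @return `VolumeImage` with units `"SUV g/mL"`.
#' @export
suv_map <- function(activity, injected_activity_kbq, body_weight_g) {
  if (!is.finite(injected_activity_kbq) || injected_activity_kbq <= 0)
    stop("injected_activity_kbq must be > 0")
  if (!is.finite(body_weight_g) || body_weight_g <= 0)
    stop("body_weight_g must be > 0")
  volume_image(activity$voxels / (injected_activity_kbq / body_weight_g),
               spacing = activity$spacing, orientation = activity$orientation,
               units = "SUV g/mL")
}
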