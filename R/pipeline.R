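#' Per-modality method choices for a case analysis
#'
#' Defaults encode the per-modality tuning of the analysis: FLT is delineated
#' with the fuzzy locally adaptive Bayesian class model (2 or 3 classes);
#' FMISO with the contralateral statistical threshold mean + 3.3 SDs, hidden
#' by the FLAIR hypersignal; rCBV with mean + 1.96 SDs restricted to FLAIR;
#' hot spots at the 95th percentile within FLAIR for every modality.
#'
#' @param flt_method `"flab"` or `"stat"`.
#' @param flt_classes 2 or 3 FLAB classes.
#' @param fmiso_k,rcbv_k SD multipliers for the statistical thresholds.
#' @param hotspot_percentile Hot-spot percentile within FLAIR.
#' @param cbv_noise_floor Peak delta-R2* (1/ms) below which a voxel is not
#'   fitted during CBV mapping.
#' @return A named list of method parameters for [run_case()].
#' @export
case_methods <- function(flt_method = c("flab", "stat"), flt_classes = 2L,
                         fmiso_k = 3.3, rcbv_k = 1.96,
                         hotspot_percentile = 95, cbv_noise_floor = 1e-4) {
  list(flt_method = match.arg(flt_method), flt_classes = flt_classes,
       fmiso_k = fmiso_k, rcbv_k = rcbv_k,
       hotspot_percentile = hotspot_percentile,
       cbv_noise_floor = cbv_noise_floor)
}

#' Run the full per-case analysis
#'
#' Orchestrates the whole pipeline on one case: DSC to delta-R2* to CBV to
#' rCBV, per-modality tumor segmentation, hot-spot extraction within FLAIR,
#' and the peripheral volume / hot-spot percentages against the CE mask.
#'
#' @param case A `PhantomCase` from [make_phantom()], or a named list of
#'   file paths (`dsc` plus optional sidecar convention of [read_series()],
#'   `flt`, `fmiso`, `ce`, `flair`, `brain`, `tumor_hemisphere`) to
#'   co-registered NIfTI inputs on a shared grid.
#' @param methods Method parameters from [case_methods()].
#' @param out_dir Optional directory: all masks and maps are written as
#'   NIfTI plus `report.json` and a one-row `report.csv`, so every reported
#'   number is recomputable from saved intermediates.
#' @param case_id Label used in the report.
#' @return A `CaseReport`: list with `metrics` (the [overlap_summary()]
#'   data.frame), `thresholds`, `qc`, `provenance`, and the segmentation
#'   masks.
#' @export
run_case <- function(case, methods = case_methods(), out_dir = NULL,
                     case_id = "case") {
  if (inherits(case, "PhantomCase")) {
    flt <- case$flt; fmiso <- case$fmiso; dsc <- case$dsc
    ce <- case$masks$ce; flair <- case$masks$flair
    brain <- case$masks$brain
    tumor_hemi <- case$masks$right_hemisphere
  } else {
    dsc <- read_series(case$dsc)
    flt <- read_volume(case$flt, units = "SUV g/mL")
    fmiso <- read_volume(case$fmiso, units = "SUV g/mL")
    ce <- read_mask(case$ce); flair <- read_mask(case$flair)
    brain <- read_mask(case$brain)
    tumor_hemi <- read_mask(case$tumor_hemisphere)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  contra_ref <- stage("contralateral reference",
                      contralateral_reference(brain, tumor_hemi, flair))

  # rCBV mapping
  conc <- stage("deltaR2star", signal_to_deltaR2star(dsc, brain))
  cbv <- stage("cbv", compute_cbv(conc, noise_floor = methods$cbv_noise_floor))
  rcbv <- stage("rcbv", normalize_rcbv(cbv, contra_ref))

  # volume segmentation per modality
  flt_seg <- stage("flt segmentation", {
    if (methods$flt_method == "flab")
      flab_seg(flt, n_classes = methods$flt_classes, roi = bbox_roi(flair))
    else
      stat_threshold_seg(flt, contralateral_stats(flt, contra_ref), k = 3.3,
                         restrict = NULL)
  })
  fmiso_stats <- stage("fmiso contra stats",
                       contralateral_stats(fmiso, contra_ref))
  fmiso_seg <- stage("fmiso segmentation",
                     stat_threshold_seg(fmiso, fmiso_stats,
                                        k = methods$fmiso_k, restrict = flair))
  rcbv_stats <- stage("rcbv contra stats",
                      contralateral_stats(rcbv, contra_ref))
  rcbv_seg <- stage("rcbv segmentation",
                    stat_threshold_seg(rcbv, rcbv_stats,
                                       k = methods$rcbv_k, restrict = flair))

  # hot spots within FLAIR
  p <- methods$hotspot_percentile
  hs <- stage("hot spots", list(
    FLT = hotspot_seg(flt, flair, p),
    rCBV = hotspot_seg(rcbv, flair, p),
    FMISO = hotspot_seg(fmiso, flair, p)))

  seg_masks <- list(FLT = flt_seg$mask, rCBV = rcbv_seg$mask,
                    FMISO = fmiso_seg$mask)
  hs_masks <- lapply(hs, function(s) s$mask)
  metrics <- stage("metrics", overlap_summary(seg_masks, ce, hs_masks))

  report <- structure(list(
    case_id = case_id,
    metrics = metrics,
    thresholds = list(
      flt = if (methods$flt_method == "flab") flt_seg$params
            else flt_seg$threshold_value,
      fmiso = fmiso_seg$threshold_value,
      rcbv = rcbv_seg$threshold_value,
      hotspot = lapply(hs, function(s) s$threshold_value)),
    qc = list(cbv = attr(cbv, "qc"),
              fmiso_contra = unclass(fmiso_stats)[c("mean", "sd", "n_voxels")],
              rcbv_contra = unclass(rcbv_stats)[c("mean", "sd", "n_voxels")]),
    provenance = list(
      version = as.character(utils::packageVersion("perivox")),
      methods = methods,
      seed = if (inherits(case, "PhantomCase")) case$config$seed else NA),
    masks = c(seg_masks,
              stats::setNames(hs_masks, paste0(names(hs_masks), "_hotspot")),
              list(ce = ce)),
    maps = list(rcbv = rcbv)),
    class = "CaseReport")

  if (!is.null(out_dir)) write_case_report(report, out_dir)
  report
}

write_case_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$masks))
    write_volume(report$masks[[nm]],
                 file.path(out_dir, paste0(tolower(nm), "_mask.nii")))
  write_volume(report$maps$rcbv, file.path(out_dir, "rcbv.nii"))
  jsonlite::write_json(
    list(case_id = report$case_id, metrics = report$metrics,
         thresholds = report$thresholds, qc = report$qc,
         provenance = report$provenance),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", force = TRUE)
  utils::write.csv(cbind(case_id = report$case_id, report$metrics),
                   file.path(out_dir, "report.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.CaseReport <- function(x, ...) {
  cat(sprintf("<CaseReport %s>\n", x$case_id))
  print(x$metrics)
  invisible(x)
}

#' Cohort summary of peripheral percentages
#'
#' Per modality: min / median / max of the peripheral volume and hot-spot
#' percentages over the cases, and binned counts of the peripheral volume
#' with edges 0-20%, 20-40%, >40%.
#'
#' @param reports List of `CaseReport`s (>= 1).
#' @return A list with `stats` (one row per modality) and `bins` (counts per
#'   modality and bin); bins always sum to the number of cases.
#' @export
summarize_cohort <- function(reports) {
  if (length(reports) == 0L) stop("no case reports supplied")
  tab <- do.call(rbind, lapply(reports, function(r)
    cbind(case_id = r$case_id, r$metrics)))
  mods <- unique(tab$modality)
  stats_df <- do.call(rbind, lapply(mods, function(m) {
    v <- tab$peripheral_volume_pct[tab$modality == m]
    h <- tab$peripheral_hotspot_pct[tab$modality == m]
    data.frame(modality = m, n = length(v),
               min_pct = min(v), median_pct = stats::median(v),
               max_pct = max(v),
               min_hotspot_pct = min(h), median_hotspot_pct = stats::median(h),
               max_hotspot_pct = max(h), stringsAsFactors = FALSE)
  }))
  bins_df <- do.call(rbind, lapply(mods, function(m) {
    v <- tab$peripheral_volume_pct[tab$modality == m]
    data.frame(modality = m,
               bin_0_20 = sum(v >= 0 & v < 20),
               bin_20_40 = sum(v >= 20 & v < 40),
               bin_over_40 = sum(v >= 40), stringsAsFactors = FALSE)
  }))
  list(stats = stats_df, bins = bins_df, cases = tab)
}
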