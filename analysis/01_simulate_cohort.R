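#!/usr/bin/env Rscript
# Simulate a small cohort of digital glioblastoma cases spanning the spectrum
# of peripheral-volume behaviour: from tumors whose proliferative margin
# barely exceeds the enhancing rim to extensively infiltrative ones, plus a
# hypoxic/hypervascular-margin variant. Each case is written as a directory
# of NIfTI volumes (maps, DSC series, masks) with the ground truth as JSON.
#
# Images are scratch output (binary); tables downstream go to results/.

suppressMessages(library(perivox))

out_root <- "scratch/cases"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

base <- phantom_config()

cohort <- list(
  # infiltrative margin well beyond CE (FLT-avid, mildly hypoxic)
  infiltrative = phantom_config(seed = 1L),
  # margin barely beyond the rim: small peripheral volumes
  compact = phantom_config(margin_radius_mm = 12, seed = 2L),
  # intermediate infiltration
  intermediate = phantom_config(margin_radius_mm = 13, seed = 3L),
  # metabolically bland margin: proliferation confined to the rim
  bland_margin = phantom_config(
    flt = utils::modifyList(base$flt, list(margin = c(0.8, 0.15))),
    fmiso = utils::modifyList(base$fmiso, list(margin = c(1.1, 0.15))),
    seed = 4L),
  # strongly hypoxic and hypervascular margin
  hypoxic_margin = phantom_config(
    fmiso = utils::modifyList(base$fmiso, list(margin = c(1.8, 0.2))),
    cbv_scale = c(core = 0.3, rim = 3.0, margin = 1.6),
    seed = 5L),
  # small tumor
  small_tumor = phantom_config(core_radius_mm = 4, rim_radius_mm = 8,
                               margin_radius_mm = 11, seed = 6L))

for (id in names(cohort)) {
  ph <- make_phantom(cohort[[id]])
  dir <- file.path(out_root, id)
  dir.create(dir, showWarnings = FALSE)
  write_series(ph$dsc, file.path(dir, "dsc.nii"))
  write_volume(ph$flt, file.path(dir, "flt_suv.nii"))
  write_volume(ph$fmiso, file.path(dir, "fmiso_suv.nii"))
  for (nm in names(ph$masks))
    write_volume(ph$masks[[nm]], file.path(dir, paste0(nm, "_mask.nii")))
  jsonlite::write_json(
    list(volumes_ml = as.list(ph$truth$volumes_ml),
         peripheral_pct = as.list(ph$truth$peripheral_pct),
         means = ph$truth$means, seed = ph$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  cat(sprintf("%-15s CE %5.2f mL, FLAIR %5.2f mL, truth peripheral FLT %.1f%%\n",
              id, ph$truth$volumes_ml[["ce"]], ph$truth$volumes_ml[["flair"]],
              ph$truth$peripheral_pct[["FLT"]]))
}
cat("cases written under", out_root, "\n")
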