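test_that("phantom generation is deterministic given the seed", {
  a <- make_phantom(small_phantom_config(seed = 5L, dsc_noise_sd = 2))
  b <- make_phantom(small_phantom_config(seed = 5L, dsc_noise_sd = 2))
  expect_identical(a$flt$voxels, b$flt$voxels)
  expect_identical(a$fmiso$voxels, b$fmiso$voxels)
  expect_identical(a$dsc$frames, b$dsc$frames)
  c2 <- make_phantom(small_phantom_config(seed = 6L, dsc_noise_sd = 2))
  expect_false(identical(a$flt$voxels, c2$flt$voxels))
})

test_that("noise-free, PSF-free compartments equal their configured means", {
  cfg <- small_phantom_config(
    seed = 1L,
    flt = list(bg = c(0.4, 0), core = c(0.3, 0),
               rim = c(2.5, 0), margin = c(1.5, 0)),
    fmiso = list(bg = c(1.0, 0), core = c(0.8, 0),
                 rim = c(2.2, 0), margin = c(1.45, 0)))
  ph <- make_phantom(cfg)
  expect_true(all(ph$flt$voxels[ph$masks$rim$voxels] == 2.5))
  expect_true(all(ph$flt$voxels[ph$masks$margin$voxels] == 1.5))
  expect_true(all(ph$fmiso$voxels[ph$masks$core$voxels] == 0.8))
  nontumor <- ph$masks$brain$voxels &
    !(ph$masks$core$voxels | ph$masks$rim$voxels | ph$masks$margin$voxels)
  expect_true(all(ph$flt$voxels[nontumor] == 0.4))
})

test_that("truth bookkeeping matches spatial metrics exactly", {
  ph <- make_phantom(small_phantom_config(seed = 2L))
  # stored volumes are spacing-weighted voxel counts
  for (nm in names(ph$masks))
    expect_identical(ph$truth$volumes_ml[[nm]], volume_ml(ph$masks[[nm]]))
  # stored peripheral percentages recompute from the truth masks
  for (nm in names(ph$truth$modality_masks))
    expect_identical(
      ph$truth$peripheral_pct[[nm]],
      peripheral_volume_pct(ph$truth$modality_masks[[nm]], ph$masks$ce))
})

test_that("compartments are nested and all masks share the case geometry", {
  ph <- make_phantom(small_phantom_config(seed = 4L))
  expect_equal(sum(ph$masks$core$voxels & ph$masks$rim$voxels), 0L)
  expect_equal(sum(ph$masks$rim$voxels & ph$masks$margin$voxels), 0L)
  expect_true(all(vapply(ph$masks, function(m)
    same_geometry(m, ph$flt), logical(1))))
  # CE is the enhancing rim; FLAIR is rim + margin
  expect_identical(ph$masks$ce$voxels, ph$masks$rim$voxels)
  expect_identical(ph$masks$flair$voxels,
                   ph$masks$rim$voxels | ph$masks$margin$voxels)
  # hemispheres partition the brain
  expect_identical(ph$masks$left_hemisphere$voxels |
                     ph$masks$right_hemisphere$voxels,
                   ph$masks$brain$voxels)
})

test_that("voxelized sphere volumes approach the analytic value", {
  cfg <- phantom_config(grid_dims = c(60L, 60L, 60L),
                        spacing_mm = c(1, 1, 1),
                        brain_semiaxes_mm = c(29, 29, 29),
                        tumor_center_offset_mm = 6,
                        core_radius_mm = 4, rim_radius_mm = 8,
                        margin_radius_mm = 12, nawm_radius_mm = 5,
                        psf_fwhm_mm = 0, seed = 1L)
  ph <- make_phantom(cfg)
  vol_sphere <- function(r) 4 / 3 * pi * r^3 / 1000
  got <- volume_ml(ph$masks$core)
  expect_lt(abs(got - vol_sphere(4)) / vol_sphere(4), 0.1)
  nested <- volume_ml(ph$masks$core) + volume_ml(ph$masks$rim)
  expect_lt(abs(nested - vol_sphere(8)) / vol_sphere(8), 0.05)
})

test_that("DSC forward model: flat before injection, gamma-shaped after", {
  cfg <- small_phantom_config(seed = 7L)
  ph <- make_phantom(cfg)
  t_frames <- (seq_len(dim(ph$dsc$frames)[4]) - 1) * ph$dsc$tr_s
  pre <- which(t_frames < cfg$dsc$injection_delay_s)
  s0 <- cfg$dsc$s0
  brain_lin <- which(ph$masks$brain$voxels)
  for (k in pre) {
    fr <- ph$dsc$frames[, , , k]
    expect_true(all(fr[brain_lin] == s0))
  }
  # zero bolus amplitude -> constant series at S0
  cfg0 <- small_phantom_config(seed = 7L)
  cfg0$dsc$K <- 0
  ser0 <- make_dsc_series(cfg0, make_phantom(cfg0)$masks)
  expect_true(all(ser0$frames[rep(ph$masks$brain$voxels,
                                  dim(ser0$frames)[4])] == s0))
})

test_that("configuration contract violations are caught", {
  expect_error(phantom_config(core_radius_mm = 9, rim_radius_mm = 5),
               "nested")
  expect_error(phantom_config(tumor_center_offset_mm = 100),
               "exceed")
  expect_error(phantom_config(
    flt = list(bg = c(0.4, -1), core = c(0.3, 0),
               rim = c(2.5, 0), margin = c(1.5, 0))),
    "SD")
  cfg <- small_phantom_config()
  cfg$dsc$noise_sd <- -1
  expect_error(make_phantom(cfg), "SD")
})

test_that("raising a compartment mean cannot shrink a fixed-threshold mask", {
  seg_vol <- function(rim_mean) {
    cfg <- small_phantom_config(
      seed = 9L,
      flt = list(bg = c(0.4, 0.08), core = c(0.3, 0.05),
                 rim = c(rim_mean, 0.3), margin = c(1.5, 0.25)))
    ph <- make_phantom(cfg)
    sum(ratio_seg(ph$flt, reference_value = 1, factor = 1.2)$mask$voxels)
  }
  vols <- vapply(c(2.0, 2.5, 3.5, 5.0), seg_vol, numeric(1))
  expect_true(all(diff(vols) >= 0))
})
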