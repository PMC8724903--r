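# Small in-code fixtures shared across test files.

unit_spacing <- c(1, 1, 1)

# mask from a logical/0-1 array with unit spacing unless stated
mk_mask <- function(arr, spacing = unit_spacing) {
  binary_mask(array(as.logical(arr), dim = dim(arr)), spacing = spacing)
}

# random mask with inclusion probability p
rand_mask <- function(dims, p = 0.3, spacing = unit_spacing) {
  mk_mask(array(stats::runif(prod(dims)) < p, dim = dims), spacing)
}

# a small, fast phantom configuration used by pipeline-level tests:
# coarser grid than the default study conditions, noise-free DSC so that
# CBV fitting deduplicates to the four distinct tissue curves
small_phantom_config <- function(seed = 1L, dsc_noise_sd = 0,
                                 psf_fwhm_mm = 0, ...) {
  base <- phantom_config()
  phantom_config(
    grid_dims = c(26L, 26L, 12L),
    spacing_mm = c(3, 3, 5),
    brain_semiaxes_mm = c(34, 34, 26),
    tumor_center_offset_mm = 15,
    core_radius_mm = 5, rim_radius_mm = 9, margin_radius_mm = 12,
    nawm_radius_mm = 7,
    dsc = utils::modifyList(base$dsc, list(noise_sd = dsc_noise_sd)),
    psf_fwhm_mm = psf_fwhm_mm,
    seed = seed, ...)
}

# two-class delineation phantom: background 1.0 +/- 0.1, tumor 3.0 +/- 0.2,
# tumor fraction ~10%; returns map, truth mask, and a background mask
two_class_phantom <- function(seed = 11L, dims = c(22L, 22L, 12L),
                              bg_mean = 1.0, bg_sd = 0.1,
                              tumor_mean = 3.0, tumor_sd = 0.2) {
  set.seed(seed)
  truth <- array(FALSE, dims)
  truth[9:14, 9:14, 5:9] <- TRUE  # 180 voxels, ~3-10% depending on dims
  vals <- array(stats::rnorm(prod(dims), bg_mean, bg_sd), dims)
  vals[truth] <- stats::rnorm(sum(truth), tumor_mean, tumor_sd)
  list(map = volume_image(vals, spacing = unit_spacing),
       truth = mk_mask(truth),
       background = mk_mask(!truth))
}
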