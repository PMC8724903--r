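#' Configuration for the digital glioblastoma phantom
#'
#' Defines a two-hemisphere brain with a three-compartment tumor (necrotic
#' core, enhancing rim, infiltrative margin, as nested spheres), per-modality
#' compartment statistics, and the DSC acquisition parameters. Defaults
#' emulate the acquisition this pipeline targets: PET maps on a
#' 1.95 x 1.95 x 3.27 mm grid, DSC with 35 frames at TR 2.28 s, TE 60 ms and
#' a 20 s injection delay. The per-compartment uptake means encode the
#' expected biology: FLT (proliferation) elevated in rim and margin, FMISO
#' (hypoxia) highest in the rim and moderate in the margin, blood volume
#' strongly elevated in the enhancing rim only (the infiltrative margin is
#' not angiogenic). CE is the enhancing rim;
#' FLAIR hypersignal is rim + margin.
#'
#' @param grid_dims Integer triple, default `c(44, 44, 20)`.
#' @param spacing_mm Voxel size in mm, default `c(1.95, 1.95, 3.27)` (the PET
#'   reconstruction grid; all modalities share it — use
#'   [resample_to_reference()] for multi-grid workflows).
#' @param brain_semiaxes_mm Brain ellipsoid semi-axes, mm.
#' @param tumor_center_offset_mm Tumor center offset from the brain center
#'   along the left-right axis (positive = right hemisphere), mm.
#' @param core_radius_mm,rim_radius_mm,margin_radius_mm Nested tumor radii,
#'   mm (core < rim < margin).
#' @param nawm_radius_mm Radius of the normal-appearing white-matter sphere,
#'   placed at the mirror image of the tumor center.
#' @param flt,fmiso Per-modality statistics: named list with `bg`, `core`,
#'   `rim`, `margin`, each `c(mean, sd)` in SUV g/mL.
#' @param cbv_scale Per-compartment multipliers of the background bolus
#'   amplitude: named vector with `core`, `rim`, `margin` (background = 1).
#' @param dsc List of DSC parameters: `tr_s`, `te_ms`, `n_frames`,
#'   `injection_delay_s`, `s0`, `noise_sd` (signal units), and the background
#'   bolus gamma-variate parameters `K`, `t0`, `alpha`, `beta`.
#' @param psf_fwhm_mm Isotropic Gaussian PSF FWHM applied to the PET mean
#'   images before noise (0 = off), emulating PET resolution.
#' @param truth_volumes Named list giving, per modality label, the compartment
#'   names whose union is that modality's true elevated-signal volume.
#' @param seed Integer seed; the case is fully deterministic given it.
#' @return A `PhantomConfig` list.
#' @export
phantom_config <- function(
    grid_dims = c(44L, 44L, 20L),
    spacing_mm = c(1.95, 1.95, 3.27),
    brain_semiaxes_mm = c(38, 38, 28),
    tumor_center_offset_mm = 18,
    core_radius_mm = 6,
    rim_radius_mm = 11,
    margin_radius_mm = 14,
    nawm_radius_mm = 8,
    flt = list(bg = c(0.4, 0.08), core = c(0.3, 0.05),
               rim = c(2.5, 0.30), margin = c(1.5, 0.25)),
    fmiso = list(bg = c(1.0, 0.15), core = c(0.8, 0.10),
                 rim = c(2.2, 0.20), margin = c(1.45, 0.20)),
    cbv_scale = c(core = 0.3, rim = 3.0, margin = 1.0),
    dsc = list(tr_s = 2.28, te_ms = 60, n_frames = 35L,
               injection_delay_s = 20, s0 = 600, noise_sd = 6,
               K = 0.00176, t0 = 24, alpha = 3, beta = 1.5),
    psf_fwhm_mm = 5,
    truth_volumes = list(FLT = c("rim", "margin"),
                         FMISO = c("rim", "margin"),
                         rCBV = "rim"),
    seed = 1L) {
  cfg <- list(grid_dims = as.integer(grid_dims), spacing_mm = spacing_mm,
              brain_semiaxes_mm = brain_semiaxes_mm,
              tumor_center_offset_mm = tumor_center_offset_mm,
              core_radius_mm = core_radius_mm, rim_radius_mm = rim_radius_mm,
              margin_radius_mm = margin_radius_mm,
              nawm_radius_mm = nawm_radius_mm,
              flt = flt, fmiso = fmiso, cbv_scale = cbv_scale, dsc = dsc,
              psf_fwhm_mm = psf_fwhm_mm, truth_volumes = truth_volumes,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  class(cfg) <- "PhantomConfig"
  cfg
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$grid_dims) != 3L || any(cfg$grid_dims < 1L))
    stop("grid_dims must be 3 positive integers")
  if (any(cfg$spacing_mm <= 0)) stop("spacing must be positive")
  r <- c(cfg$core_radius_mm, cfg$rim_radius_mm, cfg$margin_radius_mm)
  if (any(r <= 0)) stop("tumor radii must be > 0")
  if (!(r[1] < r[2] && r[2] < r[3]))
    stop("compartments must be nested: core < rim < margin radius")
  for (mod in c("flt", "fmiso"))
    for (cp in names(cfg[[mod]]))
      if (cfg[[mod]][[cp]][2] < 0) stop("noise SD must be >= 0 (", mod, ")")
  if (cfg$dsc$n_frames < 2L) stop("n_frames must be >= 2")
  if (cfg$dsc$noise_sd < 0) stop("DSC noise SD must be >= 0")
  if (cfg$dsc$s0 <= 0) stop("S0 must be > 0")
  if (cfg$dsc$injection_delay_s < cfg$dsc$tr_s)
    stop("injection_delay_s must cover at least one frame")
  fov <- cfg$grid_dims * cfg$spacing_mm
  ctr <- fov / 2 + c(cfg$tumor_center_offset_mm, 0, 0)
  if (any(ctr - cfg$margin_radius_mm < 0) ||
      any(ctr + cfg$margin_radius_mm > fov))
    stop("tumor compartments exceed the grid")
  invisible(cfg)
}

# center-of-voxel coordinates (mm) along each axis
voxel_centers <- function(dims, spacing) {
  lapply(1:3, function(ax) (seq_len(dims[ax]) - 0.5) * spacing[ax])
}

ellipsoid_mask <- function(dims, spacing, center, semiaxes) {
  cc <- voxel_centers(dims, spacing)
  dx2 <- ((cc[[1]] - center[1]) / semiaxes[1])^2
  dy2 <- ((cc[[2]] - center[2]) / semiaxes[2])^2
  dz2 <- ((cc[[3]] - center[3]) / semiaxes[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

sphere_mask <- function(dims, spacing, center, radius) {
  ellipsoid_mask(dims, spacing, center, rep(radius, 3))
}

# separable Gaussian smoothing, kernel truncated at 3 sigma,
# renormalized at the edges so constants are preserved
smooth_gaussian <- function(arr, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing
  d <- dim(arr)
  norm <- array(1, d)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s < 1e-6) next
    r <- max(1L, ceiling(3 * s))
    kern <- stats::dnorm(-r:r, sd = s)
    kern <- kern / sum(kern)
    arr <- conv_axis(arr, kern, ax)
    norm <- conv_axis(norm, kern, ax)
  }
  arr / norm
}

# 1D convolution along one axis with zero padding, via shifted sums
conv_axis <- function(a, kern, ax) {
  d <- dim(a)
  r <- (length(kern) - 1L) %/% 2L
  out <- array(0, d)
  n <- d[ax]
  for (o in -r:r) {
    w <- kern[o + r + 1L]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    di <- list(TRUE, TRUE, TRUE); si <- list(TRUE, TRUE, TRUE)
    di[[ax]] <- which(ok); si[[ax]] <- src[ok]
    dst_part <- do.call(`[`, c(list(out), di, list(drop = FALSE)))
    src_part <- do.call(`[`, c(list(a), si, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), di, list(dst_part + w * src_part)))
  }
  out
}

#' Generate a complete digital glioblastoma case
#'
#' Builds the compartment masks, simulates FLT and FMISO SUV maps
#' (compartment mean, optional PSF smoothing, then Gaussian noise) and the
#' DSC series via the forward signal model, and records full ground truth:
#' pre-noise compartment means, the generating delta-R2* curves, true
#' volumes in mL, and true peripheral-volume percentages against CE.
#'
#' @param config A [phantom_config()].
#' @return A `PhantomCase`: list with `flt`, `fmiso` (`VolumeImage`s), `dsc`
#'   (`DynamicSeries`), `masks` (ce, flair, brain, hemispheres, nawm,
#'   compartments), `truth`, and the `config`.
#' @export
make_phantom <- function(config) {
  validate_phantom_config(config)
  d <- config$grid_dims
  sp <- config$spacing_mm
  fov <- d * sp
  brain_ctr <- fov / 2
  tumor_ctr <- brain_ctr + c(config$tumor_center_offset_mm, 0, 0)

  brain <- ellipsoid_mask(d, sp, brain_ctr, config$brain_semiaxes_mm)
  cc <- voxel_centers(d, sp)
  right <- outer(outer(cc[[1]] > brain_ctr[1], rep(TRUE, d[2]), `&`),
                 rep(TRUE, d[3]), `&`)
  s_core <- sphere_mask(d, sp, tumor_ctr, config$core_radius_mm) & brain
  s_rim <- sphere_mask(d, sp, tumor_ctr, config$rim_radius_mm) & brain
  s_margin <- sphere_mask(d, sp, tumor_ctr, config$margin_radius_mm) & brain
  core <- s_core
  rim <- s_rim & !s_core
  margin <- s_margin & !s_rim
  nawm_ctr <- tumor_ctr; nawm_ctr[1] <- fov[1] - tumor_ctr[1]
  nawm <- sphere_mask(d, sp, nawm_ctr, config$nawm_radius_mm) & brain

  mk <- function(v) binary_mask(v, spacing = sp, orientation = "RAS")
  masks <- list(
    ce = mk(rim), flair = mk(rim | margin), brain = mk(brain),
    right_hemisphere = mk(brain & right),
    left_hemisphere = mk(brain & !right),
    nawm = mk(nawm), core = mk(core), rim = mk(rim), margin = mk(margin))

  compartment_map <- function(stats_list) {
    m <- array(0, d)
    m[brain] <- stats_list$bg[1]
    m[margin] <- stats_list$margin[1]
    m[rim] <- stats_list$rim[1]
    m[core] <- stats_list$core[1]
    m
  }
  noisy_suv <- function(stats_list, units, sub_seed) {
    mean_img <- compartment_map(stats_list)
    if (config$psf_fwhm_mm > 0)
      mean_img <- smooth_gaussian(mean_img, config$psf_fwhm_mm, sp)
    sd_img <- array(0, d)
    sd_img[brain] <- stats_list$bg[2]
    sd_img[margin] <- stats_list$margin[2]
    sd_img[rim] <- stats_list$rim[2]
    sd_img[core] <- stats_list$core[2]
    set.seed(sub_seed)
    v <- mean_img + stats::rnorm(prod(d)) * sd_img
    volume_image(array(v, d), spacing = sp, orientation = "RAS",
                 units = units)
  }
  # deterministic per-modality substreams
  flt_img <- noisy_suv(config$flt, "SUV g/mL", config$seed * 7L + 1L)
  fmiso_img <- noisy_suv(config$fmiso, "SUV g/mL", config$seed * 7L + 2L)

  dsc <- make_dsc_series(config, masks)

  time_s <- (seq_len(config$dsc$n_frames) - 1) * config$dsc$tr_s
  bg_curve <- gamma_variate(time_s, config$dsc$K, config$dsc$t0,
                            config$dsc$alpha, config$dsc$beta)
  truth_curves <- list(
    bg = bg_curve,
    core = config$cbv_scale[["core"]] * bg_curve,
    rim = config$cbv_scale[["rim"]] * bg_curve,
    margin = config$cbv_scale[["margin"]] * bg_curve)

  truth_masks <- lapply(config$truth_volumes, function(comps) {
    v <- Reduce(`|`, lapply(comps, function(cp) masks[[cp]]$voxels))
    mk(v)
  })
  truth <- list(
    means = list(flt = lapply(config$flt, `[`, 1),
                 fmiso = lapply(config$fmiso, `[`, 1),
                 cbv_scale = c(bg = 1, config$cbv_scale)),
    dsc_curves = truth_curves,
    time_s = time_s,
    volumes_ml = vapply(masks, volume_ml, numeric(1)),
    modality_masks = truth_masks,
    peripheral_pct = vapply(truth_masks, peripheral_volume_pct,
                            numeric(1), ce = masks$ce))

  structure(list(flt = flt_img, fmiso = fmiso_img, dsc = dsc,
                 masks = masks, truth = truth, config = config),
            class = "PhantomCase")
}

#' Simulate the DSC acquisition of a phantom case
#'
#' Forward signal model: per voxel,
#' \deqn{S(t) = S_0 \exp(-TE \cdot \Delta R_2^*(t))}
#' with delta-R2*(t) given by the compartment's gamma-variate bolus curve
#' (background amplitude scaled per compartment) and zero before bolus
#' arrival, plus Gaussian signal noise. Frames before the injection delay
#' therefore equal S0 (plus noise).
#'
#' @param config A [phantom_config()].
#' @param masks Mask list as produced by [make_phantom()] (needs `brain`,
#'   `core`, `rim`, `margin`).
#' @return A [dynamic_series()].
#' @export
make_dsc_series <- function(config, masks) {
  p <- config$dsc
  if (p$s0 <= 0) stop("S0 must be > 0")
  d <- config$grid_dims
  nt <- p$n_frames
  time_s <- (seq_len(nt) - 1) * p$tr_s
  bg_curve <- gamma_variate(time_s, p$K, p$t0, p$alpha, p$beta)

  scale <- array(0, d)
  scale[masks$brain$voxels] <- 1
  scale[masks$margin$voxels] <- config$cbv_scale[["margin"]]
  scale[masks$rim$voxels] <- config$cbv_scale[["rim"]]
  scale[masks$core$voxels] <- config$cbv_scale[["core"]]

  frames <- array(0, c(d, nt))
  for (k in seq_len(nt))
    frames[, , , k] <- p$s0 * exp(-p$te_ms * scale * bg_curve[k])
  if (p$noise_sd > 0) {
    set.seed(config$seed * 7L + 3L)
    frames <- frames + stats::rnorm(length(frames)) * p$noise_sd
  }
  dynamic_series(frames, tr_s = p$tr_s, te_ms = p$te_ms,
                 injection_delay_s = p$injection_delay_s,
                 spacing = config$spacing_mm, orientation = "RAS")
}

#' @export
print.PhantomCase <- function(x, ...) {
  cat(sprintf(
    "<PhantomCase %s grid, CE %.2f mL, FLAIR %.2f mL, seed %d>\n",
    paste(x$config$grid_dims, collapse = "x"),
    x$truth$volumes_ml[["ce"]], x$truth$volumes_ml[["flair"]],
    x$config$seed))
  invisible(x)
}
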