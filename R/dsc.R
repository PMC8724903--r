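#' Convert a DSC signal series to delta-R2* concentration curves
#'
#' Per voxel, the pre-bolus baseline signal S0 is the mean over the baseline
#' frames, and
#' \deqn{\Delta R_2^*(t) = -\ln(S(t)/S_0) / TE}
#' in 1/ms (TE in ms). Baseline frames are all frames acquired before the
#' injection delay, discarding the first frame (steady-state transient) when
#' more than three are available. Voxels outside the brain mask, or with
#' non-positive S0 or signal, are flagged invalid and their curves zeroed.
#'
#' @param series A [dynamic_series()].
#' @param brain Optional `BinaryMask` restricting the conversion.
#' @return A `ConcentrationSeries`: list with `curves` (4D array, 1/ms),
#'   `time_s`, `baseline_frames`, `valid` (3D logical), plus geometry.
#' @export
signal_to_deltaR2star <- function(series, brain = NULL) {
  d <- dim(series$frames)
  time_s <- (seq_len(d[4]) - 1) * series$tr_s
  pre <- which(time_s < series$injection_delay_s)
  if (length(pre) == 0L) stop("no baseline frames available before injection")
  if (length(pre) > 3L) pre <- pre[-1]  # drop steady-state transient

  nvox <- prod(d[1:3])
  sig <- matrix(series$frames, nrow = nvox, ncol = d[4])
  s0 <- rowMeans(sig[, pre, drop = FALSE])

  valid <- s0 > 0 & apply(sig > 0, 1, all)
  if (!is.null(brain)) {
    stopifnot_same_geometry(series, brain)
    valid <- valid & as.vector(brain$voxels)
  }

  curves <- matrix(0, nrow = nvox, ncol = d[4])
  if (any(valid))
    curves[valid, ] <- -log(sig[valid, , drop = FALSE] / s0[valid]) /
      series$te_ms

  structure(
    list(curves = array(curves, dim = d), time_s = time_s,
         baseline_frames = pre, valid = array(valid, dim = d[1:3]),
         spacing = series$spacing, orientation = series$orientation),
    class = "ConcentrationSeries")
}

#' Compute a CBV map by gamma-variate integration
#'
#' Each valid voxel's concentration curve is fitted with a first-pass
#' gamma-variate model and CBV is taken as the area under the fitted curve —
#' by default the closed form \eqn{K \beta^{\alpha+1} \Gamma(\alpha+1)},
#' optionally numerical integration of the fitted curve (the two agree to
#' machine-level tolerance). Voxels whose curve never exceeds `noise_floor`
#' are skipped (CBV 0); failed fits are set to 0 and counted, never NaN.
#' Identical curves are fitted once, so noise-free phantom data with few
#' distinct tissue classes is processed quickly.
#'
#' @param conc A `ConcentrationSeries` from [signal_to_deltaR2star()].
#' @param noise_floor Peak threshold below which a voxel is not fitted
#'   (same units as the curves, 1/ms).
#' @param integration `"closed_form"` or `"quadrature"`.
#' @return A `VolumeImage` of CBV values (1/ms * s) with a `qc` attribute:
#'   list(n_fitted, n_failed, n_skipped, median_rmse).
#' @export
compute_cbv <- function(conc, noise_floor = 1e-4,
                        integration = c("closed_form", "quadrature")) {
  integration <- match.arg(integration)
  d <- dim(conc$curves)
  nvox <- prod(d[1:3])
  cm <- matrix(conc$curves, nrow = nvox, ncol = d[4])
  valid <- as.vector(conc$valid)

  peak <- apply(cm, 1, max)
  to_fit <- which(valid & peak > noise_floor)
  cbv <- numeric(nvox)
  n_failed <- 0L
  rmses <- numeric(0)

  if (length(to_fit)) {
    sub <- cm[to_fit, , drop = FALSE]
    key <- do.call(paste, c(as.data.frame(sub), sep = ","))
    uidx <- which(!duplicated(key))
    ufit <- vector("list", length(uidx))
    for (i in seq_along(uidx))
      ufit[[i]] <- fit_gamma_variate(sub[uidx[i], ], conc$time_s,
                                     noise_floor = noise_floor)
    map <- match(key, key[uidx])
    auc_of <- function(f) {
      if (!f$converged) return(NA_real_)
      if (integration == "closed_form") f$auc
      else stats::integrate(gamma_variate, lower = f$t0, upper = Inf,
                            K = f$K, t0 = f$t0, alpha = f$alpha,
                            beta = f$beta, rel.tol = 1e-10)$value
    }
    uauc <- vapply(ufit, auc_of, numeric(1))
    urmse <- vapply(ufit, function(f) f$rmse, numeric(1))
    vox_auc <- uauc[map]
    n_failed <- sum(is.na(vox_auc))
    vox_auc[is.na(vox_auc)] <- 0
    cbv[to_fit] <- vox_auc
    rmses <- urmse[map]
  }

  out <- volume_image(array(cbv, dim = d[1:3]), spacing = conc$spacing,
                      orientation = conc$orientation, units = "CBV a.u.")
  attr(out, "qc") <- list(
    n_fitted = length(to_fit) - n_failed, n_failed = n_failed,
    n_skipped = nvox - length(to_fit),
    median_rmse = if (length(rmses)) stats::median(rmses, na.rm = TRUE)
                  else NA_real_)
  out
}

#' Normalize a CBV map to rCBV by the contralateral mean
#'
#' rCBV = CBV / mean(CBV over the normal-appearing contralateral mask), so
#' the mean of the output over that mask is 1 by construction.
#'
#' @param cbv CBV `VolumeImage`.
#' @param contralateral Non-empty `BinaryMask` of normal-appearing
#'   contralateral tissue; its CBV mean must be positive.
#' @return rCBV `VolumeImage` (units `"rCBV ratio"`).
#' @export
normalize_rcbv <- function(cbv, contralateral) {
  stopifnot_same_geometry(cbv, contralateral)
  n <- sum(contralateral$voxels)
  if (n == 0L) stop("contralateral mask is empty")
  m <- mean(cbv$voxels[contralateral$voxels])
  if (!is.finite(m) || m <= 0)
    stop("contralateral CBV mean must be positive, got ", format(m))
  volume_image(cbv$voxels / m, spacing = cbv$spacing,
               orientation = cbv$orientation, units = "rCBV ratio")
}

#' Default contralateral reference mask for rCBV normalization
#'
#' The mirrored tumor-free hemisphere: brain AND mirrored hemisphere AND NOT
#' mirrored FLAIR hypersignal — a mirror-image stand-in for the
#' normal-appearing contralateral side.
#'
#' @param brain Brain `BinaryMask`.
#' @param tumor_hemisphere `BinaryMask` of the hemisphere containing the tumor.
#' @param flair FLAIR-hypersignal `BinaryMask`.
#' @return `BinaryMask` of normal-appearing contralateral tissue.
#' @export
contralateral_reference <- function(brain, tumor_hemisphere, flair) {
  m <- mask_ops(brain, mirror_mask(tumor_hemisphere), "AND")
  mask_ops(m, mirror_mask(flair), "NOT")
}
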