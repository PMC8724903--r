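#' Fuzzy locally adaptive Bayesian class segmentation
#'
#' Semi-automated PET delineation by an iterative Bayesian estimation of 2 or
#' 3 Gaussian intensity classes within an operator ROI. Voxels carry fuzzy
#' class memberships (posterior probabilities), and the class prior of each
#' voxel adapts to its local 6-neighbourhood membership statistics, which
#' regularizes the delineation spatially. The tumor mask is the
#' highest-mean class after hard assignment. The estimation is fully
#' deterministic: initialization is by intensity quantiles, no random draws.
#'
#' @param map `VolumeImage` (e.g. an FLT SUV map).
#' @param n_classes 2 or 3 intensity classes.
#' @param roi `BinaryMask` search region (e.g. the dilated FLAIR bounding
#'   box, see [bbox_roi()]); needs at least `10 * n_classes` voxels and a
#'   non-constant intensity distribution.
#' @param spatial_weight Weight in \[0, 1) of the local-neighbourhood prior
#'   against the global class proportions.
#' @param max_iter,tol Iteration cap and convergence tolerance on the class
#'   means (relative to the ROI intensity range).
#' @return A `SegmentationResult` with method `"flab"`; `params` records the
#'   class means/SDs/proportions, iterations and a `converged` flag.
#' @export
flab_seg <- function(map, n_classes = 2, roi, spatial_weight = 0.3,
                     max_iter = 100L, tol = 1e-6) {
  if (!n_classes %in% c(2L, 3L)) stop("n_classes must be 2 or 3")
  stopifnot_same_geometry(map, roi)
  idx <- which(roi$voxels & is.finite(map$voxels))
  y <- map$voxels[idx]
  if (length(y) < 10L * n_classes)
    stop("ROI too small: need at least ", 10L * n_classes, " voxels")
  rng <- diff(range(y))
  if (rng <= .Machine$double.eps * max(abs(y), 1))
    stop("degenerate ROI: constant intensities, no class structure to estimate")

  k <- n_classes
  # initialization: centers equally spaced in intensity (robust to the tumor
  # being a small mass fraction), refined by deterministic Lloyd k-means
  ctr <- min(y) + rng * (2 * seq_len(k) - 1) / (2 * k)
  km <- tryCatch(
    stats::kmeans(y, centers = matrix(ctr), iter.max = 50,
                  algorithm = "Lloyd"),
    warning = function(w) suppressWarnings(
      stats::kmeans(y, centers = matrix(ctr), iter.max = 200,
                    algorithm = "Lloyd")),
    error = function(e) NULL)
  if (!is.null(km) && length(unique(km$cluster)) == k) {
    ord <- order(km$centers)
    mu <- as.vector(km$centers)[ord]
    sigma <- vapply(ord, function(c) {
      v <- stats::sd(y[km$cluster == c])
      if (!is.finite(v) || v <= 0) stats::sd(y) / (4 * k) else v
    }, numeric(1))
    prop <- as.vector(table(factor(km$cluster, levels = ord))) / length(y)
  } else {
    mu <- ctr
    sigma <- rep(stats::sd(y) / k, k)
    prop <- rep(1 / k, k)
  }
  sig_floor <- 1e-8 * rng

  dims <- dim(map$voxels)
  in_roi <- array(FALSE, dims); in_roi[idx] <- TRUE
  n_nb <- neighbor_sum(array(as.numeric(in_roi), dims))[idx]
  n_nb[n_nb == 0] <- 1

  u <- matrix(1 / k, nrow = length(y), ncol = k)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # locally adaptive prior: blend global proportions with the
    # neighbourhood average membership of each class
    prior <- matrix(rep(prop, each = length(y)), ncol = k)
    if (spatial_weight > 0) {
      for (c in seq_len(k)) {
        uc <- array(0, dims); uc[idx] <- u[, c]
        prior[, c] <- (1 - spatial_weight) * prop[c] +
          spatial_weight * neighbor_sum(uc)[idx] / n_nb
      }
    }
    lik <- vapply(seq_len(k),
                  function(c) stats::dnorm(y, mu[c], max(sigma[c], sig_floor)),
                  numeric(length(y)))
    u_new <- prior * lik
    tot <- rowSums(u_new)
    tot[tot <= 0] <- 1
    u_new <- u_new / tot

    w <- colSums(u_new)
    mu_new <- colSums(u_new * y) / w
    sigma_new <- sqrt(colSums(u_new * (y - rep(mu_new, each = length(y)))^2) / w)
    prop_new <- w / length(y)

    delta <- max(abs(mu_new - mu)) / rng
    u <- u_new; mu <- mu_new; sigma <- sigma_new; prop <- prop_new
    if (delta < tol) { converged <- TRUE; break }
  }

  tumor_class <- which.max(mu)
  hard <- max.col(u, ties.method = "first")
  sel <- array(FALSE, dims)
  sel[idx[hard == tumor_class]] <- TRUE
  mask <- binary_mask(sel, spacing = map$spacing,
                      orientation = map$orientation)
  new_segmentation_result(
    mask, "flab", NULL,
    list(n_classes = k, class_means = mu, class_sds = sigma,
         class_props = prop, tumor_class = tumor_class,
         spatial_weight = spatial_weight, iterations = iter,
         converged = converged))
}

#' Default FLAB operator ROI: dilated bounding box of a mask
#'
#' The bounding box of the FLAIR hypersignal, dilated by a margin of voxels
#' and clipped to the grid — a generous search region containing tumor and
#' surrounding background, as an operator would draw.
#'
#' @param mask Non-empty `BinaryMask`.
#' @param margin Dilation margin in voxels (default 2).
#' @return A `BinaryMask` of the dilated bounding box.
#' @export
bbox_roi <- function(mask, margin = 2L) {
  if (!any(mask$voxels)) stop("mask is empty")
  dims <- dim(mask$voxels)
  w <- which(mask$voxels, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - margin, 1L)
  hi <- pmin(apply(w, 2, max) + margin, dims)
  v <- array(FALSE, dims)
  v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  binary_mask(v, spacing = mask$spacing, orientation = mask$orientation)
}

# sum over the 6-neighbourhood (face-adjacent voxels), zero padding
neighbor_sum <- function(a) {
  d <- dim(a)
  out <- array(0, d)
  out[-1, , ] <- out[-1, , ] + a[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] + a[-1, , ]
  out[, -1, ] <- out[, -1, ] + a[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] + a[, -1, ]
  out[, , -1] <- out[, , -1] + a[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] + a[, , -1]
  out
}
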