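test_that("contralateral statistics are the masked sample mean and SD", {
  const <- volume_image(array(5, c(4, 4, 4)), spacing = c(1, 1, 1))
  allm <- mk_mask(array(TRUE, c(4, 4, 4)), spacing = c(1, 1, 1))
  s <- contralateral_stats(const, allm)
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)

  v <- array(0, c(3, 1, 1)); v[] <- c(1, 2, 3)
  s2 <- contralateral_stats(volume_image(v, spacing = c(1, 1, 1)),
                            mk_mask(array(TRUE, c(3, 1, 1))))
  expect_equal(s2$mean, 2)
  expect_equal(s2$sd, 1)

  # Monte-Carlo: large Gaussian sample recovers (mu, sigma) within 3 SEs
  set.seed(71)
  n <- 40^3
  g <- volume_image(array(rnorm(n, 1.5, 0.2), c(40, 40, 40)),
                    spacing = c(1, 1, 1))
  s3 <- contralateral_stats(g, mk_mask(array(TRUE, c(40, 40, 40))))
  expect_lt(abs(s3$mean - 1.5), 3 * 0.2 / sqrt(n))
  expect_lt(abs(s3$sd - 0.2), 3 * 0.2 / sqrt(2 * n))

  expect_error(contralateral_stats(const, mk_mask(array(FALSE, c(4, 4, 4)))),
               "2 finite")
})

test_that("statistical thresholding selects the Gaussian upper tail", {
  dims <- c(60, 60, 60)
  set.seed(72)
  g <- volume_image(array(rnorm(prod(dims), 1.0, 0.15), dims),
                    spacing = c(1, 1, 1))
  allm <- mk_mask(array(TRUE, dims))
  st <- contralateral_stats(g, allm)
  n <- prod(dims)
  for (k in c(1.96, 3.3)) {
    res <- stat_threshold_seg(g, st, k)
    frac <- sum(res$mask$voxels) / n
    p <- 1 - pnorm(k)
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
    expect_equal(res$threshold_value, st$mean + k * st$sd)
    # self-describing: mask reproducible from the recorded threshold
    expect_identical(res$mask$voxels, g$voxels > res$threshold_value)
  }

  flat <- volume_image(array(st$mean, dims), spacing = c(1, 1, 1))
  expect_equal(sum(stat_threshold_seg(flat, st, 1.96)$mask$voxels), 0L)
})

test_that("percent-of-max segmentation thresholds at f * max over the search", {
  v <- array(0, c(10, 10, 1))
  v[1:100] <- 1:100
  map <- volume_image(v, spacing = c(1, 1, 1))
  srch <- mk_mask(array(TRUE, c(10, 10, 1)))
  res <- percent_max_seg(map, 0.4, srch)
  expect_equal(res$threshold_value, 40)
  expect_equal(sum(res$mask$voxels), 61L)  # values 40..100 inclusive

  const <- volume_image(array(2.5, c(4, 4, 2)), spacing = c(1, 1, 1))
  call <- mk_mask(array(TRUE, c(4, 4, 2)))
  expect_equal(sum(percent_max_seg(const, 0.4, call)$mask$voxels), 32L)
  expect_error(percent_max_seg(map, 0.4, mk_mask(array(FALSE, c(10, 10, 1)))),
               "empty")
})

test_that("ratio segmentation thresholds at factor * reference", {
  v <- array(0, c(2, 1, 1)); v[] <- c(2.3, 2.5)
  map <- volume_image(v, spacing = c(1, 1, 1))
  res <- ratio_seg(map, reference_value = 2.0, factor = 1.2)
  expect_equal(res$threshold_value, 2.4)
  expect_identical(as.vector(res$mask$voxels), c(FALSE, TRUE))

  # agrees with statistical thresholding given an equivalent absolute cutoff
  set.seed(73)
  for (i in 1:50) {
    dims <- c(8, 8, 4)
    m <- volume_image(array(runif(prod(dims), 0, 4), dims),
                      spacing = c(1, 1, 1))
    ref <- runif(1, 0.5, 2); fac <- runif(1, 1, 2)
    fake <- structure(list(mean = ref * fac, sd = 1, n_voxels = 2,
                           source = "abs"), class = "ContralateralStats")
    expect_identical(ratio_seg(m, ref, fac)$mask$voxels,
                     stat_threshold_seg(m, fake, k = 1e-12)$mask$voxels)
  }
  expect_error(ratio_seg(map, 0, 1.2), "reference")
})

test_that("NAWM-ratio segmentation separates an elevated-rCBV tumor", {
  dims <- c(10, 10, 4)
  v <- array(1, dims)
  tum <- array(FALSE, dims); tum[4:6, 4:6, 2:3] <- TRUE
  v[tum] <- 3
  map <- volume_image(v, spacing = c(1, 1, 1))
  res <- ratio_seg(map, reference_value = 1.0, factor = 2)
  expect_identical(res$mask$voxels, tum)
})

test_that("hot-spot segmentation takes the top of the FLAIR histogram", {
  dims <- c(10, 10, 10)
  set.seed(70)
  perm <- sample(1000)  # distinct values
  map <- volume_image(array(perm, dims), spacing = c(1, 1, 1))
  flair <- mk_mask(array(TRUE, dims))
  res <- hotspot_seg(map, flair, 95)
  expect_equal(sum(res$mask$voxels), 50L)  # exactly the top 5%
  expect_true(all(map$voxels[res$mask$voxels] > 950))

  # linear-interpolation percentile: values 1..100 -> threshold 95.05
  v100 <- volume_image(array(1:100, c(10, 10, 1)), spacing = c(1, 1, 1))
  f100 <- mk_mask(array(TRUE, c(10, 10, 1)))
  r100 <- hotspot_seg(v100, f100, 95)
  expect_equal(r100$threshold_value, 95.05)
  expect_equal(sum(r100$mask$voxels), 5L)  # 96..100

  # constant ROI: >= rule selects the full FLAIR region
  const <- volume_image(array(2, dims), spacing = c(1, 1, 1))
  expect_equal(sum(hotspot_seg(const, flair)$mask$voxels), sum(flair$voxels))

  # always a subset of FLAIR
  set.seed(74)
  for (i in 1:20) {
    m <- volume_image(array(rnorm(prod(dims)), dims), spacing = c(1, 1, 1))
    fl <- rand_mask(dims, p = runif(1, 0.2, 0.8))
    hs <- hotspot_seg(m, fl, 95)
    expect_equal(sum(hs$mask$voxels & !fl$voxels), 0L)
  }
  expect_error(hotspot_seg(const, mk_mask(array(FALSE, dims))), "empty")
})

test_that("raising any cutoff parameter never grows the mask", {
  set.seed(75)
  dims <- c(12, 12, 6)
  map <- volume_image(array(rnorm(prod(dims), 1, 0.3), dims),
                      spacing = c(1, 1, 1))
  allm <- mk_mask(array(TRUE, dims))
  st <- contralateral_stats(map, allm)
  subset_of <- function(a, b) sum(a$mask$voxels & !b$mask$voxels) == 0L
  for (i in 1:10) {
    k1 <- runif(1, 0.5, 2); k2 <- k1 + runif(1, 0.1, 2)
    expect_true(subset_of(stat_threshold_seg(map, st, k2),
                          stat_threshold_seg(map, st, k1)))
    f1 <- runif(1, 0.2, 0.6); f2 <- f1 + runif(1, 0.05, 0.3)
    expect_true(subset_of(percent_max_seg(map, f2, allm),
                          percent_max_seg(map, f1, allm)))
    p1 <- runif(1, 50, 90); p2 <- p1 + runif(1, 1, 9)
    expect_true(subset_of(hotspot_seg(map, allm, p2),
                          hotspot_seg(map, allm, p1)))
  }
})

test_that("SUV maps implement activity over injected dose per body weight", {
  act <- volume_image(array(5, c(2, 2, 2)), spacing = c(1, 1, 1))
  # 5 MBq/kg dosing: 350,000 kBq into 70,000 g -> SUV 1.0
  s <- suv_map(act, injected_activity_kbq = 350000, body_weight_g = 70000)
  expect_true(all(s$voxels == 1))
  expect_identical(s$units, "SUV g/mL")
  zero <- volume_image(array(0, c(2, 2, 2)), spacing = c(1, 1, 1))
  expect_true(all(suv_map(zero, 350000, 70000)$voxels == 0))
  s2 <- suv_map(act, 350000, 140000)
  expect_equal(s2$voxels, 2 * s$voxels)
  expect_error(suv_map(act, 0, 70000), "injected")
})

test_that("non-finite voxels are excluded from statistics and never selected", {
  dims <- c(4, 4, 2)
  v <- array(1, dims); v[1, 1, 1] <- NaN; v[2, 2, 2] <- 10
  map <- volume_image(v, spacing = c(1, 1, 1))
  allm <- mk_mask(array(TRUE, dims))
  st <- contralateral_stats(map, allm)
  expect_equal(st$n_voxels, prod(dims) - 1L)
  res <- stat_threshold_seg(map, st, 1.0)
  expect_false(res$mask$voxels[1, 1, 1])
  hs <- hotspot_seg(map, allm, 95)
  expect_false(hs$mask$voxels[1, 1, 1])
})
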