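test_that("mask volumes are spacing-weighted voxel counts in mL", {
  expect_equal(volume_ml(mk_mask(array(FALSE, c(4, 4, 4)))), 0)
  expect_equal(volume_ml(mk_mask(array(TRUE, c(10, 10, 10)))), 1)
  v <- array(FALSE, c(10, 10, 10)); v[1:100] <- TRUE
  expect_equal(volume_ml(mk_mask(v, spacing = c(2.19, 2.19, 7))),
               3.35727, tolerance = 1e-9)
})

test_that("peripheral percentages implement |A \\ CE| / |CE| * 100", {
  dims <- c(10, 10, 4)
  ce <- array(FALSE, dims); ce[3:7, 3:6, 2] <- TRUE  # 20 voxels
  stopifnot(sum(ce) == 20)
  expect_equal(peripheral_volume_pct(mk_mask(ce), mk_mask(ce)), 0)

  disj <- array(FALSE, dims); disj[3:7, 3:6, 4] <- TRUE
  expect_equal(peripheral_volume_pct(mk_mask(disj), mk_mask(ce)), 100)

  # |mod| = 31, |ce| = 20, overlap 15 -> 80%
  mod <- array(FALSE, dims)
  mod[3:7, 3:5, 2] <- TRUE            # 15 in ce
  mod[1:8, 1:2, 1] <- TRUE            # 16 outside
  stopifnot(sum(mod) == 31, sum(mod & ce) == 15)
  expect_equal(peripheral_volume_pct(mk_mask(mod), mk_mask(ce)), 80)

  # hot spot entirely inside CE -> 0; disjoint tenth-size -> 10%
  hs_in <- array(FALSE, dims); hs_in[3:4, 3, 2] <- TRUE
  expect_equal(peripheral_hotspot_pct(mk_mask(hs_in), mk_mask(ce)), 0)
  hs_out <- array(FALSE, dims); hs_out[1:2, 9, 4] <- TRUE
  expect_equal(peripheral_hotspot_pct(mk_mask(hs_out), mk_mask(ce)), 10)

  expect_error(peripheral_volume_pct(mk_mask(mod),
                                     mk_mask(array(FALSE, dims))),
               "empty")
})

test_that("percentages agree exactly with brute-force voxel enumeration", {
  set.seed(81)
  dims <- c(7, 6, 5)
  for (i in 1:100) {
    m <- rand_mask(dims, p = runif(1, 0.1, 0.9))
    ce <- rand_mask(dims, p = runif(1, 0.2, 0.9))
    if (sum(ce$voxels) == 0) next
    brute <- 0
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3])
      if (m$voxels[x, y, z] && !ce$voxels[x, y, z]) brute <- brute + 1
    expect_identical(peripheral_volume_pct(m, ce),
                     100 * brute / sum(ce$voxels))
  }
})

test_that("peripheral percentage can exceed 100% when CE is the denominator", {
  dims <- c(12, 6, 4)
  ce <- array(FALSE, dims); ce[1:2, 1:5, 1] <- TRUE        # 10 voxels
  big <- array(FALSE, dims); big[4:12, 1:4, 2:3] <- TRUE   # 72, disjoint
  pct <- peripheral_volume_pct(mk_mask(big), mk_mask(ce))
  expect_equal(pct, 720)
  expect_gt(pct, 100)
})

test_that("zero peripheral volume is equivalent to mask inclusion", {
  set.seed(82)
  for (i in 1:30) {
    ce <- rand_mask(c(6, 6, 4), p = 0.5)
    if (sum(ce$voxels) == 0) next
    m <- rand_mask(c(6, 6, 4), p = 0.4)
    inside <- mask_ops(m, ce, "AND")
    expect_equal(peripheral_volume_pct(inside, ce), 0)
    pct <- peripheral_volume_pct(m, ce)
    is_subset <- sum(m$voxels & !ce$voxels) == 0L
    expect_identical(pct == 0, is_subset)
  }
})

test_that("nearest resampling both masks preserves percentages", {
  set.seed(83)
  m <- rand_mask(c(8, 8, 4), p = 0.4, spacing = c(2, 2, 2))
  ce <- rand_mask(c(8, 8, 4), p = 0.5, spacing = c(2, 2, 2))
  ref <- mk_mask(array(FALSE, c(16, 16, 8)), spacing = c(1, 1, 1))
  m2 <- resample_to_reference(m, ref, "nearest")
  ce2 <- resample_to_reference(ce, ref, "nearest")
  expect_equal(peripheral_volume_pct(m2, ce2),
               peripheral_volume_pct(m, ce), tolerance = 1e-12)
})

test_that("overlap summary rows are internally consistent and order-invariant", {
  set.seed(84)
  dims <- c(8, 8, 6)
  masks <- list(FLT = rand_mask(dims, 0.5), rCBV = rand_mask(dims, 0.3),
                FMISO = rand_mask(dims, 0.4))
  ce <- rand_mask(dims, 0.45)
  hs <- list(FLT = mask_ops(masks$FLT, rand_mask(dims, 0.2), "AND"))
  tab <- overlap_summary(masks, ce, hs)
  expect_equal(nrow(tab), 3)
  # invariant: peripheral pct = 100 (volume - overlap) / ce volume
  expect_equal(tab$peripheral_volume_pct,
               100 * (tab$volume_ml - tab$overlap_ml) / tab$ce_volume_ml,
               tolerance = 1e-9)
  expect_equal(tab$peripheral_hotspot_pct[tab$modality == "FLT"],
               peripheral_hotspot_pct(hs$FLT, ce))
  # permuting labels leaves values unchanged
  tab2 <- overlap_summary(rev(masks), ce, hs)
  for (m in tab$modality)
    expect_equal(tab[tab$modality == m, -1], tab2[tab2$modality == m, -1],
                 ignore_attr = TRUE)
  # all masks equal to CE -> all peripheral percentages zero
  same <- list(FLT = ce, rCBV = ce, FMISO = ce)
  expect_true(all(overlap_summary(same, ce)$peripheral_volume_pct == 0))
})

test_that("Dice coefficient behaves at the boundaries", {
  a <- rand_mask(c(5, 5, 5), 0.5)
  expect_equal(dice_coefficient(a, a), 1)
  empty <- mk_mask(array(FALSE, c(5, 5, 5)))
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_equal(dice_coefficient(a, mask_ops(empty, a, "AND")), 0)
})
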