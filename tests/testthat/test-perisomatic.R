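test_that("Bernsen matches the per-pixel oracle on random images", {
  set.seed(41)
  for (rep in 1:12) {
    n <- sample(8:24, 1); m <- sample(8:24, 1)
    img <- matrix(sample(0:255, n * m, replace = TRUE), n, m)
    r <- sample(2:5, 1)
    ct <- sample(5:60, 1)
    expect_identical(bernsenBinarize(img, r, ct), oracleBernsen(img, r, ct))
  }
})

test_that("Bernsen low-contrast rule classifies by the midpoint vs mid-gray", {
  # uniform dark image: contrast 0 < 15, midpoint below mid-gray -> background
  expect_false(any(bernsenBinarize(matrix(40, 8, 8), 3, 15)))
  # uniform bright image: midpoint above mid-gray -> foreground
  expect_true(all(bernsenBinarize(matrix(200, 8, 8), 3, 15)))
  # midpoint exactly at mid-gray (127.5): the rule is >=, so foreground
  expect_true(all(bernsenBinarize(matrix(127.5, 8, 8), 3, 15)))
})

test_that("Bernsen contrast rule separates dark and bright at the midpoint", {
  img <- matrix(20, 9, 9); img[5, 5] <- 220  # local contrast 200 >= 15
  b <- bernsenBinarize(img, 3, 15)
  expect_true(b[5, 5])     # 220 > midpoint 120
  expect_false(b[5, 4])    # 20 < 120
})

test_that("Bernsen rescales >8-bit inputs to 0-255 first", {
  img <- matrix(20, 9, 9); img[5, 5] <- 220
  b8 <- bernsenBinarize(img, 3, 15)
  expect_identical(bernsenBinarize(img * 16, 3, 15), b8)  # 12-bit range
})

test_that("grouped projection + selection + Bernsen compose in preprocessStack", {
  set.seed(42)
  # bright disks on a dark background (a dense uniform-noise guide would
  # leave no shadows after boundary closing and is rejected upstream)
  raw <- array(30, c(16, 16, 10))
  d2a <- outer((1:16 - 5)^2, (1:16 - 5)^2, "+")
  d2b <- outer((1:16 - 11)^2, (1:16 - 12)^2, "+")
  for (s in 1:10) {
    img <- raw[, , s]
    img[d2a <= (2 + s / 10)^2] <- 230
    img[d2b <= (3 - s / 10)^2] <- 200
    raw[, , s] <- img + sample(0:10, 256, replace = TRUE)
  }
  cs <- preprocessStack(raw, group = 5, selected = c(1, 2), guide = 1,
                        radiusPx = 3)
  expect_s4_class(cs, "CompressedStack")
  expect_equal(dim(cs@slices)[3], 2)
  expect_equal(cs@provenance, c(1L, 2L))
  # recompute slice 2 by hand: median filter, max-project slices 6..10, Bernsen
  filt <- array(0, dim(raw))
  for (s in 1:10) filt[, , s] <- medianFilterDisk(raw[, , s], 1)
  proj2 <- oracleGroupMax(filt, 5)[, , 2]
  expect_identical(cs@slices[, , 2], bernsenBinarize(proj2, 3))
})

test_that("preprocessStack validates the slice selection", {
  raw <- array(100, c(8, 8, 6))
  expect_error(preprocessStack(raw, selected = integer()), "selection")
  expect_error(preprocessStack(raw, group = 5, selected = 5), "out of range")
})

test_that("control image closes a gapped ring so region growing cannot leak", {
  guide <- matrix(FALSE, 31, 31)
  d <- sqrt(outer((1:31 - 16)^2, (1:31 - 16)^2, "+"))
  guide[d >= 9 & d <= 11] <- TRUE
  guide[15:17, 25:31] <- FALSE          # cut a gap in the ring
  ctrl <- makeControlImage(guide)
  expect_true(all(ctrl[guide]))          # foreground preserved
  roi <- growShadowROI(ctrl, c(16, 16), dilationRadiusPx = 0,
                       minSomaAreaPx = 1)
  expect_lt(roi@coreAreaPx, 400)         # leak would flood most of 31*31
  # without ridge closing the fill escapes through the gap
  leak <- floodFill(!guide, c(16, 16), connectivity = 4)
  expect_gt(sum(leak), 700)
})

test_that("growShadowROI grows 4-connected and dilates by a disk", {
  ctrl <- matrix(FALSE, 11, 11)
  ctrl[4, 4:8] <- TRUE; ctrl[8, 4:8] <- TRUE
  ctrl[4:8, 4] <- TRUE; ctrl[4:8, 8] <- TRUE   # closed 5x5 box outline
  roi <- growShadowROI(ctrl, c(6, 6), dilationRadiusPx = 2, minSomaAreaPx = 1)
  expect_equal(roi@coreAreaPx, 9L)             # 3x3 interior
  expect_identical(roi@coreMask,
                   oracleFloodFill(!ctrl, c(6, 6), 4))
  expect_identical(roi@dilatedMask, oracleDiskDilate(roi@coreMask, 2))
  expect_identical(roi@ringMask, roi@dilatedMask & !roi@coreMask)
  expect_false(roi@flagged)
})

test_that("growShadowROI flags out-of-bounds areas instead of erroring", {
  ctrl <- matrix(FALSE, 11, 11)
  ctrl[4, 4:8] <- TRUE; ctrl[8, 4:8] <- TRUE
  ctrl[4:8, 4] <- TRUE; ctrl[4:8, 8] <- TRUE
  small <- growShadowROI(ctrl, c(6, 6), minSomaAreaPx = 30)
  expect_true(small@flagged)
  expect_match(small@flagReason, "below")
  big <- growShadowROI(ctrl, c(1, 1), minSomaAreaPx = 1, maxSomaAreaPx = 20)
  expect_true(big@flagged)
  expect_match(big@flagReason, "above")
  expect_error(growShadowROI(ctrl, c(4, 4)), "foreground")
})

test_that("perisomaticDensity normalizes by core area and slice count", {
  slices <- array(FALSE, c(11, 11, 2))
  slices[5, 5, 1] <- TRUE; slices[5, 6, 1] <- TRUE   # 2 fg px in slice 1
  slices[7, 7, 2] <- TRUE                            # 1 fg px in slice 2
  ctrl <- matrix(FALSE, 11, 11)
  ctrl[4, 4:8] <- TRUE; ctrl[8, 4:8] <- TRUE
  ctrl[4:8, 4] <- TRUE; ctrl[4:8, 8] <- TRUE
  cs <- new("CompressedStack", slices = slices, provenance = c(1L, 2L),
            controlImage = ctrl)
  roi <- growShadowROI(ctrl, c(6, 6), dilationRadiusPx = 2, minSomaAreaPx = 1)
  res <- perisomaticDensity(cs, roi)
  # all three fg pixels fall inside the dilated ROI
  expect_equal(res@stainedPxPerSlice, c(2L, 1L))
  expect_equal(res@normalizedDensity, 3 / 9 / 2)
  expect_equal(res@nSlices, 2L)
})

test_that("the control image is excluded from the density sums", {
  # a control image full of ridges must not inflate the density
  slices <- array(FALSE, c(11, 11, 1))
  ctrl <- matrix(FALSE, 11, 11)
  ctrl[4, 4:8] <- TRUE; ctrl[8, 4:8] <- TRUE
  ctrl[4:8, 4] <- TRUE; ctrl[4:8, 8] <- TRUE
  cs <- new("CompressedStack", slices = slices, provenance = 1L,
            controlImage = ctrl)
  roi <- growShadowROI(ctrl, c(6, 6), minSomaAreaPx = 1)
  expect_equal(perisomaticDensity(cs, roi)@normalizedDensity, 0)
})

test_that("batchQuantify excludes flagged ROIs and warns on duplicate seeds", {
  slices <- array(FALSE, c(11, 11, 1))
  slices[5, 5, 1] <- TRUE
  ctrl <- matrix(FALSE, 11, 11)
  ctrl[4, 4:8] <- TRUE; ctrl[8, 4:8] <- TRUE
  ctrl[4:8, 4] <- TRUE; ctrl[4:8, 8] <- TRUE
  cs <- new("CompressedStack", slices = slices, provenance = 1L,
            controlImage = ctrl)
  expect_warning(
    res <- batchQuantify(cs, rbind(c(6, 6), c(6, 7), c(1, 1)),
                         minSomaAreaPx = 1, maxSomaAreaPx = 20),
    "already-analyzed")
  expect_equal(nrow(res$perNeuron), 3)
  expect_equal(sum(res$perNeuron$flagged), 1)      # the outside region
  # mean over the unflagged duplicates of the same soma
  expect_equal(res$meanDensity, 1 / 9)
  expect_error(batchQuantify(cs, rbind(c(1, 1)), minSomaAreaPx = 1,
                             maxSomaAreaPx = 20), "flagged")
})

test_that("full PV pipeline recovers a plausible density on a synthetic soma", {
  gt <- PVGroundTruth(somaCenters = c(45L, 45L), ringCoverage = 0.8,
                      nSlices = 5L, seed = 33)
  pv <- genConfocalPVStack(gt, shape = c(90, 90))
  cs <- preprocessStack(pv$stack, group = 5, selected = 1)
  res <- batchQuantify(cs, rbind(c(45L, 45L)))
  expect_false(res$perNeuron$flagged[1])
  # the grown core approximates the true soma disk
  expect_gt(res$perNeuron$core_area_px[1], 0.7 * sum(pv$somaMask))
  expect_lt(res$perNeuron$core_area_px[1], 1.5 * sum(pv$somaMask))
  expect_gt(res$meanDensity, 0)
})
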