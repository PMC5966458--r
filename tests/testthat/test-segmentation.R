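# The operator chain: channel split, disk median, rolling ball, automated
# threshold, mask refinement, particle analysis and shape filtering.

test_that("splitRedChannel keeps the red plane and the calibration", {
  rgb <- array(0, c(8, 8, 3))
  rgb[, , 1] <- 200
  img <- CalibratedImage(rgb, 0.5, stageOriginUm = c(10, 20))
  red <- splitRedChannel(img)
  expect_true(all(pixels(red) == 200))
  expect_equal(pixelSize(red), 0.5)
  expect_equal(stageOrigin(red), c(10, 20))
  expect_identical(imageChannel(red), "red")

  rgb[3, 4, ] <- c(10, 250, 250)
  expect_equal(pixels(splitRedChannel(CalibratedImage(rgb, 1)))[3, 4], 10)
  expect_error(splitRedChannel(CalibratedImage(matrix(0, 4, 4), 1)),
               "3-channel")
})

test_that("disk median removes a hot pixel and matches the brute oracle", {
  m <- matrix(0, 9, 9)
  m[5, 5] <- 255
  expect_true(all(diskMedian(m, 2) == 0))  # 13-pixel disk median is 0
  const <- matrix(7, 6, 6)
  expect_identical(diskMedian(const, 2), const)
  expect_identical(diskMedian(m, 0), m)
  expect_error(diskMedian(m, -1), ">= 0")

  set.seed(31)
  r <- matrix(runif(15 * 12), 15, 12)
  for (radius in c(1, 2, 3))
    expect_equal(diskMedian(r, radius), medianOracle(r, radius))
})

test_that("rolling ball removes flat background and preserves narrow peaks", {
  expect_true(all(rollingBallSubtract(matrix(100, 32, 32), 20) == 0))
  expect_error(rollingBallSubtract(matrix(1, 4, 4), 0), ">= 1")

  # bright disk (radius 3 px, amplitude 50) on background 100
  m <- matrix(100, 41, 41) + 50 * drawDiskMask(41, 3)
  out <- rollingBallSubtract(m, 20)
  expect_true(all(out <= m + 1e-12))
  expect_lt(abs(max(out) - 50) / 50, 0.05)
  # compare against brute-force opening with the same scaled ball
  se <- ballHeightsOracle(6)
  m2 <- matrix(10, 21, 21) + 5 * drawDiskMask(21, 2)
  s <- 255 / diff(range(m2))
  bg <- openingOracle(m2 * s, se) / s
  expect_equal(rollingBallSubtract(m2, 6), pmax(m2 - bg, 0),
               tolerance = 1e-12)

  # zero-background features survive essentially unchanged
  f <- 50 * drawDiskMask(41, 3)
  out2 <- rollingBallSubtract(f + 0, 20)
  expect_lt(max(abs(out2 - f)), 0.01 * 50)
})

test_that("rolling ball output is scale invariant and never exceeds input", {
  set.seed(5)
  m <- matrix(runif(40 * 40), 40, 40)
  out <- rollingBallSubtract(m, 10)
  expect_true(all(out >= 0))
  expect_true(all(out <= m + 1e-12))
  expect_equal(rollingBallSubtract(m * 37.5, 10), out * 37.5,
               tolerance = 1e-9)
})

test_that("automated thresholding separates a two-valued image exactly", {
  m <- matrix(c(0, 255), 10, 10)
  mask <- autoThreshold(m)
  expect_identical(sum(mask), 50L)
  expect_true(all(m[mask] == 255))
  expect_error(autoThreshold(matrix(4, 5, 5)),
               class = "degenerateHistogramError")
})

test_that("otsu agrees with brute-force between-class variance search", {
  set.seed(8)
  m <- matrix(c(rnorm(300, 0.2, 0.05), rnorm(100, 0.8, 0.05)), 20, 20)
  m <- matrix(pmin(1, pmax(0, m)), 20, 20)
  ours <- attr(autoThreshold(m, "otsu"), "threshold")
  # exhaustive search over all 256-bin cuts
  lo <- min(m); hi <- max(m); nbin <- 256
  bin <- pmin(nbin, pmax(1, floor((m - lo) / (hi - lo) * nbin) + 1))
  counts <- tabulate(bin, nbin)
  mids <- lo + (seq_len(nbin) - 0.5) / nbin * (hi - lo)
  best <- -Inf; bt <- NA
  for (k in seq_len(nbin - 1)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / w0
    m1 <- sum(counts[-(1:k)] * mids[-(1:k)]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; bt <- (mids[k] + mids[k + 1]) / 2 }
  }
  expect_equal(ours, bt)
})

test_that("threshold mask covers ring pixels with almost no background", {
  sim <- simulateRosetteField(imageSimParams(nRosettes = 4, nFibers = 0,
                                             noiseSd = 0.02, seed = 13))
  bs <- rollingBallSubtract(diskMedian(sim$image, 2), 20)
  mask <- autoThreshold(bs)
  truth <- sim$truth$labelMask > 0
  # every rosette disk contains thresholded pixels and the false-positive
  # background rate is below 1%
  expect_lt(mean(mask & !truth), 0.01)
  for (i in seq_len(4))
    expect_gt(sum(mask[sim$truth$labelMask == i]), 0)
})

test_that("refineMask fills rings, is idempotent and never removes pixels", {
  ring <- drawDiskMask(33, 12) & !drawDiskMask(33, 8)
  filled <- refineMask(ring)
  expect_identical(filled, drawDiskMask(33, 12))

  disk <- drawDiskMask(21, 7)
  expect_identical(refineMask(disk), disk)

  # one-pixel ring broken by a one-pixel gap: closing bridges the gap,
  # then the enclosed hole is filled
  sq <- matrix(FALSE, 21, 21)
  sq[5, 5:17] <- sq[17, 5:17] <- TRUE
  sq[5:17, 5] <- sq[5:17, 17] <- TRUE
  gap <- sq
  gap[11, 5] <- FALSE
  open <- refineMask(gap, closingRadiusPx = 0)
  expect_false(all(open[6:16, 6:16]))          # no closing: hole stays open
  out <- refineMask(gap, closingRadiusPx = 1)
  expect_true(all(out[6:16, 6:16]))            # gap closed, interior filled

  set.seed(21)
  for (i in 1:20) {
    m <- matrix(runif(30 * 30) < 0.4, 30, 30)
    once <- refineMask(m)
    expect_identical(refineMask(once), once)   # idempotence
    expect_true(all(once[m]))                  # superset of the input
  }
})

test_that("particle analysis measures the documented shape descriptors", {
  expect_identical(nRegions(labelRegions(matrix(FALSE, 10, 10), 1)), 0L)

  # axis-aligned 2 x 20 px rectangle at 1 um/px
  m <- matrix(FALSE, 30, 40)
  m[10:11, 10:29] <- TRUE
  tab <- regionTable(labelRegions(m, 1))
  expect_equal(tab$area_um2, 40)
  expect_equal(tab$perimeter_um, 2 * (20 + 2) - 4)  # centre-trace polygon
  expect_equal(tab$circularity, 4 * pi * 40 / 40^2, tolerance = 1e-12)
  expect_equal(tab$centroid_x_px, mean(c(9, 28)))
  expect_equal(tab$centroid_y_px, mean(c(9, 10)))

  # connectivity semantics for diagonally touching pixels
  two <- matrix(FALSE, 6, 6)
  two[2, 2] <- two[3, 3] <- TRUE
  expect_identical(nRegions(labelRegions(two, 1, connectivity = 8)), 1L)
  expect_identical(nRegions(labelRegions(two, 1, connectivity = 4)), 2L)
})

test_that("labelling agrees with EBImage on random 4-connected masks", {
  skip_if_not(hasEBImage(), "EBImage not installed")
  set.seed(17)
  for (i in 1:5) {
    m <- matrix(runif(40 * 40) < 0.35, 40, 40)
    ours <- max(labelMask(labelRegions(m, 1, connectivity = 4)))
    ref <- max(EBImage::bwlabel(EBImage::Image(t(m))))
    expect_identical(as.integer(ours), as.integer(ref))
  }
})

test_that("area is exactly pixel count times pixel size squared", {
  set.seed(41)
  m <- matrix(runif(50 * 50) < 0.3, 50, 50)
  rs <- labelRegions(m, 0.65)
  tab <- regionTable(rs)
  for (i in seq_len(nrow(tab)))
    expect_identical(tab$area_um2[i],
                     sum(labelMask(rs) == tab$label[i]) * 0.65^2)
})

test_that("rasterized disk circularity is between 0.9 and 1", {
  for (r in c(10, 12, 16, 25)) {
    tab <- regionTable(labelRegions(drawDiskMask(2 * r + 9, r), 1))
    expect_gte(tab$circularity, 0.9)
    expect_lte(tab$circularity, 1)
  }
})

test_that("filterRegions applies the printed inclusive bounds in order", {
  params <- segmentationParams()
  tab <- data.frame(
    label = 1:6,
    area_um2 = c(9.5, 40, 28.3, 10, 50, 12),
    circularity = c(0.9, 0.26, 0.9, 0.35, 1.0, 0.34))
  kept <- filterRegions(tab, params)
  # area 9.5 rejected (below 10); circularity 0.26 and 0.34 rejected
  # (below 0.35); exact bounds 10 um^2, 0.35 and 1.0 retained (inclusive)
  expect_identical(kept$label, c(3L, 4L, 5L))
})

test_that("the full chain recovers rosettes and rejects fibre distractors", {
  expect_identical(nRegions(segmentRosettes(matrix(3, 64, 64))), 0L)

  # published-scale example: 6 um rosettes at 0.5 um/px, area ~ pi * 3^2
  sim <- simulateRosetteField(imageSimParams(
    fieldWidthPx = 256, fieldHeightPx = 256, pixelSizeUm = 0.5,
    nRosettes = 3, rosetteDiameterRangeUm = c(6, 6), nFibers = 0,
    noiseSd = 0.02, seed = 7))
  rs <- segmentRosettes(sim$image)
  expect_identical(nRegions(rs), 3L)
  expect_true(all(abs(regionTable(rs)$area_um2 - pi * 9) / (pi * 9) < 0.15))

  # adding fibre bars must not add regions
  simF <- simulateRosetteField(imageSimParams(
    fieldWidthPx = 256, fieldHeightPx = 256, pixelSizeUm = 0.5,
    nRosettes = 3, rosetteDiameterRangeUm = c(6, 6), nFibers = 5,
    noiseSd = 0.02, seed = 7))
  expect_identical(nRegions(segmentRosettes(simF$image)), 3L)
})

test_that("returned regions always satisfy the configured filters", {
  params <- segmentationParams()
  for (seed in c(3, 14)) {
    sim <- simulateRosetteField(imageSimParams(nRosettes = 6, nFibers = 5,
                                               noiseSd = 0.2, seed = seed))
    tab <- regionTable(segmentRosettes(sim$image, params))
    expect_true(all(tab$area_um2 >= params@minAreaUm2))
    expect_true(all(tab$circularity >= params@circularityRange[1]))
    expect_true(all(tab$circularity <= params@circularityRange[2]))
  }
})
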