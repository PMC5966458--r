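# High-content scoring: illumination correction, top-hat enhancement,
# object/nucleus detection, per-field phenotypes and group statistics.

test_that("illumination correction flattens a gradient, preserving the mean", {
  flat <- matrix(3.2, 64, 64)
  out <- correctIllumination(flat, 30)
  expect_lt(max(abs(out - flat)) / 3.2, 1e-6)

  # 20% linear gradient across the field, smoothing scale well below the
  # field size so the illumination estimate can follow the ramp
  grad <- matrix(rep(seq(0.9, 1.1, length.out = 128), each = 128), 128,
                 128, byrow = TRUE)
  img <- 2 * grad
  corr <- correctIllumination(img, 16)
  expect_equal(mean(corr), mean(img), tolerance = 1e-6)
  # residual gradient: slope of a plane fit, relative to the mean
  xs <- rep(seq_len(128), each = 128)
  fit <- lm(as.vector(t(corr)) ~ xs)
  residualAmp <- abs(coef(fit)[2]) * 127
  expect_lt(residualAmp / mean(img), 0.02)
  expect_error(correctIllumination(img, 0), "positive")
})

test_that("top-hat keeps narrow peaks and suppresses broad plateaus", {
  expect_true(all(tophatEnhance(matrix(5, 32, 32), 10) == 0))
  expect_error(tophatEnhance(matrix(1, 4, 4), 0), ">= 1")

  peak <- 2 * drawDiskMask(41, 3)
  out <- tophatEnhance(peak + 0, 10)
  expect_lt(abs(max(out) - 2) / 2, 0.05)
  se <- diskOffsetsOracle(10)
  se$h <- 0
  expect_equal(out, peak - openingOracle(peak + 0, se), tolerance = 1e-12)

  plateau <- matrix(0, 61, 61)
  plateau[16:46, 16:46] <- 1  # 31 px plateau, wider than the 10 px disk
  outP <- tophatEnhance(plateau, 10)
  inner <- outP[26:36, 26:36]
  expect_lt(max(inner), 0.05)
})

test_that("detectObjects keeps rosettes and drops fibres and blanks", {
  blank <- matrix(1, 64, 64)
  expect_identical(nRegions(detectObjects(blank, hcaParams())), 0L)

  sim <- simulateRosetteField(imageSimParams(nRosettes = 3, nFibers = 5,
                                             seed = 5))
  enh <- tophatEnhance(correctIllumination(sim$image, 50), 15)
  objs <- detectObjects(enh, hcaParams())
  expect_identical(nRegions(objs), 3L)
  tab <- regionTable(objs)
  p <- hcaParams()
  expect_true(all(tab$area_um2 >= p@areaRangeUm2[1] &
                  tab$area_um2 <= p@areaRangeUm2[2]))
  expect_true(all(tab$major_axis_um <= p@axisRangeUm[2]))
  expect_true(all(tab$solidity >= p@solidityMin))
})

test_that("a solid disk has solidity 1", {
  m <- 0.9 * drawDiskMask(41, 12)
  tab <- regionTable(detectObjects(CalibratedImage(m, 0.5), hcaParams()))
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$solidity, 1)
})

test_that("nucleus counting uses primary detection without declumping", {
  expect_identical(countNuclei(matrix(0.2, 64, 64), hcaParams()), 0L)

  z <- simulateZymographyPair(0, 20, 5, seed = 9)
  expect_identical(countNuclei(z$nuclei, hcaParams()), 5L)

  # two merged nuclei count as one object
  merged <- matrix(0.05, 80, 80)
  merged <- merged + drawDiskMask(80, 10, cx = -6) + drawDiskMask(80, 10, cx = 6)
  merged[merged > 1] <- 1
  expect_identical(countNuclei(merged, hcaParams()), 1L)
})

test_that("rosettes per nucleus is the exact quotient and guards zero", {
  expect_identical(rosettesPerNucleus(12, 4), 3)
  expect_identical(rosettesPerNucleus(0, 7), 0)
  expect_error(rosettesPerNucleus(5, 0), "without nuclei")
})

test_that("degraded area per cell recovers the synthetic ground truth", {
  expect_equal(degradedAreaPerCell(matrix(1, 64, 64), 5), 0)

  z <- simulateZymographyPair(10, 20, 5, seed = 3)
  d5 <- degradedAreaPerCell(z$gelatin, 5)
  expect_equal(d5, z$truth$degradedAreaUm2 / 5, tolerance = 0.05)
  expect_equal(degradedAreaPerCell(z$gelatin, 10), d5 / 2)
  expect_error(degradedAreaPerCell(z$gelatin, 0), "without nuclei")

  # recovery within 5% across seeds
  errs <- vapply(1:20, function(s) {
    z <- simulateZymographyPair(8, 25, 4, seed = s)
    est <- degradedAreaPerCell(z$gelatin, 4)
    abs(est - z$truth$degradedAreaUm2 / 4) / (z$truth$degradedAreaUm2 / 4)
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  r <- compareGroups(list(ctrl = c(1, 2, 3), trt = c(4, 5, 6)), "ctrl")
  expect_equal(r$F, 13.5)
  expect_equal(unname(r$df), c(1, 4))
  expect_equal(r$p, pf(13.5, 1, 4, lower.tail = FALSE))

  set.seed(55)
  for (i in 1:20) {
    g <- lapply(seq_len(sample(2:5, 1)), function(j) rnorm(sample(3:8, 1)))
    names(g) <- paste0("g", seq_along(g))
    ours <- compareGroups(g, "g1")
    oracle <- anovaOracle(g)
    expect_equal(ours$F, oracle$F, tolerance = 1e-10)
    expect_equal(ours$p, oracle$p, tolerance = 1e-10)
  }
})

test_that("Bonferroni adjustment is exactly min(1, m p)", {
  set.seed(66)
  g <- list(ctrl = rnorm(6), a = rnorm(6, 1), b = rnorm(6), c = rnorm(6, 2))
  r <- compareGroups(g, "ctrl")
  expect_equal(r$comparisons$p_adj, pmin(1, 3 * r$comparisons$p_raw))
  expect_equal(r$comparisons$p_adj,
               unname(p.adjust(r$comparisons$p_raw, "bonferroni")))
  # a raw p of 0.02 over 3 comparisons is not significant at 0.05
  expect_false(min(1, 3 * 0.02) < 0.05)
})

test_that("degenerate ANOVA follows the documented convention", {
  expect_warning(
    same <- compareGroups(list(a = c(2, 2), b = c(2, 2)), "a"),
    "identical")
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_warning(
    diff <- compareGroups(list(a = c(1, 1), b = c(2, 2)), "a"),
    "differing means")
  expect_equal(diff$p, 0)
  expect_error(compareGroups(list(a = 1, b = c(1, 2)), "b"), "at least 2")
  expect_error(compareGroups(list(a = c(1, 2)), "a"))
  expect_error(compareGroups(list(a = c(1, 2), b = c(1, 2)), "c"),
               "not found")
})

test_that("scoreField assembles the per-field record", {
  sim <- simulateRosetteField(imageSimParams(nRosettes = 3, nFibers = 2,
                                             seed = 5))
  z <- simulateZymographyPair(10, 20, 5, seed = 3)
  res <- scoreField(sim$image, z$nuclei, z$gelatin, hcaParams(), "w1_f1")
  expect_identical(res$rosette_count, 3L)
  expect_identical(res$nuclei_count, 5L)
  expect_equal(res$rosettes_per_nucleus, 3 / 5)
  expect_equal(res$degraded_area_per_cell_um2, 40, tolerance = 0.05)
})
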