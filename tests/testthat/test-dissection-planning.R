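# Stage-coordinate calibration, tiling and the element-file round trip.

test_that("extractCalibration passes sidecar metadata through", {
  fld <- extractCalibration(list(stage_origin_um = c(1000, 2000),
                                 pixel_size_um = 0.65,
                                 width_px = 1024, height_px = 1024))
  expect_equal(stageOrigin(fld), c(1000, 2000))
  expect_equal(pixelSize(fld), 0.65)
  expect_identical(fld@widthPx, 1024L)

  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(stage_origin_um = c(5, 6), pixel_size_um = 0.5,
                            width_px = 256, height_px = 128),
                       f, auto_unbox = TRUE)
  fld2 <- extractCalibration(f)
  expect_equal(stageOrigin(fld2), c(5, 6))
  expect_identical(fld2@heightPx, 128L)
})

test_that("extractCalibration names missing or implausible fields", {
  expect_error(extractCalibration(list(stage_origin_um = c(0, 0),
                                       pixel_size_um = 0,
                                       width_px = 10, height_px = 10)),
               "pixel_size_um")
  expect_error(extractCalibration(list(pixel_size_um = 1, width_px = 10,
                                       height_px = 10)),
               "stage_origin_um")
  expect_error(extractCalibration(list(stage_origin_um = c(0, 0),
                                       pixel_size_um = 1, width_px = 10)),
               "height_px")
})

test_that("resolution-tag calibration uses the reciprocal rule", {
  fld <- extractCalibration(list(stage_origin_um = c(0, 0),
                                 x_resolution_px_per_um = 1 / 0.65,
                                 width_px = 64, height_px = 64))
  expect_equal(pixelSize(fld), 0.65)
})

test_that("pixel-to-stage transforms match hand-computed values", {
  fld <- calibratedField(c(1000, 2000), 0.65, 1024, 1024)
  expect_equal(drop(pixelToStage(c(0, 0), fld)), c(x_um = 1000, y_um = 2000))
  expect_equal(drop(pixelToStage(c(512, 512), fld)),
               c(x_um = 1332.8, y_um = 2332.8))
  expect_error(pixelToStage(c(-1, 5), fld), "bounds")
  expect_error(pixelToStage(c(1024, 0), fld), "bounds")
})

test_that("pixel/stage round trips are exact to 1e-9 um", {
  for (flip in c(FALSE, TRUE)) {
    fld <- calibratedField(c(-350.25, 7801.5), 0.3249, 1392, 1040,
                           yAxisFlip = flip)
    set.seed(77)
    p <- cbind(runif(200, 0, 1391), runif(200, 0, 1039))
    back <- stageToPixel(pixelToStage(p, fld), fld)
    expect_lt(max(abs(back - p)) * pixelSize(fld), 1e-9)
  }
})

test_that("tile grids abut exactly at one field pitch", {
  fld <- calibratedField(c(0, 0), 0.65, 1024, 1024)
  expect_equal(nrow(planTileGrid(c(5, 5), fld, 1, 1)), 1L)
  expect_equal(drop(planTileGrid(c(5, 5), fld, 1, 1)),
               c(x_um = 5, y_um = 5))

  g <- planTileGrid(c(0, 0), fld, 2, 2)
  expect_equal(g[, "x_um"], c(0, 665.6, 0, 665.6))
  expect_equal(g[, "y_um"], c(0, 0, 665.6, 665.6))

  row3 <- planTileGrid(c(10, 10), fld, 3, 1)
  expect_equal(diff(row3[, "x_um"]), rep(1024 * 0.65, 2))

  serp <- planTileGrid(c(0, 0), fld, 3, 2, serpentine = TRUE)
  expect_equal(serp[4:6, "x_um"], rev(serp[1:3, "x_um"]))
  expect_error(planTileGrid(c(0, 0), fld, 0, 2), ">= 1")
})

test_that("buildPlan transforms region boundaries into stage frame", {
  fld <- calibratedField(c(0, 0), 1, 256, 256)
  empty <- labelRegions(matrix(FALSE, 256, 256), 1)
  expect_length(planElements(buildPlan(empty, fld)), 0L)

  m <- matrix(FALSE, 256, 256)
  m[101:110, 101:110] <- TRUE  # 10 x 10 px square at pixel (100, 100)
  plan <- buildPlan(labelRegions(m, 1), fld)
  poly <- planElements(plan)[[1]]
  expect_identical(nrow(poly), 4L)
  expect_setequal(poly[, 1], c(100, 110))
  expect_setequal(poly[, 2], c(100, 110))

  # vertex count preserved by the transform
  sim <- simulateRosetteField(imageSimParams(nRosettes = 2, seed = 3))
  regs <- segmentRosettes(sim$image)
  fld2 <- calibratedField(c(100, 100), pixelSize(sim$image), 512, 512)
  plan2 <- buildPlan(regs, fld2)
  for (i in seq_len(nRegions(regs))) {
    raw <- invadoLCM:::.cppTraceOutline(labelMask(regs),
                                        regionTable(regs)$label[i], 8L)
    expect_identical(nrow(planElements(plan2)[[i]]), nrow(raw))
  }
})

test_that("element files round trip to 0.01 um", {
  f <- tempfile(fileext = ".xml")
  empty <- dissectionPlan()
  exportElementFile(empty, f)
  doc <- xml2::read_xml(f)
  expect_length(xml2::xml_find_all(doc, "./element"), 0L)
  expect_length(planElements(parseElementFile(f)), 0L)

  sq <- cbind(c(0, 4.125, 4.125, 0), c(0, 0, 4.125, 4.125))
  plan <- dissectionPlan(matrix(c(10.5, 20.25), 1), 7L, list(sq))
  exportElementFile(plan, f)
  expect_length(xml2::xml_find_all(xml2::read_xml(f), ".//vertex"), 4L)
  back <- parseElementFile(f)
  expect_identical(back@elementIds, 7L)
  expect_lt(max(abs(planElements(back)[[1]] - sq)), 0.005 + 1e-12)
  expect_lt(max(abs(fieldCenters(back) - fieldCenters(plan))), 0.005 + 1e-12)

  set.seed(9)
  polys <- lapply(1:3, function(i)
    cbind(runif(5, -1000, 1000), runif(5, -1000, 1000)))
  plan2 <- dissectionPlan(cbind(runif(2), runif(2)), 1:3, polys)
  exportElementFile(plan2, f)
  back2 <- parseElementFile(f)
  expect_identical(lengths(planElements(back2)), lengths(planElements(plan2)))
  for (i in 1:3)
    expect_lt(max(abs(planElements(back2)[[i]] - polys[[i]])), 0.005 + 1e-12)
})

test_that("parseElementFile reports malformed input", {
  f <- tempfile(fileext = ".xml")
  writeLines("<dissectionPlan><element type='dissection'/></dissectionPlan>",
             f)
  expect_error(parseElementFile(f), "id")
  writeLines("<somethingElse/>", f)
  expect_error(parseElementFile(f), "root node")
  writeLines("<dissectionPlan><element id='1'", f)
  expect_error(parseElementFile(f))
})
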