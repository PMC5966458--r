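## Microdissection planning: stage-coordinate calibration, adjacent-field
## tiling and the exportable element list consumed by the dissector
## workflow.

#' Extract acquisition calibration
#'
#' Builds a [CalibratedField-class] from acquisition metadata. Accepted
#' inputs: a named list (`stage_origin_um`, `pixel_size_um`, `width_px`,
#' `height_px`, optional `y_axis_flip`, or `x_resolution_px_per_um` in
#' place of the pixel size -- resolution tags are pixels per micrometre,
#' so the pixel size is their reciprocal), the path of a JSON sidecar
#' with those fields, or the path of a TIFF whose resolution tags carry
#' the calibration (a TIFF source needs the stage origin supplied via
#' `stageOriginUm`, since TIFF tags do not record it). Missing or
#' implausible fields are reported by name.
#'
#' @param metadata list or file path as described.
#' @param stageOriginUm optional `(x, y)` stage origin override (um).
#' @param yAxisFlip optional flip override.
#' @return A [CalibratedField-class].
#' @examples
#' extractCalibration(list(stage_origin_um = c(1000, 2000),
#'                         pixel_size_um = 0.65,
#'                         width_px = 1024, height_px = 1024))
#' @export
extractCalibration <- function(metadata, stageOriginUm = NULL,
                               yAxisFlip = NULL) {
  if (is.character(metadata) && length(metadata) == 1L) {
    if (grepl("\\.json$", metadata, ignore.case = TRUE)) {
      metadata <- jsonlite::read_json(metadata, simplifyVector = TRUE)
    } else if (grepl("\\.tiff?$", metadata, ignore.case = TRUE)) {
      img <- tiff::readTIFF(metadata, info = TRUE)
      xres <- attr(img, "x.resolution")
      if (is.null(xres) || !is.numeric(xres) || xres <= 0)
        stop("TIFF lacks a usable x.resolution tag for 'pixel_size_um'")
      d <- dim(img)
      metadata <- list(pixel_size_um = 1 / xres,
                       width_px = d[2], height_px = d[1])
    } else {
      stop("unrecognized metadata file type: ", metadata)
    }
  }
  stopifnot(is.list(metadata))
  if (!is.null(stageOriginUm)) metadata$stage_origin_um <- stageOriginUm
  if (!is.null(yAxisFlip)) metadata$y_axis_flip <- yAxisFlip
  # resolution-tag style calibration: pixels per micrometre, reciprocal rule
  if (is.null(metadata$pixel_size_um) &&
      !is.null(metadata$x_resolution_px_per_um)) {
    xr <- metadata$x_resolution_px_per_um
    if (!is.numeric(xr) || length(xr) != 1L || !is.finite(xr) || xr <= 0)
      stop("implausible 'x_resolution_px_per_um': must be a single ",
           "positive number")
    metadata$pixel_size_um <- 1 / xr
  }
  missing <- setdiff(c("stage_origin_um", "pixel_size_um", "width_px",
                       "height_px"), names(metadata))
  if (length(missing))
    stop("calibration metadata lacks field(s): ",
         paste(missing, collapse = ", "))
  ps <- metadata$pixel_size_um
  if (!is.numeric(ps) || length(ps) != 1L || !is.finite(ps) || ps <= 0)
    stop("implausible 'pixel_size_um': must be a single positive number")
  if (!is.numeric(metadata$width_px) || metadata$width_px <= 0)
    stop("implausible 'width_px': must be positive")
  if (!is.numeric(metadata$height_px) || metadata$height_px <= 0)
    stop("implausible 'height_px': must be positive")
  so <- as.numeric(unlist(metadata$stage_origin_um))
  if (length(so) != 2L || any(!is.finite(so)))
    stop("implausible 'stage_origin_um': need two finite numbers")
  calibratedField(so, ps, metadata$width_px, metadata$height_px,
                  isTRUE(metadata$y_axis_flip))
}

## continuous pixel -> stage transform; works for pixel centres (integers)
## and for polygon vertices at pixel corners alike
.toStage <- function(xPx, yPx, field) {
  px <- field@pixelSizeUm
  x <- field@stageOriginUm[1] + xPx * px
  y <- if (field@yAxisFlip)
    field@stageOriginUm[2] + (field@heightPx - yPx) * px
  else field@stageOriginUm[2] + yPx * px
  cbind(x_um = x, y_um = y)
}

.fromStage <- function(xUm, yUm, field) {
  px <- field@pixelSizeUm
  x <- (xUm - field@stageOriginUm[1]) / px
  y <- if (field@yAxisFlip)
    field@heightPx - (yUm - field@stageOriginUm[2]) / px
  else (yUm - field@stageOriginUm[2]) / px
  cbind(x_px = x, y_px = y)
}

#' Convert pixel coordinates to stage coordinates
#'
#' `stage = origin + p * pixelSize` (with the y term reflected about the
#' field when the calibration has `yAxisFlip`). Pixel coordinates are
#' 0-based with the pixel-centre convention; the transform is exactly
#' inverted by [stageToPixel()].
#'
#' @param pPx numeric `(x, y)` pixel point or an n x 2 matrix of points;
#'   must lie within the image bounds.
#' @param field a [CalibratedField-class].
#' @return n x 2 matrix of stage points (um).
#' @examples
#' fld <- calibratedField(c(1000, 2000), 0.65, 1024, 1024)
#' pixelToStage(c(512, 512), fld)  # (1332.8, 2332.8)
#' @export
pixelToStage <- function(pPx, field) {
  stopifnot(is(field, "CalibratedField"))
  p <- if (is.matrix(pPx)) pPx else matrix(pPx, ncol = 2)
  if (any(p[, 1] < 0 | p[, 1] > field@widthPx - 1L |
          p[, 2] < 0 | p[, 2] > field@heightPx - 1L))
    stop("pixel point outside the image bounds")
  .toStage(p[, 1], p[, 2], field)
}

#' Convert stage coordinates to pixel coordinates
#'
#' Exact inverse of [pixelToStage()].
#'
#' @param pUm numeric `(x, y)` stage point (um) or an n x 2 matrix.
#' @param field a [CalibratedField-class].
#' @return n x 2 matrix of pixel points.
#' @examples
#' fld <- calibratedField(c(1000, 2000), 0.65, 1024, 1024)
#' stageToPixel(c(1332.8, 2332.8), fld)
#' @export
stageToPixel <- function(pUm, field) {
  stopifnot(is(field, "CalibratedField"))
  p <- if (is.matrix(pUm)) pUm else matrix(pUm, ncol = 2)
  .fromStage(p[, 1], p[, 2], field)
}

#' Plan an adjacent-field tiling grid
#'
#' Computes the matrix of stage points placed at the centres of adjacent
#' acquisition fields: a row-major `nCols` x `nRows` grid starting at
#' `startCenterUm`, spaced exactly one field width horizontally and one
#' field height vertically, so fields abut without gap or overlap.
#' Optionally the traversal is serpentine (every second row reversed) to
#' minimize stage travel.
#'
#' @param startCenterUm `(x, y)` stage centre (um) of the first field.
#' @param field a [CalibratedField-class] providing field size.
#' @param nCols,nRows grid dimensions, >= 1.
#' @param serpentine reverse every second row (default `FALSE`).
#' @return (nCols * nRows) x 2 matrix of stage centres (um), in traversal
#'   order.
#' @examples
#' fld <- calibratedField(c(0, 0), 0.65, 1024, 1024)
#' planTileGrid(c(0, 0), fld, 2, 2)  # spacing 665.6 um
#' @export
planTileGrid <- function(startCenterUm, field, nCols, nRows,
                         serpentine = FALSE) {
  stopifnot(is(field, "CalibratedField"), length(startCenterUm) == 2L)
  if (nCols < 1 || nRows < 1)
    stop("grid dimensions must be >= 1")
  wUm <- field@widthPx * field@pixelSizeUm
  hUm <- field@heightPx * field@pixelSizeUm
  out <- matrix(NA_real_, nCols * nRows, 2,
                dimnames = list(NULL, c("x_um", "y_um")))
  k <- 1L
  for (i in seq_len(nRows)) {
    cols <- seq_len(nCols)
    if (serpentine && i %% 2L == 0L) cols <- rev(cols)
    for (j in cols) {
      out[k, ] <- c(startCenterUm[1] + (j - 1L) * wUm,
                    startCenterUm[2] + (i - 1L) * hUm)
      k <- k + 1L
    }
  }
  out
}

#' Build a microdissection plan from segmented regions
#'
#' Traces each region's boundary polygon (pixel-corner vertices along the
#' crack boundary, the full traced outline without decimation) and
#' transforms it to stage coordinates; region labels become element ids.
#' The plan records the source field's centre as its single field point.
#'
#' @param regions a [RegionSet-class] from [segmentRosettes()] /
#'   [labelRegions()].
#' @param field a [CalibratedField-class].
#' @return A [DissectionPlan-class].
#' @examples
#' m <- matrix(FALSE, 256, 256); m[101:110, 101:110] <- TRUE
#' regs <- labelRegions(m, pixelSizeUm = 1)
#' fld <- calibratedField(c(0, 0), 1, 256, 256)
#' planElements(buildPlan(regs, fld))[[1]][1, ]
#' @export
buildPlan <- function(regions, field) {
  stopifnot(is(regions, "RegionSet"), is(field, "CalibratedField"))
  tab <- regionTable(regions)
  polys <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    poly <- .cppTraceOutline(labelMask(regions), tab$label[i],
                             regions@connectivity)
    if (nrow(poly) < 3L)
      stop("region ", tab$label[i], " lacks a traceable boundary")
    polys[[i]] <- .toStage(poly[, 1], poly[, 2], field)
  }
  center <- .toStage(field@widthPx / 2, field@heightPx / 2, field)
  new("DissectionPlan",
      fieldCentersUm = matrix(center, 1, 2,
                              dimnames = list(NULL, c("x_um", "y_um"))),
      elementIds = as.integer(tab$label), polygons = polys)
}

#' Create a dissection plan from raw pieces
#'
#' Low-level constructor used by the element-file parser and by tests.
#'
#' @param fieldCentersUm n x 2 matrix of stage points (um).
#' @param elementIds integer ids, one per polygon.
#' @param polygons list of m x 2 stage-frame vertex matrices (um).
#' @return A [DissectionPlan-class].
#' @export
dissectionPlan <- function(fieldCentersUm = matrix(numeric(), 0, 2),
                           elementIds = integer(), polygons = list()) {
  fieldCentersUm <- matrix(as.numeric(fieldCentersUm),
                           ncol = 2, dimnames = list(NULL, c("x_um", "y_um")))
  new("DissectionPlan", fieldCentersUm = fieldCentersUm,
      elementIds = as.integer(elementIds), polygons = polygons)
}

#' Export / parse a dissection element file
#'
#' The dissector's native region-list format is proprietary, so the plan
#' is serialized to an open XML surrogate: one `<point>` per field centre
#' and one `<element>` (with `id` and `type="dissection"`) per region,
#' each holding `<vertex x= y=>` nodes in stage micrometres at 0.01 um
#' precision. `parseElementFile()` inverts the export to that precision.
#'
#' @param plan a [DissectionPlan-class].
#' @param path output (or input) file path.
#' @return `exportElementFile()` returns `path` invisibly;
#'   `parseElementFile()` returns a [DissectionPlan-class].
#' @examples
#' f <- tempfile(fileext = ".xml")
#' plan <- dissectionPlan(matrix(c(10, 20), 1), 1L,
#'                        list(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))))
#' exportElementFile(plan, f)
#' parseElementFile(f)
#' @export
exportElementFile <- function(plan, path) {
  stopifnot(is(plan, "DissectionPlan"))
  validObject(plan)
  root <- xml2::xml_new_root("dissectionPlan", version = "1.0")
  for (i in seq_len(nrow(plan@fieldCentersUm))) {
    xml2::xml_add_child(root, "point",
                        x = sprintf("%.2f", plan@fieldCentersUm[i, 1]),
                        y = sprintf("%.2f", plan@fieldCentersUm[i, 2]))
  }
  for (i in seq_along(plan@polygons)) {
    el <- xml2::xml_add_child(root, "element",
                              id = as.character(plan@elementIds[i]),
                              type = "dissection")
    p <- plan@polygons[[i]]
    for (j in seq_len(nrow(p)))
      xml2::xml_add_child(el, "vertex", x = sprintf("%.2f", p[j, 1]),
                          y = sprintf("%.2f", p[j, 2]))
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' @rdname exportElementFile
#' @export
parseElementFile <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "dissectionPlan")
    stop("not a dissection plan file: root node is <",
         xml2::xml_name(doc), ">")
  pts <- xml2::xml_find_all(doc, "./point")
  centers <- matrix(numeric(), 0, 2)
  if (length(pts)) {
    centers <- cbind(as.numeric(xml2::xml_attr(pts, "x")),
                     as.numeric(xml2::xml_attr(pts, "y")))
    if (any(is.na(centers)))
      stop("point node missing x/y attribute (node ",
           which(is.na(rowSums(centers)))[1L], ")")
  }
  els <- xml2::xml_find_all(doc, "./element")
  ids <- integer(length(els))
  polys <- vector("list", length(els))
  for (i in seq_along(els)) {
    id <- xml2::xml_attr(els[[i]], "id")
    if (is.na(id))
      stop("element node ", i, " lacks required 'id' attribute")
    ids[i] <- as.integer(id)
    vs <- xml2::xml_find_all(els[[i]], "./vertex")
    p <- cbind(as.numeric(xml2::xml_attr(vs, "x")),
               as.numeric(xml2::xml_attr(vs, "y")))
    if (any(is.na(p)))
      stop("element ", id, " has a vertex missing x/y attributes")
    polys[[i]] <- p
  }
  dissectionPlan(centers, ids, polys)
}

#' Write field centres as CSV
#'
#' @param plan a [DissectionPlan-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCentersCsv <- function(plan, path) {
  stopifnot(is(plan, "DissectionPlan"))
  df <- as.data.frame(plan@fieldCentersUm)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write dissection elements as a flat CSV
#'
#' One row per vertex: `element_id`, `vertex_index`, `x_um`, `y_um`.
#'
#' @param plan a [DissectionPlan-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeElementsCsv <- function(plan, path) {
  stopifnot(is(plan, "DissectionPlan"))
  rows <- lapply(seq_along(plan@polygons), function(i) {
    p <- plan@polygons[[i]]
    data.frame(element_id = plan@elementIds[i],
               vertex_index = seq_len(nrow(p)),
               x_um = p[, 1], y_um = p[, 2])
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element_id = integer(), vertex_index = integer(),
               x_um = numeric(), y_um = numeric())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
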