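#' @title Core S4 classes
#' @name invadoLCM-classes
#' @description S4 containers used across the segmentation, planning, HCA
#'   and SILAC modules. All are created through their constructor functions
#'   rather than `new()`.
NULL

## ---------------------------------------------------------------------------
## CalibratedImage
## ---------------------------------------------------------------------------

#' Calibrated fluorescence image
#'
#' A 2-D intensity raster (or an RGB stack, height x width x 3) with the
#' pixel size in micrometres per pixel and, optionally, the stage position
#' (um) of the image's top-left corner. Pixel coordinates are 0-based with
#' the pixel-centre convention: pixel `(x, y)` sits at column `x`, row `y`.
#'
#' @slot pixels numeric matrix (grayscale) or height x width x 3 array (RGB)
#'   of non-negative intensities.
#' @slot pixelSizeUm positive scalar, micrometres per pixel.
#' @slot channel one of `"gray"`, `"red"`, `"green"`, `"blue"`, `"rgb"`.
#' @slot stageOriginUm numeric of length 2 `(x, y)` in um, or `NA` when the
#'   acquisition stage position is unknown.
#' @aliases CalibratedImage-class
#' @exportClass CalibratedImage
setClass("CalibratedImage",
  representation(
    pixels = "array",
    pixelSizeUm = "numeric",
    channel = "character",
    stageOriginUm = "numeric"
  ),
  prototype(
    pixels = matrix(0, 1, 1),
    pixelSizeUm = 1,
    channel = "gray",
    stageOriginUm = c(NA_real_, NA_real_)
  )
)

setValidity("CalibratedImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
    msg <- c(msg, "'pixels' must be a matrix or a height x width x 3 array")
  if (length(d) >= 2L && any(d[1:2] < 1L))
    msg <- c(msg, "'pixels' must be non-empty")
  if (length(object@pixelSizeUm) != 1L || is.na(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive number")
  if (!object@channel %in% c("gray", "red", "green", "blue", "rgb"))
    msg <- c(msg, "'channel' must be gray, red, green, blue or rgb")
  if (length(object@stageOriginUm) != 2L)
    msg <- c(msg, "'stageOriginUm' must have length 2")
  if (length(msg)) msg else TRUE
})

#' Construct a CalibratedImage
#'
#' @param pixels numeric matrix or height x width x 3 array.
#' @param pixelSizeUm pixel size in micrometres per pixel.
#' @param channel channel tag; defaults to `"rgb"` for 3-channel input and
#'   `"gray"` otherwise.
#' @param stageOriginUm optional `(x, y)` stage position (um) of the image's
#'   top-left corner.
#' @return A [CalibratedImage-class] object.
#' @examples
#' img <- CalibratedImage(matrix(0, 32, 32), pixelSizeUm = 0.5)
#' pixelSize(img)
#' @export
CalibratedImage <- function(pixels, pixelSizeUm, channel = NULL,
                            stageOriginUm = NULL) {
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (is.null(channel))
    channel <- if (length(dim(pixels)) == 3L) "rgb" else "gray"
  if (is.null(stageOriginUm)) stageOriginUm <- c(NA_real_, NA_real_)
  new("CalibratedImage", pixels = pixels,
      pixelSizeUm = as.numeric(pixelSizeUm), channel = channel,
      stageOriginUm = as.numeric(stageOriginUm))
}

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Segmentation parameters
#'
#' Parameters of the rosette segmentation chain. The defaults are the
#' published ones: median radius 2 px, rolling-ball radius 20 px, minimum
#' area 10 um^2 and circularity within \[0.35, 1\]; both comparison bounds
#' are inclusive.
#'
#' @slot medianRadiusPx disk radius of the median filter (px).
#' @slot rollingBallRadiusPx rolling-ball radius (px).
#' @slot thresholdMethod `"isodata"` (iterative intermeans, the historical
#'   ImageJ default) or `"otsu"`.
#' @slot closingRadiusPx disk radius of the morphological closing (px).
#' @slot connectivity 4 or 8 (default) for the connected-component analysis.
#' @slot minAreaUm2 minimum retained region area (um^2).
#' @slot circularityRange inclusive `(lo, hi)` circularity bounds.
#' @aliases SegmentationParams-class
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(
    medianRadiusPx = "integer",
    rollingBallRadiusPx = "integer",
    thresholdMethod = "character",
    closingRadiusPx = "integer",
    connectivity = "integer",
    minAreaUm2 = "numeric",
    circularityRange = "numeric"
  ),
  prototype(
    medianRadiusPx = 2L,
    rollingBallRadiusPx = 20L,
    thresholdMethod = "isodata",
    closingRadiusPx = 1L,
    connectivity = 8L,
    minAreaUm2 = 10,
    circularityRange = c(0.35, 1)
  )
)

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (object@medianRadiusPx < 0L) msg <- c(msg, "median radius must be >= 0")
  if (object@rollingBallRadiusPx < 1L)
    msg <- c(msg, "rolling-ball radius must be >= 1")
  if (!object@thresholdMethod %in% c("isodata", "otsu"))
    msg <- c(msg, "threshold method must be 'isodata' or 'otsu'")
  if (object@closingRadiusPx < 0L) msg <- c(msg, "closing radius must be >= 0")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (!is.finite(object@minAreaUm2) || object@minAreaUm2 <= 0)
    msg <- c(msg, "minimum area must be > 0")
  cr <- object@circularityRange
  if (length(cr) != 2L || cr[1] < 0 || cr[2] > 1 || cr[1] > cr[2])
    msg <- c(msg, "circularity range must satisfy 0 <= lo <= hi <= 1")
  if (length(msg)) msg else TRUE
})

#' @param medianRadiusPx,rollingBallRadiusPx,thresholdMethod,closingRadiusPx
#'   see the class slots.
#' @param connectivity,minAreaUm2,circularityRange see the class slots.
#' @return `segmentationParams()` returns a [SegmentationParams-class]
#'   object.
#' @rdname SegmentationParams-class
#' @examples
#' segmentationParams(thresholdMethod = "otsu")
#' @export
segmentationParams <- function(medianRadiusPx = 2, rollingBallRadiusPx = 20,
                               thresholdMethod = "isodata",
                               closingRadiusPx = 1, connectivity = 8,
                               minAreaUm2 = 10,
                               circularityRange = c(0.35, 1)) {
  new("SegmentationParams",
      medianRadiusPx = as.integer(medianRadiusPx),
      rollingBallRadiusPx = as.integer(rollingBallRadiusPx),
      thresholdMethod = thresholdMethod,
      closingRadiusPx = as.integer(closingRadiusPx),
      connectivity = as.integer(connectivity),
      minAreaUm2 = as.numeric(minAreaUm2),
      circularityRange = as.numeric(circularityRange))
}

#' High-content analysis parameters
#'
#' Parameters for the high-content phenotype scoring. The published
#' workflow filters candidate structures on area, major/minor axis length
#' and solidity without printing numeric cut-offs; the defaults here
#' (area 10--200 um^2, axes 2--20 um, solidity >= 0.8) are chosen for
#' rosettes of 5--7 um diameter against 20 um stress-fibre distractors.
#'
#' @slot illuminationSigmaPx Gaussian scale (px) of the illumination-field
#'   estimate.
#' @slot tophatRadiusPx disk radius (px) of the white top-hat enhancement.
#' @slot thresholdMethod `"isodata"` or `"otsu"`.
#' @slot areaRangeUm2 inclusive object area range (um^2).
#' @slot axisRangeUm inclusive range (um) applied to both the major and the
#'   minor ellipse axis length.
#' @slot solidityMin minimum solidity (area / convex hull area) in \[0, 1\].
#' @slot minNucleusAreaUm2 minimum primary-object area (um^2) used when
#'   counting nuclei; no further shape refinement is applied to nuclei.
#' @aliases HcaParams-class
#' @exportClass HcaParams
setClass("HcaParams",
  representation(
    illuminationSigmaPx = "numeric",
    tophatRadiusPx = "integer",
    thresholdMethod = "character",
    areaRangeUm2 = "numeric",
    axisRangeUm = "numeric",
    solidityMin = "numeric",
    minNucleusAreaUm2 = "numeric"
  ),
  prototype(
    illuminationSigmaPx = 50,
    tophatRadiusPx = 15L,
    thresholdMethod = "isodata",
    areaRangeUm2 = c(10, 200),
    axisRangeUm = c(2, 20),
    solidityMin = 0.8,
    minNucleusAreaUm2 = 20
  )
)

setValidity("HcaParams", function(object) {
  msg <- character()
  if (object@illuminationSigmaPx <= 0)
    msg <- c(msg, "illumination sigma must be > 0")
  if (object@tophatRadiusPx < 1L) msg <- c(msg, "top-hat radius must be >= 1")
  if (!object@thresholdMethod %in% c("isodata", "otsu"))
    msg <- c(msg, "threshold method must be 'isodata' or 'otsu'")
  if (diff(object@areaRangeUm2) < 0) msg <- c(msg, "area range not ordered")
  if (diff(object@axisRangeUm) < 0) msg <- c(msg, "axis range not ordered")
  if (object@solidityMin < 0 || object@solidityMin > 1)
    msg <- c(msg, "solidity minimum must be in [0, 1]")
  if (object@minNucleusAreaUm2 < 0)
    msg <- c(msg, "minimum nucleus area must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param illuminationSigmaPx,tophatRadiusPx,thresholdMethod see the class
#'   slots.
#' @param areaRangeUm2,axisRangeUm,solidityMin,minNucleusAreaUm2 see the
#'   class slots.
#' @return `hcaParams()` returns an [HcaParams-class] object.
#' @rdname HcaParams-class
#' @examples
#' hcaParams(solidityMin = 0.9)
#' @export
hcaParams <- function(illuminationSigmaPx = 50, tophatRadiusPx = 15,
                      thresholdMethod = "isodata",
                      areaRangeUm2 = c(10, 200), axisRangeUm = c(2, 20),
                      solidityMin = 0.8, minNucleusAreaUm2 = 20) {
  new("HcaParams",
      illuminationSigmaPx = as.numeric(illuminationSigmaPx),
      tophatRadiusPx = as.integer(tophatRadiusPx),
      thresholdMethod = thresholdMethod,
      areaRangeUm2 = as.numeric(areaRangeUm2),
      axisRangeUm = as.numeric(axisRangeUm),
      solidityMin = as.numeric(solidityMin),
      minNucleusAreaUm2 = as.numeric(minNucleusAreaUm2))
}

#' SILAC labelling scheme
#'
#' Describes the heavy-isotope labelling: which residues carry the label and
#' the mass shift per labelled residue. The default is 13C6 lysine/arginine
#' labelling, a shift of 6.02013 Da (six 13C-for-12C substitutions) per K or
#' R.
#'
#' @slot labeledResidues character vector of one-letter residue codes.
#' @slot massShiftDa mass shift in Dalton per labelled residue.
#' @slot modName modification tag expected in peptide tables (e.g. "13C6").
#' @aliases LabelingScheme-class
#' @exportClass LabelingScheme
setClass("LabelingScheme",
  representation(
    labeledResidues = "character",
    massShiftDa = "numeric",
    modName = "character"
  ),
  prototype(
    labeledResidues = c("K", "R"),
    massShiftDa = 6.02013,
    modName = "13C6"
  )
)

setValidity("LabelingScheme", function(object) {
  msg <- character()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!length(object@labeledResidues) ||
      !all(object@labeledResidues %in% aa))
    msg <- c(msg, "labelled residues must be valid one-letter amino acids")
  if (length(object@massShiftDa) != 1L || object@massShiftDa <= 0)
    msg <- c(msg, "mass shift must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @param labeledResidues,massShiftDa,modName see the class slots.
#' @return `labelingScheme()` returns a [LabelingScheme-class] object.
#' @rdname LabelingScheme-class
#' @examples
#' labelingScheme()
#' @export
labelingScheme <- function(labeledResidues = c("K", "R"),
                           massShiftDa = 6.02013, modName = "13C6") {
  new("LabelingScheme", labeledResidues = labeledResidues,
      massShiftDa = as.numeric(massShiftDa), modName = modName)
}

## ---------------------------------------------------------------------------
## RegionSet
## ---------------------------------------------------------------------------

#' Segmented regions of a calibrated image
#'
#' The result of connected-component particle analysis: an integer label
#' mask plus a per-region table of calibrated shape descriptors. Region
#' labels in the table always refer to the stored mask; after filtering,
#' the mask keeps its original labels while the table is subset.
#'
#' The table columns are `label`, `area_um2` (pixel count times pixel size
#' squared, exact), `perimeter_um`, `circularity`
#' (`min(1, 4 * pi * area / perimeter^2)`), `centroid_x_px`,
#' `centroid_y_px`, `major_axis_um`, `minor_axis_um` and `solidity`.
#'
#' @slot mask integer label matrix.
#' @slot table data.frame of per-region descriptors.
#' @slot pixelSizeUm pixel size (um/px).
#' @slot connectivity 4 or 8.
#' @aliases RegionSet-class
#' @exportClass RegionSet
setClass("RegionSet",
  representation(
    mask = "matrix",
    table = "data.frame",
    pixelSizeUm = "numeric",
    connectivity = "integer"
  ),
  prototype(
    mask = matrix(0L, 1, 1),
    table = data.frame(),
    pixelSizeUm = 1,
    connectivity = 8L
  )
)

setValidity("RegionSet", function(object) {
  msg <- character()
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive number")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (nrow(object@table) &&
      !all(object@table$label %in% unique(as.vector(object@mask))))
    msg <- c(msg, "table labels must exist in the mask")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Planning classes
## ---------------------------------------------------------------------------

#' Acquisition-field calibration
#'
#' Stage calibration of one acquired field: stage position (um) of the
#' image's top-left corner, the pixel size and the image dimensions.
#' When `yAxisFlip` is `TRUE` the stage y axis runs opposite to the image
#' row axis and pixel row `y` maps to `originY + (heightPx - y) * pixel
#' size` (continuous, pixel-corner consistent); the default `FALSE` maps
#' row `y` to `originY + y * pixel size`.
#'
#' @slot stageOriginUm numeric `(x, y)` stage position of the top-left
#'   corner (um).
#' @slot pixelSizeUm pixel size (um/px).
#' @slot widthPx,heightPx image dimensions in pixels.
#' @slot yAxisFlip logical; see description.
#' @aliases CalibratedField-class
#' @exportClass CalibratedField
setClass("CalibratedField",
  representation(
    stageOriginUm = "numeric",
    pixelSizeUm = "numeric",
    widthPx = "integer",
    heightPx = "integer",
    yAxisFlip = "logical"
  ),
  prototype(
    stageOriginUm = c(0, 0),
    pixelSizeUm = 1,
    widthPx = 1L,
    heightPx = 1L,
    yAxisFlip = FALSE
  )
)

setValidity("CalibratedField", function(object) {
  msg <- character()
  if (length(object@stageOriginUm) != 2L ||
      any(!is.finite(object@stageOriginUm)))
    msg <- c(msg, "'stageOriginUm' must be two finite numbers")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive number")
  if (object@widthPx < 1L || object@heightPx < 1L)
    msg <- c(msg, "image dimensions must be positive")
  if (length(msg)) msg else TRUE
})

#' @param stageOriginUm,pixelSizeUm,widthPx,heightPx,yAxisFlip see the class
#'   slots.
#' @return `calibratedField()` returns a [CalibratedField-class] object.
#' @rdname CalibratedField-class
#' @examples
#' calibratedField(c(1000, 2000), 0.65, 1024, 1024)
#' @export
calibratedField <- function(stageOriginUm, pixelSizeUm, widthPx, heightPx,
                            yAxisFlip = FALSE) {
  new("CalibratedField", stageOriginUm = as.numeric(stageOriginUm),
      pixelSizeUm = as.numeric(pixelSizeUm), widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx), yAxisFlip = isTRUE(yAxisFlip))
}

#' Microdissection plan
#'
#' Ordered field-centre stage points plus the dissection regions as closed
#' polygons in stage coordinates (um). Polygons are stored open (the
#' closure from the last vertex back to the first is implicit) with at
#' least three distinct vertices.
#'
#' @slot fieldCentersUm n x 2 matrix of stage points (um).
#' @slot elementIds integer region identifiers.
#' @slot polygons list of m x 2 numeric matrices of stage-frame vertices.
#' @aliases DissectionPlan-class
#' @exportClass DissectionPlan
setClass("DissectionPlan",
  representation(
    fieldCentersUm = "matrix",
    elementIds = "integer",
    polygons = "list"
  ),
  prototype(
    fieldCentersUm = matrix(numeric(), 0, 2),
    elementIds = integer(),
    polygons = list()
  )
)

setValidity("DissectionPlan", function(object) {
  msg <- character()
  if (ncol(object@fieldCentersUm) != 2L)
    msg <- c(msg, "field centres must be an n x 2 matrix")
  if (nrow(object@fieldCentersUm) &&
      anyDuplicated(object@fieldCentersUm))
    msg <- c(msg, "field centres must be unique")
  if (length(object@elementIds) != length(object@polygons))
    msg <- c(msg, "one id per polygon required")
  bad <- vapply(object@polygons, function(p) {
    p <- unique(p)
    !(is.matrix(p) && ncol(p) == 2L && nrow(p) >= 3L)
  }, logical(1))
  if (any(bad))
    msg <- c(msg, "polygons need at least 3 distinct (x, y) vertices")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DilutionCurve
## ---------------------------------------------------------------------------

#' Peptide-quantity dilution curve
#'
#' Ordinary least-squares line through (injected quantity in ng, summed
#' MS1 area of all detected 13C peptides) points, used to estimate the
#' peptide quantity of a dissected sample from its summed 13C area.
#'
#' @slot points data.frame with columns `quantity_ng` (strictly increasing)
#'   and `summed_area`.
#' @slot slope,intercept coefficients of the fitted line.
#' @slot rSquared coefficient of determination of the fit.
#' @aliases DilutionCurve-class
#' @exportClass DilutionCurve
setClass("DilutionCurve",
  representation(
    points = "data.frame",
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric"
  )
)

setValidity("DilutionCurve", function(object) {
  msg <- character()
  p <- object@points
  if (!all(c("quantity_ng", "summed_area") %in% names(p)))
    msg <- c(msg, "points need columns quantity_ng and summed_area")
  else {
    if (nrow(p) < 2L) msg <- c(msg, "at least 2 dilution points required")
    if (nrow(p) >= 2L &&
        (any(p$quantity_ng <= 0) || any(diff(p$quantity_ng) <= 0)))
      msg <- c(msg, "quantities must be strictly increasing and positive")
  }
  if (length(msg)) msg else TRUE
})
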