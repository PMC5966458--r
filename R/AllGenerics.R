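#' @title Accessor generics
#' @name invadoLCM-accessors
#' @description Accessors for the package's S4 containers; slot access is
#'   never needed directly.
NULL

#' @describeIn invadoLCM-accessors intensity raster of a
#'   [CalibratedImage-class].
#' @param x an object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @describeIn invadoLCM-accessors pixel size in um/px.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @describeIn invadoLCM-accessors stage position (um) of the top-left
#'   corner, `c(NA, NA)` when unknown.
#' @export
setGeneric("stageOrigin", function(x) standardGeneric("stageOrigin"))

#' @describeIn invadoLCM-accessors channel tag of a
#'   [CalibratedImage-class].
#' @export
setGeneric("imageChannel", function(x) standardGeneric("imageChannel"))

#' @describeIn invadoLCM-accessors per-region descriptor table of a
#'   [RegionSet-class].
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @describeIn invadoLCM-accessors integer label mask of a
#'   [RegionSet-class].
#' @export
setGeneric("labelMask", function(x) standardGeneric("labelMask"))

#' @describeIn invadoLCM-accessors number of regions in the table.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @describeIn invadoLCM-accessors ordered field-centre stage points of a
#'   [DissectionPlan-class].
#' @export
setGeneric("fieldCenters", function(x) standardGeneric("fieldCenters"))

#' @describeIn invadoLCM-accessors dissection polygons (stage um) of a
#'   [DissectionPlan-class], a named list of m x 2 matrices.
#' @export
setGeneric("planElements", function(x) standardGeneric("planElements"))

## CalibratedImage ------------------------------------------------------------

#' @rdname invadoLCM-accessors
setMethod("pixels", "CalibratedImage", function(x) x@pixels)

#' @rdname invadoLCM-accessors
setMethod("pixelSize", "CalibratedImage", function(x) x@pixelSizeUm)

#' @rdname invadoLCM-accessors
setMethod("pixelSize", "RegionSet", function(x) x@pixelSizeUm)

#' @rdname invadoLCM-accessors
setMethod("pixelSize", "CalibratedField", function(x) x@pixelSizeUm)

#' @rdname invadoLCM-accessors
setMethod("stageOrigin", "CalibratedImage", function(x) x@stageOriginUm)

#' @rdname invadoLCM-accessors
setMethod("stageOrigin", "CalibratedField", function(x) x@stageOriginUm)

#' @rdname invadoLCM-accessors
setMethod("imageChannel", "CalibratedImage", function(x) x@channel)

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CalibratedImage: %d x %d px%s, %.4g um/px, channel %s\n",
              d[2], d[1], if (length(d) == 3L) " x 3" else "",
              object@pixelSizeUm, object@channel))
  if (all(is.finite(object@stageOriginUm)))
    cat(sprintf("  stage origin: (%.2f, %.2f) um\n",
                object@stageOriginUm[1], object@stageOriginUm[2]))
  invisible(NULL)
})

## RegionSet ------------------------------------------------------------------

#' @rdname invadoLCM-accessors
setMethod("regionTable", "RegionSet", function(x) x@table)

#' @rdname invadoLCM-accessors
setMethod("labelMask", "RegionSet", function(x) x@mask)

#' @rdname invadoLCM-accessors
setMethod("nRegions", "RegionSet", function(x) nrow(x@table))

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet: %d region(s), %d x %d px mask, %.4g um/px, %d-connected\n",
              nrow(object@table), ncol(object@mask), nrow(object@mask),
              object@pixelSizeUm, object@connectivity))
  if (nrow(object@table)) {
    cat(sprintf("  area (um^2): %.1f--%.1f; circularity: %.2f--%.2f\n",
                min(object@table$area_um2), max(object@table$area_um2),
                min(object@table$circularity),
                max(object@table$circularity)))
  }
  invisible(NULL)
})

## CalibratedField / DissectionPlan -------------------------------------------

setMethod("show", "CalibratedField", function(object) {
  cat(sprintf(
    "CalibratedField: %d x %d px @ %.4g um/px, origin (%.2f, %.2f) um%s\n",
    object@widthPx, object@heightPx, object@pixelSizeUm,
    object@stageOriginUm[1], object@stageOriginUm[2],
    if (object@yAxisFlip) ", y flipped" else ""))
  invisible(NULL)
})

#' @rdname invadoLCM-accessors
setMethod("fieldCenters", "DissectionPlan", function(x) x@fieldCentersUm)

#' @rdname invadoLCM-accessors
setMethod("planElements", "DissectionPlan", function(x)
  setNames(x@polygons, x@elementIds))

setMethod("show", "DissectionPlan", function(object) {
  cat(sprintf("DissectionPlan: %d field centre(s), %d dissection element(s)\n",
              nrow(object@fieldCentersUm), length(object@polygons)))
  invisible(NULL)
})

setMethod("show", "DilutionCurve", function(object) {
  cat(sprintf(
    "DilutionCurve: %d points, area = %.4g * ng + %.4g (R^2 = %.4f)\n",
    nrow(object@points), object@slope, object@intercept, object@rSquared))
  invisible(NULL)
})
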