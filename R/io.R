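## Image input/output. Intensities are stored as 32-bit float TIFF so
## arbitrary-range data survive a round trip; calibration travels in a
## JSON sidecar (canonical) and, when reading third-party TIFFs, can also
## be recovered from resolution tags via extractCalibration().

.sidecarPath <- function(path) sub("\\.tiff?$", ".json", path,
                                   ignore.case = TRUE)

#' Write a calibrated image as TIFF plus JSON sidecar
#'
#' Intensities are mapped to \[0, 1\] for storage (32-bit float TIFF only
#' defines that range); the affine transform is recorded in the sidecar
#' as `intensity_offset` / `intensity_scale` so
#' [readCalibratedTiff()] restores the original values.
#'
#' @param img a [CalibratedImage-class].
#' @param path TIFF output path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
writeCalibratedTiff <- function(img, path) {
  stopifnot(is(img, "CalibratedImage"))
  p <- pixels(img)
  off <- min(p)
  sc <- max(p) - off
  if (sc <= 0) sc <- 1
  tiff::writeTIFF((p - off) / sc, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(pixel_size_um = pixelSize(img),
               channel = imageChannel(img),
               width_px = ncol(p), height_px = nrow(p),
               intensity_offset = off, intensity_scale = sc)
  so <- stageOrigin(img)
  if (all(is.finite(so))) meta$stage_origin_um <- so
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a calibrated image written by [writeCalibratedTiff()]
#'
#' @param path TIFF path; pixel size is taken from the JSON sidecar or,
#'   failing that, from the TIFF resolution tags (reciprocal of pixels
#'   per micrometre), or from `pixelSizeUm`.
#' @param pixelSizeUm optional override when no calibration is stored.
#' @return A [CalibratedImage-class].
#' @export
readCalibratedTiff <- function(path, pixelSizeUm = NULL) {
  m <- tiff::readTIFF(path, info = TRUE)
  side <- .sidecarPath(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
  else list()
  ps <- pixelSizeUm %||% meta$pixel_size_um
  if (is.null(ps)) {
    xres <- attr(m, "x.resolution")
    if (!is.null(xres) && is.numeric(xres) && xres > 0) ps <- 1 / xres
  }
  if (is.null(ps))
    stop("no pixel size available: supply 'pixelSizeUm' or a sidecar")
  so <- meta$stage_origin_um
  ch <- meta$channel %||% if (length(dim(m)) == 3L) "rgb" else "gray"
  attributes(m)[setdiff(names(attributes(m)), "dim")] <- NULL
  if (!is.null(meta$intensity_scale))
    m <- m * meta$intensity_scale + (meta$intensity_offset %||% 0)
  CalibratedImage(m, ps, ch, so)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a region label mask as TIFF
#'
#' Labels are scaled into the 16-bit range for storage; the region CSV
#' carries the authoritative measurements.
#'
#' @param regions a [RegionSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLabelMaskTiff <- function(regions, path) {
  stopifnot(is(regions, "RegionSet"))
  m <- labelMask(regions)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Write the per-region measurement table as CSV
#'
#' @param regions a [RegionSet-class] (or a plain region data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegionsCsv <- function(regions, path) {
  tab <- if (is(regions, "RegionSet")) regionTable(regions) else regions
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
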