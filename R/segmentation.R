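## Rosette segmentation: the automated ImageJ-style operator chain used to
## target invadosome rosettes for laser-capture microdissection.

## disk structuring element / neighbourhood: offsets with dr^2 + dc^2 <= r^2
.diskOffsets <- function(radiusPx) {
  r <- as.integer(radiusPx)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

## spherical (rolling-ball) structuring function: heights in intensity units
.ballElement <- function(radiusPx) {
  g <- .diskOffsets(radiusPx)
  h <- sqrt(pmax(0, radiusPx^2 - g$dr^2 - g$dc^2))
  list(dr = as.integer(g$dr), dc = as.integer(g$dc), h = as.numeric(h))
}

.grayErode <- function(m, dr, dc, h = numeric(length(dr)) * 0) {
  .cppGrayMorph(m, as.integer(dr), as.integer(dc), as.numeric(h), FALSE)
}

.grayDilate <- function(m, dr, dc, h = numeric(length(dr)) * 0) {
  .cppGrayMorph(m, as.integer(dr), as.integer(dc), as.numeric(h), TRUE)
}

## grayscale opening (erosion then dilation) with one structuring element
.grayOpen <- function(m, dr, dc, h = numeric(length(dr)) * 0) {
  .grayDilate(.grayErode(m, dr, dc, h), dr, dc, h)
}

.imageMatrix <- function(img) {
  if (is(img, "CalibratedImage")) {
    p <- pixels(img)
    if (length(dim(p)) == 3L)
      stop("a single-channel image is required; use splitRedChannel() first")
    p
  } else if (is.matrix(img)) {
    img
  } else {
    stop("'img' must be a CalibratedImage or a matrix")
  }
}

.rewrap <- function(img, m) {
  if (is(img, "CalibratedImage"))
    CalibratedImage(m, pixelSize(img), imageChannel(img), stageOrigin(img))
  else m
}

#' Extract the red channel of an RGB image
#'
#' The acquisition produces RGB micrographs in which the rosette marker
#' (Lifeact-mRuby) is the red channel; only that channel enters the
#' segmentation chain. Calibration and stage origin are preserved.
#'
#' @param img a 3-channel [CalibratedImage-class] (height x width x 3) or a
#'   height x width x 3 array.
#' @return A single-channel [CalibratedImage-class] tagged `"red"` (or a
#'   matrix for array input).
#' @examples
#' rgb <- array(0, c(8, 8, 3)); rgb[, , 1] <- 200
#' img <- CalibratedImage(rgb, pixelSizeUm = 0.5)
#' range(pixels(splitRedChannel(img)))
#' @export
splitRedChannel <- function(img) {
  p <- if (is(img, "CalibratedImage")) pixels(img) else img
  d <- dim(p)
  if (length(d) != 3L || d[3] != 3L)
    stop("splitRedChannel() requires a 3-channel (RGB) image")
  red <- p[, , 1L]
  if (is(img, "CalibratedImage"))
    CalibratedImage(red, pixelSize(img), "red", stageOrigin(img))
  else red
}

#' Disk median filter
#'
#' Median filter over the disk-shaped neighbourhood of the given radius
#' (the neighbourhood of radius 2 contains 13 pixels), the smoothing step
#' applied before background subtraction. Edges are handled by reflection;
#' radius 0 is the identity.
#'
#' @param img [CalibratedImage-class] or matrix.
#' @param radiusPx integer radius >= 0 in pixels (default 2).
#' @return Filtered image of the same class as the input.
#' @examples
#' m <- matrix(0, 9, 9); m[5, 5] <- 255
#' max(diskMedian(m, 2))  # hot pixel removed
#' @export
diskMedian <- function(img, radiusPx = 2) {
  if (length(radiusPx) != 1L || is.na(radiusPx) || radiusPx < 0)
    stop("median radius must be a single value >= 0")
  if (radiusPx == 0) return(img)
  m <- .imageMatrix(img)
  g <- .diskOffsets(radiusPx)
  .rewrap(img, .cppRankMedian(m, as.integer(g$dr), as.integer(g$dc)))
}

#' Rolling-ball background subtraction
#'
#' Estimates the image background as the grayscale opening with a
#' spherical structuring element of the given radius (the classical
#' rolling-ball construction, computed exactly rather than with the legacy
#' image-shrinking shortcut) and subtracts it. The ball couples the
#' spatial (pixel) and intensity axes; as in the classical algorithm,
#' which was designed around the 8-bit display range, intensities are
#' internally mapped to 0--255 before the ball is rolled and mapped back
#' afterwards, making the result invariant under rescaling of the input
#' intensities. The output is everywhere non-negative and never exceeds
#' the input; a constant image maps to zero.
#'
#' @param img [CalibratedImage-class] or matrix.
#' @param radiusPx ball radius in pixels, >= 1 (default 20).
#' @return Background-subtracted image of the same class as the input.
#' @examples
#' m <- matrix(100, 32, 32)
#' range(rollingBallSubtract(m, 20))  # identically zero
#' @export
rollingBallSubtract <- function(img, radiusPx = 20) {
  if (length(radiusPx) != 1L || is.na(radiusPx) || radiusPx < 1)
    stop("rolling-ball radius must be a single value >= 1")
  m <- .imageMatrix(img)
  rng <- max(m) - min(m)
  if (rng <= 0) return(.rewrap(img, m * 0))
  s <- 255 / rng
  se <- .ballElement(radiusPx)
  bg <- .grayOpen(m * s, se$dr, se$dc, se$h) / s
  .rewrap(img, pmax(m - bg, 0))
}

#' Automated histogram thresholding
#'
#' Computes a global threshold with the IsoData iterative-intermeans
#' method (the historical ImageJ default) or Otsu's method on a 256-bin
#' histogram, and returns the mask of pixels strictly above the threshold.
#' A constant image has no separable histogram and raises a
#' `degenerateHistogramError`; [segmentRosettes()] catches that condition
#' and treats the field as empty.
#'
#' @param img [CalibratedImage-class] or matrix with at least two distinct
#'   values.
#' @param method `"isodata"` (default) or `"otsu"`.
#' @return Logical matrix mask. The computed threshold (intensity units) is
#'   attached as attribute `"threshold"`.
#' @examples
#' m <- matrix(c(0, 255), 10, 10)
#' sum(autoThreshold(m))  # the 50 bright pixels
#' @export
autoThreshold <- function(img, method = c("isodata", "otsu")) {
  method <- match.arg(method)
  m <- .imageMatrix(img)
  lo <- min(m); hi <- max(m)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop(structure(
      class = c("degenerateHistogramError", "error", "condition"),
      list(message = "degenerate histogram: image is constant",
           call = sys.call(-1))))
  nbin <- 256L
  bin <- pmin(nbin, pmax(1L, as.integer(floor((m - lo) / (hi - lo) * nbin)) + 1L))
  counts <- tabulate(bin, nbins = nbin)
  mids <- lo + (seq_len(nbin) - 0.5) / nbin * (hi - lo)
  t <- switch(method,
    isodata = .isodataThreshold(counts, mids),
    otsu = .otsuThreshold(counts, mids))
  mask <- m > t
  attr(mask, "threshold") <- t
  mask
}

## IsoData: iterate t = (mean below + mean above) / 2 to a fixed point,
## seeded at the histogram midpoint (the classical initialisation; the
## iteration has multiple fixed points on long-tailed histograms and the
## midpoint start selects the object/background one)
.isodataThreshold <- function(counts, mids) {
  t <- 0.5 * (mids[1L] + mids[length(mids)])
  for (i in seq_len(200L)) {
    below <- mids <= t
    nb <- sum(counts[below]); na <- sum(counts[!below])
    if (nb == 0 || na == 0) {
      # push into the populated side and continue
      t <- if (nb == 0) min(mids[counts > 0]) else max(mids[counts > 0])
      below <- mids <= t
      nb <- sum(counts[below]); na <- sum(counts[!below])
      if (nb == 0 || na == 0) return(t)
    }
    tNew <- 0.5 * (sum(counts[below] * mids[below]) / nb +
                   sum(counts[!below] * mids[!below]) / na)
    if (abs(tNew - t) < 1e-10) return(tNew)
    t <- tNew
  }
  t
}

## Otsu: maximize between-class variance over bin cuts
.otsuThreshold <- function(counts, mids) {
  w <- counts / sum(counts)
  mu <- cumsum(w * mids)
  omega <- cumsum(w)
  muT <- mu[length(mu)]
  sigma <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma[!is.finite(sigma)] <- -Inf
  k <- which.max(sigma)
  # cut between bin k and k + 1
  if (k < length(mids)) 0.5 * (mids[k] + mids[k + 1]) else mids[k]
}

#' Morphological mask refinement
#'
#' Closing with a disk of the given radius -- taken in the 8-neighbourhood
#' sense, so radius 1 is the full 3 x 3 element and a one-pixel gap in a
#' one-pixel ring is bridged -- followed by filling of enclosed holes,
#' repeated to a fixed point so the operation is idempotent by
#' construction (one pass suffices on ordinary masks). The output is always
#' a superset of the input. With 8-connected foreground, holes are defined
#' by 4-connected background (and vice versa).
#'
#' @param mask logical matrix.
#' @param closingRadiusPx disk radius of the closing (px); 0 skips the
#'   closing and only fills holes.
#' @param connectivity 4 or 8 (default), foreground connectivity.
#' @return Logical matrix.
#' @examples
#' ring <- outer(-8:8, -8:8, function(y, x) {
#'   d <- sqrt(x^2 + y^2); d >= 4 & d <= 6
#' })
#' sum(refineMask(ring)) > sum(ring)  # hole filled
#' @export
refineMask <- function(mask, closingRadiusPx = 1, connectivity = 8) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- mask
  storage.mode(m) <- "logical"
  # closing element: disk including the diagonal corner ring, so radius 1
  # is the 3 x 3 box (the classical binary-closing element)
  g <- if (closingRadiusPx > 0) {
    r <- as.integer(closingRadiusPx)
    gg <- expand.grid(dr = -r:r, dc = -r:r)
    gg[gg$dr^2 + gg$dc^2 <= r^2 + r, , drop = FALSE]
  } else NULL
  for (i in seq_len(10L)) {
    cur <- m
    if (!is.null(g)) {
      num <- .grayDilate(cur + 0, g$dr, g$dc)
      num <- .grayErode(num, g$dr, g$dc)
      cur <- num > 0.5
    }
    cur <- .cppFillHoles(cur, as.integer(connectivity))
    if (identical(cur, m)) break
    m <- cur
  }
  m | mask
}

#' Connected-component particle analysis
#'
#' Labels the connected components of a binary mask (8-connected by
#' default) and measures calibrated shape descriptors per region:
#'
#' * `area_um2`: pixel count times pixel size squared (exact);
#' * `perimeter_um`: the length of the closed polygon through the centres
#'   of the region's outer boundary pixels traced with 8-connected moves
#'   (axial steps 1, diagonal steps `sqrt(2)`). The estimator is within a
#'   few percent of the true perimeter for smooth shapes of radius
#'   >= 10 px and measures an axis-aligned `w x h` rectangle as
#'   `2 * (w + h) - 4` (the trace runs through pixel centres, half a
#'   pixel inside each edge). Regions smaller than 3 boundary pixels use
#'   the unit-square fallback of 4 pixel side lengths;
#' * `circularity`: `4 * pi * area / perimeter^2`, clamped to 1 to absorb
#'   discretization overshoot on small round objects;
#' * `centroid_x_px`, `centroid_y_px`: mean pixel coordinates (0-based);
#' * `major_axis_um`, `minor_axis_um`: ellipse axis lengths from the
#'   second central moments of the pixel centres (`4 * sqrt(eigenvalue)`);
#'   a single-pixel-wide line has minor axis 0;
#' * `solidity`: area over convex-hull area of the pixel centres, clamped
#'   to 1.
#'
#' @param mask logical matrix (or a [RegionSet-class] mask to re-measure).
#' @param pixelSizeUm pixel size in um/px.
#' @param connectivity 4 or 8 (default). Two regions touching only
#'   diagonally are one component under 8- and two under 4-connectivity.
#' @return A [RegionSet-class]; an empty mask gives zero regions.
#' @examples
#' m <- matrix(FALSE, 30, 10); m[5:6, 3:4] <- TRUE
#' regionTable(labelRegions(m, pixelSizeUm = 1))
#' @export
labelRegions <- function(mask, pixelSizeUm = 1, connectivity = 8) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  connectivity <- as.integer(connectivity)
  lab <- .cppLabel(mask, connectivity)
  n <- max(lab)
  tab <- .measureRegions(lab, n, pixelSizeUm, connectivity)
  new("RegionSet", mask = lab, table = tab,
      pixelSizeUm = as.numeric(pixelSizeUm), connectivity = connectivity)
}

.emptyRegionTable <- function() {
  data.frame(label = integer(), area_um2 = numeric(),
             perimeter_um = numeric(), circularity = numeric(),
             centroid_x_px = numeric(), centroid_y_px = numeric(),
             major_axis_um = numeric(), minor_axis_um = numeric(),
             solidity = numeric())
}

.measureRegions <- function(lab, n, pixelSizeUm, connectivity) {
  if (n == 0L) return(.emptyRegionTable())
  px <- pixelSizeUm
  idx <- which(lab > 0L)
  lb <- lab[idx]
  row0 <- (idx - 1L) %% nrow(lab)        # y, 0-based
  col0 <- (idx - 1L) %/% nrow(lab)       # x, 0-based
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- lb == i
    x <- col0[sel]; y <- row0[sel]
    npix <- length(x)
    contour <- .cppContourTrace(lab, i)
    per <- .contourPerimeter(contour) * px
    area <- npix * px^2
    circ <- min(1, 4 * pi * area / per^2)
    # second central moments of pixel centres
    cx <- mean(x); cy <- mean(y)
    mxx <- mean((x - cx)^2); myy <- mean((y - cy)^2)
    mxy <- mean((x - cx) * (y - cy))
    tr <- mxx + myy
    dt <- sqrt(max(0, (mxx - myy)^2 / 4 + mxy^2))
    l1 <- tr / 2 + dt; l2 <- max(0, tr / 2 - dt)
    hull <- .hullArea(x, y)
    solidity <- if (hull <= 0) 1 else min(1, npix / hull)
    rows[[i]] <- data.frame(
      label = i, area_um2 = area, perimeter_um = per, circularity = circ,
      centroid_x_px = cx, centroid_y_px = cy,
      major_axis_um = 4 * sqrt(l1) * px, minor_axis_um = 4 * sqrt(l2) * px,
      solidity = solidity)
  }
  do.call(rbind, rows)
}

## Perimeter in pixel units of the closed polygon through the contour
## pixel centres (8-connected boundary trace): axial steps count 1,
## diagonal steps sqrt(2). Degenerate contours (< 3 pixels) fall back to
## the unit-square perimeter.
.contourPerimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 3L) return(4)
  nxt <- rbind(contour[-1L, , drop = FALSE], contour[1L, , drop = FALSE])
  sum(sqrt(rowSums((nxt - contour)^2)))
}

.hullArea <- function(x, y) {
  if (length(x) < 3L) return(0)
  h <- chull(x, y)
  xs <- x[h]; ys <- y[h]
  if (length(h) < 3L) return(0)
  abs(sum(xs * c(ys[-1L], ys[1L]) - c(xs[-1L], xs[1L]) * ys)) / 2
}

#' Filter regions on area and circularity
#'
#' Retains regions with `area_um2 >= minAreaUm2` and circularity inside the
#' inclusive `circularityRange`; the published cut-offs (area at least
#' 10 um^2, circularity within 0.35--1) are the defaults carried by
#' [segmentationParams()]. Region order is preserved; the label mask is
#' kept unchanged so retained labels still refer to it.
#'
#' @param regions a [RegionSet-class], or a data.frame with `area_um2` and
#'   `circularity` columns.
#' @param params a [SegmentationParams-class].
#' @return Same class as `regions`, with the table subset.
#' @examples
#' m <- matrix(FALSE, 40, 40); m[10:25, 10:25] <- TRUE
#' filterRegions(labelRegions(m, 1), segmentationParams())
#' @export
filterRegions <- function(regions, params = segmentationParams()) {
  stopifnot(is(params, "SegmentationParams"))
  tab <- if (is(regions, "RegionSet")) regionTable(regions) else regions
  stopifnot(is.data.frame(tab),
            all(c("area_um2", "circularity") %in% names(tab)))
  if (nrow(tab)) {
    keep <- tab$area_um2 >= params@minAreaUm2 &
      tab$circularity >= params@circularityRange[1] &
      tab$circularity <= params@circularityRange[2]
    tab <- tab[keep, , drop = FALSE]
    rownames(tab) <- NULL
  }
  if (is(regions, "RegionSet")) initialize(regions, table = tab) else tab
}

#' Segment invadosome rosettes
#'
#' The full automated segmentation chain: red-channel split (for RGB
#' input), disk median filter, rolling-ball background subtraction,
#' automated thresholding, morphological closing + hole filling,
#' connected-component particle analysis, and area/circularity filtering,
#' in that order. A field whose histogram is degenerate (constant image)
#' yields zero regions.
#'
#' @param img a [CalibratedImage-class] (single-channel or RGB) or matrix.
#' @param params a [SegmentationParams-class].
#' @return A [RegionSet-class] of the retained rosette regions.
#' @examples
#' sim <- simulateRosetteField(imageSimParams(nRosettes = 2, seed = 1))
#' nRegions(segmentRosettes(sim$image))
#' @export
segmentRosettes <- function(img, params = segmentationParams()) {
  stopifnot(is(params, "SegmentationParams"))
  validObject(params)
  if (is(img, "CalibratedImage") && length(dim(pixels(img))) == 3L)
    img <- splitRedChannel(img)
  px <- if (is(img, "CalibratedImage")) pixelSize(img) else 1
  sm <- diskMedian(img, params@medianRadiusPx)
  bs <- rollingBallSubtract(sm, params@rollingBallRadiusPx)
  mask <- tryCatch(
    autoThreshold(bs, params@thresholdMethod),
    degenerateHistogramError = function(e) NULL)
  if (is.null(mask)) {
    return(new("RegionSet", mask = matrix(0L, nrow(.imageMatrix(img)),
                                          ncol(.imageMatrix(img))),
               table = .emptyRegionTable(), pixelSizeUm = as.numeric(px),
               connectivity = params@connectivity))
  }
  mask <- refineMask(mask, params@closingRadiusPx, params@connectivity)
  regions <- labelRegions(mask, px, params@connectivity)
  filterRegions(regions, params)
}
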