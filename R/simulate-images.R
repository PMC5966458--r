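## Seeded generators for rosette-bearing fields and zymography image pairs.
## All randomness flows from the single integer seed of the call; the
## session RNG state is saved and restored.

.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Rosette-field simulation parameters
#'
#' Parameters of the synthetic rosette-field generator. Rosettes are
#' rendered as annuli -- a bright F-actin ring around a dimmer core -- with
#' outer diameters drawn uniformly from `rosetteDiameterRangeUm`
#' (default 5--7 um, the diameter range of NIH-3T3-Src rosettes).
#' Fibre distractors emulate stress fibres: 20 um long, 1 um wide bars
#' (aspect ratio 20), built to fail the circularity filter. Centres of
#' placed structures are kept at least one rosette diameter apart so
#' structures never merge. The default sampling of 0.25 um/px over a
#' 512 px field matches high-magnification widefield acquisition and
#' keeps the 1 um structures (rings, fibres) at 4 px -- comfortably above
#' Nyquist for the radius-2 median filter.
#'
#' @slot fieldWidthPx,fieldHeightPx field size in pixels.
#' @slot pixelSizeUm pixel size (um/px), > 0.
#' @slot nRosettes number of rosettes, >= 0.
#' @slot rosetteDiameterRangeUm `(lo, hi)` outer ring diameter (um).
#' @slot ringThicknessUm radial thickness of the bright ring (um).
#' @slot nFibers number of fibre distractors, >= 0.
#' @slot fiberLengthUm,fiberWidthUm fibre geometry (um).
#' @slot illuminationGradientAmplitude peak-to-peak multiplicative
#'   illumination gradient as a fraction of the signal (0.2 = +/-10%).
#' @slot noiseSd additive Gaussian noise SD (intensity units; the ring
#'   amplitude is 1).
#' @slot seed integer seed.
#' @aliases ImageSimParams-class
#' @exportClass ImageSimParams
setClass("ImageSimParams",
  representation(
    fieldWidthPx = "integer", fieldHeightPx = "integer",
    pixelSizeUm = "numeric", nRosettes = "integer",
    rosetteDiameterRangeUm = "numeric", ringThicknessUm = "numeric",
    nFibers = "integer", fiberLengthUm = "numeric", fiberWidthUm = "numeric",
    illuminationGradientAmplitude = "numeric", noiseSd = "numeric",
    seed = "integer"
  ),
  prototype(
    fieldWidthPx = 512L, fieldHeightPx = 512L, pixelSizeUm = 0.25,
    nRosettes = 5L, rosetteDiameterRangeUm = c(5, 7), ringThicknessUm = 1,
    nFibers = 5L, fiberLengthUm = 20, fiberWidthUm = 1,
    illuminationGradientAmplitude = 0.2, noiseSd = 0.05, seed = 1L
  )
)

setValidity("ImageSimParams", function(object) {
  msg <- character()
  if (object@fieldWidthPx < 1L || object@fieldHeightPx < 1L)
    msg <- c(msg, "field dimensions must be positive")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixel size must be > 0")
  if (object@nRosettes < 0L) msg <- c(msg, "number of rosettes must be >= 0")
  dr <- object@rosetteDiameterRangeUm
  if (length(dr) != 2L || dr[1] <= 0 || dr[1] > dr[2])
    msg <- c(msg, "diameter range must be positive with lo <= hi")
  if (object@ringThicknessUm <= 0 || object@ringThicknessUm > dr[1] / 2)
    msg <- c(msg, "ring thickness must be in (0, lo diameter / 2]")
  if (object@nFibers < 0L) msg <- c(msg, "number of fibres must be >= 0")
  if (object@illuminationGradientAmplitude < 0)
    msg <- c(msg, "illumination amplitude must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noise SD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param fieldWidthPx,fieldHeightPx,pixelSizeUm,nRosettes see the class
#'   slots.
#' @param rosetteDiameterRangeUm,ringThicknessUm,nFibers see the class slots.
#' @param fiberLengthUm,fiberWidthUm,illuminationGradientAmplitude,noiseSd,seed
#'   see the class slots.
#' @return `imageSimParams()` returns an [ImageSimParams-class] object.
#' @rdname ImageSimParams-class
#' @examples
#' imageSimParams(nRosettes = 3, seed = 7)
#' @export
imageSimParams <- function(fieldWidthPx = 512, fieldHeightPx = 512,
                           pixelSizeUm = 0.25, nRosettes = 5,
                           rosetteDiameterRangeUm = c(5, 7),
                           ringThicknessUm = 1, nFibers = 5,
                           fiberLengthUm = 20, fiberWidthUm = 1,
                           illuminationGradientAmplitude = 0.2,
                           noiseSd = 0.05, seed = 1) {
  new("ImageSimParams",
      fieldWidthPx = as.integer(fieldWidthPx),
      fieldHeightPx = as.integer(fieldHeightPx),
      pixelSizeUm = as.numeric(pixelSizeUm),
      nRosettes = as.integer(nRosettes),
      rosetteDiameterRangeUm = as.numeric(rosetteDiameterRangeUm),
      ringThicknessUm = as.numeric(ringThicknessUm),
      nFibers = as.integer(nFibers),
      fiberLengthUm = as.numeric(fiberLengthUm),
      fiberWidthUm = as.numeric(fiberWidthUm),
      illuminationGradientAmplitude =
        as.numeric(illuminationGradientAmplitude),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

## rejection-sample a point at least minSep from previous points and margin
## from the field border; coordinates in um (pixel-centre frame)
.placePoints <- function(n, wUm, hUm, margin, minSep, what) {
  pts <- matrix(numeric(), 0, 2)
  if (n == 0L) return(pts)
  if (wUm - 2 * margin <= 0 || hUm - 2 * margin <= 0)
    stop("field too small to place the requested ", what)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      p <- c(runif(1, margin, wUm - margin), runif(1, margin, hUm - margin))
      if (!nrow(pts) || all(sqrt(rowSums((pts - rep(p, each = nrow(pts)))^2))
                            >= minSep)) {
        pts <- rbind(pts, p)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("field too small to place the requested ", what,
           " without overlap")
  }
  pts
}

#' Simulate a rosette-bearing fluorescence field
#'
#' Renders `nRosettes` annular rosettes (bright ring of amplitude 1 around
#' a dimmer core of 0.35, over a baseline of 0.1) and `nFibers` elongated
#' fibre bars on a field with a multiplicative linear illumination gradient
#' and additive Gaussian noise. Structure edges carry a one-pixel linear
#' coverage ramp emulating optical blur. Structure centres are mutually
#' separated by at least one rosette diameter. The same parameters and
#' seed always give bit-identical output.
#'
#' @param params an [ImageSimParams-class] object.
#' @return A list:
#' \describe{
#'   \item{image}{[CalibratedImage-class] of the field.}
#'   \item{truth}{list with `rosetteCount`, a `rosettes` data.frame
#'     (`center_x_px`, `center_y_px`, `diameter_um`) and `labelMask`, an
#'     integer matrix labelling each rosette's full disk 1..n.}
#' }
#' @examples
#' sim <- simulateRosetteField(imageSimParams(nRosettes = 3, seed = 7))
#' sim$truth$rosetteCount
#' @export
simulateRosetteField <- function(params = imageSimParams()) {
  stopifnot(is(params, "ImageSimParams"))
  validObject(params)
  .withSeed(params@seed, {
    w <- params@fieldWidthPx; h <- params@fieldHeightPx
    px <- params@pixelSizeUm
    wUm <- w * px; hUm <- h * px
    dHi <- params@rosetteDiameterRangeUm[2]
    baseline <- 0.1; ringAmp <- 1; coreAmp <- 0.35; fiberAmp <- 0.9
    # pixel-centre coordinates in um
    xs <- ((seq_len(w) - 0.5) * px)
    ys <- ((seq_len(h) - 0.5) * px)
    X <- matrix(xs, h, w, byrow = TRUE)
    Y <- matrix(ys, h, w)
    img <- matrix(baseline, h, w)
    labelMask <- matrix(0L, h, w)
    rosettes <- data.frame(center_x_px = numeric(), center_y_px = numeric(),
                           diameter_um = numeric())
    # centres at least one (largest) diameter apart, edge to edge clear
    centers <- .placePoints(params@nRosettes, wUm, hUm,
                            margin = dHi / 2 + 1, minSep = 2 * dHi,
                            what = "rosettes")
    diams <- if (params@nRosettes)
      runif(params@nRosettes, params@rosetteDiameterRangeUm[1], dHi)
      else numeric()
    # soft (one-pixel) edges emulate optical blur and keep thin structures
    # intact under rasterization
    edge <- px
    S <- function(v) pmin(1, pmax(0, v / edge + 0.5))
    for (i in seq_len(params@nRosettes)) {
      r <- diams[i] / 2
      d <- sqrt((X - centers[i, 1])^2 + (Y - centers[i, 2])^2)
      ringCov <- S(d - (r - params@ringThicknessUm)) * S(r - d)
      coreCov <- S((r - params@ringThicknessUm) - d)
      img <- img + ringAmp * ringCov + coreAmp * coreCov
      labelMask[d <= r] <- i
      rosettes <- rbind(rosettes, data.frame(
        center_x_px = centers[i, 1] / px - 0.5,
        center_y_px = centers[i, 2] / px - 0.5,
        diameter_um = diams[i]))
    }
    # fibre distractors: segments kept clear of the rosettes
    halfL <- params@fiberLengthUm / 2
    halfW <- params@fiberWidthUm / 2
    placed <- 0L
    for (try in seq_len(5000L)) {
      if (placed >= params@nFibers) break
      c0 <- c(runif(1, halfL, wUm - halfL), runif(1, halfL, hUm - halfL))
      th <- runif(1, 0, pi)
      u <- c(cos(th), sin(th))
      a <- c0 - halfL * u; b <- c0 + halfL * u
      if (nrow(centers)) {
        dseg <- vapply(seq_len(nrow(centers)), function(j)
          .pointSegDist(centers[j, ], a, b), numeric(1))
        if (any(dseg < dHi / 2 + halfW + 2)) next
      }
      # distance of each pixel centre to segment ab
      t <- pmin(1, pmax(0, ((X - a[1]) * (b[1] - a[1]) +
                            (Y - a[2]) * (b[2] - a[2])) /
                           sum((b - a)^2)))
      dd <- sqrt((X - (a[1] + t * (b[1] - a[1])))^2 +
                 (Y - (a[2] + t * (b[2] - a[2])))^2)
      img <- img + fiberAmp * S(halfW - dd)
      placed <- placed + 1L
    }
    if (placed < params@nFibers)
      stop("field too small to place the requested fibres without overlap")
    # multiplicative illumination gradient along a random direction
    if (params@illuminationGradientAmplitude > 0) {
      ang <- runif(1, 0, 2 * pi)
      proj <- (X * cos(ang) + Y * sin(ang))
      proj <- (proj - min(proj)) / max(1e-12, diff(range(proj))) - 0.5
      img <- img * (1 + params@illuminationGradientAmplitude * proj)
    }
    if (params@noiseSd > 0)
      img <- img + matrix(rnorm(h * w, sd = params@noiseSd), h, w)
    img <- pmax(img, 0)
    list(
      image = CalibratedImage(img, px, "red"),
      truth = list(rosetteCount = params@nRosettes, rosettes = rosettes,
                   labelMask = labelMask))
  })
}

.pointSegDist <- function(p, a, b) {
  ab <- b - a
  t <- min(1, max(0, sum((p - a) * ab) / sum(ab^2)))
  sqrt(sum((a + t * ab - p)^2))
}

#' Simulate an in situ zymography image pair
#'
#' Generates a fluorescent-gelatin image that is uniformly bright except
#' for `nHoles` dark degradation disks, and a matching nuclei image with
#' `nNuclei` bright blobs. Each hole is rasterized to exactly
#' `round(holeAreaUm2 / pixelSize^2)` pixels (nearest pixels to the hole
#' centre), so the ground-truth degraded area is exact by construction.
#'
#' @param nHoles number of degradation holes, >= 0.
#' @param holeAreaUm2 area of each hole (um^2).
#' @param nNuclei number of nuclei, >= 0.
#' @param seed integer seed.
#' @param fieldWidthPx,fieldHeightPx,pixelSizeUm field geometry.
#' @return A list with `gelatin` and `nuclei` ([CalibratedImage-class])
#'   and `truth` (`degradedAreaUm2`, `nucleusCount`, `holeMask`).
#' @examples
#' z <- simulateZymographyPair(10, 20, 5, seed = 3)
#' z$truth$degradedAreaUm2
#' @export
simulateZymographyPair <- function(nHoles, holeAreaUm2, nNuclei, seed = 1,
                                   fieldWidthPx = 256, fieldHeightPx = 256,
                                   pixelSizeUm = 0.5) {
  stopifnot(nHoles >= 0, nNuclei >= 0, holeAreaUm2 > 0, pixelSizeUm > 0)
  .withSeed(seed, {
    w <- as.integer(fieldWidthPx); h <- as.integer(fieldHeightPx)
    px <- pixelSizeUm
    wUm <- w * px; hUm <- h * px
    holeR <- sqrt(holeAreaUm2 / pi)
    xs <- (seq_len(w) - 0.5) * px
    ys <- (seq_len(h) - 0.5) * px
    X <- matrix(xs, h, w, byrow = TRUE)
    Y <- matrix(ys, h, w)
    gelatin <- matrix(1, h, w)
    holeMask <- matrix(FALSE, h, w)
    nPixHole <- max(1L, as.integer(round(holeAreaUm2 / px^2)))
    centers <- .placePoints(nHoles, wUm, hUm, margin = holeR + 1,
                            minSep = 2 * holeR + 2, what = "holes")
    for (i in seq_len(nHoles)) {
      d <- (X - centers[i, 1])^2 + (Y - centers[i, 2])^2
      sel <- order(d)[seq_len(nPixHole)]
      gelatin[sel] <- 0.1
      holeMask[sel] <- TRUE
    }
    nuclei <- matrix(0.05, h, w)
    nucR <- 4
    nc <- .placePoints(nNuclei, wUm, hUm, margin = nucR + 1,
                       minSep = 2 * nucR + 2, what = "nuclei")
    for (i in seq_len(nNuclei)) {
      d <- sqrt((X - nc[i, 1])^2 + (Y - nc[i, 2])^2)
      nuclei[d <= nucR] <- nuclei[d <= nucR] + 1
    }
    list(
      gelatin = CalibratedImage(gelatin, px, "green"),
      nuclei = CalibratedImage(nuclei, px, "blue"),
      truth = list(degradedAreaUm2 = sum(holeMask) * px^2,
                   nucleusCount = as.integer(nNuclei),
                   holeMask = holeMask))
  })
}
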