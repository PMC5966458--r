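## High-content quantification of invadosome phenotypes: rosettes per
## nucleus across fields, gelatin degradation per cell, and the group
## statistics used for multi-condition plates.

## separable Gaussian smoothing with reflect padding
.gaussianSmooth <- function(m, sigma) {
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  sm1 <- function(mat) {  # smooth along rows (dimension 1), reflect edges
    n <- nrow(mat)
    idx <- vapply(-half:half, function(d) {
      j <- (seq_len(n) + d - 1L) %% (2L * n)   # triangular reflection,
      j[j < 0L] <- j[j < 0L] + 2L * n          # robust to any kernel width
      ifelse(j >= n, 2L * n - 1L - j, j) + 1L
    }, integer(n))
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(k)) out <- out + k[j] * mat[idx[, j], , drop = FALSE]
    out
  }
  t(sm1(t(sm1(m))))
}

#' Correct uneven illumination
#'
#' Divides the image by a heavily smoothed (Gaussian, scale `sigmaPx`)
#' estimate of the illumination field and rescales so the image mean is
#' preserved exactly. A flat image is returned unchanged (up to floating
#' point).
#'
#' @param img [CalibratedImage-class] or matrix.
#' @param sigmaPx Gaussian scale in pixels, > 0.
#' @return Corrected image of the same class as the input.
#' @examples
#' m <- matrix(1, 64, 64) * seq(0.9, 1.1, length.out = 64)
#' range(pixels(correctIllumination(CalibratedImage(m, 0.5), 30)))
#' @export
correctIllumination <- function(img, sigmaPx = 50) {
  if (length(sigmaPx) != 1L || !is.finite(sigmaPx) || sigmaPx <= 0)
    stop("illumination sigma must be a single positive number")
  m <- .imageMatrix(img)
  field <- .gaussianSmooth(m, sigmaPx)
  field[field <= 0] <- mean(field[field > 0])
  out <- m / field
  out <- out * (mean(m) / mean(out))
  .rewrap(img, out)
}

#' White top-hat enhancement
#'
#' Image minus its grayscale opening by a flat disk of the given radius:
#' flat regions and structures broader than the disk are suppressed to
#' approximately zero while narrower features keep their amplitude. This
#' is the enhancement applied to the invadosome channel before object
#' detection.
#'
#' @param img [CalibratedImage-class] or matrix.
#' @param radiusPx disk radius in pixels, >= 1.
#' @return Enhanced image of the same class as the input.
#' @examples
#' m <- matrix(0, 48, 48); m[20:28, 20:28] <- 1
#' max(tophatEnhance(m, 15))
#' @export
tophatEnhance <- function(img, radiusPx = 15) {
  if (length(radiusPx) != 1L || is.na(radiusPx) || radiusPx < 1)
    stop("top-hat radius must be a single value >= 1")
  m <- .imageMatrix(img)
  g <- .diskOffsets(radiusPx)
  .rewrap(img, m - .grayOpen(m, g$dr, g$dc))
}

#' Detect candidate invadosome objects
#'
#' Primary object detection followed by morphological refinement:
#' automated thresholding, 8-connected labelling with hole filling, then
#' filtering on area range, major and minor ellipse-axis length range and
#' minimum solidity. Merged objects are not declumped -- touching
#' structures count as one, which is the documented behaviour.
#'
#' @param img enhanced (or raw) [CalibratedImage-class] or matrix; when a
#'   matrix is supplied the pixel size defaults to 1 um/px.
#' @param params an [HcaParams-class].
#' @return A [RegionSet-class]; a degenerate (constant) image yields zero
#'   regions.
#' @examples
#' sim <- simulateRosetteField(imageSimParams(nRosettes = 3, seed = 5))
#' nRegions(detectObjects(tophatEnhance(sim$image), hcaParams()))
#' @export
detectObjects <- function(img, params = hcaParams()) {
  stopifnot(is(params, "HcaParams"))
  validObject(params)
  px <- if (is(img, "CalibratedImage")) pixelSize(img) else 1
  mask <- tryCatch(autoThreshold(img, params@thresholdMethod),
                   degenerateHistogramError = function(e) NULL)
  if (is.null(mask)) {
    m <- .imageMatrix(img)
    return(new("RegionSet", mask = matrix(0L, nrow(m), ncol(m)),
               table = .emptyRegionTable(), pixelSizeUm = as.numeric(px),
               connectivity = 8L))
  }
  mask <- .cppFillHoles(mask, 8L)
  regions <- labelRegions(mask, px, 8L)
  tab <- regionTable(regions)
  if (nrow(tab)) {
    keep <- tab$area_um2 >= params@areaRangeUm2[1] &
      tab$area_um2 <= params@areaRangeUm2[2] &
      tab$major_axis_um >= params@axisRangeUm[1] &
      tab$major_axis_um <= params@axisRangeUm[2] &
      tab$minor_axis_um >= params@axisRangeUm[1] &
      tab$minor_axis_um <= params@axisRangeUm[2] &
      tab$solidity >= params@solidityMin
    tab <- tab[keep, , drop = FALSE]
    rownames(tab) <- NULL
  }
  initialize(regions, table = tab)
}

#' Count nuclei
#'
#' Primary object detection on the nuclei channel with no shape
#' refinement beyond a minimum area. Merged nuclei (no declumping) count
#' as one object.
#'
#' @param img nuclei-channel [CalibratedImage-class] or matrix.
#' @param params an [HcaParams-class] (uses `minNucleusAreaUm2` and the
#'   threshold method).
#' @return Integer count.
#' @examples
#' z <- simulateZymographyPair(0, 20, 5, seed = 9)
#' countNuclei(z$nuclei, hcaParams())
#' @export
countNuclei <- function(img, params = hcaParams()) {
  stopifnot(is(params, "HcaParams"))
  px <- if (is(img, "CalibratedImage")) pixelSize(img) else 1
  mask <- tryCatch(autoThreshold(img, params@thresholdMethod),
                   degenerateHistogramError = function(e) NULL)
  if (is.null(mask)) return(0L)
  regions <- labelRegions(mask, px, 8L)
  tab <- regionTable(regions)
  sum(tab$area_um2 >= params@minNucleusAreaUm2)
}

#' Rosettes per nucleus
#'
#' @param rosetteCount,nucleiCount non-negative counts; `nucleiCount`
#'   must be positive -- fields without nuclei are excluded upstream and
#'   raise an error here.
#' @return Exact quotient.
#' @examples
#' rosettesPerNucleus(12, 4)
#' @export
rosettesPerNucleus <- function(rosetteCount, nucleiCount) {
  stopifnot(rosetteCount >= 0)
  if (length(nucleiCount) != 1L || nucleiCount <= 0)
    stop("rosettes per nucleus is undefined for a field without nuclei")
  rosetteCount / nucleiCount
}

#' Gelatin area degraded per cell
#'
#' Degraded area is the calibrated area of pixels falling below an
#' automated threshold on the (optionally illumination-corrected)
#' fluorescent-gelatin channel -- degradation appears dark -- divided by
#' the nucleus count. A uniform gelatin image has no degraded area.
#'
#' @param gelatinImg fluorescent-gelatin [CalibratedImage-class] or
#'   matrix.
#' @param nucleiCount positive cell count for the field.
#' @param params an [HcaParams-class].
#' @param correctIllum apply [correctIllumination()] first (default
#'   `TRUE`).
#' @return Degraded area per cell in um^2/cell.
#' @examples
#' z <- simulateZymographyPair(10, 20, 5, seed = 3)
#' degradedAreaPerCell(z$gelatin, z$truth$nucleusCount)  # ~ 40
#' @export
degradedAreaPerCell <- function(gelatinImg, nucleiCount,
                                params = hcaParams(), correctIllum = TRUE) {
  stopifnot(is(params, "HcaParams"))
  if (length(nucleiCount) != 1L || nucleiCount <= 0)
    stop("degraded area per cell is undefined for a field without nuclei")
  px <- if (is(gelatinImg, "CalibratedImage")) pixelSize(gelatinImg) else 1
  img <- if (correctIllum)
    correctIllumination(gelatinImg, params@illuminationSigmaPx)
  else gelatinImg
  mask <- tryCatch(autoThreshold(img, params@thresholdMethod),
                   degenerateHistogramError = function(e) NULL)
  if (is.null(mask)) return(0)
  degradedPx <- sum(!mask)  # at or below threshold = degraded
  degradedPx * px^2 / nucleiCount
}

#' Compare phenotype values across conditions
#'
#' One-way ANOVA over all conditions followed by pairwise comparisons of
#' each condition against the control, using the pooled within-group
#' standard deviation from the ANOVA (the classical Bonferroni
#' multiple-comparison post test) with p values multiplied by the number
#' of comparisons and capped at 1. Means are called significantly
#' different at p < 0.05.
#'
#' When every group's within-group variance is zero the ANOVA is
#' degenerate: identical means give F = 0 and p = 1; differing means give
#' p = 0, each with a warning.
#'
#' @param valuesByCondition named list of numeric vectors, one per
#'   condition; at least two conditions with two values each.
#' @param controlLabel name of the control condition.
#' @param alpha significance level (default 0.05).
#' @return A list with `F`, `p`, `df` (between, within) and `comparisons`
#'   (data.frame `condition`, `mean_diff`, `t`, `p_raw`, `p_adj`,
#'   `significant`).
#' @examples
#' compareGroups(list(ctrl = c(1, 2, 3), treated = c(4, 5, 6)), "ctrl")
#' @export
compareGroups <- function(valuesByCondition, controlLabel, alpha = 0.05) {
  stopifnot(is.list(valuesByCondition), length(valuesByCondition) >= 2L)
  if (!controlLabel %in% names(valuesByCondition))
    stop("control condition '", controlLabel, "' not found")
  sizes <- vapply(valuesByCondition, length, integer(1))
  if (any(sizes < 2L))
    stop("every condition needs at least 2 values; offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  df <- data.frame(
    value = unlist(valuesByCondition, use.names = FALSE),
    condition = factor(rep(names(valuesByCondition), sizes),
                       levels = names(valuesByCondition)))
  # suppress the perfect-fit note from anova(); degenerate cases are
  # detected and reported below with a more specific warning
  an <- suppressWarnings(anova(lm(value ~ condition, data = df)))
  ssb <- an$`Sum Sq`[1L]; ssw <- an$`Sum Sq`[2L]
  dfb <- an$Df[1L]; dfw <- an$Df[2L]
  degenerate <- ssw <= .Machine$double.eps * max(1, ssb)
  if (degenerate) {
    if (ssb <= .Machine$double.eps) {
      warning("all groups identical and constant; F = 0, p = 1")
      fStat <- 0; pAnova <- 1
    } else {
      warning("zero within-group variance with differing means; p = 0")
      fStat <- Inf; pAnova <- 0
    }
  } else {
    fStat <- an$`F value`[1L]
    pAnova <- an$`Pr(>F)`[1L]
  }
  msw <- ssw / dfw
  others <- setdiff(names(valuesByCondition), controlLabel)
  m <- length(others)
  ctrl <- valuesByCondition[[controlLabel]]
  comp <- do.call(rbind, lapply(others, function(g) {
    v <- valuesByCondition[[g]]
    diffMean <- mean(v) - mean(ctrl)
    if (degenerate) {
      t <- if (abs(diffMean) <= .Machine$double.eps) 0 else Inf * sign(diffMean)
      pRaw <- if (abs(diffMean) <= .Machine$double.eps) 1 else 0
    } else {
      se <- sqrt(msw * (1 / length(v) + 1 / length(ctrl)))
      t <- diffMean / se
      pRaw <- 2 * pt(-abs(t), dfw)
    }
    data.frame(condition = g, mean_diff = diffMean, t = t, p_raw = pRaw,
               p_adj = min(1, m * pRaw),
               significant = min(1, m * pRaw) < alpha)
  }))
  rownames(comp) <- NULL
  list(F = fStat, p = pAnova, df = c(between = dfb, within = dfw),
       comparisons = comp)
}

#' Score one field
#'
#' Convenience wrapper combining object detection, nucleus counting and
#' (when a gelatin image is supplied) degradation quantification into the
#' per-field result record.
#'
#' @param structureImg invadosome-channel image.
#' @param nucleiImg nuclei-channel image.
#' @param gelatinImg optional gelatin-channel image.
#' @param params an [HcaParams-class].
#' @param fieldId identifier carried into the result.
#' @return One-row data.frame: `field_id`, `rosette_count`,
#'   `nuclei_count`, `rosettes_per_nucleus`, `degraded_area_um2`,
#'   `degraded_area_per_cell_um2` (the last two `NA` without gelatin
#'   input, the ratio `NA` for fields without nuclei).
#' @export
scoreField <- function(structureImg, nucleiImg, gelatinImg = NULL,
                       params = hcaParams(), fieldId = "field1") {
  enhanced <- tophatEnhance(
    correctIllumination(structureImg, params@illuminationSigmaPx),
    params@tophatRadiusPx)
  rosettes <- nRegions(detectObjects(enhanced, params))
  nuclei <- countNuclei(nucleiImg, params)
  rpn <- if (nuclei > 0) rosettes / nuclei else NA_real_
  degArea <- NA_real_; degPerCell <- NA_real_
  if (!is.null(gelatinImg) && nuclei > 0) {
    degPerCell <- degradedAreaPerCell(gelatinImg, nuclei, params)
    degArea <- degPerCell * nuclei
  }
  data.frame(field_id = fieldId, rosette_count = rosettes,
             nuclei_count = nuclei, rosettes_per_nucleus = rpn,
             degraded_area_um2 = degArea,
             degraded_area_per_cell_um2 = degPerCell)
}
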