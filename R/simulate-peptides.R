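## Seeded generator for SILAC peptide identification tables with known
## ground truth: label status per row and true rosette/total ratio per
## protein.

#' Peptide-table simulation parameters
#'
#' Parameters of the synthetic SILAC peptide-table generator. Peptide MS1
#' areas are log-normal (protein abundance times a per-peptide share) with
#' multiplicative log-normal noise of the given coefficient of variation.
#' A fraction of proteins is enriched in the rosette channel by
#' `enrichmentFactor`; the remaining proteins are depleted by the
#' compensating factor that keeps both channel totals equal, so the true
#' post-normalization ratio of an enriched protein equals
#' `enrichmentFactor` exactly. Contaminating rows (no metabolic label)
#' are appended under dedicated `CON_` accessions so that the realized
#' contaminant fraction matches `contaminantFraction` to within one row.
#'
#' @slot nProteins number of labelled proteins.
#' @slot peptidesPerProteinMean,peptidesPerProteinDispersion negative
#'   binomial specification of peptides per protein (at least 2 peptides
#'   are always generated so every simulated protein is quantifiable).
#' @slot contaminantFraction fraction of classifiable rows that are
#'   contaminants, in \[0, 1\].
#' @slot enrichedSubsetFraction fraction of proteins enriched in the
#'   rosette channel, in \[0, 1\].
#' @slot enrichmentFactor true rosette/total normalized ratio of the
#'   enriched subset, > 0.
#' @slot abundanceNoiseCv coefficient of variation of the multiplicative
#'   peptide-area noise (0 = noise free).
#' @slot dilutionPointsNg strictly increasing protein quantities (ng) of
#'   the standard-curve series.
#' @slot seed integer seed.
#' @aliases PeptideSimParams-class
#' @exportClass PeptideSimParams
setClass("PeptideSimParams",
  representation(
    nProteins = "integer",
    peptidesPerProteinMean = "numeric",
    peptidesPerProteinDispersion = "numeric",
    contaminantFraction = "numeric",
    enrichedSubsetFraction = "numeric",
    enrichmentFactor = "numeric",
    abundanceNoiseCv = "numeric",
    dilutionPointsNg = "numeric",
    seed = "integer"
  ),
  prototype(
    nProteins = 50L,
    peptidesPerProteinMean = 5,
    peptidesPerProteinDispersion = 10,
    contaminantFraction = 0.05,
    enrichedSubsetFraction = 0.25,
    enrichmentFactor = 3,
    abundanceNoiseCv = 0.1,
    dilutionPointsNg = c(10, 25, 50, 100, 200),
    seed = 1L
  )
)

setValidity("PeptideSimParams", function(object) {
  msg <- character()
  if (object@nProteins < 1L) msg <- c(msg, "need at least one protein")
  if (object@peptidesPerProteinMean <= 0 ||
      object@peptidesPerProteinDispersion <= 0)
    msg <- c(msg, "peptides-per-protein mean and dispersion must be > 0")
  if (object@contaminantFraction < 0 || object@contaminantFraction > 1)
    msg <- c(msg, "contaminant fraction must be in [0, 1]")
  if (object@enrichedSubsetFraction < 0 ||
      object@enrichedSubsetFraction > 1)
    msg <- c(msg, "enriched subset fraction must be in [0, 1]")
  if (object@enrichmentFactor <= 0)
    msg <- c(msg, "enrichment factor must be > 0")
  if (object@abundanceNoiseCv < 0) msg <- c(msg, "noise CV must be >= 0")
  dp <- object@dilutionPointsNg
  if (length(dp) < 2L || any(dp <= 0) || any(diff(dp) <= 0))
    msg <- c(msg, "dilution points must be strictly increasing and positive")
  if (length(msg)) msg else TRUE
})

#' @param nProteins,peptidesPerProteinMean,peptidesPerProteinDispersion see
#'   the class slots.
#' @param contaminantFraction,enrichedSubsetFraction,enrichmentFactor see
#'   the class slots.
#' @param abundanceNoiseCv,dilutionPointsNg,seed see the class slots.
#' @return `peptideSimParams()` returns a [PeptideSimParams-class] object.
#' @rdname PeptideSimParams-class
#' @examples
#' peptideSimParams(nProteins = 20, enrichmentFactor = 3)
#' @export
peptideSimParams <- function(nProteins = 50, peptidesPerProteinMean = 5,
                             peptidesPerProteinDispersion = 10,
                             contaminantFraction = 0.05,
                             enrichedSubsetFraction = 0.25,
                             enrichmentFactor = 3, abundanceNoiseCv = 0.1,
                             dilutionPointsNg = c(10, 25, 50, 100, 200),
                             seed = 1) {
  new("PeptideSimParams",
      nProteins = as.integer(nProteins),
      peptidesPerProteinMean = as.numeric(peptidesPerProteinMean),
      peptidesPerProteinDispersion =
        as.numeric(peptidesPerProteinDispersion),
      contaminantFraction = as.numeric(contaminantFraction),
      enrichedSubsetFraction = as.numeric(enrichedSubsetFraction),
      enrichmentFactor = as.numeric(enrichmentFactor),
      abundanceNoiseCv = as.numeric(abundanceNoiseCv),
      dilutionPointsNg = as.numeric(dilutionPointsNg),
      seed = as.integer(seed))
}

## random tryptic peptide: interior drawn without K/R, C-terminal K or R
.randomTrypticSequence <- function(n = 1L, minLen = 7L, maxLen = 15L) {
  interior <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    len <- sample(minLen:maxLen, 1L)
    paste0(paste(sample(interior, len - 1L, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, character(1))
}

## full 13C6 modification string for a sequence: every K/R position tagged
.fullLabelMods <- function(sequence, modName = "13C6") {
  chars <- strsplit(sequence, "")[[1]]
  pos <- which(chars %in% c("K", "R"))
  if (!length(pos)) return("")
  paste(sprintf("%s@%s%d", modName, chars[pos], pos), collapse = ";")
}

#' Simulate a SILAC peptide identification table
#'
#' Builds a tryptic peptide table for `nProteins` metabolically labelled
#' proteins plus appended contaminant rows, together with the ground
#' truth needed to validate classification and enrichment recovery.
#' Labelled rows carry the 13C6 modification on every K/R residue;
#' contaminant rows carry none. See [PeptideSimParams-class] for the
#' abundance model.
#'
#' @param params a [PeptideSimParams-class] object.
#' @return A list:
#' \describe{
#'   \item{peptides}{data.frame with columns `peptide_id`, `sequence`,
#'     `protein_acc`, `is_specific`, `modifications`,
#'     `ms1_area_rosette`, `ms1_area_total`.}
#'   \item{proteinTruth}{data.frame `protein_acc`, `true_ratio`,
#'     `enriched_true` (post-normalization rosette/total ratio).}
#'   \item{labelTruth}{data.frame `peptide_id`, `label_status`.}
#'   \item{dilution}{data.frame `quantity_ng`, `summed_area` for the
#'     standard-curve series (slope `1e6` area units per ng before
#'     noise).}
#' }
#' @examples
#' tab <- simulatePeptideTable(peptideSimParams(nProteins = 10, seed = 2))
#' head(tab$peptides)
#' @export
simulatePeptideTable <- function(params = peptideSimParams()) {
  stopifnot(is(params, "PeptideSimParams"))
  validObject(params)
  .withSeed(params@seed, {
    n <- params@nProteins
    acc <- sprintf("PROT%04d", seq_len(n))
    abundance <- rlnorm(n, meanlog = log(1e7), sdlog = 0.8)
    nEnriched <- round(params@enrichedSubsetFraction * n)
    enriched <- seq_len(n) %in% sample(n, nEnriched)
    f <- params@enrichmentFactor
    # compensating depletion factor keeps the rosette channel total equal
    # to the total channel total, making normalized ratios exact; the
    # enriched subset's abundance share is capped at 0.5 / f so the
    # compensation stays positive for every draw
    sumAll <- sum(abundance)
    sumE <- sum(abundance[enriched])
    factor <- rep(1, n)
    if (nEnriched > 0 && nEnriched < n && f != 1) {
      wMax <- 0.5 / max(f, 1)
      w <- sumE / sumAll
      if (w > wMax) {
        alpha <- wMax * (sumAll - sumE) / (sumE * (1 - wMax))
        abundance[enriched] <- abundance[enriched] * alpha
        sumAll <- sum(abundance)
        sumE <- sum(abundance[enriched])
      }
      d <- (sumAll - f * sumE) / (sumAll - sumE)
      factor <- ifelse(enriched, f, d)
    } else if (nEnriched == n) {
      factor <- rep(f, n)  # global factor cancels under normalization
    }
    nPep <- 2L + rnbinom(n, mu = max(0.1, params@peptidesPerProteinMean - 2),
                         size = params@peptidesPerProteinDispersion)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- nPep[i]
      share <- rlnorm(k, 0, 0.5)
      share <- share / sum(share)
      baseArea <- abundance[i] * share
      noise <- function(m) if (params@abundanceNoiseCv > 0) {
        sdl <- sqrt(log(1 + params@abundanceNoiseCv^2))
        m * rlnorm(k, -sdl^2 / 2, sdl)
      } else m
      seqs <- .randomTrypticSequence(k)
      rows[[i]] <- data.frame(
        sequence = seqs,
        protein_acc = acc[i],
        is_specific = TRUE,
        modifications = vapply(seqs, .fullLabelMods, character(1),
                               USE.NAMES = FALSE),
        ms1_area_rosette = noise(baseArea * factor[i]),
        ms1_area_total = noise(baseArea))
    }
    peptides <- do.call(rbind, rows)
    nLabeled <- nrow(peptides)
    status <- rep("labeled", nLabeled)
    # contaminant rows: unlabelled, under dedicated contaminant accessions
    cf <- params@contaminantFraction
    nCont <- if (cf >= 1) stop("contaminant fraction 1 not supported") else
      as.integer(round(cf * nLabeled / (1 - cf)))
    if (nCont > 0) {
      seqs <- .randomTrypticSequence(nCont)
      cont <- data.frame(
        sequence = seqs,
        protein_acc = sprintf("CON_%04d", sample.int(max(3L, nCont %/% 5L),
                                                     nCont, replace = TRUE)),
        is_specific = TRUE,
        modifications = "",
        ms1_area_rosette = rlnorm(nCont, log(5e5), 1),
        ms1_area_total = rlnorm(nCont, log(5e5), 1))
      peptides <- rbind(peptides, cont)
      status <- c(status, rep("contaminant", nCont))
    }
    peptides <- cbind(peptide_id = sprintf("PEP%05d", seq_len(nrow(peptides))),
                      peptides)
    rownames(peptides) <- NULL
    trueRatio <- factor  # channel totals are equal by construction
    dil <- data.frame(
      quantity_ng = params@dilutionPointsNg,
      summed_area = params@dilutionPointsNg * 1e6)
    if (params@abundanceNoiseCv > 0) {
      sdl <- sqrt(log(1 + params@abundanceNoiseCv^2))
      dil$summed_area <- dil$summed_area *
        rlnorm(nrow(dil), -sdl^2 / 2, sdl)
    }
    list(
      peptides = peptides,
      proteinTruth = data.frame(protein_acc = acc, true_ratio = trueRatio,
                                enriched_true = enriched),
      labelTruth = data.frame(peptide_id = peptides$peptide_id,
                              label_status = status),
      dilution = dil)
  })
}

#' Simulate replicate protein detection
#'
#' Emulates the run-to-run reproducibility of protein identification:
#' from a universe of `nProteins` accessions, each replicate detects each
#' protein independently with probability `detectionProb`. With the
#' default detection probability of 0.7 the expected overlap coefficient
#' between two replicates falls in the published 59--76% reproducibility
#' band.
#'
#' @param nProteins size of the protein universe.
#' @param detectionProb per-protein detection probability per replicate.
#' @param nReplicates number of replicates.
#' @param seed integer seed.
#' @return A list of character vectors of detected accessions, one per
#'   replicate.
#' @examples
#' reps <- simulateReplicateDetection(500, seed = 4)
#' replicateOverlap(reps[[1]], reps[[2]])
#' @export
simulateReplicateDetection <- function(nProteins = 500, detectionProb = 0.7,
                                       nReplicates = 2, seed = 1) {
  stopifnot(nProteins >= 1, detectionProb > 0, detectionProb <= 1,
            nReplicates >= 2)
  .withSeed(seed, {
    acc <- sprintf("PROT%04d", seq_len(nProteins))
    lapply(seq_len(nReplicates), function(i)
      acc[runif(nProteins) < detectionProb])
  })
}
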