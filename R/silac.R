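## SILAC specificity filtering and label-free enrichment quantification.
## Peptides from metabolically labelled cells carry the 13C6 modification
## on every K/R; identified peptides lacking it originate outside the
## labelled cells (handling contamination) and are excluded from protein
## inference.

## parse "13C6@K4;13C6@R7" into a data.frame(mod, residue, pos)
.parseModifications <- function(modString) {
  if (is.na(modString) || !nzchar(modString))
    return(data.frame(mod = character(), residue = character(),
                      pos = integer()))
  parts <- strsplit(modString, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(.+)@([A-Z])([0-9]+)$", parts))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("malformed modification entry: ", paste(parts[bad], collapse = ", "))
  data.frame(mod = vapply(m, `[`, character(1), 2L),
             residue = vapply(m, `[`, character(1), 3L),
             pos = as.integer(vapply(m, `[`, character(1), 4L)))
}

#' Classify peptides as labelled, contaminant or indeterminate
#'
#' A peptide is `labeled` when every labellable residue (K/R by default)
#' in its sequence carries the heavy-isotope modification, `contaminant`
#' when it has at least one labellable residue of which at least one is
#' unmodified (partial labels count as contamination, since metabolic
#' label incorporation is complete in the labelled cells), and
#' `indeterminate` when the sequence contains no labellable residue at
#' all -- such peptides cannot be assigned either way.
#'
#' @param peptides data.frame with at least `sequence` and
#'   `modifications` columns (semicolon-separated entries such as
#'   `"13C6@K4"`).
#' @param scheme a [LabelingScheme-class].
#' @return The input data.frame with a `label_status` column appended.
#' @examples
#' tab <- data.frame(sequence = c("ACDK", "ACDK", "ACDEF"),
#'                   modifications = c("13C6@K4", "", ""))
#' classifyPeptideLabels(tab)$label_status
#' @export
classifyPeptideLabels <- function(peptides, scheme = labelingScheme()) {
  stopifnot(is.data.frame(peptides),
            all(c("sequence", "modifications") %in% names(peptides)),
            is(scheme, "LabelingScheme"))
  res <- character(nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    seqChars <- strsplit(peptides$sequence[i], "")[[1]]
    sites <- which(seqChars %in% scheme@labeledResidues)
    mods <- .parseModifications(peptides$modifications[i])
    labelMods <- mods[mods$mod == scheme@modName, , drop = FALSE]
    if (nrow(labelMods)) {
      if (any(labelMods$pos < 1L | labelMods$pos > length(seqChars)))
        stop("modification position outside sequence in row ", i)
      resAt <- seqChars[labelMods$pos]
      if (any(resAt != labelMods$residue))
        stop("modification residue does not match sequence in row ", i)
      if (any(!resAt %in% scheme@labeledResidues))
        stop("label modification on a non-labellable residue in row ", i)
    }
    res[i] <- if (!length(sites)) "indeterminate"
      else if (all(sites %in% labelMods$pos)) "labeled"
      else "contaminant"
  }
  peptides$label_status <- res
  peptides
}

#' Expected heavy-label mass shift of a peptide
#'
#' @param sequence character vector of peptide sequences.
#' @param scheme a [LabelingScheme-class].
#' @return Mass shift in Dalton if the peptide were fully labelled:
#'   number of labellable residues times the per-residue shift
#'   (6.02013 Da for 13C6).
#' @examples
#' labelMassShift("ACDKGR")  # 2 * 6.02013
#' @export
labelMassShift <- function(sequence, scheme = labelingScheme()) {
  stopifnot(is(scheme, "LabelingScheme"))
  vapply(sequence, function(s) {
    chars <- strsplit(s, "")[[1]]
    sum(chars %in% scheme@labeledResidues) * scheme@massShiftDa
  }, numeric(1), USE.NAMES = FALSE)
}

#' Contamination fraction of a classified peptide table
#'
#' Fraction of classifiable peptides that are contaminants:
#' contaminant / (labelled + contaminant). Indeterminate peptides (no
#' labellable residue) are excluded from numerator and denominator.
#'
#' @param peptides data.frame with a `label_status` column (see
#'   [classifyPeptideLabels()]).
#' @return Scalar fraction in \[0, 1\].
#' @examples
#' tab <- data.frame(label_status = c(rep("labeled", 10),
#'                                    rep("contaminant", 10),
#'                                    rep("indeterminate", 7)))
#' contaminationFraction(tab)  # 0.5
#' @export
contaminationFraction <- function(peptides) {
  stopifnot(is.data.frame(peptides), "label_status" %in% names(peptides))
  nLab <- sum(peptides$label_status == "labeled")
  nCon <- sum(peptides$label_status == "contaminant")
  if (nLab + nCon == 0L)
    stop("no classifiable (labelled or contaminant) peptides")
  nCon / (nLab + nCon)
}

#' Infer proteins from labelled specific peptides
#'
#' Groups labelled peptides by protein accession, counts specific
#' peptides (those assigned to exactly one protein group, as flagged by
#' the input's `is_specific` column) and retains proteins with at least
#' `minSpecific` of them. Protein abundance is the sum of the
#' specific-peptide MS1 areas; shared peptides contribute to neither the
#' count nor the abundance. Contaminant and indeterminate peptides never
#' contribute.
#'
#' @param peptides classified data.frame (see [classifyPeptideLabels()])
#'   with `protein_acc`, `is_specific` and the area column.
#' @param minSpecific minimum number of specific peptides (default 2, the
#'   published identification rule).
#' @param areaColumn name of the MS1 area column to sum.
#' @return data.frame `protein_acc`, `n_specific`, `abundance`, sorted by
#'   accession.
#' @examples
#' tab <- data.frame(sequence = c("AAAK", "CCCK", "DDDK"),
#'                   modifications = c("13C6@K4", "13C6@K4", "13C6@K4"),
#'                   protein_acc = c("P1", "P1", "P2"),
#'                   is_specific = c(TRUE, FALSE, TRUE),
#'                   ms1_area = c(10, 5, 7))
#' inferProteins(classifyPeptideLabels(tab), minSpecific = 1,
#'               areaColumn = "ms1_area")
#' @export
inferProteins <- function(peptides, minSpecific = 2,
                          areaColumn = "ms1_area_rosette") {
  stopifnot(is.data.frame(peptides),
            all(c("protein_acc", "is_specific", "label_status", areaColumn)
                %in% names(peptides)),
            minSpecific >= 0)
  sel <- peptides$label_status == "labeled" & peptides$is_specific
  if (!any(sel))
    return(data.frame(protein_acc = character(), n_specific = integer(),
                      abundance = numeric()))
  sub <- peptides[sel, , drop = FALSE]
  agg <- aggregate(sub[[areaColumn]], by = list(protein_acc = sub$protein_acc),
                   FUN = sum)
  cnt <- aggregate(rep(1L, nrow(sub)),
                   by = list(protein_acc = sub$protein_acc), FUN = sum)
  out <- merge(cnt, agg, by = "protein_acc")
  names(out) <- c("protein_acc", "n_specific", "abundance")
  out <- out[out$n_specific >= minSpecific, , drop = FALSE]
  out <- out[order(out$protein_acc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize protein abundances by total intensity
#'
#' Divides each protein's abundance by the sample's summed abundance, so
#' normalized abundances sum to 1 and downstream ratios are invariant
#' under global rescaling of the raw intensities.
#'
#' @param proteins data.frame with an `abundance` column (see
#'   [inferProteins()]).
#' @return The data.frame with a `normalized_abundance` column appended.
#' @examples
#' normalizeAbundances(data.frame(protein_acc = c("A", "B"),
#'                                abundance = c(10, 30)))
#' @export
normalizeAbundances <- function(proteins) {
  stopifnot(is.data.frame(proteins), "abundance" %in% names(proteins))
  tot <- sum(proteins$abundance)
  if (!is.finite(tot) || tot <= 0)
    stop("cannot normalize: sample total abundance is zero")
  proteins$normalized_abundance <- proteins$abundance / tot
  proteins
}

#' Protein enrichment table
#'
#' Compares normalized abundances between the dissected (rosette) sample
#' and the whole-proteome reference. For proteins detected in both, the
#' ratio is `normalized rosette / normalized total` and a protein is
#' called enriched when the ratio is at least `ratioThreshold`
#' (inclusive; the published cut-off 1.5 corresponds to log2 ratio
#' 0.585, printed as 0.6). Proteins detected in only one sample are
#' reported with status `rosette_only` / `total_only`, carry `NA` ratios
#' and are never flagged enriched.
#'
#' @param rosette,total normalized protein data.frames (see
#'   [normalizeAbundances()]).
#' @param ratioThreshold inclusive enrichment threshold (default 1.5).
#' @return data.frame with columns `protein_acc`, `n_specific`,
#'   `norm_rosette`, `norm_total`, `ratio`, `log2_ratio`, `enriched`,
#'   `status`.
#' @examples
#' ros <- normalizeAbundances(data.frame(protein_acc = c("A", "B"),
#'                                       abundance = c(10, 30)))
#' tot <- normalizeAbundances(data.frame(protein_acc = c("A", "B"),
#'                                       abundance = c(5, 35)))
#' enrichmentTable(ros, tot)
#' @export
enrichmentTable <- function(rosette, total, ratioThreshold = 1.5) {
  stopifnot(is.data.frame(rosette), is.data.frame(total),
            "normalized_abundance" %in% names(rosette),
            "normalized_abundance" %in% names(total),
            ratioThreshold > 0)
  ros <- rosette[, intersect(c("protein_acc", "n_specific",
                               "normalized_abundance"), names(rosette))]
  names(ros)[names(ros) == "normalized_abundance"] <- "norm_rosette"
  tot <- total[, c("protein_acc", "normalized_abundance")]
  names(tot)[2L] <- "norm_total"
  out <- merge(ros, tot, by = "protein_acc", all = TRUE)
  out$status <- ifelse(is.na(out$norm_rosette), "total_only",
                       ifelse(is.na(out$norm_total), "rosette_only",
                              "both_detected"))
  out$ratio <- ifelse(out$status == "both_detected",
                      out$norm_rosette / out$norm_total, NA_real_)
  out$log2_ratio <- ifelse(is.na(out$ratio), NA_real_, log2(out$ratio))
  # inclusive bound, robust to floating-point round-off at the threshold
  out$enriched <- !is.na(out$ratio) &
    out$ratio >= ratioThreshold * (1 - 1e-12)
  out <- out[order(out$protein_acc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a peptide-quantity dilution curve
#'
#' Ordinary least-squares line (free intercept, unweighted) through the
#' dilution series of injected quantity (ng) versus summed MS1 area of
#' all detected 13C peptides.
#'
#' @param points data.frame with columns `quantity_ng` (strictly
#'   increasing, positive) and `summed_area`; at least two points.
#' @return A [DilutionCurve-class].
#' @examples
#' fitDilutionCurve(data.frame(quantity_ng = c(25, 50, 100),
#'                             summed_area = c(50, 100, 200)))
#' @export
fitDilutionCurve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("quantity_ng", "summed_area") %in% names(points)))
  if (nrow(points) < 2L)
    stop("at least 2 dilution points are required")
  if (any(points$quantity_ng <= 0) || any(diff(points$quantity_ng) <= 0))
    stop("dilution quantities must be strictly increasing and positive")
  fit <- lm(summed_area ~ quantity_ng, data = points)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0)
    stop("non-informative dilution curve: slope is not positive")
  ssRes <- sum((points$summed_area - fitted(fit))^2)
  ssTot <- sum((points$summed_area - mean(points$summed_area))^2)
  r2 <- if (ssTot <= 0) 1 else 1 - ssRes / ssTot
  new("DilutionCurve", points = points[order(points$quantity_ng), ],
      slope = slope, intercept = unname(coef(fit)[1L]), rSquared = r2)
}

#' Estimate sample peptide quantity from a dilution curve
#'
#' Inverts the fitted line: `quantity = (area - intercept) / slope`.
#' Also reports the dilution point closest to the estimate -- distance
#' measured on the log scale, the natural metric for a geometric dilution
#' series, with ties resolved to the larger point -- since downstream
#' label-free comparison uses the closest measured point of the range as
#' the reference injection. Estimates beyond twice the largest dilution
#' point are flagged with a warning.
#'
#' @param curve a [DilutionCurve-class].
#' @param summedArea summed 13C MS1 area of the sample.
#' @param rangePointsNg candidate reference quantities; defaults to the
#'   curve's own dilution points.
#' @return A list with `quantity_ng`, `nearest_point_ng` and
#'   `extrapolated`.
#' @examples
#' cv <- fitDilutionCurve(data.frame(quantity_ng = c(25, 50, 100),
#'                                   summed_area = c(50, 100, 200)))
#' estimateQuantity(cv, 144)  # 72 ng, reference point 100 ng
#' @export
estimateQuantity <- function(curve, summedArea, rangePointsNg = NULL) {
  stopifnot(is(curve, "DilutionCurve"), is.numeric(summedArea),
            length(summedArea) == 1L)
  ng <- (summedArea - curve@intercept) / curve@slope
  hi <- max(curve@points$quantity_ng)
  extrapolated <- ng > 2 * hi
  if (extrapolated)
    warning("estimate (", signif(ng, 4),
            " ng) extrapolates beyond twice the largest dilution point")
  if (is.null(rangePointsNg)) rangePointsNg <- curve@points$quantity_ng
  nearest <- NA_real_
  if (ng > 0) {
    d <- abs(log(rangePointsNg) - log(ng))
    best <- which(d == min(d))
    nearest <- max(rangePointsNg[best])  # ties to the larger point
  } else {
    warning("non-positive quantity estimate; nearest point chosen by ",
            "absolute distance")
    d <- abs(rangePointsNg - ng)
    best <- which(d == min(d))
    nearest <- max(rangePointsNg[best])
  }
  list(quantity_ng = ng, nearest_point_ng = nearest,
       extrapolated = extrapolated)
}

#' Replicate overlap of protein identifications
#'
#' Set similarity of two replicate protein lists, as a percentage. The
#' default statistic is the overlap coefficient
#' `|A intersect B| / min(|A|, |B|) * 100`; the Jaccard index
#' `|A intersect B| / |A union B| * 100` is also available, and pipeline
#' reports always include both.
#'
#' @param setA,setB character vectors of protein accessions (non-empty).
#' @param mode `"overlap_coefficient"` (default) or `"jaccard"`.
#' @return Percentage in \[0, 100\].
#' @examples
#' replicateOverlap(sprintf("p%d", 1:10), sprintf("p%d", 6:15))  # 50
#' @export
replicateOverlap <- function(setA, setB,
                             mode = c("overlap_coefficient", "jaccard")) {
  mode <- match.arg(mode)
  setA <- unique(setA); setB <- unique(setB)
  if (!length(setA) || !length(setB))
    stop("replicate protein sets must be non-empty")
  ni <- length(intersect(setA, setB))
  denom <- switch(mode,
    overlap_coefficient = min(length(setA), length(setB)),
    jaccard = length(union(setA, setB)))
  100 * ni / denom
}

#' Tabulate protein class annotations
#'
#' Joins a user-supplied protein-to-class mapping onto a protein list and
#' tabulates per-class counts and percentages of the annotated proteins;
#' unannotated proteins are counted separately.
#'
#' @param proteins character vector of accessions, or a data.frame with a
#'   `protein_acc` column.
#' @param annotationMap data.frame with columns `protein_acc` and `class`.
#' @return A list with `classes` (data.frame `class`, `count`,
#'   `percent_of_annotated`), `nAnnotated` and `nUnannotated`.
#' @examples
#' tabulateAnnotations(c("A", "B", "C"),
#'                     data.frame(protein_acc = c("A", "B"),
#'                                class = c("RNA binding", "RNA binding")))
#' @export
tabulateAnnotations <- function(proteins, annotationMap) {
  if (is.data.frame(proteins)) proteins <- proteins$protein_acc
  stopifnot(is.character(proteins),
            is.data.frame(annotationMap),
            all(c("protein_acc", "class") %in% names(annotationMap)))
  proteins <- unique(proteins)
  hit <- annotationMap[match(proteins, annotationMap$protein_acc), "class"]
  annotated <- !is.na(hit)
  classes <- if (any(annotated)) {
    tab <- table(hit[annotated])
    data.frame(class = names(tab), count = as.integer(tab),
               percent_of_annotated =
                 100 * as.integer(tab) / sum(annotated))
  } else {
    data.frame(class = character(), count = integer(),
               percent_of_annotated = numeric())
  }
  rownames(classes) <- NULL
  list(classes = classes, nAnnotated = sum(annotated),
       nUnannotated = sum(!annotated))
}

#' Read a peptide identification table
#'
#' Reads the tab-separated peptide table format produced by the
#' simulator and expected by the quantification chain: columns
#' `peptide_id`, `sequence`, `protein_acc`, `is_specific`,
#' `modifications`, and one or more `ms1_area_*` columns.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPeptideTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = NA, na.strings = character())
  need <- c("peptide_id", "sequence", "protein_acc", "is_specific",
            "modifications")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("peptide table lacks required column(s): ",
         paste(miss, collapse = ", "))
  tab$is_specific <- as.logical(tab$is_specific)
  tab
}

#' Read a protein-level abundance table
#'
#' Reads protein-level input (CSV or TSV, selected by extension) for the
#' enrichment comparison when peptide-level data are not available, e.g.
#' exported protein sections of search-engine result files. Columns are
#' remapped onto the internal `protein_acc` / `abundance` schema.
#'
#' @param path file path.
#' @param accColumn,abundanceColumn column names in the file.
#' @param nSpecificColumn optional column with the specific-peptide count;
#'   when present, rows below `minSpecific` are dropped.
#' @param minSpecific minimum specific peptides (default 2).
#' @return data.frame `protein_acc`, `abundance` (plus `n_specific` when
#'   available).
#' @export
readProteinTable <- function(path, accColumn = "protein_acc",
                             abundanceColumn = "abundance",
                             nSpecificColumn = NULL, minSpecific = 2) {
  tab <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    read.csv(path, stringsAsFactors = FALSE)
  else read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c(accColumn, abundanceColumn), names(tab))
  if (length(miss))
    stop("protein table lacks required column(s): ",
         paste(miss, collapse = ", "))
  out <- data.frame(protein_acc = as.character(tab[[accColumn]]),
                    abundance = as.numeric(tab[[abundanceColumn]]))
  if (!is.null(nSpecificColumn)) {
    if (!nSpecificColumn %in% names(tab))
      stop("protein table lacks column ", nSpecificColumn)
    out$n_specific <- as.integer(tab[[nSpecificColumn]])
    out <- out[out$n_specific >= minSpecific, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
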