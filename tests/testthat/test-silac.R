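# SILAC label classification, protein inference, dilution-curve
# quantification, normalization, enrichment calling and set overlap.

test_that("peptide label classification follows the full-label rule", {
  tab <- data.frame(
    sequence = c("ACDK", "ACDK", "ACDEF", "ACDKGR"),
    modifications = c("13C6@K4", "", "", "13C6@K4"))
  out <- classifyPeptideLabels(tab)
  expect_identical(out$label_status,
                   c("labeled", "contaminant", "indeterminate",
                     "contaminant"))
  # fully labelled mass shift of ACDKGR: two labelled residues
  expect_equal(labelMassShift("ACDKGR"), 2 * 6.02013)
  expect_equal(labelMassShift("ACDKGR"), 2 * 6 * (13.003355 - 12),
               tolerance = 1e-4)
})

test_that("inconsistent modifications raise data-integrity errors", {
  expect_error(classifyPeptideLabels(
    data.frame(sequence = "ACDK", modifications = "13C6@A1")),
    "non-labellable")
  expect_error(classifyPeptideLabels(
    data.frame(sequence = "ACDK", modifications = "13C6@K9")),
    "outside sequence")
  expect_error(classifyPeptideLabels(
    data.frame(sequence = "ACDK", modifications = "13C6@R4")),
    "does not match")
  expect_error(classifyPeptideLabels(
    data.frame(sequence = "ACDK", modifications = "13C6-K4")),
    "malformed")
})

test_that("classification is row-exact on simulated tables", {
  for (seed in c(1, 12, 30)) {
    tab <- simulatePeptideTable(peptideSimParams(
      nProteins = 15, contaminantFraction = 0.2, seed = seed))
    out <- classifyPeptideLabels(tab$peptides)
    expect_identical(out$label_status, tab$labelTruth$label_status)
  }
})

test_that("contamination fraction excludes indeterminate peptides", {
  allLab <- data.frame(label_status = rep("labeled", 8))
  expect_equal(contaminationFraction(allLab), 0)
  mix <- data.frame(label_status = c(rep("labeled", 95),
                                     rep("contaminant", 5)))
  expect_equal(contaminationFraction(mix), 0.05)
  withInd <- data.frame(label_status = c(rep("labeled", 10),
                                         rep("contaminant", 10),
                                         rep("indeterminate", 7)))
  expect_equal(contaminationFraction(withInd), 0.5)
  expect_error(contaminationFraction(
    data.frame(label_status = rep("indeterminate", 3))), "classifiable")
})

test_that("protein inference counts only labelled specific peptides", {
  expect_identical(nrow(inferProteins(
    classifyPeptideLabels(data.frame(
      sequence = character(), modifications = character(),
      protein_acc = character(), is_specific = logical(),
      ms1_area_rosette = numeric())))), 0L)

  toy <- classifyPeptideLabels(data.frame(
    sequence = c("AAAK", "CCCK", "DDDK"),
    modifications = c("13C6@K4", "13C6@K4", "13C6@K4"),
    protein_acc = c("P1", "P1", "P2"),
    is_specific = c(TRUE, FALSE, TRUE),
    ms1_area_rosette = c(10, 5, 7)))
  # P1 has one specific + one shared peptide
  expect_identical(inferProteins(toy, minSpecific = 2)$protein_acc,
                   character(0))
  one <- inferProteins(toy, minSpecific = 1)
  expect_identical(one$protein_acc, c("P1", "P2"))
  expect_equal(one$abundance, c(10, 7))  # shared peptide excluded

  cont <- classifyPeptideLabels(data.frame(
    sequence = c("AAAK", "CCCK"), modifications = c("", ""),
    protein_acc = "KRT1", is_specific = TRUE,
    ms1_area_rosette = c(9, 9)))
  expect_identical(nrow(inferProteins(cont, minSpecific = 1)), 0L)
})

test_that("dilution curves invert exactly and report the log-nearest point", {
  cv <- fitDilutionCurve(data.frame(quantity_ng = c(25, 50, 100),
                                    summed_area = c(50, 100, 200)))
  est <- estimateQuantity(cv, 144)
  expect_equal(est$quantity_ng, 72, tolerance = 1e-9)
  expect_equal(est$nearest_point_ng, 100)
  expect_false(est$extrapolated)

  expect_error(fitDilutionCurve(data.frame(quantity_ng = 50,
                                           summed_area = 10)), "2 dilution")
  expect_error(fitDilutionCurve(data.frame(quantity_ng = c(50, 25),
                                           summed_area = c(1, 2))),
               "increasing")
  expect_error(fitDilutionCurve(data.frame(quantity_ng = c(10, 20, 30),
                                           summed_area = c(30, 20, 10))),
               "slope")
  expect_warning(estimateQuantity(cv, 1000), "extrapolates")
})

test_that("noisy dilution curves recover the true slope within 5%", {
  errs <- vapply(1:20, function(s) {
    tab <- simulatePeptideTable(peptideSimParams(
      nProteins = 2, abundanceNoiseCv = 0.01, seed = s))
    cv <- fitDilutionCurve(tab$dilution)
    abs(cv@slope - 1e6) / 1e6
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("normalized abundances sum to one and are scale invariant", {
  df <- data.frame(protein_acc = c("A", "B"), abundance = c(10, 30))
  norm <- normalizeAbundances(df)
  expect_equal(norm$normalized_abundance, c(0.25, 0.75))
  expect_equal(normalizeAbundances(
    data.frame(abundance = 5))$normalized_abundance, 1)
  scaled <- df
  scaled$abundance <- scaled$abundance * 1e4
  expect_equal(normalizeAbundances(scaled)$normalized_abundance,
               norm$normalized_abundance)
  expect_error(normalizeAbundances(data.frame(abundance = c(0, 0))),
               "zero")
  set.seed(10)
  big <- data.frame(abundance = rlnorm(200))
  expect_equal(sum(normalizeAbundances(big)$normalized_abundance), 1,
               tolerance = 1e-12)
})

test_that("enrichment calls use the inclusive 1.5 ratio threshold", {
  ros <- normalizeAbundances(data.frame(protein_acc = c("A", "B"),
                                        abundance = c(10, 30)))
  tot <- normalizeAbundances(data.frame(protein_acc = c("A", "B"),
                                        abundance = c(5, 35)))
  enr <- enrichmentTable(ros, tot)
  expect_equal(enr$ratio[enr$protein_acc == "A"], 2)
  expect_true(enr$enriched[enr$protein_acc == "A"])
  expect_equal(enr$ratio[enr$protein_acc == "B"], 0.75 / 0.875)
  expect_false(enr$enriched[enr$protein_acc == "B"])
  expect_equal(enr$log2_ratio, log2(enr$ratio))

  same <- enrichmentTable(ros, ros)
  expect_true(all(same$ratio == 1))
  expect_false(any(same$enriched))

  # a ratio of exactly 1.5 is enriched; the log2 threshold prints as 0.6
  r3 <- normalizeAbundances(data.frame(protein_acc = c("A", "B"),
                                       abundance = c(3, 2)))
  t3 <- normalizeAbundances(data.frame(protein_acc = c("A", "B"),
                                       abundance = c(2, 3)))
  e3 <- enrichmentTable(r3, t3)
  expect_equal(e3$ratio[e3$protein_acc == "A"], 1.5)
  expect_true(e3$enriched[e3$protein_acc == "A"])
  expect_equal(round(log2(1.5), 1), 0.6)
})

test_that("single-sample proteins are reported but never enriched", {
  ros <- normalizeAbundances(data.frame(protein_acc = c("A", "B"),
                                        abundance = c(10, 90)))
  tot <- normalizeAbundances(data.frame(protein_acc = c("B", "C"),
                                        abundance = c(50, 50)))
  enr <- enrichmentTable(ros, tot)
  expect_identical(enr$status[enr$protein_acc == "A"], "rosette_only")
  expect_identical(enr$status[enr$protein_acc == "C"], "total_only")
  expect_true(all(is.na(enr$ratio[enr$status != "both_detected"])))
  expect_false(any(enr$enriched[enr$status != "both_detected"]))
})

test_that("the enriched set shrinks monotonically with the threshold", {
  tab <- simulatePeptideTable(peptideSimParams(nProteins = 40, seed = 8))
  cl <- classifyPeptideLabels(tab$peptides)
  ros <- normalizeAbundances(inferProteins(cl, 2, "ms1_area_rosette"))
  tot <- normalizeAbundances(inferProteins(cl, 2, "ms1_area_total"))
  counts <- vapply(c(1, 1.25, 1.5, 2, 3, 5), function(th)
    sum(enrichmentTable(ros, tot, th)$enriched), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("spiked ratios are exact without noise and accurate at 10% CV", {
  tab <- simulatePeptideTable(peptideSimParams(
    nProteins = 20, enrichedSubsetFraction = 0.25, enrichmentFactor = 3,
    abundanceNoiseCv = 0, contaminantFraction = 0.05, seed = 2))
  cl <- classifyPeptideLabels(tab$peptides)
  ros <- normalizeAbundances(inferProteins(cl, 2, "ms1_area_rosette"))
  tot <- normalizeAbundances(inferProteins(cl, 2, "ms1_area_total"))
  mg <- merge(enrichmentTable(ros, tot), tab$proteinTruth)
  expect_equal(mg$ratio, mg$true_ratio, tolerance = 1e-12)
  expect_identical(sum(mg$enriched), 5L)

  relerr <- vapply(1:10, function(s) {
    tab <- simulatePeptideTable(peptideSimParams(
      nProteins = 20, peptidesPerProteinMean = 5, abundanceNoiseCv = 0.1,
      seed = s))
    cl <- classifyPeptideLabels(tab$peptides)
    ros <- normalizeAbundances(inferProteins(cl, 2, "ms1_area_rosette"))
    tot <- normalizeAbundances(inferProteins(cl, 2, "ms1_area_total"))
    mg <- merge(enrichmentTable(ros, tot), tab$proteinTruth)
    median(abs(mg$ratio - mg$true_ratio) / mg$true_ratio)
  }, numeric(1))
  expect_lt(median(relerr), 0.1)
})

test_that("replicate overlap statistics match their set definitions", {
  a <- sprintf("p%d", 1:10)
  b <- sprintf("p%d", 6:15)
  expect_equal(replicateOverlap(a, a), 100)
  expect_equal(replicateOverlap(a, b), 50)
  expect_equal(replicateOverlap(a, b, "jaccard"), 100 * 5 / 15)
  expect_equal(replicateOverlap(a, sprintf("q%d", 1:4)), 0)
  expect_error(replicateOverlap(character(), a), "non-empty")
})

test_that("annotation tabulation joins, counts and conserves", {
  out <- tabulateAnnotations(c("A", "B", "C"),
                             data.frame(protein_acc = c("A", "B"),
                                        class = "RNA binding"))
  expect_identical(out$nAnnotated, 2L)
  expect_identical(out$nUnannotated, 1L)
  expect_equal(out$classes$percent_of_annotated, 100)

  none <- tabulateAnnotations(c("A", "B"),
                              data.frame(protein_acc = character(),
                                         class = character()))
  expect_identical(none$nAnnotated, 0L)
  expect_identical(none$nUnannotated, 2L)

  # 60 of 312 proteins in one class is 19.2%
  acc <- sprintf("P%03d", 1:312)
  map <- data.frame(protein_acc = acc[1:60], class = "RNA binding")
  res <- tabulateAnnotations(acc, map)
  expect_equal(res$classes$percent_of_annotated, 100)
  expect_equal(100 * res$classes$count / length(acc), 19.2, tolerance = 0.05)
  expect_identical(res$nAnnotated + res$nUnannotated, 312L)
})

test_that("peptide tables round trip through TSV", {
  tab <- simulatePeptideTable(peptideSimParams(nProteins = 5, seed = 1))
  f <- tempfile(fileext = ".tsv")
  write.table(tab$peptides, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- readPeptideTable(f)
  expect_identical(back$sequence, tab$peptides$sequence)
  expect_identical(back$is_specific, tab$peptides$is_specific)
  expect_equal(back$ms1_area_rosette, tab$peptides$ms1_area_rosette)
  bad <- tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", bad)
  expect_error(readPeptideTable(bad), "lacks required")
})
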