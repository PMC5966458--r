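# invadoLCM

Laser-capture microdissection (LCM) targeting and SILAC proteomics
post-processing for invadosome rosettes.

Invadosome rosettes are ring-shaped F-actin structures (5–7 µm outer
diameter) that Src-transformed fibroblasts form on degradable matrix.
Mapping their proteome means microdissecting tens of thousands of
individual rosettes from fixed cells and identifying the collected
protein by mass spectrometry — which raises two computational problems
this package solves for the people running such experiments:

1. **Targeting.** Every acquired fluorescence field is segmented
   automatically with the classical ImageJ-style operator chain — red
   channel split, disk median (radius 2 px), rolling-ball background
   subtraction (radius 20 px), automated thresholding (IsoData),
   closing + hole filling, connected-component particle analysis, then
   retention of objects with area ≥ 10 µm² and circularity within
   [0.35, 1] — and the retained outlines are converted into calibrated
   stage coordinates, with an adjacent-field tiling matrix and an open
   XML element file for the dissection run.
2. **Specificity.** The cells are SILAC-labelled (¹³C₆ lysine/arginine,
   +6.02013 Da per residue), so any identified peptide whose K/R
   residues are not all heavy-labelled must come from ambient
   contamination, not the dissected cells. Peptides are classified
   labelled / contaminant / indeterminate, proteins are inferred from
   ≥ 2 specific labelled peptides, abundances are normalized by summed
   intensity, and a protein is called **enriched** in the rosette
   fraction when

   rosette/total normalized abundance ratio ≥ 1.5  (log₂ ratio ≥ 0.585 ≈ 0.6).

A high-content module scores the validation phenotypes (rosettes per
nucleus, gelatin area degraded per cell, one-way ANOVA with Bonferroni
post tests vs control), and seeded synthetic-data generators produce
rosette fields, zymography pairs and peptide tables with exact ground
truth, so the whole pipeline is testable without instrument data.

## Worked example

```r
library(invadoLCM)

# a synthetic field: 5 rosettes + 5 stress-fibre distractors, SNR 20
sim <- simulateRosetteField(imageSimParams(nRosettes = 5, nFibers = 5, seed = 42))
rs  <- segmentRosettes(sim$image)
rs
#> RegionSet: 5 region(s), 512 x 512 px mask, 0.25 um/px, 8-connected
#>   area (um^2): 24.3--37.3; circularity: 0.96--0.98
```

All five rosettes are recovered; the fibres (circularity < 0.1) are
rejected by the shape filter. Region areas of 24–37 µm² are what disks
of 5.5–6.9 µm diameter should give, and circularities near 1 say the
filled rings are round. Convert to a dissection plan in stage µm:

```r
fld  <- calibratedField(c(1000, 2000), pixelSize(sim$image), 512, 512)
plan <- buildPlan(rs, fld)
plan
#> DissectionPlan: 1 field centre(s), 5 dissection element(s)
exportElementFile(plan, "plan.xml")
```

SILAC post-processing on a synthetic peptide table with a 5%
contaminant spike and a threefold enrichment of a quarter of the
proteins:

```r
tab <- simulatePeptideTable(peptideSimParams(nProteins = 20,
                                             enrichmentFactor = 3,
                                             abundanceNoiseCv = 0, seed = 42))
cl  <- classifyPeptideLabels(tab$peptides)
round(100 * contaminationFraction(cl), 1)
#> 5.4                                  # percent contaminating peptides

ros <- normalizeAbundances(inferProteins(cl, 2, "ms1_area_rosette"))
tot <- normalizeAbundances(inferProteins(cl, 2, "ms1_area_total"))
enr <- enrichmentTable(ros, tot)      # ratio >= 1.5 is enriched
head(enr[order(-enr$ratio), c("protein_acc", "ratio", "log2_ratio", "enriched")], 5)
#>    protein_acc ratio log2_ratio enriched
#> 4     PROT0004     3   1.584963     TRUE
#> 8     PROT0008     3   1.584963     TRUE
#> 17    PROT0017     3   1.584963     TRUE
#> 11    PROT0011     3   1.584963     TRUE
#> 15    PROT0015     3   1.584963     TRUE
sum(enr$enriched)
#> 5                                    # exactly the spiked quarter
```

The recovered ratios equal the spiked factor exactly because the
generator balances both channel totals by construction (see the methods
vignette, `vignettes/invadoLCM-methods.Rmd`).

There is also a thin command-line wrapper:

```sh
exec/invadolcm run --seed 7 --out out/         # full synthetic pipeline
exec/invadolcm segment --input field.tif --pixel-size 0.65 --out out/
exec/invadolcm quant --peptides pep.tsv --min-specific 2 --out out/
```

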