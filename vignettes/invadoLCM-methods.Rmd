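---
title: "Methods: automated rosette targeting and SILAC enrichment analysis"
author: "invadoLCM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated rosette targeting and SILAC enrichment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invadoLCM)
```

# The problem

Invadosome rosettes are ring-shaped F-actin structures, 5--7 µm in outer
diameter, that Src-transformed fibroblasts assemble on degradable matrix.
Characterising their proteome requires cutting tens of thousands of
individual rosettes out of fixed cells by laser-capture microdissection
(LCM) and identifying the collected protein by mass spectrometry. Two desk-side
computations make that workflow practical, and this package implements
both:

1. **Targeting.** Each acquired fluorescence field is segmented
   automatically so the microdissector can cut every rosette without an
   operator drawing outlines, and the segmented outlines are converted
   into calibrated stage coordinates with an adjacent-field tiling plan.
2. **Specificity.** Because the mass spectrometer is sensitive enough to
   pick up keratin flakes and other ambient protein, the cells are
   SILAC-labelled (^13^C~6~ lysine/arginine) beforehand; a peptide
   identified *without* the heavy label cannot come from the dissected
   cells and is discarded as contamination before protein-level
   quantification.

A third, supporting area quantifies the cell-biological phenotypes used
to validate hits: rosettes per nucleus and gelatin area degraded per
cell, with one-way ANOVA and Bonferroni-vs-control post tests.

# The segmentation chain

`segmentRosettes()` reproduces the classical ImageJ-macro operator
sequence, in order:

1. **Red-channel split** (`splitRedChannel()`): the rosette marker
   (Lifeact-mRuby) is the red channel of the acquired RGB image.
2. **Disk median filter** (`diskMedian()`, radius 2 px): despeckling
   over the 13-pixel disk neighbourhood, reflect edges.
3. **Rolling-ball background subtraction** (`rollingBallSubtract()`,
   radius 20 px): the background is the grayscale opening with a
   spherical structuring element, computed exactly (no legacy
   image-shrinking shortcut). The ball couples the spatial and
   intensity axes, so — as in the classical 8-bit formulation —
   intensities are internally mapped to 0--255 and back. This makes the
   result invariant under rescaling of the input; without the mapping a
   radius-20 ball "climbs" unit-amplitude rings and eats the very
   structures being segmented.
4. **Automated thresholding** (`autoThreshold()`): IsoData iterative
   intermeans on a 256-bin histogram by default (the historical
   default of the original macro environment), Otsu selectable. The
   IsoData iteration is seeded at the histogram midpoint; seeding at
   the image mean can converge to a second fixed point inside the
   background noise lobe when foreground pixels are rare, which is
   exactly the situation in a sparse rosette field. The mask keeps
   pixels strictly above the threshold; a constant image raises a
   degenerate-histogram condition that the chain converts into an
   empty result.
5. **Closing and hole filling** (`refineMask()`): closing with the
   radius-1 element, then flood-filling of enclosed holes (4-connected
   background under 8-connected foreground). The closing element is the
   disk in the 8-neighbourhood sense — radius 1 is the full 3×3 box —
   so a one-pixel break in a one-pixel ring is healed; the Euclidean
   5-pixel cross cannot do that. The closing+fill pair is iterated to a
   fixed point, which makes the operation idempotent by construction;
   on ordinary masks one pass suffices. Hole filling is what turns a
   bright ring into the solid disk the laser should cut.
6. **Particle analysis** (`labelRegions()`): connected components
   (8-connected by default, 4 selectable) with calibrated descriptors.
7. **Shape filtering** (`filterRegions()`): area ≥ 10 µm² and
   circularity within [0.35, 1], both bounds inclusive as printed.
   Circular rosette disks pass; stress fibres — 20 µm × 1 µm bars with
   circularity well below 0.1 — are rejected on shape even though they
   are as bright as rosettes.

## Shape descriptors and the perimeter estimator

Area is exact: pixel count × pixel size². The perimeter is the length
of the closed polygon through the centres of the region's outer
boundary pixels, traced with 8-connected moves (axial steps 1, diagonal
steps √2). On rasterized disks of radius ≥ 10 px this estimator is
within a few percent of 2πr, giving circularities of 0.91--0.94, and it
measures diagonal bars accurately, which matters because the
circularity filter is what rejects them. Two properties are worth
knowing: an axis-aligned w×h rectangle measures 2(w+h)−4 because the
trace runs half a pixel inside each edge (the 2×20 px rectangle
therefore has circularity 0.314, still comfortably rejected by the 0.35
bound), and circularity is clamped at 1.0 to absorb discretization
overshoot on small round regions. During development we also evaluated
the crack-edge count (exact on rectangles but giving π²/16 ≈ 0.62 for
*every* digital disk) and the corner-corrected crack trace (disks land
at 0.89, just under the behaviour we require of round objects); the
centre trace is the only variant that measures both round rosettes and
elongated fibres in a way the printed filter bounds can act on.

Ellipse axis lengths come from the second central moments of the pixel
centres (4√λ); a one-pixel-wide line has minor axis 0, and no 1/12
pixel-extent correction is applied. Solidity is pixel count over the
convex hull area of the pixel centres, clamped at 1 (for convex digital
shapes the hull of centres slightly underestimates the pixelated area).

# Dissection planning

Stage calibration is a pixel→µm affine map: `stage = origin + p ·
pixelSize`, with 0-based pixel coordinates in the pixel-centre
convention. Boundary polygons for export use pixel-corner vertices from
a crack-boundary trace (the full outline; no vertex decimation). The
`yAxisFlip` option reflects the y term about the field for instruments
whose stage y-axis runs opposite to image rows; the default is `FALSE`
and the transform is exactly invertible either way. `planTileGrid()`
produces the row-major (optionally serpentine) matrix of adjacent field
centres spaced exactly one field width/height, so tiles abut without
gap or overlap.

The microdissector's native element-list format is proprietary, so
`exportElementFile()` writes an open XML surrogate (one `<point>` per
field centre, one `<element>` of `<vertex>` nodes per region, stage µm
at 0.01 µm precision — an order of magnitude below the laser spot) plus
a flat CSV; `parseElementFile()` inverts it to that precision.

# High-content phenotype scoring

The invadosome channel is corrected for uneven illumination (division
by a Gaussian estimate of the illumination field, mean-preserving),
enhanced by white top-hat filtering (image minus flat-disk opening,
radius 15 px — wider than a rosette, so rosettes survive and broad
plateaus vanish), thresholded, hole-filled and filtered on area
(10--200 µm²), major/minor ellipse axis length (2--20 µm) and solidity
(≥ 0.8). The published workflow names these morphological filters
without printing cut-offs; the defaults here are chosen from the
geometry of the structures themselves (a 5--7 µm rosette disk has axes
5--7 µm and solidity ≈ 1; a 20 µm fibre fails both the axis range and,
once fragmented, the area bound) and all of them are configuration.
Nuclei are counted by primary detection with only a minimum-area rule
(20 µm²); there is no declumping, so touching nuclei count once —
documented behaviour, consistent for the ratio read-outs.

In situ zymography is quantified as the calibrated area *below* an
automated threshold on the illumination-corrected fluorescent-gelatin
channel (degradation is dark), divided by the nucleus count
(`degradedAreaPerCell()`).

`compareGroups()` runs a regular one-way ANOVA (via `stats::lm`)
followed by comparisons of each condition against the control using the
pooled within-group standard deviation from the ANOVA — the classical
Bonferroni multiple-comparison post test — with raw p values multiplied
by the number of comparisons and capped at 1; significance is called at
p < 0.05. Degenerate inputs (zero within-group variance) return F = 0,
p = 1 for identical means and p = 0 otherwise, with a warning.

# SILAC specificity and enrichment

`classifyPeptideLabels()` applies the full-label rule: a peptide is
**labelled** only if *every* K/R in its sequence carries the ^13^C~6~
modification (+6.02013 Da per residue), **contaminant** if at least one
K/R is unmodified (metabolic incorporation is complete in the labelled
cells, so partial labels indicate artefacts), and **indeterminate** if
it contains no K/R at all — such peptides are excluded from the
contamination fraction because the variable-modification search cannot
classify them either. Modification entries that contradict the sequence
raise data-integrity errors rather than silently misclassifying.

Protein inference keeps labelled peptides that the input table assigns
to exactly one protein group (`is_specific`; no razor-peptide logic —
grouping is the search engine's job and its assignment is taken as
given), requires at least 2 of them per protein by default, and sums
their MS1 areas. Abundances are normalized by each sample's summed
intensity, making ratios invariant under global rescaling — which is
also why the dissected sample and the reference injection need not be
at the same absolute load. Enrichment is a plain inclusive ratio
cut-off: rosette/total normalized abundance ≥ 1.5 (log₂ 1.5 ≈ 0.585,
printed as 0.6); proteins detected in only one sample are reported as
`rosette_only`/`total_only` with `NA` ratios and are never called
enriched, avoiding infinite ratios. The inclusive bound carries a 10⁻¹²
relative tolerance because exact rational inputs (3/5 ÷ 2/5) land at
1.4999999999999998 in floating point.

Sample quantity is estimated from a dilution series by unweighted OLS
(`fitDilutionCurve()`, free intercept) and line inversion;
`estimateQuantity()` also reports the dilution point nearest to the
estimate for use as the reference injection. Nearness is measured on
the log scale — the natural metric for a geometric dilution series, and
the choice under which an estimate of 72 ng in a {25, 50, 100} ng range
selects 100 ng; ties go to the larger point, and estimates beyond twice
the largest point are flagged as extrapolation.

Replicate reproducibility is reported as both the overlap coefficient
(|A∩B|/min(|A|,|B|), the default) and the Jaccard index, since the
denominator convention of a printed overlap percentage is often
ambiguous; pipeline outputs always carry both. Functional annotation is
a plain join against a user-supplied protein→class table
(`tabulateAnnotations()`) — live database queries are out of scope.

# The synthetic-data generators

All three generators (`simulateRosetteField()`,
`simulateZymographyPair()`, `simulatePeptideTable()`) draw every random
number from the single integer seed of the call and restore the session
RNG afterwards; identical parameters and seed give bit-identical
output.

**Rosette fields.** Rosettes are annuli — bright ring (amplitude 1,
thickness 1 µm, outer diameter uniform in 5--7 µm) around a dimmer core
(0.35) on a 0.1 baseline — because hole filling is only meaningful if
the structures really are rings. Fibre distractors are 20 µm × 1 µm
bars (amplitude 0.9) that fail the circularity filter by construction.
Structure centres are kept at least one rosette diameter apart
(edge-to-edge), so counts are unambiguous; a multiplicative linear
illumination gradient (default 20% peak-to-peak along a random
direction) and additive Gaussian noise complete the field. Edges carry
a one-pixel linear coverage ramp emulating optical blur. The default
sampling is 0.25 µm/px over 512 px (high-magnification widefield
scale): at 0.5 µm/px the 1 µm structures are 2 px wide — at the Nyquist
limit of the prescribed radius-2 median — and hard-edged rasters then
fragment under filtering, which is an artefact of undersampling, not of
the method. What the generator does *not* emulate: a real PSF,
photon-counting noise statistics, out-of-focus structures, rosettes
touching other actin structures, or biological variation in ring
completeness — so passing counts here demonstrate the operator chain's
correctness at realistic contrast (tests run at SNR 5), not
segmentation performance on difficult real fields.

**Zymography pairs.** Degradation holes are rasterized to exactly
`round(area/px²)` pixels (nearest pixels to the centre), so the
ground-truth degraded area is exact by construction; nuclei are
non-overlapping bright disks.

**Peptide tables.** Tryptic sequences (C-terminal K/R), fully modified
on every K/R for labelled rows, no modifications for contaminant rows,
which are appended under dedicated `CON_` accessions at a count
matching the requested contaminant fraction to within one row. MS1
areas are log-normal (protein abundance × per-peptide share) with
multiplicative log-normal noise at the requested CV, matching MS1
intensity behaviour. The enrichment spike applies factor *f* to a
random protein subset and the exactly compensating depletion factor to
the rest, so both channel totals are equal and the true
post-normalization ratio of a spiked protein is *f* — exactly — rather
than *f* times an arbitrary normalization constant. For the
compensation to stay positive the enriched subset's abundance share is
capped at 0.5/f (rescaling the subset's base abundances when a draw
exceeds it). Every protein gets at least 2 peptides so that the
min-2-specific identification rule never silently removes simulated
truth.

# Problem sizes and numerical choices

The validation suite runs at these sizes, chosen so the whole suite
completes in a few minutes on one core while keeping the statistics
meaningful: 50 seeded fields (512 px, 3--10 rosettes, 5 fibres, SNR 5)
for count recovery; 50 seeds × 20 proteins for ratio recovery at 10%
CV; 500-point clouds for the geometric round trips. Count recovery is
expected in ≥ 95% of fields with zero fibre false positives; the
current implementation achieves 100% with none. Numerical conventions
collected in one place: reflect padding for all neighbourhood filters;
thresholds select strictly-above pixels; all printed filter bounds are
inclusive; circularity and solidity are clamped at 1; region labels are
assigned in raster-scan order (deterministic); the traced polygon of a
region smaller than 3 boundary pixels falls back to the unit-square
perimeter.

# Known limitations

* The rolling ball is exact but O(pixels × ball area); fields much
  larger than ~10⁶ px with large radii will be noticeably slower than
  the legacy shrinking approximation.
* Perimeter (hence circularity) of regions only a few pixels across is
  dominated by discretization; the area filter is the meaningful guard
  at that scale.
* No object declumping anywhere: touching rosettes, nuclei or merged
  structures count once.
* `readCalibratedTiff()` restores arbitrary-range intensities only via
  the sidecar's affine transform; plain float TIFFs from other tools
  are assumed to be in [0, 1].
* The element-file schema is an open surrogate, not the instrument's
  proprietary format; a site-specific converter is expected downstream.
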