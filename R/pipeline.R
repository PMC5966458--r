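## Configuration handling and the end-to-end pipeline driver tying
## simulate -> segment -> plan -> hca -> quant together.

#' Default pipeline configuration
#'
#' Nested list of every tunable parameter with the published values as
#' defaults: median radius 2 px, rolling-ball radius 20 px, minimum area
#' 10 um^2, circularity 0.35--1, enrichment ratio threshold 1.5, minimum
#' specific peptides 2.
#'
#' @return Named nested list.
#' @examples
#' str(defaultConfig(), max.level = 1)
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    out_dir = "invadolcm-out",
    simulate = list(
      field_width_px = 512L, field_height_px = 512L, pixel_size_um = 0.25,
      n_rosettes = 5L, rosette_diameter_range_um = c(5, 7),
      ring_thickness_um = 1, n_fibers = 5L,
      illumination_gradient_amplitude = 0.2, noise_sd = 0.05,
      n_proteins = 50L, contaminant_fraction = 0.05,
      enriched_subset_fraction = 0.25, enrichment_factor = 3,
      abundance_noise_cv = 0.1),
    segmentation = list(
      median_radius_px = 2L, rolling_ball_radius_px = 20L,
      threshold_method = "isodata", closing_radius_px = 1L,
      connectivity = 8L, min_area_um2 = 10,
      circularity_range = c(0.35, 1)),
    planning = list(
      y_axis_flip = FALSE, grid_cols = 1L, grid_rows = 1L,
      serpentine = FALSE),
    hca = list(
      illumination_sigma_px = 50, tophat_radius_px = 15L,
      threshold_method = "isodata", area_range_um2 = c(10, 200),
      axis_range_um = c(2, 20), solidity_min = 0.8,
      min_nucleus_area_um2 = 20),
    silac = list(
      min_specific = 2L, ratio_threshold = 1.5,
      labeled_residues = c("K", "R"), mass_shift_da = 6.02013)
  )
}

.checkKnownKeys <- function(raw, ref, path = "") {
  unknown <- setdiff(names(raw), names(ref))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(raw)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(raw[[k]]))
        stop("configuration section '", path, k, "' must be a mapping")
      .checkKnownKeys(raw[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
}

.deepMerge <- function(ref, raw) {
  for (k in names(raw)) {
    ref[[k]] <- if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      .deepMerge(ref[[k]], raw[[k]]) else raw[[k]]
  }
  ref
}

#' Validate a raw configuration
#'
#' Fills defaults, rejects unknown keys (guarding against typos) and
#' checks every invariant, collecting human-readable messages. Accepts a
#' nested list or the path of a YAML/JSON document.
#'
#' @param raw nested list, file path, or `NULL` for pure defaults.
#' @return The validated, fully populated configuration list.
#' @examples
#' cfg <- validateConfig(list(segmentation = list(min_area_um2 = 12)))
#' cfg$segmentation$min_area_um2
#' @export
validateConfig <- function(raw = NULL) {
  if (is.character(raw) && length(raw) == 1L)
    raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  stopifnot(is.list(raw))
  ref <- defaultConfig()
  .checkKnownKeys(raw, ref)
  cfg <- .deepMerge(ref, raw)
  errs <- character()
  seg <- cfg$segmentation
  if (seg$median_radius_px < 0) errs <- c(errs, "median radius must be >= 0")
  if (seg$rolling_ball_radius_px < 1)
    errs <- c(errs, "rolling-ball radius must be >= 1")
  if (!seg$threshold_method %in% c("isodata", "otsu"))
    errs <- c(errs, "segmentation threshold method must be isodata or otsu")
  if (!seg$connectivity %in% c(4, 8))
    errs <- c(errs, "connectivity must be 4 or 8")
  if (seg$min_area_um2 <= 0) errs <- c(errs, "minimum area must be > 0")
  cr <- seg$circularity_range
  if (length(cr) != 2 || cr[1] < 0 || cr[2] > 1 || cr[1] > cr[2])
    errs <- c(errs, "circularity range must satisfy 0 <= lo <= hi <= 1")
  sim <- cfg$simulate
  if (sim$pixel_size_um <= 0) errs <- c(errs, "pixel size must be > 0")
  if (sim$contaminant_fraction < 0 || sim$contaminant_fraction > 1)
    errs <- c(errs, "contaminant fraction must be in [0, 1]")
  if (cfg$silac$ratio_threshold <= 0)
    errs <- c(errs, "enrichment ratio threshold must be > 0")
  if (cfg$silac$min_specific < 0)
    errs <- c(errs, "minimum specific peptides must be >= 0")
  if (cfg$planning$grid_cols < 1 || cfg$planning$grid_rows < 1)
    errs <- c(errs, "tile grid dimensions must be >= 1")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg
}

#' Write a configuration to YAML
#'
#' Configurations round-trip through [validateConfig()] unchanged.
#'
#' @param config configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.segParamsFromConfig <- function(cfg) {
  seg <- cfg$segmentation
  segmentationParams(
    medianRadiusPx = seg$median_radius_px,
    rollingBallRadiusPx = seg$rolling_ball_radius_px,
    thresholdMethod = seg$threshold_method,
    closingRadiusPx = seg$closing_radius_px,
    connectivity = seg$connectivity,
    minAreaUm2 = seg$min_area_um2,
    circularityRange = seg$circularity_range)
}

.logStage <- function(level, stage, msg, logLevel = "info") {
  levels <- c(debug = 0L, info = 1L, warn = 2L, quiet = 3L)
  if (levels[[level]] >= levels[[logLevel]])
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", msg)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in order on simulated inputs --
#' `simulate` (rosette field + peptide table), `segment`, `plan`, `hca`
#' (zymography scoring) and `quant` -- writing every artefact under
#' `config$out_dir` and returning a run manifest (parameter hash, seed,
#' per-stage record counts, output paths). Identical configuration and
#' seed reproduce byte-identical outputs. Any stage error aborts the run
#' with the stage name; the manifest then marks the run incomplete.
#'
#' @param config validated configuration (see [validateConfig()]); a raw
#'   list or path is validated first.
#' @param stages character subset of
#'   `c("simulate", "segment", "plan", "hca", "quant")`.
#' @param logLevel `"debug"`, `"info"`, `"warn"` or `"quiet"`.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @examples
#' cfg <- validateConfig(list(out_dir = tempfile("run")))
#' m <- runPipeline(cfg, stages = c("simulate", "segment"),
#'                  logLevel = "quiet")
#' m$counts$regions
#' @export
runPipeline <- function(config = defaultConfig(),
                        stages = c("simulate", "segment", "plan", "hca",
                                   "quant"),
                        logLevel = "info") {
  cfg <- validateConfig(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameter_hash =
                     rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
                   seed = cfg$seed,
                   stages = stages, outputs = list(), counts = list(),
                   complete = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- "setup"
  result <- tryCatch({
    sim <- NULL; pep <- NULL; regions <- NULL
    if ("simulate" %in% stages) {
      stage <- "simulate"
      .logStage("info", stage, paste0("seed ", cfg$seed), logLevel)
      s <- cfg$simulate
      sim <- simulateRosetteField(imageSimParams(
        fieldWidthPx = s$field_width_px, fieldHeightPx = s$field_height_px,
        pixelSizeUm = s$pixel_size_um, nRosettes = s$n_rosettes,
        rosetteDiameterRangeUm = s$rosette_diameter_range_um,
        ringThicknessUm = s$ring_thickness_um, nFibers = s$n_fibers,
        illuminationGradientAmplitude = s$illumination_gradient_amplitude,
        noiseSd = s$noise_sd, seed = cfg$seed))
      writeCalibratedTiff(sim$image, out("field.tif"))
      write.csv(sim$truth$rosettes, out("field_truth.csv"),
                row.names = FALSE)
      pep <- simulatePeptideTable(peptideSimParams(
        nProteins = s$n_proteins,
        contaminantFraction = s$contaminant_fraction,
        enrichedSubsetFraction = s$enriched_subset_fraction,
        enrichmentFactor = s$enrichment_factor,
        abundanceNoiseCv = s$abundance_noise_cv, seed = cfg$seed))
      write.table(pep$peptides, out("peptides.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      manifest$outputs$field <- out("field.tif")
      manifest$outputs$peptides <- out("peptides.tsv")
      manifest$counts$rosettes_true <- sim$truth$rosetteCount
      manifest$counts$peptides <- nrow(pep$peptides)
    }
    if ("segment" %in% stages) {
      stage <- "segment"
      img <- if (!is.null(sim)) sim$image else
        readCalibratedTiff(out("field.tif"))
      regions <- segmentRosettes(img, .segParamsFromConfig(cfg))
      .logStage("info", stage, paste0(nRegions(regions), " regions"),
                logLevel)
      writeRegionsCsv(regions, out("regions.csv"))
      writeLabelMaskTiff(regions, out("labels.tif"))
      manifest$outputs$regions <- out("regions.csv")
      manifest$counts$regions <- nRegions(regions)
    }
    if ("plan" %in% stages) {
      stage <- "plan"
      if (is.null(regions)) stop("plan stage requires the segment stage")
      s <- cfg$simulate
      field <- calibratedField(c(0, 0), s$pixel_size_um, s$field_width_px,
                               s$field_height_px,
                               cfg$planning$y_axis_flip)
      plan <- buildPlan(regions, field)
      centers <- planTileGrid(fieldCenters(plan)[1L, ], field,
                              cfg$planning$grid_cols,
                              cfg$planning$grid_rows,
                              cfg$planning$serpentine)
      plan <- dissectionPlan(centers, plan@elementIds, plan@polygons)
      exportElementFile(plan, out("plan.xml"))
      writeCentersCsv(plan, out("centers.csv"))
      writeElementsCsv(plan, out("elements.csv"))
      .logStage("info", stage, paste0(length(plan@polygons), " elements, ",
                                      nrow(centers), " field centres"),
                logLevel)
      manifest$outputs$plan <- out("plan.xml")
      manifest$counts$elements <- length(plan@polygons)
      manifest$counts$field_centers <- nrow(centers)
    }
    if ("hca" %in% stages) {
      stage <- "hca"
      z <- simulateZymographyPair(10, 20, 5, seed = cfg$seed,
                                  pixelSizeUm = cfg$simulate$pixel_size_um)
      h <- cfg$hca
      params <- hcaParams(
        illuminationSigmaPx = h$illumination_sigma_px,
        tophatRadiusPx = h$tophat_radius_px,
        thresholdMethod = h$threshold_method,
        areaRangeUm2 = h$area_range_um2, axisRangeUm = h$axis_range_um,
        solidityMin = h$solidity_min,
        minNucleusAreaUm2 = h$min_nucleus_area_um2)
      nuc <- countNuclei(z$nuclei, params)
      fieldRes <- data.frame(
        field_id = "zymo1",
        nuclei_count = nuc,
        degraded_area_per_cell_um2 =
          if (nuc > 0) degradedAreaPerCell(z$gelatin, nuc, params)
          else NA_real_)
      write.csv(fieldRes, out("hca_fields.csv"), row.names = FALSE)
      .logStage("info", stage, paste0(nuc, " nuclei"), logLevel)
      manifest$outputs$hca <- out("hca_fields.csv")
      manifest$counts$hca_fields <- nrow(fieldRes)
    }
    if ("quant" %in% stages) {
      stage <- "quant"
      tab <- if (!is.null(pep)) pep$peptides else
        readPeptideTable(out("peptides.tsv"))
      scheme <- labelingScheme(cfg$silac$labeled_residues,
                               cfg$silac$mass_shift_da)
      classified <- classifyPeptideLabels(tab, scheme)
      write.table(classified, out("peptides_classified.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      ros <- normalizeAbundances(inferProteins(
        classified, cfg$silac$min_specific, "ms1_area_rosette"))
      tot <- normalizeAbundances(inferProteins(
        classified, cfg$silac$min_specific, "ms1_area_total"))
      enr <- enrichmentTable(ros, tot, cfg$silac$ratio_threshold)
      write.csv(enr, out("enrichment.csv"), row.names = FALSE)
      contam <- contaminationFraction(classified)
      jsonlite::write_json(
        list(contamination_fraction = contam,
             n_proteins = nrow(ros),
             n_enriched = sum(enr$enriched)),
        out("quant_report.json"), auto_unbox = TRUE, digits = NA)
      .logStage("info", stage,
                sprintf("%d proteins, %d enriched, contamination %.1f%%",
                        nrow(ros), sum(enr$enriched), 100 * contam),
                logLevel)
      manifest$outputs$enrichment <- out("enrichment.csv")
      manifest$counts$proteins <- nrow(ros)
      manifest$counts$enriched <- sum(enr$enriched)
    }
    manifest$complete <- TRUE
    manifest
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  jsonlite::write_json(result, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(result)
}
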