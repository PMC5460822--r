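## End-to-end orchestration: volume I/O, configuration, reports and a
## run manifest.

#' Load a NIfTI image + mask pair
#'
#' Reads both volumes with RNifti, takes voxel spacing from the image
#' header, binarizes the mask at > 0 and verifies the two grids are
#' congruent.
#'
#' @param imagePath,maskPath Paths to NIfTI-1 volumes (.nii / .nii.gz).
#' @return A list with elements \code{image} (\linkS4class{ImageVolume})
#'   and \code{mask} (\linkS4class{ROIMask}).
#' @export
loadVolume <- function(imagePath, maskPath) {
  img <- RNifti::readNifti(imagePath)
  msk <- RNifti::readNifti(maskPath)
  di <- dim(img)
  dm <- dim(msk)
  if (!identical(di, dm))
    stop(sprintf("image and mask shapes differ: %s vs %s",
                 paste(di, collapse = "x"), paste(dm, collapse = "x")))
  if (length(di) != 3L)
    stop("expected 3D volumes, got ", length(di), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  list(image = ImageVolume(array(as.numeric(img), dim = di), sp),
       mask = new("ROIMask", values = array(as.numeric(msk) > 0,
                                            dim = di)))
}

#' Assemble a pipeline configuration
#'
#' Describes one full robustness run: either a synthetic cohort (size +
#' base phantom spec) or a list of image/mask NIfTI pairs, the
#' preprocessing grid, the CV options, and where to write outputs.
#'
#' @param nSubjects Synthetic cohort size (ignored when \code{inputs} is
#'   given).
#' @param baseSpec Base \linkS4class{PhantomSpec} for the cohort.
#' @param inputs Optional data.frame with columns \code{image} and
#'   \code{mask}: NIfTI paths, one row per subject. All must exist.
#' @param spatialConfigs List of \linkS4class{SpatialConfig}, or NULL for
#'   the source-derived default grid.
#' @param greyLevels Integer vector of dynamic ranges.
#' @param sdType CV standard-deviation flavour ("sample"/"population").
#' @param threshold Robustness threshold in percent.
#' @param outputDir Directory for reports; created if absent.
#' @param seed Master seed for the synthetic cohort.
#' @param writeProfiles Also write per-subject max-normalized profiles.
#' @return A list of class "PipelineConfig".
#' @export
pipelineConfig <- function(nSubjects = 20L, baseSpec = phantomSpec(),
                           inputs = NULL,
                           spatialConfigs = NULL,
                           greyLevels = c(16L, 32L, 64L),
                           sdType = "sample", threshold = 10,
                           outputDir = tempfile("radtex3d_run_"),
                           seed = 1L, writeProfiles = FALSE) {
  if (!is.null(inputs)) {
    stopifnot(is.data.frame(inputs),
              all(c("image", "mask") %in% names(inputs)))
    missing <- c(inputs$image, inputs$mask)
    missing <- missing[!file.exists(missing)]
    if (length(missing))
      stop("input files not found: ", paste(missing, collapse = ", "))
  }
  structure(list(
    nSubjects = as.integer(nSubjects), baseSpec = baseSpec,
    inputs = inputs, spatialConfigs = spatialConfigs,
    greyLevels = as.integer(greyLevels), sdType = sdType,
    threshold = as.numeric(threshold), outputDir = outputDir,
    seed = as.integer(seed), writeProfiles = isTRUE(writeProfiles)),
    class = "PipelineConfig")
}

#' Run the full texture-robustness pipeline
#'
#' Simulates (or loads) the cohort, builds the configuration grid per
#' subject, extracts the 16 features per configuration, runs both CV
#' experiments (across dynamic ranges and across spatial resolutions),
#' and writes the feature table, both robustness tables, the effective
#' configuration and a JSON manifest with per-file MD5 checksums into
#' \code{outputDir}. Deterministic for a fixed config + seed. When the
#' grid cannot support an experiment (fewer than 2 values to vary), that
#' experiment is skipped with a message and recorded in the manifest.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @return Invisibly, the manifest list (also written as
#'   \code{manifest.json}): stages run, parameters, warnings, output
#'   files with checksums.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(nSubjects = 2, seed = 1)
#' man <- runPipeline(cfg)
#' names(man$outputs)
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  warningsLog <- character(0)
  note <- function(msg) {
    message(msg)
    warningsLog <<- c(warningsLog, msg)
  }

  message("stage 1/4: cohort")
  cohort <- if (is.null(config$inputs)) {
    generateCohort(config$nSubjects, config$baseSpec, config$seed)
  } else {
    subj <- sprintf("subject%02d", seq_len(nrow(config$inputs)))
    stats::setNames(lapply(seq_len(nrow(config$inputs)), function(i)
      loadVolume(config$inputs$image[i], config$inputs$mask[i])), subj)
  }

  message("stage 2/4: configuration grid + feature extraction")
  features <- cohortFeatureTable(cohort, config$spatialConfigs,
                                 config$greyLevels)
  featPath <- file.path(config$outputDir, "features.csv")
  write.csv(features, featPath, row.names = FALSE)
  outputs <- c(features = featPath)

  message("stage 3/4: robustness experiments")
  nSpatial <- length(unique(paste(features$matrixSize,
                                  features$sliceThickness)))
  nGrey <- length(unique(features$nLevels))
  exp1 <- exp2 <- NULL
  if (nGrey >= 2L) {
    exp1 <- classifyRobust(
      cvAcrossDynamicRange(features, config$sdType), config$threshold)
    p <- file.path(config$outputDir, "robustness_dynamic_range.csv")
    writeRobustnessCSV(exp1, p)
    outputs <- c(outputs, robustness_dynamic_range = p)
  } else {
    note("dynamic-range experiment skipped: fewer than 2 grey-level counts")
  }
  if (nSpatial >= 2L) {
    exp2 <- classifyRobust(
      cvAcrossResolution(features, config$sdType), config$threshold)
    p <- file.path(config$outputDir, "robustness_spatial_resolution.csv")
    writeRobustnessCSV(exp2, p)
    outputs <- c(outputs, robustness_spatial_resolution = p)
  } else {
    note("spatial-resolution experiment skipped: fewer than 2 spatial configurations")
  }
  if (config$writeProfiles) {
    for (sub in unique(features$subject)) {
      p <- file.path(config$outputDir,
                     sprintf("profiles_%s.csv", sub))
      write.csv(normalizeProfiles(features[features$subject == sub, ]),
                p, row.names = FALSE)
      outputs <- c(outputs, stats::setNames(p, paste0("profiles_", sub)))
    }
  }

  message("stage 4/4: manifest")
  cfgPath <- file.path(config$outputDir, "effective_config.yaml")
  yaml::write_yaml(list(
    nSubjects = length(cohort),
    synthetic = is.null(config$inputs),
    greyLevels = config$greyLevels,
    sdType = config$sdType, threshold = config$threshold,
    seed = config$seed,
    nConfigurationsPerSubject = nrow(features) / length(cohort)), cfgPath)
  outputs <- c(outputs, effective_config = cfgPath)

  manifest <- list(
    package = "RadTex3D",
    stages = c("cohort", "features", "robustness", "reports"),
    nSubjects = length(cohort),
    nConfigurations = nrow(features),
    nFeatureValues = nrow(features) * length(.featureNames),
    warnings = warningsLog,
    outputs = lapply(stats::setNames(nm = names(outputs)), function(k)
      list(path = outputs[[k]],
           md5 = unname(tools::md5sum(outputs[[k]])))))
  manPath <- file.path(config$outputDir, "manifest.json")
  jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, pretty = TRUE)
  manifest$manifestPath <- manPath
  invisible(manifest)
}
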