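## Central S4 data objects for the texture-robustness pipeline.
##
## Coordinate convention, used everywhere: arrays are indexed (x, y, z)
## with x and y in-plane and z the slice axis; voxel i (1-based) is
## centered at physical position (i - 0.5) * spacing[axis] mm.

#' ImageVolume: a 3D scalar image with physical voxel spacing
#'
#' A plain 3D numeric array of finite intensities together with the voxel
#' spacing in millimetres along (x, y, z).
#'
#' @slot values 3D numeric array of finite intensities.
#' @slot spacing Numeric length 3, voxel spacing in mm, strictly positive.
#' @aliases ImageVolume-class
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(values = "array", spacing = "numeric"))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "all voxel values must be finite")
  if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive lengths (mm)")
  if (length(msg)) msg else TRUE
})

#' ROIMask: a binary region-of-interest mask
#'
#' Logical 3D array congruent with its paired \linkS4class{ImageVolume};
#' TRUE voxels belong to the tumor volume of interest.
#'
#' @slot values 3D logical array.
#' @aliases ROIMask-class
#' @exportClass ROIMask
setClass("ROIMask", representation(values = "array"))

setValidity("ROIMask", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (!is.logical(object@values) || anyNA(object@values))
    msg <- c(msg, "mask values must be logical and non-missing")
  if (length(msg)) msg else TRUE
})

#' QuantizedVolume: integer grey levels on the masked voxels
#'
#' The result of min--max uniform quantization of an ImageVolume over its
#' ROI: masked voxels hold an integer level in 1..N, voxels outside the
#' mask hold NA.
#'
#' @slot levels 3D integer array; NA outside the mask.
#' @slot nLevels Integer N >= 2, the dynamic range.
#' @slot spacing Voxel spacing in mm carried through from the source image.
#' @aliases QuantizedVolume-class
#' @exportClass QuantizedVolume
setClass("QuantizedVolume",
  representation(levels = "array", nLevels = "integer", spacing = "numeric"))

setValidity("QuantizedVolume", function(object) {
  msg <- character()
  if (length(dim(object@levels)) != 3L)
    msg <- c(msg, "'levels' must be a 3D array")
  if (length(object@nLevels) != 1L || is.na(object@nLevels) ||
      object@nLevels < 1L)
    msg <- c(msg, "'nLevels' must be a single positive integer")
  lv <- object@levels[!is.na(object@levels)]
  if (length(lv) == 0L)
    msg <- c(msg, "mask is empty: no quantized voxels")
  else if (any(lv < 1L) || any(lv > object@nLevels))
    msg <- c(msg, "masked levels must lie in [1, nLevels]")
  if (length(msg)) msg else TRUE
})

#' CooccurrenceMatrix: 3D grey-level co-occurrence counts
#'
#' Square matrix of co-occurrence counts over the 26-neighbourhood at unit
#' Chebyshev distance: cell (i, j) counts the ordered pairs of adjacent
#' masked voxels with levels i and j. Both orders of each pair are
#' counted, so the matrix is symmetric. Feature formulas operate on the
#' count matrix normalized to unit sum (see \code{\link{probabilities}}).
#'
#' @slot counts N x N numeric matrix of non-negative counts.
#' @slot nLevels Integer N.
#' @aliases CooccurrenceMatrix-class
#' @exportClass CooccurrenceMatrix
setClass("CooccurrenceMatrix",
  representation(counts = "matrix", nLevels = "integer"))

setValidity("CooccurrenceMatrix", function(object) {
  msg <- character()
  cm <- object@counts
  if (nrow(cm) != object@nLevels || ncol(cm) != object@nLevels)
    msg <- c(msg, "'counts' must be nLevels x nLevels")
  if (any(cm < 0))
    msg <- c(msg, "counts must be non-negative")
  if (sum(cm) <= 0)
    msg <- c(msg, "total count must be positive")
  if (!isTRUE(all.equal(cm, t(cm))))
    msg <- c(msg, "counts must be symmetric")
  if (length(msg)) msg else TRUE
})

#' RunLengthMatrix: 3D grey-level run-length counts
#'
#' Cell (i, j) counts the maximal collinear runs of j consecutive masked
#' voxels at level i, accumulated over all 13 antipodal direction pairs of
#' the 3D 26-neighbourhood. Runs break at mask boundaries and level
#' changes; every masked voxel belongs to exactly one run per direction,
#' so sum(counts * runLength) = 13 * (number of masked voxels).
#'
#' @slot counts N x M numeric matrix; column j holds runs of length j.
#' @slot nLevels Integer N.
#' @aliases RunLengthMatrix-class
#' @exportClass RunLengthMatrix
setClass("RunLengthMatrix",
  representation(counts = "matrix", nLevels = "integer"))

setValidity("RunLengthMatrix", function(object) {
  msg <- character()
  rlm <- object@counts
  if (nrow(rlm) != object@nLevels)
    msg <- c(msg, "'counts' must have nLevels rows")
  if (any(rlm < 0))
    msg <- c(msg, "counts must be non-negative")
  if (sum(rlm) <= 0)
    msg <- c(msg, "number of runs must be positive")
  if (ncol(rlm) > 0 && all(rlm[, ncol(rlm)] == 0))
    msg <- c(msg, "last column must be non-zero (max run length is tight)")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of a synthetic tumor phantom
#'
#' Describes one synthetic contrast-enhanced T1-weighted tumor volume: an
#' ellipsoidal tumor with a bright enhancing rim and darker core, a
#' spatially correlated intra-tumor intensity field, and additive noise.
#' All lengths in mm, intensities in arbitrary units.
#'
#' @slot gridShape Integer length 3: voxels along (x, y, z).
#' @slot voxelSpacing Numeric length 3: voxel size in mm.
#' @slot tumorCenter Numeric length 3: ellipsoid center, physical mm.
#' @slot tumorRadii Numeric length 3: ellipsoid semi-axes in mm.
#' @slot rimFraction Fraction of each radius occupied by the rim, in [0, 1).
#' @slot coreLevel,rimLevel,backgroundLevel Mean intensities; the
#'   enhancing-rim phenotype requires rimLevel > coreLevel > backgroundLevel.
#' @slot textureAmplitude Standard deviation of the correlated
#'   intra-tumor field (intensity units).
#' @slot textureCorrelationLength Isotropic correlation length in mm.
#' @slot noiseSigma Additive Gaussian noise standard deviation.
#' @slot seed Integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @aliases PhantomSpec-class
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    gridShape = "integer", voxelSpacing = "numeric",
    tumorCenter = "numeric", tumorRadii = "numeric",
    rimFraction = "numeric",
    coreLevel = "numeric", rimLevel = "numeric",
    backgroundLevel = "numeric",
    textureAmplitude = "numeric", textureCorrelationLength = "numeric",
    noiseSigma = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "'gridShape' must be 3 positive integers")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msg <- c(msg, "'voxelSpacing' must be 3 positive lengths (mm)")
  if (length(object@tumorRadii) != 3L || any(object@tumorRadii <= 0))
    msg <- c(msg, "'tumorRadii' must be 3 strictly positive lengths (mm)")
  if (object@rimFraction < 0 || object@rimFraction >= 1)
    msg <- c(msg, "'rimFraction' must lie in [0, 1)")
  if (!(object@rimLevel > object@coreLevel &&
        object@coreLevel > object@backgroundLevel))
    msg <- c(msg,
      "enhancing-rim phenotype requires rimLevel > coreLevel > backgroundLevel")
  if (object@textureAmplitude < 0 || object@noiseSigma < 0 ||
      object@textureCorrelationLength <= 0)
    msg <- c(msg,
      "'textureAmplitude'/'noiseSigma' must be >= 0 and correlation length > 0")
  ## the full ellipsoid must sit inside the grid's physical extent
  if (length(msg) == 0L) {
    extent <- object@gridShape * object@voxelSpacing
    lo <- object@tumorCenter - object@tumorRadii
    hi <- object@tumorCenter + object@tumorRadii
    bad <- which(lo < 0 | hi > extent)
    if (length(bad))
      msg <- c(msg, sprintf(
        "tumor ellipsoid exceeds the grid along axis %s (extent %.1f mm)",
        paste(c("x", "y", "z")[bad], collapse = ", "),
        extent[bad[1]]))
  }
  if (length(msg)) msg else TRUE
})

#' TumorPhantom: a synthetic image + ROI mask pair
#'
#' @slot image An \linkS4class{ImageVolume}.
#' @slot mask The congruent \linkS4class{ROIMask}.
#' @slot spec The \linkS4class{PhantomSpec} that generated it.
#' @aliases TumorPhantom-class
#' @exportClass TumorPhantom
setClass("TumorPhantom",
  representation(image = "ImageVolume", mask = "ROIMask",
                 spec = "PhantomSpec"))

setValidity("TumorPhantom", function(object) {
  msg <- character()
  if (!identical(dim(object@image@values), dim(object@mask@values)))
    msg <- c(msg, "image and mask must share the same grid shape")
  if (!any(object@mask@values))
    msg <- c(msg, "mask must be non-empty")
  if (length(msg)) msg else TRUE
})

#' SpatialConfig: one spatial-resolution configuration
#'
#' Target in-plane matrix size and slice thickness for preprocessing.
#' The slice thickness must be 1x or 2x the source thickness (2x is
#' obtained by merging consecutive slice pairs).
#'
#' @slot matrixSize Integer in-plane target (both in-plane axes).
#' @slot sliceThickness Target slice thickness in mm.
#' @aliases SpatialConfig-class
#' @exportClass SpatialConfig
setClass("SpatialConfig",
  representation(matrixSize = "integer", sliceThickness = "numeric"))

setValidity("SpatialConfig", function(object) {
  msg <- character()
  if (length(object@matrixSize) != 1L || object@matrixSize < 2L)
    msg <- c(msg, "'matrixSize' must be a single integer >= 2")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    msg <- c(msg, "'sliceThickness' must be a single positive length (mm)")
  if (length(msg)) msg else TRUE
})

#' RobustnessTable: cohort coefficient-of-variation summary
#'
#' One row per texture feature, one column per grouping (spatial
#' configurations when the dynamic range is varied; dynamic ranges when
#' the spatial resolution is varied). Cells hold the mean and standard
#' deviation, across subjects, of the per-subject coefficient of
#' variation, both in percent. A cell is robust when its mean CV is
#' strictly below the threshold (default 10 percent).
#'
#' @slot meanCV Numeric matrix, features x groupings, percent.
#' @slot sdCV Numeric matrix, same shape, percent.
#' @slot experiment Character: what was varied within each CV series
#'   ("dynamic-range" or "spatial-resolution").
#' @slot nSubjects Number of subjects aggregated.
#' @slot threshold Robustness threshold in percent (strict inequality).
#' @aliases RobustnessTable-class
#' @exportClass RobustnessTable
setClass("RobustnessTable",
  representation(meanCV = "matrix", sdCV = "matrix",
                 experiment = "character", nSubjects = "integer",
                 threshold = "numeric"))

setValidity("RobustnessTable", function(object) {
  msg <- character()
  if (!identical(dim(object@meanCV), dim(object@sdCV)))
    msg <- c(msg, "'meanCV' and 'sdCV' must have the same shape")
  if (any(object@meanCV < 0, na.rm = TRUE) ||
      any(object@sdCV < 0, na.rm = TRUE))
    msg <- c(msg, "CV means and SDs must be non-negative")
  if (length(object@threshold) != 1L || object@threshold <= 0)
    msg <- c(msg, "'threshold' must be a single positive percentage")
  if (length(msg)) msg else TRUE
})
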