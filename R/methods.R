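## Constructors, accessors and show() methods.

#' Construct an ImageVolume
#'
#' @param values 3D numeric array of finite intensities.
#' @param spacing Voxel spacing in mm along (x, y, z).
#' @return An \linkS4class{ImageVolume}.
#' @examples
#' vol <- ImageVolume(array(runif(8 * 8 * 4), c(8, 8, 4)), c(1, 1, 1))
#' dim(voxelData(vol))
#' @export
ImageVolume <- function(values, spacing = c(1, 1, 1)) {
  new("ImageVolume", values = values, spacing = as.numeric(spacing))
}

#' Construct an ROIMask
#'
#' @param values 3D array; coerced to logical (non-zero = inside).
#' @return An \linkS4class{ROIMask}.
#' @export
ROIMask <- function(values) {
  v <- values
  if (!is.logical(v)) {
    v <- array(as.logical(v != 0), dim = dim(values))
  }
  new("ROIMask", values = v)
}

#' Construct a SpatialConfig
#'
#' @param matrixSize Target in-plane matrix size (applied to both in-plane
#'   axes).
#' @param sliceThickness Target slice thickness in mm (must be 1x or 2x
#'   the source thickness when used).
#' @return A \linkS4class{SpatialConfig}.
#' @export
SpatialConfig <- function(matrixSize, sliceThickness) {
  new("SpatialConfig", matrixSize = as.integer(matrixSize),
      sliceThickness = as.numeric(sliceThickness))
}

#' @rdname RadTex3D-generics
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@values)
#' @rdname RadTex3D-generics
#' @export
setMethod("voxelData", "ROIMask", function(x) x@values)
#' @rdname RadTex3D-generics
#' @export
setMethod("voxelData", "QuantizedVolume", function(x) x@levels)

#' @rdname RadTex3D-generics
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)
#' @rdname RadTex3D-generics
#' @export
setMethod("spacing", "QuantizedVolume", function(x) x@spacing)

#' @rdname RadTex3D-generics
#' @export
setMethod("nLevels", "QuantizedVolume", function(x) x@nLevels)
#' @rdname RadTex3D-generics
#' @export
setMethod("nLevels", "CooccurrenceMatrix", function(x) x@nLevels)
#' @rdname RadTex3D-generics
#' @export
setMethod("nLevels", "RunLengthMatrix", function(x) x@nLevels)

#' @rdname RadTex3D-generics
#' @export
setMethod("counts", "CooccurrenceMatrix", function(object, ...) object@counts)
#' @rdname RadTex3D-generics
#' @export
setMethod("counts", "RunLengthMatrix", function(object, ...) object@counts)

#' @rdname RadTex3D-generics
#' @export
setMethod("probabilities", "CooccurrenceMatrix",
          function(x) x@counts / sum(x@counts))

#' @rdname RadTex3D-generics
#' @export
setMethod("nRuns", "RunLengthMatrix", function(x) sum(x@counts))
#' @rdname RadTex3D-generics
#' @export
setMethod("maxRunLength", "RunLengthMatrix", function(x) ncol(x@counts))

#' @rdname RadTex3D-generics
#' @export
setMethod("phantomImage", "TumorPhantom", function(x) x@image)
#' @rdname RadTex3D-generics
#' @export
setMethod("phantomMask", "TumorPhantom", function(x) x@mask)

#' @rdname RadTex3D-generics
#' @export
setMethod("meanCV", "RobustnessTable", function(x) x@meanCV)
#' @rdname RadTex3D-generics
#' @export
setMethod("sdCV", "RobustnessTable", function(x) x@sdCV)

#' @rdname RadTex3D-generics
#' @export
setMethod("robustFlags", "RobustnessTable",
          function(x) x@meanCV < x@threshold)

#' @rdname RadTex3D-generics
#' @export
setMethod("overallRobust", "RobustnessTable", function(x) {
  fl <- robustFlags(x)
  apply(fl, 1L, all)
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageVolume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "ROIMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("ROIMask: %d x %d x %d grid, %d voxels in ROI\n",
              d[1], d[2], d[3], sum(object@values)))
})

setMethod("show", "QuantizedVolume", function(object) {
  d <- dim(object@levels)
  cat(sprintf(
    "QuantizedVolume: %d x %d x %d grid, %d masked voxels, %d grey levels\n",
    d[1], d[2], d[3], sum(!is.na(object@levels)), object@nLevels))
})

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat(sprintf(
    "CooccurrenceMatrix: %d grey levels, %d ordered neighbor pairs\n",
    object@nLevels, sum(object@counts)))
})

setMethod("show", "RunLengthMatrix", function(object) {
  cat(sprintf(
    "RunLengthMatrix: %d grey levels, %d runs, longest run %d voxels\n",
    object@nLevels, sum(object@counts), ncol(object@counts)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec\n")
  cat(sprintf("  grid %s voxels at %s mm\n",
              paste(object@gridShape, collapse = " x "),
              paste(format(object@voxelSpacing), collapse = " x ")))
  cat(sprintf("  tumor radii %s mm, rim fraction %.2f\n",
              paste(format(object@tumorRadii), collapse = " x "),
              object@rimFraction))
  cat(sprintf("  levels bg/core/rim = %.4g / %.4g / %.4g\n",
              object@backgroundLevel, object@coreLevel, object@rimLevel))
  cat(sprintf(
    "  texture sd %.4g (corr. length %.4g mm), noise sd %.4g, seed %d\n",
    object@textureAmplitude, object@textureCorrelationLength,
    object@noiseSigma, object@seed))
})

setMethod("show", "TumorPhantom", function(object) {
  d <- dim(object@image@values)
  cat(sprintf("TumorPhantom: %d x %d x %d voxels, %d in ROI (%.1f%%)\n",
              d[1], d[2], d[3], sum(object@mask@values),
              100 * mean(object@mask@values)))
})

setMethod("show", "SpatialConfig", function(object) {
  cat(sprintf("SpatialConfig: matrix %dx%d, slice thickness %g mm\n",
              object@matrixSize, object@matrixSize, object@sliceThickness))
})

setMethod("show", "RobustnessTable", function(object) {
  cat(sprintf(
    "RobustnessTable (%s varied): %d features x %d groupings, %d subjects\n",
    object@experiment, nrow(object@meanCV), ncol(object@meanCV),
    object@nSubjects))
  disp <- matrix(sprintf("%.2f (%.2f)", object@meanCV, object@sdCV),
                 nrow = nrow(object@meanCV),
                 dimnames = dimnames(object@meanCV))
  disp[robustFlags(object)] <- paste0(disp[robustFlags(object)], " *")
  print(as.data.frame(disp), right = FALSE)
  cat(sprintf("* mean CV < %g%% (robust)\n", object@threshold))
})

#' Coerce a RobustnessTable to a tidy data.frame
#'
#' @param x A \linkS4class{RobustnessTable}.
#' @param ... Unused.
#' @return A data.frame with columns feature, grouping, mean_cv, sd_cv,
#'   robust and a human-readable "mean (SD)" column.
#' @export
as.data.frame.RobustnessTable <- function(x, ...) {
  mc <- x@meanCV
  fl <- robustFlags(x)
  data.frame(
    feature = rep(rownames(mc), times = ncol(mc)),
    grouping = rep(colnames(mc), each = nrow(mc)),
    mean_cv = as.vector(mc),
    sd_cv = as.vector(x@sdCV),
    robust = as.vector(fl),
    display = sprintf("%.2f (%.2f)", as.vector(mc), as.vector(x@sdCV)),
    stringsAsFactors = FALSE)
}
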