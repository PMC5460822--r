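## Preprocessing: in-plane resampling, slice merging, grey-level
## quantization, and the spatial x dynamic-range configuration grid.

#' Resample a volume in-plane by bilinear interpolation
#'
#' Downsamples both in-plane axes to \code{target} samples per axis using
#' bilinear interpolation evaluated at the new voxel centres (voxel-centre
#' convention: output centre j sits at old fractional index
#' \code{(j - 0.5) * nOld / nNew + 0.5}). The physical in-plane extent is
#' preserved: the new spacing is the old spacing scaled by
#' \code{nOld / nNew}. The mask is interpolated the same way and
#' re-binarized at 0.5 (values >= 0.5 are inside). Upsampling is refused;
#' the identity target returns the inputs unchanged.
#'
#' @param volume An \linkS4class{ImageVolume}.
#' @param mask The congruent \linkS4class{ROIMask}.
#' @param target Target in-plane matrix size (both in-plane axes).
#' @return A list with elements \code{image} and \code{mask}.
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 1))
#' low <- resampleInPlane(phantomImage(ph), phantomMask(ph), 38)
#' dim(voxelData(low$image))
#' @export
resampleInPlane <- function(volume, mask, target) {
  stopifnot(is(volume, "ImageVolume"), is(mask, "ROIMask"))
  target <- as.integer(target)
  d <- dim(volume@values)
  if (!identical(dim(mask@values), d))
    stop("image and mask shapes differ")
  if (target > d[1] || target > d[2])
    stop(sprintf(
      "upsampling not supported: target %d exceeds in-plane size %dx%d",
      target, d[1], d[2]))
  if (target == d[1] && target == d[2])
    return(list(image = volume, mask = mask))

  img <- .bilinearInPlane(volume@values, target)
  mnum <- .bilinearInPlane(array(as.numeric(mask@values), dim = d), target)
  m <- mnum >= 0.5
  if (!any(m))
    stop(sprintf("mask empty after resampling to %dx%d", target, target))
  newSpacing <- volume@spacing * c(d[1] / target, d[2] / target, 1)
  list(image = ImageVolume(img, newSpacing),
       mask = new("ROIMask", values = m))
}

## Separable bilinear interpolation of the two in-plane axes of a 3D
## array onto a target x target in-plane grid, voxel-centre convention.
.bilinearInPlane <- function(x, target) {
  .linearAxis(.linearAxis(x, target, 1L), target, 2L)
}

.linearAxis <- function(x, target, axis) {
  d <- dim(x)
  n <- d[axis]
  u <- (seq_len(target) - 0.5) * (n / target) + 0.5
  u <- pmin(pmax(u, 1), n)
  i0 <- pmin(pmax(floor(u), 1), n - 1)
  w <- u - i0
  if (axis == 1L) {
    lo <- x[i0, , , drop = FALSE]
    hi <- x[i0 + 1, , , drop = FALSE]
    lo * (1 - w) + hi * w           # w recycles down the first dimension
  } else {
    lo <- x[, i0, , drop = FALSE]
    hi <- x[, i0 + 1, , drop = FALSE]
    sweep(lo, 2L, 1 - w, "*") + sweep(hi, 2L, w, "*")
  }
}

#' Halve the through-plane resolution by merging slice pairs
#'
#' Each output slice is the voxelwise mean of one disjoint pair of
#' consecutive input slices, doubling the slice thickness. With an odd
#' slice count the trailing slice is dropped with a warning. The mask is
#' merged the same way and re-binarized at 0.5.
#'
#' @param volume An \linkS4class{ImageVolume} with at least 2 slices.
#' @param mask The congruent \linkS4class{ROIMask}.
#' @return A list with elements \code{image} and \code{mask}.
#' @export
mergeSlices <- function(volume, mask) {
  stopifnot(is(volume, "ImageVolume"), is(mask, "ROIMask"))
  d <- dim(volume@values)
  if (!identical(dim(mask@values), d))
    stop("image and mask shapes differ")
  nz <- d[3]
  if (nz < 2L)
    stop("slice merging needs at least 2 slices")
  if (nz %% 2L == 1L) {
    warning(sprintf("odd slice count %d: dropping the final slice", nz))
    nz <- nz - 1L
  }
  odd <- seq.int(1L, nz, by = 2L)
  img <- (volume@values[, , odd, drop = FALSE] +
            volume@values[, , odd + 1L, drop = FALSE]) / 2
  mv <- mask@values
  mnum <- (mv[, , odd, drop = FALSE] + mv[, , odd + 1L, drop = FALSE]) / 2
  m <- mnum >= 0.5
  if (!any(m))
    stop("mask empty after slice merging")
  list(image = ImageVolume(img, volume@spacing * c(1, 1, 2)),
       mask = new("ROIMask", values = m))
}

#' Quantize ROI intensities into N equal-width grey levels
#'
#' Min--max uniform quantization computed within the ROI: the masked
#' intensity range is split into N equal-width bins, half-open with the
#' top bin closed, so the minimum maps to level 1 and the maximum to
#' level N. If all masked intensities are equal every masked voxel maps
#' to level 1. Voxels outside the mask are NA. Bounds are recomputed per
#' call, i.e. per configuration after any resampling.
#'
#' @param volume An \linkS4class{ImageVolume}.
#' @param mask The congruent \linkS4class{ROIMask} with >= 2 voxels.
#' @param nLevels The dynamic range N >= 2 (16, 32 or 64 in the default
#'   analysis grid).
#' @return A \linkS4class{QuantizedVolume}.
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 1))
#' q <- quantizeVolume(phantomImage(ph), phantomMask(ph), 16)
#' range(voxelData(q), na.rm = TRUE)
#' @export
quantizeVolume <- function(volume, mask, nLevels) {
  stopifnot(is(volume, "ImageVolume"), is(mask, "ROIMask"))
  nLevels <- as.integer(nLevels)
  if (is.na(nLevels) || nLevels < 2L)
    stop("'nLevels' must be an integer >= 2")
  d <- dim(volume@values)
  if (!identical(dim(mask@values), d))
    stop("image and mask shapes differ")
  m <- mask@values
  nvox <- sum(m)
  if (nvox < 2L)
    stop("quantization needs a mask with at least 2 voxels")
  v <- volume@values[m]
  mn <- min(v)
  mx <- max(v)
  lv <- array(NA_integer_, dim = d)
  if (mx > mn) {
    lev <- floor((v - mn) / (mx - mn) * nLevels) + 1L
    lev[lev > nLevels] <- nLevels      # the top bin is closed
    lv[m] <- as.integer(lev)
  } else {
    lv[m] <- 1L                        # degenerate constant ROI
  }
  new("QuantizedVolume", levels = lv, nLevels = nLevels,
      spacing = volume@spacing)
}

#' Default spatial-resolution configurations for a source volume
#'
#' Mirrors the analysed acquisition grid: the native in-plane matrix and
#' a standard-matrix downsampling in the native proportion 256/432, each
#' at the native slice thickness and at twice that thickness — four
#' configurations. For the emulated full-scale acquisition these are
#' 432/256 pixels at 1/2 mm.
#'
#' @param volume An \linkS4class{ImageVolume} (source geometry).
#' @return A list of 4 \linkS4class{SpatialConfig} objects.
#' @export
defaultSpatialConfigs <- function(volume) {
  stopifnot(is(volume, "ImageVolume"))
  n <- dim(volume@values)[1]
  st <- volume@spacing[3]
  sizes <- c(n, as.integer(round(n * 256 / 432)))
  out <- list()
  for (ms in sizes)
    for (f in c(1, 2))
      out[[length(out) + 1L]] <- SpatialConfig(ms, st * f)
  out
}

#' Build the spatial x dynamic-range configuration grid for one subject
#'
#' Applies each spatial configuration (in-plane resampling, then slice
#' merging when the target thickness is twice the source) and each
#' grey-level count to the subject's image + mask, re-quantizing per
#' configuration. The default grid is 4 spatial x 3 grey-level = 12
#' labelled datasets. Labels follow \code{m\{matrix\}_st\{thickness\}mm_dr\{N\}}.
#'
#' @param phantom A \linkS4class{TumorPhantom}, or a list with elements
#'   \code{image} and \code{mask}.
#' @param spatialConfigs List of \linkS4class{SpatialConfig}; default
#'   \code{defaultSpatialConfigs(image)}.
#' @param greyLevels Integer vector of dynamic ranges; default
#'   \code{c(16, 32, 64)}.
#' @return A named list, one element per configuration, each a list with
#'   \code{q} (the \linkS4class{QuantizedVolume}), \code{matrixSize},
#'   \code{sliceThickness}, \code{nLevels} and \code{label}.
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 1))
#' grid <- buildConfigurationGrid(ph)
#' names(grid)
#' @export
buildConfigurationGrid <- function(phantom,
                                   spatialConfigs = NULL,
                                   greyLevels = c(16L, 32L, 64L)) {
  if (is(phantom, "TumorPhantom")) {
    image <- phantom@image
    mask <- phantom@mask
  } else {
    image <- phantom$image
    mask <- phantom$mask
  }
  stopifnot(is(image, "ImageVolume"), is(mask, "ROIMask"))
  if (is.null(spatialConfigs))
    spatialConfigs <- defaultSpatialConfigs(image)
  if (length(spatialConfigs) == 0L || length(greyLevels) == 0L)
    stop("configuration lists must be non-empty")
  greyLevels <- as.integer(greyLevels)

  out <- list()
  for (sc in spatialConfigs) {
    validObject(sc)
    ratio <- sc@sliceThickness / image@spacing[3]
    if (!isTRUE(all.equal(ratio, 1)) && !isTRUE(all.equal(ratio, 2)))
      stop(sprintf(
        "slice thickness %g mm is neither 1x nor 2x the source (%g mm)",
        sc@sliceThickness, image@spacing[3]))
    pre <- tryCatch({
      r <- resampleInPlane(image, mask, sc@matrixSize)
      if (isTRUE(all.equal(ratio, 2))) r <- mergeSlices(r$image, r$mask)
      r
    }, error = function(e) {
      stop(sprintf("configuration m%d_st%gmm failed: %s",
                   sc@matrixSize, sc@sliceThickness,
                   conditionMessage(e)), call. = FALSE)
    })
    for (N in greyLevels) {
      label <- sprintf("m%d_st%gmm_dr%d", sc@matrixSize,
                       sc@sliceThickness, N)
      q <- tryCatch(
        quantizeVolume(pre$image, pre$mask, N),
        error = function(e) {
          stop(sprintf("configuration %s failed: %s", label,
                       conditionMessage(e)), call. = FALSE)
        })
      out[[label]] <- list(q = q, matrixSize = sc@matrixSize,
                           sliceThickness = sc@sliceThickness,
                           nLevels = N, label = label)
    }
  }
  out
}
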