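## Synthetic tumor phantoms: seeded, controllable stand-ins for
## contrast-enhanced T1-weighted brain tumor MRI.

#' Construct a PhantomSpec
#'
#' Defaults describe a test-scale phantom: a 64 x 64 x 16 grid at
#' 1 x 1 x 1 mm holding a centred ellipsoidal tumor with an enhancing rim
#' (brightest), a darker core, a spatially correlated intra-tumor
#' intensity field and additive Gaussian noise. The acquisition the
#' phantom emulates uses a 432 x 432 in-plane matrix at 0.5 x 0.5 x 1 mm;
#' use \code{fullScale = TRUE} for that geometry.
#'
#' @param gridShape Voxels along (x, y, z).
#' @param voxelSpacing Voxel size in mm.
#' @param tumorCenter Ellipsoid centre in physical mm; default grid centre.
#' @param tumorRadii Ellipsoid semi-axes in mm.
#' @param rimFraction Fraction of each radius occupied by the bright rim.
#' @param coreLevel,rimLevel,backgroundLevel Mean intensities (a.u.);
#'   must satisfy rimLevel > coreLevel > backgroundLevel.
#' @param textureAmplitude SD of the correlated intra-tumor field (a.u.).
#' @param textureCorrelationLength Isotropic correlation length in mm.
#' @param noiseSigma Additive Gaussian noise SD (a.u.).
#' @param seed Integer seed; same spec + seed is bit-reproducible.
#' @param fullScale If TRUE, override geometry to the emulated
#'   acquisition: 432 x 432 x 96 voxels at 0.5 x 0.5 x 1 mm with
#'   proportionally scaled tumor radii.
#' @return A validated \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(seed = 7)
#' spec
#' @export
phantomSpec <- function(gridShape = c(64, 64, 16),
                        voxelSpacing = c(1, 1, 1),
                        tumorCenter = NULL,
                        tumorRadii = c(18, 14, 6),
                        rimFraction = 0.3,
                        coreLevel = 100, rimLevel = 160,
                        backgroundLevel = 20,
                        textureAmplitude = 15,
                        textureCorrelationLength = 3,
                        noiseSigma = 5,
                        seed = 1L,
                        fullScale = FALSE) {
  if (fullScale) {
    gridShape <- c(432, 432, 96)
    voxelSpacing <- c(0.5, 0.5, 1)
    tumorRadii <- c(60, 45, 30)
    tumorCenter <- NULL
  }
  if (is.null(tumorCenter))
    tumorCenter <- gridShape * voxelSpacing / 2
  new("PhantomSpec",
      gridShape = as.integer(gridShape),
      voxelSpacing = as.numeric(voxelSpacing),
      tumorCenter = as.numeric(tumorCenter),
      tumorRadii = as.numeric(tumorRadii),
      rimFraction = as.numeric(rimFraction),
      coreLevel = as.numeric(coreLevel),
      rimLevel = as.numeric(rimLevel),
      backgroundLevel = as.numeric(backgroundLevel),
      textureAmplitude = as.numeric(textureAmplitude),
      textureCorrelationLength = as.numeric(textureCorrelationLength),
      noiseSigma = as.numeric(noiseSigma),
      seed = as.integer(seed))
}

## Squared normalized ellipsoid radius at every voxel centre:
## r2 <= 1 inside the tumor, r2 <= (1 - rimFraction)^2 inside the core.
.ellipsoidR2 <- function(spec) {
  d <- spec@gridShape
  sp <- spec@voxelSpacing
  ex <- ((.axisCenters(d[1], sp[1]) - spec@tumorCenter[1]) /
           spec@tumorRadii[1])^2
  ey <- ((.axisCenters(d[2], sp[2]) - spec@tumorCenter[2]) /
           spec@tumorRadii[2])^2
  ez <- ((.axisCenters(d[3], sp[3]) - spec@tumorCenter[3]) /
           spec@tumorRadii[3])^2
  outer(outer(ex, ey, "+"), ez, "+")
}

#' Generate a synthetic tumor phantom
#'
#' Builds the voxelized ellipsoid mask (ellipsoid inequality evaluated at
#' voxel centres), assigns mean intensities (background outside, core
#' inside the shrunken ellipsoid of relative radius 1 - rimFraction, rim
#' in between), adds a spatially correlated zero-mean field inside the
#' tumor (seeded white noise smoothed by an isotropic Gaussian kernel of
#' width textureCorrelationLength, rescaled so its ROI standard deviation
#' equals textureAmplitude), adds independent Gaussian noise everywhere,
#' and clips at zero to mimic magnitude MRI.
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @return A \linkS4class{TumorPhantom}. Identical spec + seed gives a
#'   bit-identical result.
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 3))
#' ph
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  d <- spec@gridShape
  r2 <- .ellipsoidR2(spec)
  mask <- r2 <= 1
  if (!any(mask))
    stop("tumor ellipsoid contains no voxel centre")
  core <- r2 <= (1 - spec@rimFraction)^2

  img <- array(spec@backgroundLevel, dim = d)
  img[mask] <- spec@rimLevel
  img[core] <- spec@coreLevel

  .withSeed(spec@seed, {
    if (spec@textureAmplitude > 0) {
      white <- array(rnorm(prod(d)), dim = d)
      sigmaVox <- spec@textureCorrelationLength / spec@voxelSpacing
      field <- .smoothGaussian3D(white, sigmaVox)
      s <- stats::sd(field[mask])
      if (is.finite(s) && s > 0) {
        field <- (field - mean(field[mask])) / s * spec@textureAmplitude
        img[mask] <- img[mask] + field[mask]
      }
    }
    if (spec@noiseSigma > 0)
      img <- img + array(rnorm(prod(d), sd = spec@noiseSigma), dim = d)
  })
  img[img < 0] <- 0

  new("TumorPhantom",
      image = ImageVolume(img, spec@voxelSpacing),
      mask = new("ROIMask", values = mask),
      spec = spec)
}

#' Generate a cohort of jittered phantoms
#'
#' Emulates a patient cohort: each subject receives a per-subject
#' perturbation of the base spec (tumor radii, centre, tissue levels,
#' texture amplitude and noise), drawn from a seeded stream so the cohort
#' is fully reproducible. The default cohort size matches the emulated
#' study population of 20 subjects.
#'
#' @param nSubjects Number of phantoms (>= 1).
#' @param baseSpec The \linkS4class{PhantomSpec} to jitter; default
#'   \code{phantomSpec()}.
#' @param seed Integer master seed for the cohort.
#' @return A list of \linkS4class{TumorPhantom}, names "subject01", ...
#' @examples
#' cohort <- generateCohort(3, seed = 11)
#' length(cohort)
#' @export
generateCohort <- function(nSubjects = 20L, baseSpec = phantomSpec(),
                           seed = 1L) {
  nSubjects <- as.integer(nSubjects)
  if (is.na(nSubjects) || nSubjects < 1L)
    stop("'nSubjects' must be a positive integer")
  validObject(baseSpec)
  lapply(stats::setNames(
    seq_len(nSubjects),
    sprintf("subject%02d", seq_len(nSubjects))), function(i) {
      subSeed <- (as.integer(seed) + i * 10007L) %% 2147483629L
      spec <- .withSeed(subSeed, .jitterSpec(baseSpec, subSeed))
      generatePhantom(spec)
    })
}

## One subject's perturbed spec; called inside a seeded RNG context.
.jitterSpec <- function(base, subSeed) {
  radii <- base@tumorRadii * runif(3, 0.85, 1.15)
  centre <- base@tumorCenter + runif(3, -1, 1)
  ## keep the jittered ellipsoid inside the grid
  extent <- base@gridShape * base@voxelSpacing
  radii <- pmin(radii, pmin(centre, extent - centre) * 0.999)
  lvl <- runif(1, 0.9, 1.1)
  phantomSpec(
    gridShape = base@gridShape,
    voxelSpacing = base@voxelSpacing,
    tumorCenter = centre,
    tumorRadii = radii,
    rimFraction = min(0.95, base@rimFraction * runif(1, 0.8, 1.2)),
    coreLevel = base@coreLevel * lvl,
    rimLevel = base@rimLevel * lvl * runif(1, 1.0, 1.1),
    backgroundLevel = base@backgroundLevel * lvl,
    textureAmplitude = base@textureAmplitude * runif(1, 0.8, 1.2),
    textureCorrelationLength = base@textureCorrelationLength,
    noiseSigma = base@noiseSigma * runif(1, 0.8, 1.2),
    seed = (subSeed + 1L) %% 2147483629L)
}

#' Write a phantom as a NIfTI-1 image + mask pair
#'
#' The image is stored as 32-bit float, the mask as 8-bit unsigned
#' integer; voxel spacing goes into the NIfTI pixdim.
#'
#' @param phantom A \linkS4class{TumorPhantom}.
#' @param imagePath,maskPath Output .nii or .nii.gz paths.
#' @return Invisibly, a character vector of the two paths written.
#' @export
writePhantom <- function(phantom, imagePath, maskPath) {
  sp <- spacing(phantom@image)
  img <- RNifti::asNifti(voxelData(phantom@image))
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, imagePath, datatype = "float")
  msk <- RNifti::asNifti(array(as.integer(voxelData(phantom@mask)),
                               dim = dim(voxelData(phantom@mask))))
  RNifti::pixdim(msk) <- sp
  RNifti::writeNifti(msk, maskPath, datatype = "uint8")
  invisible(c(image = imagePath, mask = maskPath))
}

#' Serialize / restore a PhantomSpec as plain-text YAML
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @param path File path for the YAML document.
#' @return \code{writePhantomSpec} invisibly returns the path;
#'   \code{readPhantomSpec} returns the restored
#'   \linkS4class{PhantomSpec}.
#' @export
writePhantomSpec <- function(spec, path) {
  validObject(spec)
  sl <- methods::slotNames(spec)
  vals <- lapply(stats::setNames(sl, sl), function(s) methods::slot(spec, s))
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(phantomSpec, vals)
}
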