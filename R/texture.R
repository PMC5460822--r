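## The texture contribution: 3D co-occurrence and run-length matrices
## over the ROI, and the 16 heterogeneity features derived from them.

#' Build the 3D grey-level co-occurrence matrix
#'
#' Counts, for every ordered pair of masked voxels at unit Chebyshev
#' distance (i.e. over all 26 neighbors in 3D), the pair of grey levels
#' (level of the first voxel, level of the second). Both orders of every
#' unordered pair are counted, so the matrix is symmetric by
#' construction. Implemented by shifting the level array along the 13
#' antipodal-unique offsets and adding the transpose.
#'
#' @param q A \linkS4class{QuantizedVolume} with at least one masked
#'   voxel pair adjacent in the 26-neighbourhood.
#' @return A \linkS4class{CooccurrenceMatrix}.
#' @examples
#' lv <- array(NA_integer_, c(2, 1, 1)); lv[] <- c(1L, 2L)
#' q <- new("QuantizedVolume", levels = lv, nLevels = 2L,
#'          spacing = c(1, 1, 1))
#' counts(buildCM(q))
#' @export
buildCM <- function(q) {
  stopifnot(is(q, "QuantizedVolume"))
  lv <- q@levels
  N <- q@nLevels
  d <- dim(lv)
  if (sum(!is.na(lv)) < 2L)
    stop("co-occurrence needs at least 2 masked voxels")
  half <- matrix(0, N, N)
  dirs <- .directions13()
  for (k in seq_len(nrow(dirs))) {
    dd <- dirs[k, ]
    ia <- .shiftRanges(d, dd)
    if (is.null(ia)) next
    a <- lv[ia$src1, ia$src2, ia$src3, drop = FALSE]
    b <- lv[ia$dst1, ia$dst2, ia$dst3, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- (a[ok] - 1L) * N + b[ok]
    tab <- tabulate(idx, nbins = N * N)
    half <- half + matrix(tab, N, N, byrow = TRUE)
  }
  cnt <- half + t(half)
  if (sum(cnt) == 0)
    stop("no masked voxel pair is adjacent in the 26-neighbourhood; ",
         "texture is undefined for scattered masks")
  new("CooccurrenceMatrix", counts = cnt, nLevels = N)
}

## Index ranges pairing every voxel with its neighbor at offset d;
## NULL when the offset does not fit inside the grid.
.shiftRanges <- function(dims, d) {
  rng <- function(n, s) {
    if (s >= 0) list(src = seq_len(n - s), dst = seq_len(n - s) + s)
    else list(src = seq_len(n + s) - s, dst = seq_len(n + s))
  }
  if (any(dims - abs(d) < 1L)) return(NULL)
  r1 <- rng(dims[1], d[1]); r2 <- rng(dims[2], d[2]); r3 <- rng(dims[3], d[3])
  list(src1 = r1$src, src2 = r2$src, src3 = r3$src,
       dst1 = r1$dst, dst2 = r2$dst, dst3 = r3$dst)
}

#' Co-occurrence features: Entropy, Homogeneity, Contrast, Dissimilarity,
#' Uniformity
#'
#' Computed on the count matrix normalized to unit sum (the formulas are
#' only meaningful on probabilities), with natural logarithms and the
#' convention 0 * ln 0 = 0. A raw probability matrix may be supplied
#' instead; it is rejected unless it sums to 1.
#'
#' @param cm A \linkS4class{CooccurrenceMatrix}, or a square numeric
#'   matrix of probabilities summing to 1.
#' @return Named numeric vector of the 5 co-occurrence features.
#' @export
cmFeatures <- function(cm) {
  if (is(cm, "CooccurrenceMatrix")) {
    p <- probabilities(cm)
  } else if (is.matrix(cm)) {
    if (nrow(cm) != ncol(cm) || any(cm < 0) ||
        !isTRUE(all.equal(sum(cm), 1)))
      stop("matrix input must be square, non-negative probabilities ",
           "summing to 1")
    p <- cm
  } else stop("'cm' must be a CooccurrenceMatrix or a probability matrix")
  i <- row(p)
  j <- col(p)
  pos <- p > 0
  c(Entropy = -sum(p[pos] * log(p[pos])),
    Homogeneity = sum(p / (1 + (i - j)^2)),
    Contrast = sum(p * (i - j)^2),
    Dissimilarity = sum(p * abs(i - j)),
    Uniformity = sum(p^2))
}

#' Build the 3D grey-level run-length matrix
#'
#' For each of the 13 antipodal-unique directions of the 3D
#' 26-neighbourhood, the masked voxels are partitioned into maximal
#' collinear runs of constant grey level (runs break at level changes and
#' at unmasked voxels), and all runs of all 13 directions are accumulated
#' into a single matrix whose cell (i, j) counts runs of length j at
#' level i. The number of columns equals the longest observed run.
#'
#' Every masked voxel belongs to exactly one run per direction, so
#' \code{sum(counts * col(counts))} equals 13 times the ROI size.
#'
#' @param q A \linkS4class{QuantizedVolume} with a non-empty mask.
#' @return A \linkS4class{RunLengthMatrix}.
#' @export
buildRLM <- function(q) {
  stopifnot(is(q, "QuantizedVolume"))
  lv <- q@levels
  N <- q@nLevels
  d <- dim(lv)
  n <- prod(d)
  v <- as.integer(lv)
  v[is.na(v)] <- 0L                     # sentinel: breaks runs, discarded
  if (!any(v > 0L))
    stop("run-length matrix needs a non-empty mask")

  xs <- rep.int(seq_len(d[1]), d[2] * d[3])
  ys <- rep.int(rep(seq_len(d[2]), each = d[1]), d[3])
  zs <- rep(seq_len(d[3]), each = d[1] * d[2])
  K <- max(d) + 1
  B <- 3 * max(d) + 2

  dirs <- .directions13()
  allLev <- integer(0)
  allLen <- integer(0)
  for (k in seq_len(nrow(dirs))) {
    dd <- dirs[k, ]
    ax <- which(dd != 0L)[1]
    t <- switch(ax, xs, ys, zs)
    key <- ((xs - t * dd[1] + K) * B + (ys - t * dd[2] + K)) * B +
      (zs - t * dd[3] + K)
    ord <- order(key, t, method = "radix")
    kv <- key[ord]
    vv <- v[ord]
    newRun <- c(TRUE, kv[-1L] != kv[-n] | vv[-1L] != vv[-n])
    grp <- cumsum(newRun)
    len <- tabulate(grp)
    runLev <- vv[newRun]
    keep <- runLev > 0L
    allLev <- c(allLev, runLev[keep])
    allLen <- c(allLen, len[keep])
  }
  M <- max(allLen)
  cnt <- matrix(as.numeric(tabulate((allLen - 1L) * N + allLev,
                                    nbins = N * M)), N, M)
  new("RunLengthMatrix", counts = cnt, nLevels = N)
}

#' Run-length features
#'
#' The eleven run-length features: emphases on short/long runs and
#' low/high grey levels and their four combinations, grey-level and
#' run-length non-uniformity, and run percentage. All are computed on the
#' raw run counts with the 1/nr prefactor, where nr is the total number
#' of runs; run percentage is nr divided by the total voxel-direction
#' incidences \code{sum(counts * runLength)} (13 times the ROI size), so
#' it lies in (0, 1].
#'
#' @param rlm A \linkS4class{RunLengthMatrix}.
#' @return Named numeric vector of the 11 run-length features (LRE, SRE,
#'   LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE, GLNU, RLNU, RPC).
#' @export
rlmFeatures <- function(rlm) {
  stopifnot(is(rlm, "RunLengthMatrix"))
  R <- rlm@counts
  nr <- sum(R)
  if (nr <= 0) stop("run-length matrix holds no runs")
  i2 <- row(R)^2
  j2 <- col(R)^2
  c(LRE = sum(R * j2) / nr,
    SRE = sum(R / j2) / nr,
    LGRE = sum(R / i2) / nr,
    HGRE = sum(R * i2) / nr,
    SRLGE = sum(R / (i2 * j2)) / nr,
    SRHGE = sum(R * i2 / j2) / nr,
    LRLGE = sum(R * j2 / i2) / nr,
    LRHGE = sum(R * i2 * j2) / nr,
    GLNU = sum(rowSums(R)^2) / nr,
    RLNU = sum(colSums(R)^2) / nr,
    RPC = nr / sum(R * col(R)))
}

#' Extract all 16 texture features from a quantized volume
#'
#' Concatenates the 5 co-occurrence features of \code{\link{cmFeatures}}
#' and the 11 run-length features of \code{\link{rlmFeatures}}, in the
#' canonical order of \code{\link{textureFeatureNames}}.
#'
#' @param q A \linkS4class{QuantizedVolume}.
#' @return Named numeric vector of length 16.
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 1))
#' q <- quantizeVolume(phantomImage(ph), phantomMask(ph), 16)
#' extractFeatures(q)
#' @export
extractFeatures <- function(q) {
  fv <- c(cmFeatures(buildCM(q)), rlmFeatures(buildRLM(q)))
  fv[.featureNames]
}

#' Compute the cohort feature table
#'
#' Runs the configuration grid and feature extraction for every subject
#' and returns one tidy row per (subject, configuration): provenance
#' columns (subject, matrixSize, sliceThickness, nLevels, label) followed
#' by the 16 feature columns. With the default 4 x 3 grid a 20-subject
#' cohort yields 240 rows, i.e. 3840 feature values.
#'
#' @param phantoms Named list of \linkS4class{TumorPhantom} (or
#'   image/mask lists), e.g. from \code{\link{generateCohort}}.
#' @param spatialConfigs,greyLevels Passed to
#'   \code{\link{buildConfigurationGrid}}.
#' @return A data.frame.
#' @export
cohortFeatureTable <- function(phantoms, spatialConfigs = NULL,
                               greyLevels = c(16L, 32L, 64L)) {
  if (is.null(names(phantoms)))
    names(phantoms) <- sprintf("subject%02d", seq_along(phantoms))
  rows <- list()
  for (sub in names(phantoms)) {
    grid <- buildConfigurationGrid(phantoms[[sub]], spatialConfigs,
                                   greyLevels)
    for (cfg in grid) {
      fv <- extractFeatures(cfg$q)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sub, matrixSize = cfg$matrixSize,
        sliceThickness = cfg$sliceThickness, nLevels = cfg$nLevels,
        label = cfg$label, t(fv), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
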