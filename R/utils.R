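## Internal helpers: seeded evaluation, separable Gaussian smoothing,
## and the canonical 3D direction set.

## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's state afterwards.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## The 13 antipodal-unique unit directions of the 3D 26-neighbourhood
## (first non-zero component positive). Together with their negatives
## they enumerate all 26 neighbor offsets at unit Chebyshev distance.
.directions13 <- function() {
  d <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  storage.mode(d) <- "integer"
  d
}

## Separable Gaussian smoothing of a 3D array; sigma per axis in voxels.
## Edges are renormalized (convolution divided by the smoothed indicator)
## so a constant input stays exactly constant.
.smoothGaussian3D <- function(x, sigmaVox) {
  stopifnot(length(dim(x)) == 3L, length(sigmaVox) == 3L)
  num <- x
  den <- array(1, dim = dim(x))
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- dnorm(seq.int(-r, r), sd = s)
    k <- k / sum(k)
    num <- .convolveAlong(num, k, ax)
    den <- .convolveAlong(den, k, ax)
  }
  num / den
}

## 1D convolution of a 3D array along axis `ax` with an odd-length kernel,
## zero-padded at the boundaries.
.convolveAlong <- function(x, k, ax) {
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  n <- dp[1]
  m <- matrix(xp, nrow = n)
  r <- (length(k) - 1L) %/% 2L
  pad <- matrix(0, nrow = r, ncol = ncol(m))
  mp <- rbind(pad, m, pad)
  ## stats::filter runs the kernel over every column at once
  f <- stats::filter(mp, filter = k, method = "convolution", sides = 2)
  out <- f[(r + 1L):(r + n), , drop = FALSE]
  res <- array(as.numeric(out), dim = dp)
  aperm(res, order(perm))
}

## 1-based voxel-center coordinates along each axis, in mm.
.axisCenters <- function(n, sp) (seq_len(n) - 0.5) * sp

.featureNames <- c(
  "Entropy", "Homogeneity", "Contrast", "Dissimilarity", "Uniformity",
  "LRE", "SRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
  "GLNU", "RLNU", "RPC")

#' Names of the sixteen texture features, in canonical order
#'
#' Five co-occurrence features (Entropy, Homogeneity, Contrast,
#' Dissimilarity, Uniformity) followed by eleven run-length features
#' (LRE, SRE, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE, GLNU, RLNU, RPC).
#'
#' @return Character vector of length 16.
#' @export
textureFeatureNames <- function() .featureNames
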