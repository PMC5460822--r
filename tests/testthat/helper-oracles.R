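# Independent brute-force oracles and small fixtures, kept deliberately
# naive: they restate the definitions directly and share no code with the
# package implementation.

# Quantized volume from an integer array (NA = outside mask).
makeQ <- function(levels, nLevels = max(levels, na.rm = TRUE),
                  spacing = c(1, 1, 1)) {
  if (is.null(dim(levels))) dim(levels) <- c(length(levels), 1L, 1L)
  storage.mode(levels) <- "integer"
  new("QuantizedVolume", levels = levels, nLevels = as.integer(nLevels),
      spacing = spacing)
}

# All-26-neighbor co-occurrence counts by testing every ordered voxel
# pair for unit Chebyshev distance.
bruteCM <- function(q) {
  lv <- voxelData(q)
  N <- nLevels(q)
  d <- dim(lv)
  idx <- which(!is.na(lv), arr.ind = TRUE)
  lev <- lv[!is.na(lv)]
  n <- nrow(idx)
  cnt <- matrix(0, N, N)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      if (max(abs(idx[a, ] - idx[b, ])) == 1L)
        cnt[lev[a], lev[b]] <- cnt[lev[a], lev[b]] + 1
    }
  }
  cnt
}

# Run-length counts by walking every line of every direction from its
# run starts; a voxel starts a run when its predecessor along the
# direction is outside the grid, unmasked, or a different level.
bruteRLM <- function(q) {
  lv <- voxelData(q)
  N <- nLevels(q)
  d <- dim(lv)
  dirs <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  inside <- function(p) all(p >= 1L) && all(p <= d)
  at <- function(p) lv[p[1], p[2], p[3]]
  runs <- list()
  idx <- which(!is.na(lv), arr.ind = TRUE)
  for (k in seq_len(nrow(dirs))) {
    dd <- dirs[k, ]
    for (v in seq_len(nrow(idx))) {
      p <- idx[v, ]
      prev <- p - dd
      if (inside(prev) && !is.na(at(prev)) && at(prev) == at(p)) next
      len <- 1L
      nxt <- p + dd
      while (inside(nxt) && !is.na(at(nxt)) && at(nxt) == at(p)) {
        len <- len + 1L
        nxt <- nxt + dd
      }
      runs[[length(runs) + 1L]] <- c(at(p), len)
    }
  }
  runs <- do.call(rbind, runs)
  M <- max(runs[, 2])
  cnt <- matrix(0, N, M)
  for (r in seq_len(nrow(runs)))
    cnt[runs[r, 1], runs[r, 2]] <- cnt[runs[r, 1], runs[r, 2]] + 1
  cnt
}

# Random small quantized volume; guarantees a non-empty mask and (for
# co-occurrence use) at least one adjacent masked pair.
randomQ <- function(maxDim = 6L, maxLevels = 4L) {
  repeat {
    d <- sample(4:maxDim, 3L, replace = TRUE)
    N <- sample(2:maxLevels, 1L)
    lv <- array(sample.int(N, prod(d), replace = TRUE), dim = d)
    keep <- array(stats::runif(prod(d)) < 0.7, dim = d)
    lv[!keep] <- NA_integer_
    if (sum(keep) < 2L) next
    q <- makeQ(lv, N)
    ok <- tryCatch({ buildCM(q); TRUE }, error = function(e) FALSE)
    if (ok) return(q)
  }
}

# Small phantom spec used across test files: quick to simulate but with
# genuine rim/core/texture structure.
testSpec <- function(seed = 1L, ...) {
  phantomSpec(gridShape = c(32, 32, 12), voxelSpacing = c(1, 1, 1),
              tumorRadii = c(9, 7, 4), seed = seed, ...)
}
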