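# Co-occurrence and run-length construction and the 16 features.

test_that("the two-voxel volume gives the single symmetric pair", {
  q <- makeQ(c(1L, 2L))
  cm <- buildCM(q)
  expect_identical(counts(cm), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(probabilities(cm), matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("a constant ROI concentrates all co-occurrence mass", {
  q <- makeQ(array(2L, c(3, 3, 3)), nLevels = 4L)
  cm <- buildCM(q)
  p <- probabilities(cm)
  expect_equal(p[2, 2], 1)
  expect_equal(sum(p), 1)
})

test_that("co-occurrence counts match the brute-force pair enumeration", {
  set.seed(101)
  for (rep in 1:30) {
    q <- randomQ()
    expect_identical(unname(counts(buildCM(q))), bruteCM(q))
  }
})

test_that("co-occurrence matrices are symmetric with unit mass", {
  set.seed(202)
  for (rep in 1:20) {
    q <- randomQ()
    cm <- buildCM(q)
    expect_identical(counts(cm), t(counts(cm)))
    expect_equal(sum(probabilities(cm)), 1)
  }
})

test_that("a scattered mask with no adjacent pair is rejected", {
  lv <- array(NA_integer_, c(5, 5, 1))
  lv[1, 1, 1] <- 1L
  lv[5, 5, 1] <- 2L
  expect_error(buildCM(makeQ(lv, 2L)), "adjacent")
})

test_that("co-occurrence features reproduce the worked 2x2 example", {
  fv <- cmFeatures(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(fv[["Entropy"]], log(2))
  expect_equal(fv[["Contrast"]], 1)
  expect_equal(fv[["Dissimilarity"]], 1)
  expect_equal(fv[["Homogeneity"]], 0.5)
  expect_equal(fv[["Uniformity"]], 0.5)
})

test_that("degenerate and maximum-entropy distributions hit the bounds", {
  pConst <- matrix(0, 3, 3)
  pConst[2, 2] <- 1
  fv <- cmFeatures(pConst)
  expect_equal(fv[["Entropy"]], 0)
  expect_equal(fv[["Contrast"]], 0)
  expect_equal(fv[["Dissimilarity"]], 0)
  expect_equal(fv[["Homogeneity"]], 1)
  expect_equal(fv[["Uniformity"]], 1)
  for (N in c(4L, 8L)) {
    pU <- matrix(1 / N^2, N, N)
    fvU <- cmFeatures(pU)
    expect_equal(fvU[["Entropy"]], 2 * log(N))
    expect_equal(fvU[["Uniformity"]], 1 / N^2)
  }
  expect_error(cmFeatures(matrix(1, 2, 2)), "summing to 1")
})

test_that("a single masked voxel yields one length-1 run per direction", {
  lv <- array(NA_integer_, c(3, 3, 3))
  lv[2, 2, 2] <- 3L
  rlm <- buildRLM(makeQ(lv, 4L))
  expect_identical(nRuns(rlm), 13)
  expect_equal(counts(rlm)[3, 1], 13)
  expect_equal(sum(counts(rlm)), 13)
  fv <- rlmFeatures(rlm)
  expect_equal(fv[["SRE"]], 1)
  expect_equal(fv[["LRE"]], 1)
  expect_equal(fv[["LGRE"]], 1 / 9)
  expect_equal(fv[["HGRE"]], 9)
  expect_equal(fv[["GLNU"]], 13)
  expect_equal(fv[["RLNU"]], 13)
  expect_equal(fv[["RPC"]], 1)
})

test_that("the [1,1,2] line reproduces the enumerated run-length matrix", {
  q <- makeQ(c(1L, 1L, 2L))
  rlm <- buildRLM(q)
  cnt <- counts(rlm)
  # x axis: one run of two 1s and one single 2; the other 12 directions
  # each see three isolated voxels.
  expect_equal(cnt[1, 1], 24)
  expect_equal(cnt[1, 2], 1)
  expect_equal(cnt[2, 1], 13)
  expect_equal(nRuns(rlm), 38)
  expect_equal(sum(cnt * col(cnt)), 13 * 3)   # voxel conservation
  fv <- rlmFeatures(rlm)
  expect_equal(fv[["SRE"]], 37.25 / 38)
  expect_equal(fv[["LRE"]], 41 / 38)
})

test_that("run-length counts match the brute-force line walker", {
  set.seed(303)
  for (rep in 1:30) {
    q <- randomQ()
    expect_identical(unname(counts(buildRLM(q))), bruteRLM(q))
  }
})

test_that("every masked voxel joins exactly one run per direction", {
  set.seed(404)
  for (rep in 1:20) {
    q <- randomQ()
    cnt <- counts(buildRLM(q))
    nMasked <- sum(!is.na(voxelData(q)))
    expect_equal(sum(cnt * col(cnt)), 13 * nMasked)
    expect_true(any(cnt[, ncol(cnt)] > 0))   # max run length is tight
  }
})

test_that("short and long run emphases bracket 1", {
  set.seed(505)
  for (rep in 1:10) {
    fv <- rlmFeatures(buildRLM(randomQ()))
    expect_lte(fv[["SRE"]], 1)
    expect_gte(fv[["LRE"]], 1)
  }
})

test_that("grey-level reversal preserves the symmetric features and swaps
           the low/high emphases", {
  set.seed(606)
  q <- randomQ()
  N <- nLevels(q)
  lvRev <- N + 1L - voxelData(q)
  qRev <- makeQ(lvRev, N)
  symm <- c("Entropy", "Homogeneity", "Contrast", "Dissimilarity",
            "Uniformity", "SRE", "LRE", "RPC", "GLNU", "RLNU")
  f1 <- extractFeatures(q)
  f2 <- extractFeatures(qRev)
  expect_equal(f1[symm], f2[symm])
  # low/high emphases change under reversal; hand-computed on [1,1,2]
  # (runs: 24 x (1,len1), 1 x (1,len2), 13 x (2,len1), nr = 38) and its
  # reversal [2,2,1] (24 x (2,len1), 1 x (2,len2), 13 x (1,len1)).
  g1 <- rlmFeatures(buildRLM(makeQ(c(1L, 1L, 2L))))
  g2 <- rlmFeatures(buildRLM(makeQ(c(2L, 2L, 1L))))
  expect_equal(g1[["LGRE"]], (25 + 13 / 4) / 38)
  expect_equal(g1[["HGRE"]], (25 + 13 * 4) / 38)
  expect_equal(g2[["LGRE"]], (13 + 25 / 4) / 38)
  expect_equal(g2[["HGRE"]], (13 + 25 * 4) / 38)
  expect_false(isTRUE(all.equal(g1[["LGRE"]], g2[["LGRE"]])))
})

test_that("extractFeatures returns 16 named finite values in order", {
  p <- generatePhantom(testSpec(seed = 6))
  q <- quantizeVolume(phantomImage(p), phantomMask(p), 16)
  fv <- extractFeatures(q)
  expect_identical(names(fv), textureFeatureNames())
  expect_true(all(is.finite(fv)))
  expect_gte(fv[["Entropy"]], 0)
  expect_true(fv[["Homogeneity"]] > 0 && fv[["Homogeneity"]] <= 1)
  expect_true(fv[["RPC"]] > 0 && fv[["RPC"]] <= 1)
})

test_that("entropy grows and uniformity shrinks with quantization depth", {
  for (seed in c(2, 7)) {
    p <- generatePhantom(testSpec(seed = seed))
    ent <- uni <- numeric(0)
    for (N in c(16L, 32L, 64L)) {
      fv <- cmFeatures(buildCM(
        quantizeVolume(phantomImage(p), phantomMask(p), N)))
      ent <- c(ent, fv[["Entropy"]])
      uni <- c(uni, fv[["Uniformity"]])
    }
    expect_true(all(diff(ent) >= 0))
    expect_true(all(diff(uni) <= 0))
  }
})
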