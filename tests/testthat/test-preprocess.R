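# In-plane resampling, slice merging, quantization and the grid.

test_that("in-plane resampling preserves extent and rescales spacing", {
  p <- generatePhantom(testSpec(seed = 1))
  out <- resampleInPlane(phantomImage(p), phantomMask(p), 19)
  expect_identical(dim(voxelData(out$image))[1:2], c(19L, 19L))
  expect_equal(spacing(out$image)[1:2], c(32 / 19, 32 / 19))
  # physical extent unchanged
  expect_equal(dim(voxelData(out$image))[1] * spacing(out$image)[1],
               32 * 1)
  expect_true(any(voxelData(out$mask)))
})

test_that("resampling a constant volume returns the same constant", {
  vol <- ImageVolume(array(7.5, c(16, 16, 4)), c(1, 1, 1))
  msk <- ROIMask(array(TRUE, c(16, 16, 4)))
  out <- resampleInPlane(vol, msk, 9)
  expect_true(all(voxelData(out$image) == 7.5))
  expect_true(all(voxelData(out$mask)))
})

test_that("4x4 ramp downsampled to 2x2 matches the hand-evaluated bilinear", {
  # values = x index (0-based ramp along x), single slice
  ramp <- array(rep(0:3, times = 4), c(4, 4, 1))
  vol <- ImageVolume(ramp, c(1, 1, 1))
  msk <- ROIMask(array(TRUE, c(4, 4, 1)))
  out <- resampleInPlane(vol, msk, 2)
  # new centres sit at old fractional indices 1.5 and 3.5 (1-based), i.e.
  # halfway between samples 1,2 and 3,4: ramp values 0.5 and 2.5.
  expect_equal(voxelData(out$image)[, 1, 1], c(0.5, 2.5))
  expect_equal(voxelData(out$image)[, 2, 1], c(0.5, 2.5))
})

test_that("upsampling and identity targets behave as specified", {
  p <- generatePhantom(testSpec(seed = 1))
  expect_error(resampleInPlane(phantomImage(p), phantomMask(p), 64),
               "upsampling")
  same <- resampleInPlane(phantomImage(p), phantomMask(p), 32)
  expect_identical(voxelData(same$image), voxelData(phantomImage(p)))
})

test_that("slice merging halves slices, doubles thickness, averages pairs", {
  v <- array(0, c(2, 2, 4))
  v[, , 2] <- 2            # pair (1,2): constants 0 and 2 -> 1
  v[, , 3] <- 5
  v[, , 4] <- 5            # pair (3,4): identical slices -> unchanged
  vol <- ImageVolume(v, c(1, 1, 1))
  msk <- ROIMask(array(TRUE, c(2, 2, 4)))
  out <- mergeSlices(vol, msk)
  expect_identical(dim(voxelData(out$image)), c(2L, 2L, 2L))
  expect_equal(spacing(out$image)[3], 2)
  expect_true(all(voxelData(out$image)[, , 1] == 1))
  expect_true(all(voxelData(out$image)[, , 2] == 5))
})

test_that("an odd trailing slice is dropped with a warning", {
  vol <- ImageVolume(array(1, c(2, 2, 5)), c(1, 1, 1))
  msk <- ROIMask(array(TRUE, c(2, 2, 5)))
  expect_warning(out <- mergeSlices(vol, msk), "dropping")
  expect_identical(dim(voxelData(out$image))[3], 2L)
  vol1 <- ImageVolume(array(1, c(2, 2, 1)), c(1, 1, 1))
  msk1 <- ROIMask(array(TRUE, c(2, 2, 1)))
  expect_error(mergeSlices(vol1, msk1), "at least 2")
})

test_that("quantization maps the ROI range onto levels 1..N", {
  # masked intensities exactly 0..15 with N = 16: value v -> level v + 1
  v <- array(0, c(16, 1, 2))
  v[, 1, 1] <- 0:15
  v[, 1, 2] <- 0:15
  vol <- ImageVolume(v, c(1, 1, 1))
  msk <- ROIMask(array(TRUE, c(16, 1, 2)))
  q <- quantizeVolume(vol, msk, 16)
  expect_identical(voxelData(q)[, 1, 1], 0:15 + 1L)
  # extremes of a [0, 100] range
  v2 <- array(runif(64, 1, 99), c(4, 4, 4))
  v2[1] <- 0
  v2[64] <- 100
  q2 <- quantizeVolume(ImageVolume(v2, c(1, 1, 1)),
                       ROIMask(array(TRUE, c(4, 4, 4))), 16)
  expect_identical(voxelData(q2)[1], 1L)
  expect_identical(voxelData(q2)[64], 16L)
})

test_that("a constant ROI quantizes to level 1 everywhere", {
  vol <- ImageVolume(array(3, c(4, 4, 2)), c(1, 1, 1))
  msk <- ROIMask(array(TRUE, c(4, 4, 2)))
  q <- quantizeVolume(vol, msk, 16)
  expect_true(all(voxelData(q) == 1L))
})

test_that("quantization rejects degenerate inputs", {
  vol <- ImageVolume(array(1:32, c(4, 4, 2)), c(1, 1, 1))
  msk <- ROIMask(array(FALSE, c(4, 4, 2)))
  expect_error(quantizeVolume(vol, msk, 16), "at least 2")
  mskOK <- ROIMask(array(TRUE, c(4, 4, 2)))
  expect_error(quantizeVolume(vol, mskOK, 1), ">= 2")
})

test_that("levels 1 and N are always attained on a non-degenerate ROI", {
  p <- generatePhantom(testSpec(seed = 4))
  for (N in c(16L, 32L, 64L)) {
    q <- quantizeVolume(phantomImage(p), phantomMask(p), N)
    lv <- voxelData(q)[!is.na(voxelData(q))]
    expect_identical(range(lv), c(1L, N))
  }
})

test_that("bins are nested: collapsing 2N-level pairs reproduces N levels", {
  p <- generatePhantom(testSpec(seed = 8))
  for (N in c(16L, 32L)) {
    qN <- quantizeVolume(phantomImage(p), phantomMask(p), N)
    q2N <- quantizeVolume(phantomImage(p), phantomMask(p), 2L * N)
    collapsed <- (voxelData(q2N) + 1L) %/% 2L
    expect_identical(collapsed, voxelData(qN))
  }
})

test_that("the default configuration grid yields 12 labelled datasets", {
  p <- generatePhantom(testSpec(seed = 1))
  grid <- buildConfigurationGrid(p)
  expect_length(grid, 12L)
  expect_match(names(grid), "^m\\d+_st\\d+mm_dr\\d+$", all = TRUE)
  # 2 matrix sizes x 2 thicknesses x 3 dynamic ranges, each once
  meta <- do.call(rbind, lapply(grid, function(g)
    data.frame(g$matrixSize, g$sliceThickness, g$nLevels)))
  expect_identical(nrow(unique(meta)), 12L)
  # quantization range is recomputed per configuration
  for (g in grid) {
    lv <- voxelData(g$q)[!is.na(voxelData(g$q))]
    expect_identical(range(lv), c(1L, g$nLevels))
  }
})

test_that("a single spatial x grey configuration yields one dataset", {
  p <- generatePhantom(testSpec(seed = 1))
  grid <- buildConfigurationGrid(
    p, spatialConfigs = list(SpatialConfig(32, 1)), greyLevels = 16L)
  expect_length(grid, 1L)
  expect_identical(names(grid), "m32_st1mm_dr16")
})

test_that("an unsupported slice thickness is rejected naming the config", {
  p <- generatePhantom(testSpec(seed = 1))
  expect_error(
    buildConfigurationGrid(
      p, spatialConfigs = list(SpatialConfig(32, 3)), greyLevels = 16L),
    "neither 1x nor 2x")
})
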