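# Coefficient of variation and the two robustness experiments.

test_that("the coefficient of variation matches hand computation", {
  expect_equal(coefficientOfVariation(c(2, 2, 2)), 0)
  expect_equal(coefficientOfVariation(c(1, 2, 3)), 50)   # sd 1, mean 2
  # population flavour rescales by sqrt((n-1)/n)
  expect_equal(coefficientOfVariation(c(1, 2, 3), sdType = "population"),
               100 * sqrt(2 / 3) / 2)
})

test_that("degenerate CV inputs raise distinct errors", {
  expect_error(coefficientOfVariation(c(0, 0, 0)), "mean")
  expect_error(coefficientOfVariation(5), "at least 2")
  expect_error(coefficientOfVariation(c(1, NA)), "finite")
})

test_that("the CV is invariant under positive rescaling", {
  v <- c(3, 5, 9, 4)
  base <- coefficientOfVariation(v)
  for (k in c(0.01, 1, 250)) {
    expect_equal(coefficientOfVariation(k * v), base)
  }
})

# Minimal synthetic feature tables built directly, bypassing imaging.
fakeTable <- function(subjects, spatial, levels, value) {
  g <- expand.grid(subject = subjects, s = seq_along(spatial),
                   nLevels = levels, stringsAsFactors = FALSE)
  df <- data.frame(subject = g$subject,
                   matrixSize = spatial[g$s],
                   sliceThickness = 1,
                   nLevels = g$nLevels,
                   label = sprintf("m%d_st1mm_dr%d", spatial[g$s],
                                   g$nLevels),
                   stringsAsFactors = FALSE)
  for (f in textureFeatureNames()) df[[f]] <- value(df)
  df
}

test_that("dynamic-range CVs reproduce the single-subject worked cell", {
  # one subject, one spatial config, feature values 1/2/3 across N
  tab <- fakeTable("s1", 64L, c(16L, 32L, 64L),
                   function(df) match(df$nLevels, c(16, 32, 64)))
  rt <- cvAcrossDynamicRange(tab)
  expect_identical(dim(meanCV(rt)), c(16L, 1L))
  expect_true(all(abs(meanCV(rt) - 50) < 1e-12))
  expect_true(all(sdCV(rt) == 0))     # single subject: SD across is 0
})

test_that("resolution CVs reproduce the (1,1,1,3) worked cell", {
  tab <- fakeTable("s1", c(32L, 48L, 56L, 64L), 16L,
                   function(df) ifelse(df$matrixSize == 64L, 3, 1))
  rt <- cvAcrossResolution(tab)
  expect_identical(dim(meanCV(rt)), c(16L, 1L))
  expect_true(all(abs(meanCV(rt) - 100 * 1 / 1.5) < 1e-12))
})

test_that("a feature constant across the varied axis is robust with 0 CV", {
  tab <- fakeTable(c("s1", "s2"), c(32L, 64L), c(16L, 32L, 64L),
                   function(df) 7 + (df$subject == "s2"))
  rt <- classifyRobust(cvAcrossDynamicRange(tab))
  expect_true(all(meanCV(rt) == 0))
  expect_true(all(robustFlags(rt)))
  expect_true(all(overallRobust(rt)))
})

test_that("missing cells fail loudly, listing the gap", {
  tab <- fakeTable(c("s1", "s2"), 64L, c(16L, 32L, 64L), function(df) 1)
  expect_error(cvAcrossDynamicRange(tab[-2, ]), "missing")
})

test_that("the 10% threshold is strict", {
  tab <- fakeTable("s1", 64L, c(16L, 32L, 64L), function(df) 1)
  rt <- cvAcrossDynamicRange(tab)
  rt@meanCV[] <- 10
  rt@meanCV[1, 1] <- 9.99
  rt <- classifyRobust(rt, 10)
  fl <- robustFlags(rt)
  expect_true(fl[1, 1])               # 9.99 < 10: robust
  expect_false(any(fl[-1, ]))         # exactly 10: not robust
  ov <- overallRobust(rt)
  expect_false(any(ov[-1]))
})

test_that("normalized profiles peak at exactly one per feature", {
  tab <- fakeTable("s1", c(32L, 64L), c(16L, 32L, 64L),
                   function(df) runif(nrow(df), 1, 9))
  norm <- normalizeProfiles(tab)
  for (f in textureFeatureNames()) {
    expect_equal(max(norm[[f]]), 1)
  }
  # worked example (2, 4, 8) -> (0.25, 0.5, 1)
  tab2 <- fakeTable("s1", 64L, c(16L, 32L, 64L),
                    function(df) c(2, 4, 8)[match(df$nLevels,
                                                  c(16, 32, 64))])
  norm2 <- normalizeProfiles(tab2)
  expect_equal(sort(norm2$Entropy), c(0.25, 0.5, 1))
  # constant values normalize to all ones
  tab3 <- fakeTable("s1", 64L, c(16L, 32L, 64L), function(df) 4)
  expect_true(all(normalizeProfiles(tab3)$Contrast == 1))
})

test_that("aggregation over one subject equals that subject's CV", {
  tab <- fakeTable("only", c(32L, 64L), c(16L, 32L, 64L),
                   function(df) df$nLevels / 10 + df$matrixSize)
  rt <- cvAcrossDynamicRange(tab)
  for (g in seq_len(ncol(meanCV(rt)))) {
    ms <- unique(tab$matrixSize)[g]
    vals <- sort(tab$Entropy[tab$matrixSize ==
                               sort(unique(tab$matrixSize))[g]])
    expect_equal(meanCV(rt)["Entropy", g],
                 coefficientOfVariation(vals))
  }
  expect_true(all(sdCV(rt) == 0))
})
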