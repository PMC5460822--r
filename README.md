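# RadTex3D

Robustness analysis of 3D second-order texture features in tumor MRI.

## The problem

Texture features computed over a segmented tumor — statistics of the
grey-level co-occurrence matrix (GLCM) and grey-level run-length matrix
(GLRLM) — are widely used as imaging biomarkers of heterogeneity. But a
feature is only usable across scanners and sites if its value survives
the reconstruction choices that routinely differ between studies: the
in-plane matrix size, the slice thickness, and the number of grey
levels the tumor intensities are discretized into (the dynamic range).
RadTex3D is for imaging researchers who want to quantify that
sensitivity: it recomputes sixteen 3D texture features under a grid of
resolution and dynamic-range configurations and reports, per feature,
the coefficient of variation (CV) across configurations, aggregated
over a cohort.

## The method

For a volume quantized to levels 1..N over its region of interest
(ROI):

- **GLCM**: `CM(i,j)` counts ordered pairs of masked voxels at unit
  Chebyshev distance (all 26 neighbors in 3D) with levels *i* and *j*;
  both orders are counted, so the matrix is symmetric. Five features
  (Entropy, Homogeneity, Contrast, Dissimilarity, Uniformity) are
  computed on the counts normalized to unit sum, e.g.
  `Entropy = -Σᵢⱼ p(i,j) ln p(i,j)`.
- **GLRLM**: `RLM(i,j)` counts maximal collinear runs of *j* masked
  voxels at level *i*, summed over the 13 antipodal direction pairs of
  the 26-neighbourhood. Eleven features (LRE, SRE, LGRE, HGRE, SRLGE,
  SRHGE, LRLGE, LRHGE, GLNU, RLNU, RPC) use the `1/nr` prefactor with
  `nr` the number of runs; `RPC = nr / Σᵢⱼ RLM(i,j)·j ∈ (0,1]`. Every
  masked voxel joins exactly one run per direction, so
  `Σᵢⱼ RLM(i,j)·j = 13·|ROI|` — an invariant the tests assert on every
  input.
- **Robustness**: for each feature and subject, `CV = 100·s/|mean|`
  across the varied factor (dynamic ranges 16/32/64 at fixed
  resolution, or the 4 matrix-size × slice-thickness combinations at
  fixed dynamic range), then mean ± SD over subjects. A feature with
  mean CV strictly below 10% in a cell is robust there.

Because no patient data ship with the package, a seeded phantom
generator emulates contrast-enhanced T1-weighted tumor volumes
(ellipsoid with bright enhancing rim, darker core, spatially correlated
intra-tumor texture, additive noise), so the whole pipeline is
reproducible from a single seed. See the methods vignette
(`vignettes/texture-robustness.Rmd`) for conventions and limitations.

## Worked example

```r
library(RadTex3D)
cohort   <- generateCohort(4, phantomSpec(), seed = 1)
features <- cohortFeatureTable(cohort)      # 48 rows x (5 id + 16 feature) cols
exp2 <- classifyRobust(cvAcrossResolution(features))
exp2
```

```
RobustnessTable (spatial-resolution varied): 16 features x 3 groupings, 4 subjects
              16            32            64
Entropy       6.34 (1.66) * 5.13 (1.35) * 3.94 (1.03) *
Homogeneity   21.82 (2.96)  24.76 (4.47)  26.18 (5.45)
Contrast      36.23 (6.22)  36.56 (6.27)  36.65 (6.31)
...
RPC           9.22 (1.87) * 4.43 (1.07) * 2.12 (0.50) *
* mean CV < 10% (robust)
```

Each cell is the mean (and SD) over subjects of the per-subject CV, in
percent, of that feature across the four spatial configurations at the
given dynamic range. Here CM Entropy stays robust (mean CV 3.9–6.3%,
well under 10%) at every dynamic range, while e.g. Contrast varies by
more than a third of its mean. `cvAcrossDynamicRange(features)` runs
the complementary experiment; on heterogeneous phantoms no feature is
robust there — Entropy alone has a mean CV above 20%, since entropy
grows roughly like ln N.

The one-call version writes the feature table, both robustness tables
and a checksummed manifest:

```r
man <- runPipeline(pipelineConfig(nSubjects = 20, seed = 1,
                                  outputDir = "run1"))
```

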