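---
title: "Measuring the robustness of 3D texture features with RadTex3D"
author: "RadTex3D authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the robustness of 3D texture features with RadTex3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RadTex3D)
```

## The question the package answers

Second-order texture features — statistics of grey-level co-occurrence
and run-length matrices — are popular imaging biomarkers of tumor
heterogeneity. Their values, however, depend on choices that differ
between scanners and sites: the in-plane matrix size, the slice
thickness, and the number of grey levels the tumor intensities are
discretized into (the *dynamic range*). RadTex3D quantifies that
dependence. For each subject it computes all sixteen features under a
grid of spatial-resolution and dynamic-range configurations and
summarizes, across a cohort, the per-subject coefficient of variation
(CV) of each feature when one factor is varied and the other held
fixed. A feature whose mean CV stays strictly below 10% is called
*robust* to that factor.

Two complementary experiments are run on the same feature table:

* **CV across the dynamic range** — for each feature, subject and
  spatial configuration, the CV over the grey-level counts
  (16, 32, 64). Output: features x spatial configurations (16 x 4).
* **CV across the spatial resolution** — for each feature, subject and
  dynamic range, the CV over the four matrix-size x slice-thickness
  combinations. Output: features x dynamic ranges (16 x 3).

## The texture model

All statistics are computed over a segmented region of interest (ROI)
of a 3D volume whose masked intensities have been quantized to integer
levels $1..N$.

**Co-occurrence matrix (CM).** Because tumors are 3D objects and
patients are not positioned identically, no single direction is
privileged: the CM aggregates *all* 26 neighbors of each voxel at unit
Chebyshev distance. Cell $CM(i,j)$ counts the ordered pairs of adjacent
masked voxels with levels $i$ and $j$; both orders are counted, so the
matrix is symmetric. The five CM features (Entropy, Homogeneity,
Contrast, Dissimilarity, Uniformity) are computed on the count matrix
normalized to unit sum — the entropy formula is only a conventional
non-negative entropy on probabilities — with natural logarithms and
$0 \ln 0 = 0$.

**Run-length matrix (RLM).** Cell $RLM(i,j)$ counts the maximal
collinear runs of $j$ consecutive masked voxels at level $i$,
accumulated over the 13 antipodal direction pairs of the
26-neighbourhood. Runs break at level changes and at unmasked voxels.
The 13 directional matrices are *summed* into one matrix rather than
averaged: for the ten $1/n_r$-normalized features the two conventions
coincide, but GLNU, RLNU and RPC would differ, and summation keeps the
exact conservation law
$\sum_{i,j} RLM(i,j)\, j = 13\,|\mathrm{ROI}|$
(every masked voxel belongs to exactly one run per direction), which
the test suite asserts on every input. RPC is defined as
$n_r / \sum_{i,j} RLM(i,j)\, j$, the classical run percentage, so it
lies in $(0, 1]$.

Degenerate masks with no adjacent voxel pair raise an error rather than
returning silent zeros: texture is undefined for scattered masks.

## Preprocessing conventions

The preprocessing stage reproduces the analysed acquisition grid: two
in-plane matrix sizes (the native one and a standard-matrix
downsampling in the proportion 256/432), each at the native and at
twice the native slice thickness, crossed with $N \in \{16, 32, 64\}$ —
12 configurations per subject.

* **In-plane resampling** is separable bilinear interpolation at the
  new voxel centres (voxel-centre convention, 0.5-voxel offset), the
  simplest kernel consistent with plain interpolation of the raw
  images. Physical extent is preserved; spacing rescales by
  $n_{old}/n_{new}$. Upsampling is refused.
* **Slice merging** averages disjoint consecutive slice pairs —
  interpolation on each pair of initial slices — halving the slice
  count and doubling the thickness; a trailing odd slice is dropped
  with a warning.
* **Mask resampling** interpolates the 0/1 mask linearly and
  re-binarizes at 0.5, a majority-like rule.
* **Quantization** is min–max uniform binning of the masked
  intensities into $N$ equal-width bins (half-open, top bin closed):
  the ROI minimum maps to level 1 and the maximum to level $N$. This is
  the most common radiomics convention; note that fixed-bin-width
  alternatives exist and give different absolute feature values. A
  constant ROI maps to level 1 everywhere. Bins for $N$ and $2N$ are
  nested, which yields a clean monotonicity property: CM Entropy is
  non-decreasing and Uniformity non-increasing in $N$ on a fixed
  volume — asserted in the tests.
* **Bounds per configuration.** Quantization bounds are recomputed
  after each resampling rather than inherited from the raw image; the
  alternative convention is defensible, but recomputation keeps every
  configuration self-contained and is applied uniformly.

## The coefficient of variation

$CV = 100 \cdot s / |\bar x|$ with the sample ($n-1$) standard
deviation by default. The series here have only 3 or 4 values, so the
sample/population choice visibly rescales the result; it is therefore
an explicit argument (`sdType`) rather than a constant. The absolute
mean keeps CVs non-negative regardless of sign conventions (all sixteen
features are positive in practice). The 10% robustness threshold is a
strict inequality: a mean CV of exactly 10.0% is not robust. Series
with near-zero mean or fewer than two values are rejected with distinct
errors; missing table cells fail loudly with the offending
subject/configuration listed — no imputation.

## What the phantom generator emulates

No patient images ship with the package, so the cohort is synthetic: a
seeded generator emulates contrast-enhanced T1-weighted brain tumor
volumes. Each phantom is an ellipsoidal tumor (semi-axes in mm, voxel
spacing respected) with:

* a **bright enhancing rim** occupying the outer `rimFraction` of each
  radius, a **darker core**, and a darker **background**
  (`rimLevel > coreLevel > backgroundLevel`);
* a **spatially correlated intra-tumor field**: seeded white noise
  smoothed by an isotropic Gaussian kernel whose width is the
  correlation length (3 mm by default, a plausible scale for
  enhancement heterogeneity), rescaled to a chosen ROI standard
  deviation — the simplest controllable spatial texture;
* **additive Gaussian noise**, clipped at zero to mimic magnitude MRI.
  A Rician noise model would be more faithful at low SNR but the
  analysis is noise-model-agnostic, so the simpler model is the
  default.

The mask is the ellipsoid inequality evaluated at voxel centres
(centre-in convention), which makes the brute-force oracle test
unambiguous. Cohorts jitter geometry, tissue levels, texture amplitude
and noise per subject from a seeded stream; identical spec + seed is
bit-reproducible.

The emulated acquisition is a 432 x 432 matrix at 0.5 x 0.5 x 1 mm
(`phantomSpec(fullScale = TRUE)`). The package's default geometry —
and the scale used throughout the tests and the acceptance script — is
64 x 64 x 16 voxels at 1 mm, which keeps a 20-subject, 12-configuration
run around half a minute while preserving every structural property of
the analysis. No published intra-tumor intensity statistics constrain
the phantom, so its realism is a free design choice, documented as
such.

**What passing tests do and do not show.** The structural results —
counts, conservation laws, oracle agreement, exact worked examples, CV
arithmetic — hold for any input. The *qualitative* robustness pattern
on phantoms (CM Entropy far from robust when the dynamic range varies,
because entropy grows roughly logarithmically with $N$; Entropy
comfortably robust when only the spatial resolution varies)
reproduces the direction of the published patient-data findings, but
synthetic tumors cannot certify patient-data CV magnitudes: phantoms
lack vasculature, necrosis geometry, bias fields and scanner effects.
On phantoms a few additional features (e.g. SRE, RPC) can also fall
under the resolution threshold; that is a property of the phantom's
homogeneity, not a contradiction.

## Numerical and interface choices

* All randomness flows from explicit integer seeds; the generator
  restores the caller's RNG state.
* Grey levels, run lengths and counts are exact integers; features are
  double-precision sums over at most $64 \times M$ cells, so no special
  summation is needed.
* The pipeline entry point is `runPipeline()` on a `pipelineConfig()`;
  as an analysis library the exported functions are the interface (no
  shell executable). Outputs are plain CSV/YAML/JSON with a manifest of
  MD5 checksums; a run with a fixed config and seed is byte-identical.
* NIfTI-1 is the supported on-disk format (via RNifti), image as float,
  mask as uint8. DICOM series input is not implemented.

## Worked example

```{r example}
cohort <- generateCohort(4, phantomSpec(), seed = 1)
features <- cohortFeatureTable(cohort)
dim(features)
exp2 <- classifyRobust(cvAcrossResolution(features))
exp2
overallRobust(exp2)
```

## Known limitations

* Single-sequence emulation only; no multi-sequence, bias-field or
  scanner-vendor effects.
* Min–max quantization makes features sensitive to single extreme
  voxels; that sensitivity is part of what the CV measures.
* The interpolation kernel is fixed to bilinear + pair-averaging;
  other kernels (cubic, anti-aliased) would perturb feature values in
  detail.
* Robustness here means insensitivity to reconstruction parameters; it
  says nothing about biological or prognostic validity.
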