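---
title: "Grey-level discretization and 3D texture features for brain MRI lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey-level discretization and 3D texture features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mritexture)
```

## The problem

Radiomic texture indices (TIs) computed from MRI lesions depend not only on
the underlying tissue heterogeneity but on every pre-processing choice made
before the grey-level matrices are built. The most influential of these is
discretization: continuous voxel intensities must be mapped to a small set
of integer grey levels before a co-occurrence, run-length or size-zone
matrix can be assembled. Different discretization conventions produce TI
values that differ by orders of magnitude on the same voxels, which makes
cross-study comparisons meaningless unless the convention and its parameter
are reported and matched. This package implements the three conventions in
common use, the 40-feature TI set computed from them, the two
volume-of-interest (VOI) segmentation styles they are typically combined
with, and the statistical stages used to compare them: rank-sum screening
of pathological versus mirrored control VOIs and Spearman correlation of
each TI with lesion volume.

Because patient MRI cannot be redistributed, the package ships a synthetic
brain-lesion phantom generator that reproduces the *structure* of such a
cohort — textured lesions on a textured background, two co-registered
contrasts per subject, three disease groups, paired co-lateral control VOIs
— so that every stage of the analysis is exercised end to end on data
generated in code.

## Discretization schemes

Let $I(i)$ be the intensity of voxel $i$ inside the VOI, $I_{min}$,
$I_{max}$ the VOI extremes, $B$ a bin width in intensity units, and $D$ a
bin count.

* **LAR** (lesion absolute resampling, fixed bin size anchored at the VOI
  minimum):
  $I_{LAR}(i) = \lfloor I(i)/B \rfloor - \lfloor I_{min}/B \rfloor + 1$.
  The minimum level is exactly 1.
* **AR** (absolute resampling, fixed bin size anchored at absolute zero):
  $I_{AR}(i) = \lceil I(i)/B \rceil - 1$. Levels are independent of where
  the VOI's intensity range sits, which is the property that makes AR
  robust against lesion-to-lesion range variation. Levels can be 0; they
  are shifted by +1 when a matrix is built so grey values start at 1 —
  the shift preserves all level differences and keeps the
  low-grey-level-weighted features ($1/g^2$ terms) finite.
* **LRR** (lesion relative resampling, fixed bin number): the VOI range is
  split into $D$ equal bins, $I_{LRR}(i) = 1$ if $I(i) = I_{min}$, else
  $\lceil D\,(I(i)-I_{min})/(I_{max}-I_{min}) \rceil$. Levels lie in
  $\{1..D\}$ with the extremes pinned to 1 and $D$; LRR is invariant under
  any positive affine intensity map, and consequently blind to absolute
  intensity scale.

For the fixed-bin-size schemes the VOI intensities are first winsorized at
their 10th and 90th percentiles (`percentileClip()`): voxels are retained
at the bounds rather than excluded, so the voxel lattice — which the
texture matrices need — stays intact. LRR uses the unclipped VOI extremes
by default. Whether clipping should also precede LRR is genuinely
ambiguous in the conventions this package follows; both behaviors are
supported (`clipLRR`), with the unclipped default. Percentiles use the
linear-interpolation (type 7) definition, pinned for reproducibility.

The parameter sweeps are `defaultGrids()`:
$B \in \{1, 5, 10, \ldots, 100\}$ (21 values) and
$D \in \{8, 16, 32, 64, 128, 256, 512, 1024\}$ (8 values), with
$B = 50$, $D = 64$ as the headline settings used in the worked examples.

## Texture matrices and the 40 indices

All three matrices are built in 3D on the masked voxel lattice:

* **GLCM** — ordered neighbor pairs at Chebyshev distance 1 along the 13
  unique 3D directions, both orderings counted (symmetric), all directions
  merged into one matrix and normalized. Merging (rather than averaging
  per-direction features) is pinned as the default; per-direction analysis
  can be done by passing explicit `directions`.
* **GLRLM** — maximal runs of equal level along the same 13 directions,
  truncated at the mask boundary, counts summed over directions. The
  partition identity $\sum_{g,r} r \cdot c(g,r) = 13\,N_{vox}$ holds by
  construction and is asserted in the tests.
* **GLSZM** — connected components of equal level under 26-connectivity;
  $\sum_{g,s} s \cdot c(g,s) = N_{vox}$.

Grey levels are indexed $1..N_g$ with $N_g$ the maximum observed level;
unobserved intermediate levels are kept as empty rows because the
intensity-weighted features use the level *value*, which is what
distinguishes absolute binning (AR) from relative binning (LRR).

`extractAll()` evaluates 18 GLCM, 11 GLRLM and 11 GLSZM indices with
IBSI-style formulas (joint/difference/sum statistics, cluster moments,
run/zone emphases, non-uniformities, run and zone percentages). Degenerate
single-level VOIs get defined fallbacks instead of NaN — entropies 0,
`Correlation` 0, `NormInvDiff` 1 — because parameter sweeps on small or
clipped VOIs do hit them and silent NaNs would poison the downstream
statistics. Every matrix builder and every formula is verified against an
independent brute-force implementation (plain loops and flood fill) to
1e-12 relative on random grids.

## VOI construction

Two segmentation styles are modelled:

* `ellipsoidVOI()` rasterizes a 3D ellipsoid by voxel-center membership;
  in the pipeline its semi-axes are the true lesion radii shrunk by the
  boundary-blur width, emulating placement on the inner lesion area away
  from partial-volume voxels.
* `manualLikeVOI()` dilates the true lesion mask by a physical margin
  (default 2 mm, ball structuring element in mm), emulating hand-drawn
  contours that include mixed boundary tissue. The margin is a free
  parameter: published manual delineations do not quantify how far beyond
  the lesion they extend, so 2 mm (one to two voxels at typical spacing)
  was fixed once as a plausible halo.

`mirrorVOI()` reflects a VOI across the midsagittal plane to produce the
co-lateral control; reflection preserves voxel count, volume and pairwise
distances. `filterMinVolume()` enforces the 1 cm³ minimum VOI volume used
by the screening design. Coordinates are 0-based voxel indices with world
position = index × spacing; NIfTI files are read and written with
**RNifti**, and a plain-text per-voxel dialect (`x y z intensity`, `#`
comments, LF endings) is supported for interoperability with VOI exports
from clinical tools.

## The synthetic cohort generator

Each tissue compartment is a stationary correlated Gaussian random field:
white noise smoothed by an isotropic Gaussian kernel of width equal to the
correlation length (in mm, converted to voxels via the spacing), then
rescaled to the target mean and standard deviation. This is the simplest
field with a controllable correlation length; `textureParams()` holds its
four parameters. Lesions are ellipsoids whose interiors are overwritten by
a second field; partial-volume mixing at the lesion boundary is emulated by
blending the volume with a Gaussian-smoothed copy in a shell around the
boundary (weight $4\tilde m(1-\tilde m)$ where $\tilde m$ is the smoothed
mask, so the blend peaks at the boundary and vanishes away from it).
Intensities are clamped to a floor of 1 unit so AR levels stay
non-negative.

The default cohort design is 22 + 22 + 27 subjects (ischemic stroke,
multiple sclerosis, tumor) at two contrasts on a 64³ grid at 1 mm spacing.
Groups differ only in lesion-count range, size range and lesion texture
presets; no clinical realism is claimed — the statistical stages only need
group structure. Because no quantitative texture description of real
lesions is available to calibrate against, all cohort-level findings on
synthetic data are illustrative of the *mechanisms* (binning response,
volume-correlation inflation, boundary-mixing dilution), not reproductions
of patient numbers.

Determinism is strict: per-subject seeds are derived from the master seed
by a stable 32-bit integer mix keyed on (group, within-group index), so a
cohort is a pure function of its design and shrinking one group never
perturbs another group's subjects. Both contrasts of a subject share
identical lesion geometry, as for co-registered acquisitions.

What the generator does **not** emulate: MR physics (TR/TE, coil
sensitivity, bias fields), scanner protocol differences, registration
error, intensity normalization, non-ellipsoidal lesion shapes. Passing
tests on synthetic cohorts therefore demonstrate correctness of the
pipeline and the direction of the studied effects, not performance on real
MRI.

## Statistical stages

The observation unit is the lesion, not the patient. For every
(method, parameter, segmentation) cell:

* `ranksumDiseaseVsControl()` — two-sided Wilcoxon rank-sum comparing
  pathological vs control values of each TI within each disease group and
  contrast: 40 × 3 × 2 = 240 tests per cell. Exact enumeration is used
  when $n_1+n_2 \le 10$ with no ties (verified against full permutation
  enumeration), otherwise the normal approximation with tie and continuity
  corrections. Significance is counted at strict $p < 0.05$ with no
  multiple-testing correction, matching the screening convention this
  reproduces; that convention is statistically liberal, and the counts
  should be read as descriptive.
* `spearmanFeatureVolume()` — Spearman correlation of each TI with lesion
  volume for all six lesion groups (3 disease × pathological/control) and
  both contrasts: 480 analyses per cell, reported as $R^2$ maps with cells
  flagged highly volume-correlated when $R^2 > 0.5$
  ($|R| > \sqrt{0.5} \approx 0.71$). Constant inputs are flagged
  degenerate and excluded from maps rather than coerced to 0.

## Numerical and design notes

* **Null calibration.** The type-I property test draws pathological and
  control VOIs from identical texture parameters *with the boundary blur
  disabled*: the partial-volume blur acts only around lesions, so with
  blur enabled the pathological VOI is smoothed while its mirrored control
  is not and the two are not exchangeable — that asymmetry is precisely
  the boundary-mixing mechanism, and it is exercised by the directional
  cohort checks instead. For the same reason the random field is rescaled
  by the theoretical variance of kernel-smoothed noise rather than by
  empirical standardization, which would tie local field statistics to the
  size of the generation domain. The rejection fraction is computed over
  tests that are mutually independent by construction — one rotating
  feature per (cohort, group, contrast, subject-half) block of disjoint
  voxel data — because all 40 features of one VOI set are strongly
  dependent and a binomial band is meaningless over their pooled
  rejections.
* **Entropy vs binning.** Joint entropy is non-decreasing in $D$ under LRR
  without exception: the doubling grid is nested, and refining a partition
  cannot decrease entropy. The $B$ grid is not nested; once the bin width
  reaches the VOI's (clipped) intensity spread only one or two levels
  survive and the position of the bin boundary, not the resolution, drives
  the entropy, producing a shallow non-monotone tail at the coarsest bin
  widths. The tests therefore require strict monotone decrease while bins
  are finer than the intensity spread and a strong decreasing trend across
  the whole grid.
* **Problem sizes.** The routine test suite and the acceptance script run
  reduced designs — 6 subjects per group, 64³ grids, the headline
  settings $B=50$/$D=64$, and 40³ null cohorts — chosen to keep a desk run
  in minutes while leaving every code path identical to the full sweep;
  `defaultGrids()` with the full 22/22/27 design is a configuration
  change, not a code change.
* **What synthetic cohorts can and cannot show.** The directional
  expectations — absolute resampling finds more discriminating TIs than
  relative resampling, relative resampling inflates TI–volume correlation
  — reproduce robustly on synthetic cohorts and are reported by the tests.
  The segmentation contrast does not transfer: on phantoms the manual-like
  VOI's boundary shell *adds* pathological-vs-control signal (the blurred
  mix differs sharply from the mirrored control region), whereas in real
  brain images boundary voxels mix in surrounding healthy tissue drawn
  from the same anatomy as the control and dilute the signal. The
  segmentation comparison on synthetic data is therefore logged as a soft
  observation, not asserted.
* **Degenerate inputs.** Constant VOIs propagate a degeneracy flag through
  discretization, features and statistics; degenerate rank-sum records
  count as non-significant and degenerate correlations are excluded from
  maps.

## A worked example

```{r example, eval = FALSE}
library(mritexture)
cfg <- studyConfig(design = cohortDesign(6, 6, 6, masterSeed = 1),
                   grids = list(B = 50, D = 64))
res <- runStudy(cfg, verbose = TRUE)
res$significance
```

The significance table counts, for each discretization method and
segmentation style, how many of the 240 pathological-vs-control tests come
out below 0.05; on default synthetic cohorts AR yields at least as many
significant TIs as LRR, reflecting that absolute binning preserves
between-VOI intensity differences that relative binning normalizes away.
`res$r2maps` holds the 480-cell $R^2$ maps, in which LRR typically flags
more TIs as volume-correlated than AR does at matched settings.
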