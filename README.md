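# mritexture

Grey-level discretization and 3D texture features for brain MRI lesions.

Radiomic texture indices (TIs) computed from MRI depend strongly on how
continuous voxel intensities are discretized into grey levels before the
texture matrices are built — often more strongly than on the tissue being
imaged. **mritexture** is an R package for studying exactly that effect. It
implements, end to end:

* the three discretization conventions in common use —
  **LAR** (lesion absolute resampling, fixed bin size anchored at the VOI
  minimum): `I_LAR = floor(I/B) − floor(Imin/B) + 1`;
  **AR** (absolute resampling, fixed bin size anchored at zero):
  `I_AR = ceil(I/B) − 1`;
  **LRR** (lesion relative resampling, fixed bin number):
  `I_LRR = 1` at `Imin`, else `ceil(D·(I − Imin)/(Imax − Imin))` —
  with 10th–90th percentile winsorization for the fixed-bin-size methods
  and the standard parameter sweeps `B ∈ {1, 5, 10, …, 100}`,
  `D ∈ {8, 16, …, 1024}`;
* 3D **GLCM** (13 merged symmetric directions, distance 1), **GLRLM**
  (merged runs) and **GLSZM** (26-connected zones) matrices and the
  40-feature IBSI-style index set (18 + 11 + 11), all verified against
  brute-force oracle implementations to 1e-12;
* VOI tools: elliptical VOIs, manual-like VOIs (lesion mask dilated by a
  physical margin), mirrored co-lateral control VOIs, the ≥ 1 cm³ volume
  rule, NIfTI I/O and a plain-text per-voxel dialect;
* a deterministic synthetic brain-lesion phantom generator (correlated
  Gaussian random fields, three disease groups, two contrasts,
  partial-volume boundary blur) standing in for patient MRI;
* the statistical comparison stages: Wilcoxon rank-sum screening of
  pathological vs control VOIs (240 tests per discretization setting and
  segmentation), Spearman TI–volume correlation (480 analyses per
  setting), significance counting at strict p < 0.05 and R² map tables
  with the high-correlation flag at R² > 0.5 (|R| ≈ 0.71).

## A worked example

```r
library(mritexture)
cfg <- studyConfig(design = cohortDesign(6, 6, 6, masterSeed = 1),
                   grids = list(B = 50, D = 64))
res <- runStudy(cfg)
res$significance
```

On this reduced synthetic cohort (6 subjects per disease group, headline
settings B = 50, D = 64) the run prints:

```
 method param segmentation n_tests n_significant alpha
     AR    50   elliptical     240           144  0.05
     AR    50       manual     240           190  0.05
    LAR    50   elliptical     240           137  0.05
    LAR    50       manual     240           180  0.05
    LRR    64   elliptical     240           116  0.05
    LRR    64       manual     240           120  0.05
```

Each row counts, out of 240 pathological-vs-control rank-sum tests
(40 features × 3 groups × 2 contrasts), how many came out significant at
p < 0.05 for that discretization method and segmentation style. The
pattern the package is built to expose is visible already at this scale:
absolute resampling (AR/LAR, which preserves between-VOI intensity
differences) yields substantially more discriminating TIs than relative
resampling (LRR, which normalizes them away). `res$r2maps` holds the
corresponding 480-cell R² maps of TI–volume correlation; `res$features`
is the long per-VOI feature table and `res$spearman` / `res$ranksum` the
full statistical records.

A thin command-line wrapper over the same functions is in
`inst/scripts/mritexture-cli.R` (`simulate`, `extract`, `run-study`
subcommands).

## Documentation

The methods vignette (`vignettes/discretization-methods.Rmd`) describes
the discretization schemes, the matrix and feature definitions, the
synthetic cohort model and its limitations, and the numerical and design
choices (clipping scope, degenerate-input fallbacks, null-calibration
design, entropy-vs-binning monotonicity).
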