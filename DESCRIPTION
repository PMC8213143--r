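Package: mritexture
Title: Grey-Level Discretization and 3D Texture Features for Brain MRI Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how grey-level discretization affects
    radiomic texture analysis of brain MRI lesions. Implements three
    discretization schemes (lesion absolute resampling, absolute
    resampling, lesion relative resampling), 10th-90th percentile
    winsorization, 3D grey-level co-occurrence, run-length and size-zone
    matrices with 40 IBSI-style texture indices, elliptical and
    manual-like volume-of-interest construction with co-lateral mirrored
    controls, a synthetic brain-lesion phantom cohort generator, and the
    statistical comparison stages (Spearman feature-volume correlation,
    Wilcoxon rank-sum screening of pathological versus control areas,
    significance counting and R-squared map tables).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
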