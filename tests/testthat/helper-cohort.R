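# Compact synthetic cohorts for the statistical property tests: subjects on
# a 40^3 grid with two explicitly placed lesions each, so generation stays
# cheap. With lesionTp == backgroundTp this is a null cohort (pathological
# and control VOIs share the same texture distribution).

# Note: the null cohort uses no boundary blur (blurSigma = 0). The
# partial-volume blur acts only around lesions, so with blur enabled the
# pathological VOI would be smoothed while its mirrored control is not and
# the two would not be exchangeable -- that mechanism is exercised by the
# directional cohort checks instead.
smallCohortSpecs <- function(seedBase, nPerGroup = 8, nLesions = 3,
                             backgroundTp = textureParams(100, 10, 1.5, 0),
                             lesionTp = backgroundTp,
                             grid = c(40, 40, 40)) {
  allCenters <- list(c(9.75, 11, 11), c(9.75, 28, 28), c(9.75, 11, 28))
  specs <- list()
  gi <- 0
  for (g in c("IS", "MS", "TU")) {
    gi <- gi + 1
    for (s in seq_len(nPerGroup)) {
      seed <- deriveSeed(seedBase, gi * 1000 + s)
      radii <- mritexture:::withSeed(seed, {
        lapply(seq_len(nLesions), function(...) stats::runif(3, 6.5, 7.5))
      })
      centers <- allCenters[seq_len(nLesions)]
      specs[[length(specs) + 1L]] <- subjectSpec(
        sprintf("%s_%02d", g, s), g, radii,
        backgroundParams = backgroundTp,
        lesionParams = list(T1 = lesionTp, T2 = lesionTp),
        seed = seed, lesionCenters = centers)
    }
  }
  list(specs = specs, grid = grid, spacing = c(1, 1, 1))
}

# Long feature table for one scheme over a spec list: elliptical VOI per
# lesion plus its mirrored co-lateral control, both contrasts.
smallCohortFeatures <- function(specList, method = "AR", param = 10,
                                contrasts = c("T1", "T2")) {
  rows <- list()
  for (spec in specList$specs) {
    for (ct in contrasts) {
      gen <- generateSubjectVolume(spec, ct, specList$grid,
                                   specList$spacing)
      for (li in seq_along(gen$lesions)) {
        les <- gen$lesions[[li]]
        voi <- ellipsoidVOI(les$center, pmax(les$radii - 1, 1),
                            specList$grid, specList$spacing,
                            label = sprintf("%s_L%d", spec$subjectId, li))
        ctrl <- mirrorVOI(voi, gen$midIndex)
        for (v in list(voi, ctrl)) {
          f <- extractAll(discretizeVOI(gen$volume, v, method, param))
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = spec$subjectId, group = spec$diseaseGroup,
            contrast = ct, role = voiRole(v),
            lesion_volume_mm3 = voiVolume(v),
            feature = names(f), value = unname(f),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

# Rank-sum p per feature x group x contrast from such a table
smallCohortRanksumP <- function(ft) {
  parts <- split(ft, list(ft$feature, ft$group, ft$contrast), drop = TRUE)
  vapply(parts, function(sub) {
    ranksumDiseaseVsControl(sub$value[sub$role == "pathological"],
                            sub$value[sub$role == "control"])$p
  }, numeric(1))
}

# Mutually independent null rank-sum tests: every test lives in its own
# (cohort seed x group x contrast x subject-half) block of voxel data and
# tests a single feature, rotating through all 40 features so each is
# exercised. Tests sharing a block would be strongly correlated (all 40
# features are computed from the same VOIs), which would invalidate a
# binomial band on their rejection fraction.
independentNullRanksumP <- function(seedBase, nSeeds = 20, nPerGroup = 8) {
  feats <- featureNames()
  b <- 0L
  pvals <- c()
  for (seed in seq_len(nSeeds)) {
    sc <- smallCohortSpecs(seedBase + seed, nPerGroup = nPerGroup)
    ft <- smallCohortFeatures(sc)
    half <- ifelse(as.integer(sub(".*_", "", ft$subject_id)) <=
                     nPerGroup / 2, "a", "b")
    parts <- split(ft, list(ft$group, ft$contrast, half), drop = TRUE)
    for (nm in sort(names(parts))) {
      b <- b + 1L
      sub <- parts[[nm]]
      sub <- sub[sub$feature == feats[(b - 1L) %% length(feats) + 1L], ]
      pvals <- c(pvals, ranksumDiseaseVsControl(
        sub$value[sub$role == "pathological"],
        sub$value[sub$role == "control"])$p)
    }
  }
  pvals
}
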