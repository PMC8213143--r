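#' Configuration for a full discretization-comparison study
#'
#' Bundles everything [runStudy()] needs: the cohort design, the two
#' segmentation settings, the discretization grids, clipping and alpha.
#' The default grids are a reduced sweep (\code{B} in \{10, 50, 100\},
#' \code{D} in \{8, 64, 256\}) sized for routine desk runs; pass
#' \code{grids = defaultGrids()} for the full 21 + 8 parameter sweep.
#'
#' @param design a [cohortDesign()].
#' @param manualMarginMm dilation margin of the manual-like VOI, mm.
#' @param ellipticalShrinkMm how much the elliptical VOI semi-axes are shrunk
#'   relative to the true lesion radii, so the ellipsoid sits in the inner
#'   lesion area away from the blurred boundary; default = the lesion blur
#'   sigma.
#' @param grids list with numeric \code{B} and \code{D} components.
#' @param clip percentile clip bounds for LAR/AR, default \code{c(10, 90)}.
#' @param clipLRR also clip for LRR (default FALSE).
#' @param alpha significance level for the screening stage.
#' @param minCm3 minimum VOI volume in cm^3.
#' @param outDir optional output directory for CSV/NIfTI artifacts.
#' @return a \code{studyConfig} list.
#' @export
studyConfig <- function(design = cohortDesign(),
                        manualMarginMm = 2,
                        ellipticalShrinkMm = NULL,
                        grids = list(B = c(10, 50, 100), D = c(8, 64, 256)),
                        clip = c(10, 90), clipLRR = FALSE,
                        alpha = 0.05, minCm3 = 1.0, outDir = NULL) {
  structure(list(design = design, manualMarginMm = manualMarginMm,
                 ellipticalShrinkMm = ellipticalShrinkMm, grids = grids,
                 clip = clip, clipLRR = clipLRR, alpha = alpha,
                 minCm3 = minCm3, outDir = outDir),
            class = "studyConfig")
}

# One record per (lesion x segmentation style x role): the VOI plus metadata.
segmentCohort <- function(cohort, manualMarginMm = 2,
                          ellipticalShrinkMm = NULL, minCm3 = 1.0,
                          log = NULL) {
  records <- list()
  for (subj in cohort) {
    sp <- subj$spec
    spacing <- voxelSpacing(subj$volumes[[1]])
    gridShape <- dim(voxelData(subj$volumes[[1]]))
    blur <- max(vapply(sp$lesionParams, function(p) p$blurSigma, numeric(1)))
    shrink <- if (is.null(ellipticalShrinkMm)) blur else ellipticalShrinkMm
    for (li in seq_along(subj$lesions)) {
      les <- subj$lesions[[li]]
      lab <- sprintf("%s_L%d", sp$subjectId, li)
      semi <- pmax(les$radii - shrink, max(spacing))
      vois <- list()
      vois$elliptical <- tryCatch(
        ellipsoidVOI(les$center, semi, gridShape, spacing, label = lab),
        error = function(e) NULL)
      vois$manual <- manualLikeVOI(les$mask, manualMarginMm,
                                   spacing = spacing, label = lab)
      for (style in names(vois)) {
        v <- vois[[style]]
        if (is.null(v)) {
          if (!is.null(log))
            log(sprintf("skip %s %s: elliptical VOI construction failed",
                        lab, style))
          next
        }
        if (voiVolume(v) < minCm3 * 1000) {
          if (!is.null(log))
            log(sprintf("skip %s %s: below %g cm^3", lab, style, minCm3))
          next
        }
        ctrl <- mirrorVOI(v, subj$midIndex)
        for (rec in list(v, ctrl)) {
          records[[length(records) + 1L]] <- list(
            subjectId = sp$subjectId, group = sp$diseaseGroup,
            lesion = li, segmentation = style, role = voiRole(rec),
            voi = rec, volume_mm3 = voiVolume(rec))
        }
      }
    }
  }
  records
}

schemeSettings <- function(grids) {
  rbind(
    if (length(grids$B))
      data.frame(method = rep(c("LAR", "AR"), each = length(grids$B)),
                 param = rep(grids$B, 2), stringsAsFactors = FALSE),
    if (length(grids$D))
      data.frame(method = "LRR", param = grids$D, stringsAsFactors = FALSE))
}

# Long feature table over VOI records x contrasts x scheme settings.
extractFeatureTable <- function(cohortVolumes, records, settings,
                                clip = c(10, 90), clipLRR = FALSE,
                                log = NULL) {
  rows <- list()
  for (rec in records) {
    vols <- cohortVolumes[[rec$subjectId]]
    for (ct in names(vols)) {
      for (si in seq_len(nrow(settings))) {
        method <- settings$method[si]; param <- settings$param[si]
        f <- tryCatch(
          extractAll(discretizeVOI(vols[[ct]], rec$voi, method, param,
                                   clip = clip, clipLRR = clipLRR)),
          error = function(e) {
            if (!is.null(log))
              log(sprintf("skip %s %s %s %s=%g: %s", rec$subjectId,
                          rec$segmentation, rec$role, method, param,
                          conditionMessage(e)))
            NULL
          })
        if (is.null(f)) next
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = rec$subjectId, group = rec$group,
          lesion = rec$lesion, contrast = ct,
          segmentation = rec$segmentation, role = rec$role,
          lesion_volume_mm3 = rec$volume_mm3,
          method = method, param = param,
          feature = names(f), value = unname(f),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Spearman records: one per feature x (group x role) x contrast per setting.
spearmanTable <- function(featureTable) {
  ft <- featureTable
  ft$cellGroup <- paste(ft$group,
                        ifelse(ft$role == "pathological", "path", "ctrl"),
                        sep = "_")
  parts <- split(ft, list(ft$method, ft$param, ft$segmentation, ft$feature,
                          ft$cellGroup, ft$contrast), drop = TRUE)
  rows <- lapply(parts, function(sub) {
    res <- if (nrow(sub) >= 3)
      spearmanFeatureVolume(sub$value, sub$lesion_volume_mm3)
    else list(rho = NA_real_, r2 = NA_real_, p = NA_real_, n = nrow(sub),
              degenerate = TRUE)
    data.frame(
      method = sub$method[1], param = sub$param[1],
      segmentation = sub$segmentation[1], feature = sub$feature[1],
      group = sub$cellGroup[1], contrast = sub$contrast[1],
      rho = res$rho, r2 = res$r2, p = res$p, n = res$n,
      degenerate = res$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$method, out$param, out$segmentation, out$feature,
            out$group, out$contrast), ]
}

# Rank-sum records: pathological vs control per feature x group x contrast.
ranksumTable <- function(featureTable) {
  ft <- featureTable
  parts <- split(ft, list(ft$method, ft$param, ft$segmentation, ft$feature,
                          ft$group, ft$contrast), drop = TRUE)
  rows <- lapply(parts, function(sub) {
    pa <- sub$value[sub$role == "pathological"]
    co <- sub$value[sub$role == "control"]
    res <- if (length(pa) >= 2 && length(co) >= 2)
      ranksumDiseaseVsControl(pa, co)
    else list(p = NA_real_, exact = NA, n1 = length(pa), n2 = length(co),
              degenerate = TRUE)
    data.frame(
      method = sub$method[1], param = sub$param[1],
      segmentation = sub$segmentation[1], feature = sub$feature[1],
      group = sub$group[1], contrast = sub$contrast[1],
      p = res$p, n1 = res$n1, n2 = res$n2,
      degenerate = res$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$method, out$param, out$segmentation, out$feature,
            out$group, out$contrast), ]
}

#' Run the full synthetic study
#'
#' Synthesize the cohort, build both segmentations with mirrored co-lateral
#' controls, enforce the minimum-volume rule, sweep the discretization
#' settings, extract all 40 features per VOI, and run the statistical
#' comparison stage. Deterministic: the same config yields byte-identical
#' CSV outputs.
#'
#' @param config a [studyConfig()].
#' @param verbose print per-stage progress.
#' @return list with \code{features} (long table), \code{spearman},
#'   \code{ranksum}, \code{significance} (per-cell counts),
#'   \code{r2maps} (per method/param/segmentation), \code{log}, and
#'   \code{files} (paths + md5, when \code{outDir} is set).
#' @export
runStudy <- function(config, verbose = FALSE) {
  logLines <- character()
  log <- function(msg) logLines <<- c(logLines, msg)
  say <- function(...) if (verbose) message(...)

  say("generating cohort (", config$design$nIS, "+", config$design$nMS,
      "+", config$design$nTU, " subjects)")
  cohort <- generateCohort(config$design)
  vols <- stats::setNames(lapply(cohort, `[[`, "volumes"),
                          vapply(cohort, function(s) s$spec$subjectId, ""))

  say("segmenting VOIs")
  records <- segmentCohort(cohort, config$manualMarginMm,
                           config$ellipticalShrinkMm, config$minCm3, log)
  settings <- schemeSettings(config$grids)
  say("extracting features: ", length(records), " VOIs x ",
      nrow(settings), " settings")
  features <- extractFeatureTable(vols, records, settings,
                                  clip = config$clip,
                                  clipLRR = config$clipLRR, log = log)
  say("statistics")
  sp <- spearmanTable(features)
  rs <- ranksumTable(features)
  sig <- countSignificant(rs, config$alpha)
  r2maps <- list()
  cells <- unique(sp[, c("method", "param", "segmentation")])
  for (k in seq_len(nrow(cells))) {
    sel <- sp$method == cells$method[k] & sp$param == cells$param[k] &
      sp$segmentation == cells$segmentation[k]
    key <- sprintf("%s_%g_%s", cells$method[k], cells$param[k],
                   cells$segmentation[k])
    r2maps[[key]] <- correlationMatrixTable(sp[sel, ])
  }
  out <- list(features = features, spearman = sp, ranksum = rs,
              significance = sig, r2maps = r2maps, log = logLines)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(features = "features.csv", spearman = "spearman.csv",
               ranksum = "ranksum.csv", significance = "significance.csv")
    for (nm in names(paths)) {
      p <- file.path(config$outDir, paths[nm])
      utils::write.csv(out[[nm]], p, row.names = FALSE)
    }
    writeLines(logLines, file.path(config$outDir, "run.log"))
    fp <- file.path(config$outDir, paths)
    out$files <- data.frame(path = fp, md5 = unname(tools::md5sum(fp)),
                            stringsAsFactors = FALSE)
  }
  out
}

# ---- real-data ingestion -------------------------------------------------

readNiftiVolume <- function(path, contrast = "T1") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  imageVolume(array(as.numeric(img), dim(img)[1:3]), sp, contrast)
}

readNiftiMask <- function(path, role = "pathological", style = "manual",
                          label = "voi") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  voiMask(array(as.numeric(img) > 0, dim(img)[1:3]), sp, role = role,
          style = style, label = label)
}

# Build a (volume, mask) pair from a Carimas-like voxel-list export.
voxelListToVolumeVOI <- function(path, spacing, contrast = "T1",
                                 role = "pathological", style = "manual",
                                 label = "voi", gridShape = NULL) {
  vl <- readVoxelList(path)
  if (!nrow(vl$coords)) stop("voxel list ", path, " is empty")
  if (is.null(gridShape)) gridShape <- apply(vl$coords, 2, max) + 2L
  vox <- array(1e-6, gridShape)   # positive floor outside the VOI
  vox[vl$coords + 1L] <- vl$intensities
  m <- array(FALSE, gridShape)
  m[vl$coords + 1L] <- TRUE
  list(volume = imageVolume(pmax(vox, 1e-6), spacing, contrast),
       voi = voiMask(m, spacing, role = role, style = style, label = label))
}

#' Ingest real NIfTI volumes and masks (or voxel-list exports)
#'
#' Builds the same per-VOI records the synthetic path produces, so the
#' downstream feature extraction and statistics are shared. The design table
#' must have columns \code{subject_id}, \code{group}, \code{contrast},
#' \code{role}, \code{segmentation}, and either \code{volume_path} +
#' \code{mask_path} (NIfTI) or \code{voxlist_path} (Carimas-like text, with
#' \code{spacing} columns \code{sx,sy,sz}).
#'
#' @param designTable data.frame as described.
#' @return list with \code{volumes} (per subject x contrast) and
#'   \code{records} (per VOI), as consumed by the internal extraction step.
#' @export
realDataIngest <- function(designTable) {
  volumes <- list()
  records <- list()
  for (k in seq_len(nrow(designTable))) {
    row <- designTable[k, ]
    lab <- sprintf("%s_%d", row$subject_id, k)
    if (!is.null(row$voxlist_path) && !is.na(row$voxlist_path) &&
        nzchar(row$voxlist_path)) {
      sp <- c(row$sx, row$sy, row$sz)
      built <- voxelListToVolumeVOI(row$voxlist_path, sp, row$contrast,
                                    row$role, row$segmentation, lab)
      vol <- built$volume; voi <- built$voi
    } else {
      vol <- readNiftiVolume(row$volume_path, row$contrast)
      voi <- readNiftiMask(row$mask_path, row$role, row$segmentation, lab)
      if (!identical(dim(voxelData(vol)), dim(voiMaskArray(voi))))
        stop("grid mismatch: ", row$volume_path, " is ",
             paste(dim(voxelData(vol)), collapse = "x"), " but ",
             row$mask_path, " is ",
             paste(dim(voiMaskArray(voi)), collapse = "x"))
      if (max(abs(voxelSpacing(vol) - voxelSpacing(voi))) > 1e-6)
        stop("spacing mismatch between ", row$volume_path, " and ",
             row$mask_path)
    }
    volumes[[row$subject_id]][[row$contrast]] <- vol
    records[[length(records) + 1L]] <- list(
      subjectId = row$subject_id, group = row$group, lesion = k,
      segmentation = row$segmentation, role = row$role, voi = voi,
      volume_mm3 = voiVolume(voi))
  }
  list(volumes = volumes, records = records)
}

#' Extract the long feature table for ingested real data
#'
#' @param ingest output of [realDataIngest()].
#' @param grids,clip,clipLRR as in [studyConfig()].
#' @return the long feature data.frame (same columns as the synthetic path).
#' @export
extractIngestedFeatures <- function(ingest,
                                    grids = list(B = 50, D = 64),
                                    clip = c(10, 90), clipLRR = FALSE) {
  # records reference only their own subject's contrasts: restrict each
  # record's extraction to the contrast its row declared
  rows <- list()
  settings <- schemeSettings(grids)
  for (rec in ingest$records) {
    cts <- names(ingest$volumes[[rec$subjectId]])
    for (ct in cts) {
      vol <- ingest$volumes[[rec$subjectId]][[ct]]
      if (!identical(dim(voxelData(vol)), dim(voiMaskArray(rec$voi))))
        next
      for (si in seq_len(nrow(settings))) {
        f <- extractAll(discretizeVOI(vol, rec$voi, settings$method[si],
                                      settings$param[si], clip = clip,
                                      clipLRR = clipLRR))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = rec$subjectId, group = rec$group,
          lesion = rec$lesion, contrast = ct,
          segmentation = rec$segmentation, role = rec$role,
          lesion_volume_mm3 = rec$volume_mm3,
          method = settings$method[si], param = settings$param[si],
          feature = names(f), value = unname(f),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
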