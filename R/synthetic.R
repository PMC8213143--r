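#' Texture parameters for a synthetic tissue compartment
#'
#' Describes the second-order structure of a stationary random field used to
#' fill a tissue compartment (background or lesion interior): target mean and
#' standard deviation in arbitrary MR units, a spatial correlation length, and
#' the partial-volume blur applied at lesion boundaries.
#'
#' @param meanIntensity target mean, arbitrary MR units, > 0.
#' @param intensitySd target standard deviation, same units, >= 0.
#' @param corrLength correlation length in mm (0 = white noise).
#' @param blurSigma Gaussian sigma in mm of the boundary partial-volume blur.
#' @return a \code{textureParams} list.
#' @examples
#' textureParams(100, 10, corrLength = 1.5)
#' @export
textureParams <- function(meanIntensity, intensitySd = 0, corrLength = 0,
                          blurSigma = 0) {
  stopifnot(meanIntensity > 0, intensitySd >= 0, corrLength >= 0,
            blurSigma >= 0)
  structure(list(meanIntensity = meanIntensity, intensitySd = intensitySd,
                 corrLength = corrLength, blurSigma = blurSigma),
            class = "textureParams")
}

#' Specification of one synthetic subject
#'
#' @param subjectId identifier string.
#' @param diseaseGroup one of \code{"IS"}, \code{"MS"}, \code{"TU"}.
#' @param lesionRadii list of length-3 numeric vectors (semi-axes, mm),
#'   one per lesion.
#' @param backgroundParams [textureParams()] shared by both contrasts,
#'   or a named list per contrast.
#' @param lesionParams named list (one [textureParams()] per contrast label).
#' @param seed integer subject seed.
#' @param lesionCenters optional list of length-3 mm coordinates; when
#'   \code{NULL} the generator places lesions in the left hemisphere so that
#'   each lesion and its mirrored co-lateral control fit inside the grid
#'   without overlap.
#' @return a \code{subjectSpec} list.
#' @export
subjectSpec <- function(subjectId, diseaseGroup, lesionRadii,
                        backgroundParams, lesionParams, seed,
                        lesionCenters = NULL) {
  stopifnot(diseaseGroup %in% c("IS", "MS", "TU"),
            length(lesionRadii) >= 1L)
  structure(list(subjectId = subjectId, diseaseGroup = diseaseGroup,
                 nLesions = length(lesionRadii), lesionRadii = lesionRadii,
                 backgroundParams = backgroundParams,
                 lesionParams = lesionParams, seed = as.integer(seed),
                 lesionCenters = lesionCenters),
            class = "subjectSpec")
}

#' Cohort design
#'
#' Group sizes default to the three-group brain-MRI design this package
#' emulates: 22 ischemic stroke, 22 multiple sclerosis, 27 tumor subjects,
#' imaged at two contrasts (T1-like and T2-like) on a common voxel grid.
#'
#' @param nIS,nMS,nTU subjects per disease group.
#' @param gridShape voxels per axis (length 3).
#' @param spacing mm per axis (length 3).
#' @param masterSeed integer master seed; all subject streams derive from it.
#' @param contrasts ordered contrast labels.
#' @return a \code{cohortDesign} list.
#' @export
cohortDesign <- function(nIS = 22, nMS = 22, nTU = 27,
                         gridShape = c(64, 64, 64), spacing = c(1, 1, 1),
                         masterSeed = 1L, contrasts = c("T1", "T2")) {
  stopifnot(nIS >= 1, nMS >= 1, nTU >= 1, all(spacing > 0),
            length(gridShape) == 3L, length(spacing) == 3L)
  structure(list(nIS = as.integer(nIS), nMS = as.integer(nMS),
                 nTU = as.integer(nTU), gridShape = as.integer(gridShape),
                 spacing = as.numeric(spacing),
                 masterSeed = as.integer(masterSeed),
                 contrasts = as.character(contrasts)),
            class = "cohortDesign")
}

# ---- random fields -------------------------------------------------------

# Separable Gaussian smoothing of a 3D array; sigma given in voxels per
# axis. Kernel truncated at 3 sigma and normalized to sum 1; boundaries are
# handled by circular wrap-around, which keeps the smoothed field exactly
# stationary (no edge-variance inflation).
gaussSmooth3d <- function(a, sigmaVox) {
  for (axis in 1:3) {
    s <- sigmaVox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    a <- convolveAxisCirc(a, k / sum(k), axis)
  }
  a
}

convolveAxisCirc <- function(a, kern, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(kern) - 1L) / 2L
  out <- array(0, d)
  ii <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (o in -r:r) {
    w <- kern[o + r + 1L]
    si <- ii
    si[[axis]] <- ((seq_len(n) - 1L + o) %% n) + 1L
    out <- out + w * a[si[[1]], si[[2]], si[[3]]]
  }
  out
}

# Stationary correlated Gaussian field: white noise smoothed by an isotropic
# Gaussian of width corrLength (mm), rescaled to the target mean/sd using
# the theoretical variance of the smoothed noise (interior voxels). The
# theoretical scale keeps the field honestly stationary: empirical
# standardization would absorb domain-mean fluctuation and make the field's
# local statistics depend on the size of the generation domain.
correlatedField <- function(gridShape, spacing, params, seed) {
  if (params$intensitySd == 0)
    return(array(params$meanIntensity, gridShape))
  withSeed(seed, {
    z <- array(stats::rnorm(prod(gridShape)), gridShape)
    scale <- 1
    if (params$corrLength > 0) {
      sVox <- params$corrLength / spacing
      z <- gaussSmooth3d(z, sVox)
      f2 <- 1
      for (s in sVox) {
        if (s <= 0) next
        r <- max(1L, ceiling(3 * s))
        k <- exp(-((-r:r)^2) / (2 * s^2))
        w <- k / sum(k)
        f2 <- f2 * sum(w^2)
      }
      scale <- sqrt(f2)
    }
    params$meanIntensity + params$intensitySd * z / scale
  })
}

# Ellipsoid membership of voxel centers: world coordinate = index * spacing
# (0-based indices).
ellipsoidArray <- function(center, semiAxes, gridShape, spacing) {
  cx <- (seq_len(gridShape[1]) - 1) * spacing[1]
  cy <- (seq_len(gridShape[2]) - 1) * spacing[2]
  cz <- (seq_len(gridShape[3]) - 1) * spacing[3]
  qx <- ((cx - center[1]) / semiAxes[1])^2
  qy <- ((cy - center[2]) / semiAxes[2])^2
  qz <- ((cz - center[3]) / semiAxes[3])^2
  q <- outer(outer(qx, qy, "+"), qz, "+")
  q <= 1
}

maskBoundingBox <- function(mask, pad) {
  d <- dim(mask)
  ix <- arrayInd(which(mask), d)
  lapply(1:3, function(a) {
    max(1L, min(ix[, a]) - pad[min(a, length(pad))]):
      min(d[a], max(ix[, a]) + pad[min(a, length(pad))])
  })
}

strHash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (mulmod32(h, 31) + v) %% MOD32
  h
}

# Deterministic lesion placement in the left hemisphere (x below the
# midsagittal plane) so every lesion and its mirrored control fit the grid.
placeLesions <- function(spec, gridShape, spacing) {
  if (!is.null(spec$lesionCenters)) return(spec$lesionCenters)
  extent <- (gridShape - 1) * spacing
  mid <- extent[1] / 2
  blur <- max(vapply(spec$lesionParams, function(p) p$blurSigma, numeric(1)))
  centers <- list()
  withSeed(deriveSeed(spec$seed, 0), {
    for (li in seq_len(spec$nLesions)) {
      r <- spec$lesionRadii[[li]]
      pad <- r + blur + spacing
      loX <- pad[1]; hiX <- mid - pad[1]
      lo <- pad; hi <- extent - pad
      if (loX > hiX || any(lo > hi))
        stop("lesion of radii (", paste(r, collapse = ", "),
             ") mm does not fit the grid with its mirrored control")
      ok <- FALSE
      for (try in 1:2000) {
        cand <- c(stats::runif(1, loX, hiX),
                  stats::runif(1, lo[2], hi[2]),
                  stats::runif(1, lo[3], hi[3]))
        ok <- TRUE
        for (cj in seq_along(centers)) {
          rj <- spec$lesionRadii[[cj]]
          if (all(abs(cand - centers[[cj]]) <= (r + rj + 2 * blur))) {
            ok <- FALSE; break
          }
        }
        if (ok) break
      }
      if (!ok) stop("could not place non-overlapping lesions for subject ",
                    spec$subjectId)
      centers[[li]] <- cand
    }
  })
  centers
}

#' Generate one synthetic subject volume
#'
#' Background voxels are drawn from a stationary correlated Gaussian random
#' field; lesion interiors are overwritten by a field with the lesion
#' parameters of the requested contrast; the volume is then blended with a
#' Gaussian-smoothed copy in a shell around the lesion boundary, emulating
#' partial-volume mixing; finally intensities are clamped to a floor of 1
#' unit so that absolute-resampling discretization stays well defined.
#' Identical (spec, contrast, gridShape, spacing) inputs yield identical
#' outputs; lesion geometry is shared across contrasts.
#'
#' @param spec a [subjectSpec()].
#' @param contrast contrast label (must be a name of \code{spec$lesionParams}).
#' @param gridShape voxels per axis.
#' @param spacing mm per axis, strictly positive.
#' @return list with \code{volume} (an [ImageVolume-class]), \code{lesions}
#'   (list of \code{center}, \code{radii}, \code{mask}), and
#'   \code{midIndex} (midsagittal voxel coordinate used for mirroring).
#' @export
generateSubjectVolume <- function(spec, contrast, gridShape, spacing) {
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  gridShape <- as.integer(gridShape)
  lp <- spec$lesionParams[[contrast]]
  if (is.null(lp)) stop("no lesion params for contrast ", contrast)
  bp <- if (inherits(spec$backgroundParams, "textureParams"))
    spec$backgroundParams else spec$backgroundParams[[contrast]]
  centers <- placeLesions(spec, gridShape, spacing)
  extent <- (gridShape - 1) * spacing

  cseed <- deriveSeed(spec$seed, 7 + strHash(contrast) %% 1000003)
  vol <- correlatedField(gridShape, spacing, bp, cseed)
  lesions <- vector("list", spec$nLesions)
  allMask <- array(FALSE, gridShape)
  for (li in seq_len(spec$nLesions)) {
    m <- ellipsoidArray(centers[[li]], spec$lesionRadii[[li]],
                        gridShape, spacing)
    if (!any(m)) stop("lesion ", li, " rasterized to zero voxels")
    allMask <- allMask | m
    lesions[[li]] <- list(center = centers[[li]],
                          radii = spec$lesionRadii[[li]], mask = m)
  }
  # lesion texture and boundary blur act only inside (a margin around) the
  # lesions; both are computed on the lesion bounding box for speed
  pad <- ceiling(3 * max(lp$corrLength, lp$blurSigma) / spacing) + 1
  box <- maskBoundingBox(allMask, pad)
  subShape <- vapply(box, length, integer(1))
  lesField <- correlatedField(subShape, spacing, lp, deriveSeed(cseed, 1))
  subMask <- allMask[box[[1]], box[[2]], box[[3]], drop = FALSE]
  subVol <- vol[box[[1]], box[[2]], box[[3]], drop = FALSE]
  subVol[subMask] <- lesField[subMask]
  if (lp$blurSigma > 0) {
    sv <- lp$blurSigma / spacing
    sm <- gaussSmooth3d(subVol, sv)
    mw <- gaussSmooth3d(subMask + 0, sv)
    w <- pmin(1, 4 * mw * (1 - mw))  # peaks at the boundary, ~0 elsewhere
    subVol <- (1 - w) * subVol + w * sm
  }
  vol[box[[1]], box[[2]], box[[3]]] <- subVol
  vol <- pmax(vol, 1.0)
  list(volume = imageVolume(vol, spacing, contrast),
       lesions = lesions,
       midIndex = (gridShape[1] - 1) / 2)
}

# Disease-group presets: groups differ only in lesion-count range, size range
# and lesion texture parameters (per contrast). No clinical realism intended.
groupPresets <- function(group) {
  switch(group,
    IS = list(nLesions = 1:2, radiiRange = c(8, 12),
              lesion = list(T1 = textureParams(80, 14, 2.0, 1.0),
                            T2 = textureParams(135, 14, 2.0, 1.0))),
    MS = list(nLesions = 1:3, radiiRange = c(8, 11),
              lesion = list(T1 = textureParams(85, 12, 1.2, 1.0),
                            T2 = textureParams(140, 12, 1.2, 1.0))),
    TU = list(nLesions = 1L, radiiRange = c(9, 13),
              lesion = list(T1 = textureParams(150, 20, 2.5, 1.0),
                            T2 = textureParams(160, 22, 2.5, 1.0))),
    stop("unknown group ", group))
}

defaultBackground <- function() {
  list(T1 = textureParams(100, 10, 1.5, 1.0),
       T2 = textureParams(110, 10, 1.5, 1.0))
}

#' Generate a reproducible synthetic cohort
#'
#' Builds \code{nIS + nMS + nTU} subjects. Per-subject seeds are derived from
#' the master seed with [deriveSeed()], so the cohort is a pure function of
#' the design and removing one subject does not change the others. Each
#' subject has one volume per contrast with identical lesion geometry across
#' contrasts (as for co-registered T1/T2).
#'
#' @param design a [cohortDesign()].
#' @param lesionParamsOverride optional: named list per contrast of
#'   [textureParams()] used for every group (e.g. to build a null cohort in
#'   which lesions and background share the same texture).
#' @param backgroundOverride optional background params (per contrast list or
#'   single \code{textureParams}).
#' @return list of subjects; each has \code{spec}, \code{volumes} (named list
#'   of [ImageVolume-class] per contrast), \code{lesions}, \code{midIndex}.
#' @examples
#' coh <- generateCohort(cohortDesign(1, 1, 1, gridShape = c(24, 24, 24),
#'                                    masterSeed = 7))
#' length(coh)  # 3 subjects
#' @export
generateCohort <- function(design, lesionParamsOverride = NULL,
                           backgroundOverride = NULL) {
  groups <- c(rep("IS", design$nIS), rep("MS", design$nMS),
              rep("TU", design$nTU))
  withinIdx <- c(seq_len(design$nIS), seq_len(design$nMS),
                 seq_len(design$nTU))
  groupCode <- c(IS = 1L, MS = 2L, TU = 3L)
  bg <- if (is.null(backgroundOverride)) defaultBackground()
        else backgroundOverride
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    preset <- groupPresets(g)
    # seed indexed by (group, within-group position): shrinking one group
    # never perturbs another group's subjects
    sseed <- deriveSeed(design$masterSeed,
                        groupCode[[g]] * 65536 + withinIdx[i])
    geom <- withSeed(deriveSeed(sseed, 999), {
      nl <- if (length(preset$nLesions) > 1)
        sample(preset$nLesions, 1) else preset$nLesions
      radii <- lapply(seq_len(nl), function(...) {
        stats::runif(3, preset$radiiRange[1], preset$radiiRange[2])
      })
      list(nl = nl, radii = radii)
    })
    lp <- if (is.null(lesionParamsOverride)) preset$lesion
          else lesionParamsOverride
    lp <- lp[design$contrasts]
    names(lp) <- design$contrasts
    spec <- subjectSpec(sprintf("%s%02d", g, withinIdx[i]), g, geom$radii,
                        bg, lp, sseed)
    vols <- list(); lesions <- NULL; midIndex <- NULL
    for (ct in design$contrasts) {
      gen <- generateSubjectVolume(spec, ct, design$gridShape,
                                   design$spacing)
      vols[[ct]] <- gen$volume
      lesions <- gen$lesions     # identical geometry across contrasts
      midIndex <- gen$midIndex
    }
    out[[i]] <- list(spec = spec, volumes = vols, lesions = lesions,
                     midIndex = midIndex)
  }
  out
}

#' Write a cohort to NIfTI files with a CSV manifest
#'
#' One \code{.nii.gz} per subject x contrast plus one binary lesion mask per
#' subject, and a manifest CSV (subject, group, contrast, paths, lesion
#' volumes in mm^3, seed).
#'
#' @param cohort output of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return the manifest as a data.frame (invisibly written to
#'   \code{manifest.csv}).
#' @export
writeCohortNifti <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (subj in cohort) {
    sp <- subj$spec
    allMask <- Reduce(`|`, lapply(subj$lesions, `[[`, "mask"))
    spacing <- voxelSpacing(subj$volumes[[1]])
    maskPath <- file.path(dir, paste0(sp$subjectId, "_lesions.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(allMask + 0L, pixdim = spacing),
                       maskPath)
    lesVol <- sum(allMask) * prod(spacing)
    for (ct in names(subj$volumes)) {
      v <- subj$volumes[[ct]]
      p <- file.path(dir, paste0(sp$subjectId, "_", ct, ".nii.gz"))
      RNifti::writeNifti(RNifti::asNifti(voxelData(v),
                                         pixdim = voxelSpacing(v)), p)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sp$subjectId, group = sp$diseaseGroup, contrast = ct,
        volume_path = p, mask_path = maskPath,
        lesion_volume_mm3 = lesVol, seed = sp$seed,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
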