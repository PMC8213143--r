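#' Percentile clipping (winsorization) of VOI intensities
#'
#' Fixed-bin-size discretization (LAR/AR) is applied after clipping the VOI
#' intensities to their 10th and 90th percentiles: values below the lower
#' percentile are set to it, values above the upper percentile likewise.
#' Voxels are retained (winsorized, not excluded), so the voxel lattice stays
#' intact for texture-matrix construction. Percentiles use the
#' linear-interpolation definition (R's default type 7 quantile).
#'
#' @param intensities numeric vector (>= 1 value).
#' @param lo,hi percentile bounds in \code{[0, 100]}, \code{lo < hi}.
#' @return list with \code{values} (clipped, same length/order) and
#'   \code{stats}: \code{pLo}, \code{pHi}, \code{nClippedLow},
#'   \code{nClippedHigh}.
#' @examples
#' percentileClip(c(1, 2, 50, 99, 100))$stats
#' @export
percentileClip <- function(intensities, lo = 10, hi = 90) {
  if (!length(intensities)) stop("empty intensity vector")
  stopifnot(lo >= 0, hi <= 100, lo < hi)
  q <- stats::quantile(intensities, c(lo, hi) / 100, names = FALSE, type = 7)
  nLow <- sum(intensities < q[1])
  nHigh <- sum(intensities > q[2])
  list(values = pmin(pmax(intensities, q[1]), q[2]),
       stats = list(pLo = q[1], pHi = q[2],
                    nClippedLow = nLow, nClippedHigh = nHigh))
}

newDiscretizedVOI <- function(levels, iMin, iMax, method, param, spacing,
                              degenerate = FALSE) {
  lv <- levels[!is.na(levels)]
  new("DiscretizedVOI", levels = levels, iMin = iMin, iMax = iMax,
      method = method, param = as.numeric(param),
      spacing = as.numeric(spacing),
      nLevelsObserved = length(unique(lv)),
      degenerate = degenerate || length(unique(lv)) == 1L)
}

asLevelArray <- function(values, template) {
  out <- template
  out[!is.na(template)] <- values
  out
}

# intensities as 3D array with NA outside the mask
maskedIntensityArray <- function(volume, voi) {
  v <- voxelData(volume); m <- voiMaskArray(voi)
  if (!identical(dim(v), dim(m)))
    stop("volume and mask grids differ")
  v[!m] <- NA_real_
  v
}

#' Lesion absolute resampling (LAR)
#'
#' Fixed bin size anchored at the VOI minimum:
#' \deqn{I_{LAR}(i) = \lfloor I(i)/B \rfloor - \lfloor I_{min}/B \rfloor + 1}
#' so the minimum level is exactly 1. Intensities are expected to be clipped
#' beforehand (see [percentileClip()]); \code{iMin} is the minimum of the
#' clipped VOI intensities.
#'
#' @param intensities 3D array with \code{NA} outside the VOI (or a plain
#'   numeric vector).
#' @param B bin width, intensity units, > 0.
#' @param iMin VOI minimum after clipping; defaults to
#'   \code{min(intensities)}.
#' @param spacing mm per axis (metadata).
#' @return a [DiscretizedVOI-class] (levels >= 1).
#' @examples
#' greyLevels(discretizeLAR(array(c(23, 27, 41), c(3, 1, 1)), B = 10))
#' @export
discretizeLAR <- function(intensities, B, iMin = NULL, spacing = c(1, 1, 1)) {
  if (B <= 0) stop("bin width B must be > 0")
  arr <- asArray3d(intensities)
  x <- arr[!is.na(arr)]
  if (!length(x)) stop("no in-mask voxels")
  if (is.null(iMin)) iMin <- min(x)
  lev <- floor(x / B) - floor(iMin / B) + 1
  newDiscretizedVOI(asLevelArray(as.integer(lev), arr), iMin, max(x),
                    "LAR", B, spacing)
}

#' Absolute resampling (AR)
#'
#' Fixed bin size anchored at absolute intensity zero:
#' \deqn{I_{AR}(i) = \lceil I(i)/B \rceil - 1}
#' Levels are >= 0 and independent of the VOI minimum, which is what makes AR
#' insensitive to where the lesion's intensity range happens to sit. All
#' intensities must be strictly positive (a level of -1 would otherwise
#' result). At matrix-construction time levels are shifted by +1 so grey
#' values start at 1 (see [buildGLCM()]).
#'
#' @inheritParams discretizeLAR
#' @return a [DiscretizedVOI-class] (levels >= 0).
#' @examples
#' greyLevels(discretizeAR(array(c(23, 27, 41), c(3, 1, 1)), B = 10))
#' @export
discretizeAR <- function(intensities, B, spacing = c(1, 1, 1)) {
  if (B <= 0) stop("bin width B must be > 0")
  arr <- asArray3d(intensities)
  x <- arr[!is.na(arr)]
  if (!length(x)) stop("no in-mask voxels")
  if (any(x <= 0)) stop("AR requires strictly positive intensities")
  lev <- ceiling(x / B) - 1
  newDiscretizedVOI(asLevelArray(as.integer(lev), arr), min(x), max(x),
                    "AR", B, spacing)
}

#' Lesion relative resampling (LRR, fixed bin number)
#'
#' The VOI intensity range is split into \code{D} equal bins:
#' \deqn{I_{LRR}(i) = 1 \textrm{ if } I(i) = I_{min}, \textrm{ else }
#'   \lceil D (I(i) - I_{min}) / (I_{max} - I_{min}) \rceil}
#' so levels lie in \code{{1, ..., D}} with the extremes mapped to 1 and D.
#' A constant VOI (\code{iMax == iMin}) maps every voxel to level 1 and sets
#' the degeneracy flag.
#'
#' @inheritParams discretizeLAR
#' @param D number of bins, integer >= 2.
#' @return a [DiscretizedVOI-class] with levels in \code{1..D}.
#' @examples
#' greyLevels(discretizeLRR(array(c(0.5, 50, 100), c(3, 1, 1)), D = 8))
#' @export
discretizeLRR <- function(intensities, D, spacing = c(1, 1, 1)) {
  if (D < 2 || D != round(D)) stop("bin count D must be an integer >= 2")
  arr <- asArray3d(intensities)
  x <- arr[!is.na(arr)]
  if (!length(x)) stop("no in-mask voxels")
  iMin <- min(x); iMax <- max(x)
  if (iMax == iMin) {
    lev <- rep(1L, length(x))
    return(newDiscretizedVOI(asLevelArray(lev, arr), iMin, iMax, "LRR", D,
                             spacing, degenerate = TRUE))
  }
  lev <- ifelse(x == iMin, 1L,
                as.integer(ceiling(D * (x - iMin) / (iMax - iMin))))
  newDiscretizedVOI(asLevelArray(lev, arr), iMin, iMax, "LRR", D, spacing)
}

asArray3d <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  array(as.numeric(x), c(length(x), 1L, 1L))
}

#' The bin-width and bin-count parameter grids
#'
#' The fixed-bin-size sweep uses bin widths
#' \code{B = \{1, 5, 10, 15, ..., 100\}} (21 values) and the fixed-bin-number
#' sweep uses \code{D = \{8, 16, 32, 64, 128, 256, 512, 1024\}} (8 values).
#'
#' @return list with components \code{B} and \code{D}, each sorted ascending.
#' @export
defaultGrids <- function() {
  list(B = c(1, seq(5, 100, by = 5)),
       D = 2^(3:10))
}

#' Apply a discretization scheme to one VOI of one volume
#'
#' Convenience wrapper used by the pipeline: extracts the in-mask
#' intensities, applies percentile clipping for the fixed-bin-size methods
#' (LAR, AR), and dispatches to the scheme. By default LRR uses the
#' unclipped VOI minimum/maximum; set \code{clipLRR = TRUE} to clip for LRR
#' as well.
#'
#' @param volume an [ImageVolume-class].
#' @param voi a [VOIMask-class] on the same grid.
#' @param method \code{"LAR"}, \code{"AR"} or \code{"LRR"}.
#' @param param bin width B (LAR/AR) or bin count D (LRR).
#' @param clip percentile bounds for LAR/AR, default \code{c(10, 90)};
#'   \code{NULL} disables clipping.
#' @param clipLRR also clip before LRR (default \code{FALSE}).
#' @return a [DiscretizedVOI-class].
#' @export
discretizeVOI <- function(volume, voi, method, param, clip = c(10, 90),
                          clipLRR = FALSE) {
  arr <- maskedIntensityArray(volume, voi)
  doClip <- !is.null(clip) && (method %in% c("LAR", "AR") || clipLRR)
  if (doClip) {
    msk <- !is.na(arr)
    arr[msk] <- percentileClip(arr[msk], clip[1], clip[2])$values
  }
  sp <- voxelSpacing(voi)
  switch(method,
         LAR = discretizeLAR(arr, param, spacing = sp),
         AR  = discretizeAR(arr, param, spacing = sp),
         LRR = discretizeLRR(arr, param, spacing = sp),
         stop("unknown method ", method))
}
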