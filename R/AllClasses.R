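#' @import methods
NULL

#' ImageVolume: a 3D scalar intensity grid with physical spacing
#'
#' Container for one contrast channel of one subject: a 3D array of strictly
#' positive intensities (arbitrary MR units), the voxel spacing in mm per
#' axis, and a contrast label (e.g. \code{"T1"}, \code{"T2"}).
#'
#' @slot voxels 3D numeric array, all values > 0.
#' @slot spacing numeric length-3, mm per axis, all > 0.
#' @slot contrast character scalar contrast label.
#'
#' @seealso [imageVolume()], [VOIMask-class], [discretizeVOI()]
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", contrast = "character"))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "'voxels' must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive mm values")
  if (any(!is.finite(object@voxels)) || any(object@voxels <= 0))
    msg <- c(msg, "all voxel intensities must be finite and > 0")
  if (length(object@contrast) != 1L)
    msg <- c(msg, "'contrast' must be a single label")
  if (length(msg)) msg else TRUE
})

#' VOIMask: a boolean volume-of-interest aligned to an ImageVolume
#'
#' @slot mask 3D logical array with at least one \code{TRUE} voxel.
#' @slot role \code{"pathological"} or \code{"control"}.
#' @slot style \code{"elliptical"} or \code{"manual"}.
#' @slot spacing numeric length-3, mm per axis.
#' @slot label free-text identifier (subject/lesion).
#'
#' @seealso [ellipsoidVOI()], [manualLikeVOI()], [mirrorVOI()]
#' @export
setClass("VOIMask",
  representation(mask = "array", role = "character", style = "character",
                 spacing = "numeric", label = "character"))

setValidity("VOIMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "'mask' must be a 3D logical array")
  if (!any(object@mask))
    msg <- c(msg, "mask must contain at least one TRUE voxel")
  if (!object@role %in% c("pathological", "control"))
    msg <- c(msg, "role must be 'pathological' or 'control'")
  if (!object@style %in% c("elliptical", "manual"))
    msg <- c(msg, "style must be 'elliptical' or 'manual'")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive mm values")
  if (length(msg)) msg else TRUE
})

#' DiscretizedVOI: integer grey levels on the masked voxel lattice
#'
#' Result of applying a discretization scheme to the intensities of one VOI.
#' Levels keep their 3D positions (array with \code{NA} outside the mask) so
#' that texture matrices can be built on the voxel lattice.
#'
#' @slot levels 3D integer array, \code{NA} outside the VOI.
#' @slot iMin,iMax intensity extremes within the VOI after any clipping.
#' @slot method \code{"LAR"}, \code{"AR"} or \code{"LRR"}.
#' @slot param bin width B (LAR/AR, intensity units) or bin count D (LRR).
#' @slot spacing mm per axis.
#' @slot nLevelsObserved number of distinct observed levels.
#' @slot degenerate \code{TRUE} when the VOI was constant (single level).
#'
#' @export
setClass("DiscretizedVOI",
  representation(levels = "array", iMin = "numeric", iMax = "numeric",
                 method = "character", param = "numeric", spacing = "numeric",
                 nLevelsObserved = "integer", degenerate = "logical"))

setValidity("DiscretizedVOI", function(object) {
  msg <- character()
  if (length(dim(object@levels)) != 3L)
    msg <- c(msg, "'levels' must be a 3D array")
  lv <- object@levels[!is.na(object@levels)]
  if (!length(lv)) msg <- c(msg, "no in-mask voxels")
  if (length(lv) && any(lv != round(lv)))
    msg <- c(msg, "levels must be integers")
  if (!object@method %in% c("LAR", "AR", "LRR"))
    msg <- c(msg, "method must be LAR, AR or LRR")
  if (length(msg)) msg else TRUE
})

#' Grey-level texture matrices
#'
#' \code{GLCMatrix} holds the merged-symmetric grey-level co-occurrence
#' probabilities over the 13 unique 3D directions at a given Chebyshev
#' distance; \code{GLRLMatrix} the run-length counts merged over the same 13
#' directions; \code{GLSZMatrix} the size-zone counts under 26-connectivity.
#' Grey levels are indexed 1..Ng with Ng the maximum observed level;
#' unobserved intermediate levels are kept as empty rows because
#' intensity-weighted features use the level value itself.
#'
#' @slot probabilities Ng x Ng symmetric matrix summing to 1 (GLCM).
#' @slot counts Ng x Rmax (runs) or Ng x Smax (zones) count matrix.
#' @slot nPairs,nVoxels,nDirections bookkeeping counts.
#' @slot distance co-occurrence distance in voxels.
#' @slot connectivity zone connectivity (26 in 3D).
#'
#' @name TextureMatrix-classes
#' @aliases GLCMatrix-class GLRLMatrix-class GLSZMatrix-class
NULL

#' @rdname TextureMatrix-classes
#' @export
setClass("GLCMatrix",
  representation(probabilities = "matrix", nPairs = "numeric",
                 distance = "numeric", nDirections = "integer"))

#' @rdname TextureMatrix-classes
#' @export
setClass("GLRLMatrix",
  representation(counts = "matrix", nVoxels = "integer",
                 nDirections = "integer"))

#' @rdname TextureMatrix-classes
#' @export
setClass("GLSZMatrix",
  representation(counts = "matrix", nVoxels = "integer",
                 connectivity = "integer"))

setValidity("GLCMatrix", function(object) {
  p <- object@probabilities
  msg <- character()
  if (nrow(p) != ncol(p)) msg <- c(msg, "probability matrix must be square")
  if (any(p < 0)) msg <- c(msg, "probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) msg <- c(msg, "probabilities must sum to 1")
  if (max(abs(p - t(p))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume [%s] %dx%dx%d voxels, spacing %s mm\n",
              object@contrast, d[1], d[2], d[3],
              paste(format(object@spacing), collapse = "x")))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "VOIMask", function(object) {
  cat(sprintf("VOIMask '%s' (%s, %s): %d voxels, %.1f mm^3\n",
              object@label, object@role, object@style,
              sum(object@mask), voiVolume(object)))
})

setMethod("show", "DiscretizedVOI", function(object) {
  cat(sprintf("DiscretizedVOI [%s, param=%g]: %d voxels, %d levels%s\n",
              object@method, object@param, sum(!is.na(object@levels)),
              object@nLevelsObserved,
              if (object@degenerate) " (degenerate)" else ""))
})

# ---- accessors ----

#' Accessors for the core classes
#'
#' @param x an \code{ImageVolume}, \code{VOIMask} or \code{DiscretizedVOI}.
#' @return \code{voxelData}: the 3D intensity array. \code{voxelSpacing}: mm
#'   per axis. \code{contrastLabel}: the contrast label. \code{voiMaskArray}:
#'   the logical 3D array. \code{voiVolume}: the VOI volume in mm^3.
#'   \code{voiRole}, \code{voiStyle}: role/style strings. \code{greyLevels}:
#'   the in-mask integer levels (vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
voxelData <- function(x) x@voxels

#' @rdname accessors
#' @export
voxelSpacing <- function(x) x@spacing

#' @rdname accessors
#' @export
contrastLabel <- function(x) x@contrast

#' @rdname accessors
#' @export
voiMaskArray <- function(x) x@mask

#' @rdname accessors
#' @export
voiVolume <- function(x) sum(x@mask) * prod(x@spacing)

#' @rdname accessors
#' @export
voiRole <- function(x) x@role

#' @rdname accessors
#' @export
voiStyle <- function(x) x@style

#' @rdname accessors
#' @export
greyLevels <- function(x) as.integer(x@levels[!is.na(x@levels)])

#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array of strictly positive intensities.
#' @param spacing mm per axis (length 3).
#' @param contrast contrast label, e.g. \code{"T1"}.
#' @return an \code{ImageVolume}.
#' @export
imageVolume <- function(voxels, spacing, contrast = "T1") {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      contrast = as.character(contrast))
}

#' Construct a VOIMask
#'
#' @param mask 3D logical array.
#' @param spacing mm per axis.
#' @param role \code{"pathological"} or \code{"control"}.
#' @param style \code{"elliptical"} or \code{"manual"}.
#' @param label identifier string.
#' @return a \code{VOIMask}.
#' @export
voiMask <- function(mask, spacing, role = "pathological",
                    style = "elliptical", label = "voi") {
  new("VOIMask", mask = mask, spacing = as.numeric(spacing), role = role,
      style = style, label = label)
}
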