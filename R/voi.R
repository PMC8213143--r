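#' Rasterize a 3D elliptical VOI
#'
#' A voxel belongs to the VOI iff its center (world coordinate = 0-based
#' index times spacing) satisfies \eqn{\sum_k ((x_k - c_k)/a_k)^2 \le 1}.
#'
#' @param center ellipsoid center, mm (length 3).
#' @param semiAxes semi-axes, mm (length 3), all > 0.
#' @param gridShape voxels per axis.
#' @param spacing mm per axis.
#' @param role,label passed to the mask.
#' @return a [VOIMask-class] with \code{style = "elliptical"}.
#' @examples
#' v <- ellipsoidVOI(c(15, 15, 15), c(5, 5, 5), c(31, 31, 31), c(1, 1, 1))
#' voiVolume(v)  # close to 4/3 * pi * 125
#' @export
ellipsoidVOI <- function(center, semiAxes, gridShape, spacing,
                         role = "pathological", label = "voi") {
  stopifnot(all(semiAxes > 0), all(spacing > 0))
  extent <- (gridShape - 1) * spacing
  if (any(center - semiAxes < 0) || any(center + semiAxes > extent))
    stop("ellipsoid exceeds grid bounds")
  m <- ellipsoidArray(center, semiAxes, as.integer(gridShape), spacing)
  voiMask(m, spacing, role = role, style = "elliptical", label = label)
}

# Integer offsets whose physical displacement is within radiusMm.
ballOffsets <- function(radiusMm, spacing) {
  r <- floor(radiusMm / spacing)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  g[d2 <= radiusMm^2 + 1e-9, , drop = FALSE]
}

# Shift a logical array by integer offset, padding with FALSE.
shiftMask <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    from <- max(1L, 1L + o); to <- min(d[a], d[a] + o)
    if (from > to) return(out)
    dst[[a]] <- from:to
    src[[a]] <- (from - o):(to - o)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Manual-like VOI: lesion mask dilated by a physical margin
#'
#' Emulates hand-drawn delineation that includes boundary voxels with mixed
#' tissue: morphological dilation of the true lesion mask by a ball of radius
#' \code{marginMm} (in mm, so anisotropic voxels dilate anisotropically in
#' index space). Dilation is truncated at the grid with a warning.
#'
#' @param lesionMask a [VOIMask-class] (or 3D logical array with
#'   \code{spacing} supplied).
#' @param marginMm dilation radius in mm, >= 0; default 2 mm.
#' @param spacing required when \code{lesionMask} is a bare array.
#' @param role,label passed to the result.
#' @return a [VOIMask-class] with \code{style = "manual"}; always a superset
#'   of the input mask.
#' @export
manualLikeVOI <- function(lesionMask, marginMm = 2, spacing = NULL,
                          role = "pathological", label = "voi") {
  stopifnot(marginMm >= 0)
  if (is(lesionMask, "VOIMask")) {
    m <- voiMaskArray(lesionMask); spacing <- voxelSpacing(lesionMask)
    label <- lesionMask@label; role <- lesionMask@role
  } else m <- lesionMask
  if (is.null(spacing)) stop("spacing required for a bare array mask")
  out <- m
  if (marginMm > 0) {
    offs <- ballOffsets(marginMm, spacing)
    for (k in seq_len(nrow(offs))) {
      o <- as.integer(offs[k, ])
      if (all(o == 0L)) next
      out <- out | shiftMask(m, o)
    }
    # detect truncation: any mask voxel closer to the border than the margin
    ix <- arrayInd(which(m), dim(m))
    vr <- floor(marginMm / spacing)
    if (any(t(ix) - 1 < vr) || any(dim(m) - t(ix) < vr))
      warning("dilation truncated at grid boundary")
  }
  voiMask(out, spacing, role = role, style = "manual", label = label)
}

#' Mirror a VOI across the midsagittal plane
#'
#' Reflects the mask across the plane \code{x = midIndex} (voxel coordinate,
#' may be half-integer for even grids): voxel x maps to
#' \code{2 * midIndex - x}. Used to place the co-lateral control VOI at the
#' mirrored position on the opposite hemisphere. Voxel count (and hence
#' volume and all pairwise distances) is preserved.
#'
#' @param voi a [VOIMask-class].
#' @param midIndex midsagittal plane position in 0-based voxel coordinates;
#'   \code{2 * midIndex} must be an integer.
#' @param role role of the mirrored mask, default \code{"control"}.
#' @return the reflected [VOIMask-class].
#' @export
mirrorVOI <- function(voi, midIndex, role = "control") {
  m <- voiMaskArray(voi)
  d <- dim(m)
  if (abs(2 * midIndex - round(2 * midIndex)) > 1e-9)
    stop("2 * midIndex must be an integer for a lattice-preserving mirror")
  ix <- arrayInd(which(m), d)            # 1-based
  x0 <- ix[, 1] - 1L                     # 0-based
  xr <- round(2 * midIndex - x0)
  if (any(xr < 0) || any(xr >= d[1]))
    stop("mirrored VOI falls outside the grid")
  out <- array(FALSE, d)
  out[cbind(xr + 1L, ix[, 2], ix[, 3])] <- TRUE
  voiMask(out, voxelSpacing(voi), role = role, style = voiStyle(voi),
          label = paste0(voi@label, "_mirror"))
}

#' Keep only VOIs of at least a minimum volume
#'
#' The screening analyses use VOIs of at least 1 cm^3; smaller candidates are
#' dropped, order preserved.
#'
#' @param vois list of [VOIMask-class].
#' @param minCm3 minimum volume in cm^3 (default 1).
#' @return the retained sub-list.
#' @export
filterMinVolume <- function(vois, minCm3 = 1.0) {
  keep <- vapply(vois, function(v) voiVolume(v) >= minCm3 * 1000, logical(1))
  vois[keep]
}

#' Read / write Carimas-like per-voxel text exports
#'
#' Plain-text dialect: UTF-8, lines starting with \code{#} ignored, otherwise
#' four whitespace-separated fields \code{x y z intensity} with 0-based
#' non-negative integer voxel indices and a decimal intensity; LF line
#' endings on write.
#'
#' @param path file path.
#' @return \code{readVoxelList}: list with \code{coords} (n x 3 integer
#'   matrix, 0-based) and \code{intensities} (numeric). Zero data lines give
#'   empty results without error.
#' @export
readVoxelList <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  n <- length(lines)
  coords <- matrix(integer(0), 0, 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (n == 0) return(list(coords = coords, intensities = numeric(0)))
  fields <- strsplit(trimws(lines), "\\s+")
  lineNo <- which(keep)
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop("malformed voxel-list line ", lineNo[bad[1]],
         ": expected 4 fields 'x y z intensity'")
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  xyz <- suppressWarnings(matrix(as.numeric(m[, 1:3]), ncol = 3))
  val <- suppressWarnings(as.numeric(m[, 4]))
  badRow <- apply(xyz, 1, function(r)
    any(is.na(r)) || any(r != floor(r)) || any(r < 0))
  if (any(badRow))
    stop("non-integer or negative voxel index at line ",
         lineNo[which(badRow)[1]])
  if (anyNA(val))
    stop("non-numeric intensity at line ", lineNo[which(is.na(val))[1]])
  coords <- matrix(as.integer(xyz), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  list(coords = coords, intensities = val)
}

#' @rdname readVoxelList
#' @param coords n x 3 matrix of 0-based integer voxel indices.
#' @param intensities numeric vector of length n.
#' @param header optional comment lines written with a leading \code{#}.
#' @export
writeVoxelList <- function(path, coords, intensities, header = NULL) {
  stopifnot(nrow(coords) == length(intensities))
  con <- file(path, open = "wb")  # binary: force LF line endings
  on.exit(close(con))
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  if (nrow(coords))
    lines <- c(lines, sprintf("%d %d %d %s", coords[, 1], coords[, 2],
                              coords[, 3],
                              formatC(intensities, format = "g",
                                      digits = 17)))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Extract the in-mask voxel list of a volume
#'
#' @param volume an [ImageVolume-class].
#' @param voi a [VOIMask-class] on the same grid.
#' @return list with \code{coords} (0-based) and \code{intensities}.
#' @export
voiVoxelList <- function(volume, voi) {
  v <- voxelData(volume); m <- voiMaskArray(voi)
  if (!identical(dim(v), dim(m)))
    stop("volume grid ", paste(dim(v), collapse = "x"),
         " does not match mask grid ", paste(dim(m), collapse = "x"))
  ix <- arrayInd(which(m), dim(m))
  list(coords = ix - 1L, intensities = v[m])
}
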