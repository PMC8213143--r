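# Texture-matrix construction on the masked voxel lattice. Levels are held
# in a 3D array with NA outside the VOI; all three builders crop to the mask
# bounding box first.

#' The 13 unique 3D neighbor directions
#'
#' Half of the 26-neighborhood (one representative per +/- pair), used for
#' merged-direction GLCM and GLRLM construction.
#'
#' @return 13 x 3 integer matrix of offsets.
#' @export
directions13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

levelArray <- function(x) {
  if (is(x, "DiscretizedVOI")) {
    lev <- x@levels
    # AR levels (>= 0) are shifted +1 here so grey values start at 1; level
    # differences are preserved, only intensity-weighted features see the
    # shifted value, which keeps absolute-binning semantics comparable
    if (x@method == "AR") lev <- lev + 1L
    lev
  } else x
}

cropToMask <- function(lev) {
  inm <- !is.na(lev)
  if (!any(inm)) stop("empty VOI")
  ix <- arrayInd(which(inm), dim(lev))
  rng <- apply(ix, 2, range)
  lev[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
      drop = FALSE]
}

shiftNum <- function(a, off) {
  d <- dim(a)
  out <- array(NA_real_, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    from <- max(1L, 1L + o); to <- min(d[ax], d[ax] + o)
    if (from > to) return(out)
    dst[[ax]] <- from:to
    src[[ax]] <- (from - o):(to - o)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Build the merged-symmetric grey-level co-occurrence matrix
#'
#' Counts ordered pairs of in-mask voxels at the given Chebyshev distance
#' along the 13 unique 3D directions (both orderings, i.e. the symmetric
#' GLCM), merges all directions into one matrix and normalizes to
#' probabilities. Pairs with either voxel outside the mask are skipped.
#' Grey levels are indexed 1..Ng with Ng the maximum observed level.
#'
#' @param voi a [DiscretizedVOI-class] (or a 3D level array with \code{NA}
#'   outside the mask; AR levels must then be pre-shifted to start at 1).
#' @param distance neighbor distance in voxels (default 1).
#' @param directions optional n x 3 matrix of direction offsets (defaults to
#'   [directions13()]); single directions are useful for small worked
#'   examples.
#' @return a [GLCMatrix-class].
#' @export
buildGLCM <- function(voi, distance = 1, directions = NULL) {
  lev <- cropToMask(levelArray(voi))
  if (sum(!is.na(lev)) < 2L)
    stop("degenerate VOI: GLCM needs at least 2 voxels")
  if (is.null(directions)) directions <- directions13()
  ng <- max(lev, na.rm = TRUE)
  counts <- matrix(0, ng, ng)
  for (k in seq_len(nrow(directions))) {
    off <- as.integer(directions[k, ]) * as.integer(distance)
    nb <- shiftNum(lev, -off)       # nb[x] = lev[x + off]
    ok <- !is.na(lev) & !is.na(nb)
    if (!any(ok)) next
    a <- lev[ok]; b <- nb[ok]
    tab <- tabulate((a - 1L) * ng + b, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  counts <- counts + t(counts)      # both orderings of every pair
  n <- sum(counts)
  if (n == 0) stop("degenerate VOI: no neighbor pairs inside the mask")
  new("GLCMatrix", probabilities = counts / n, nPairs = n,
      distance = as.numeric(distance),
      nDirections = nrow(directions))
}

#' Build the merged grey-level run-length matrix
#'
#' Maximal runs of equal grey level along each of the 13 unique directions,
#' truncated at the mask boundary; run counts are summed over directions.
#'
#' @inheritParams buildGLCM
#' @return a [GLRLMatrix-class] with \code{counts[g, r]} = number of runs of
#'   level g and length r.
#' @export
buildGLRLM <- function(voi, directions = NULL) {
  lev <- cropToMask(levelArray(voi))
  inm <- !is.na(lev)
  nvox <- sum(inm)
  if (nvox < 1L) stop("empty VOI")
  if (is.null(directions)) directions <- directions13()
  ng <- max(lev, na.rm = TRUE)
  maxLen <- max(dim(lev))
  counts <- matrix(0, ng, maxLen)
  for (k in seq_len(nrow(directions))) {
    off <- as.integer(directions[k, ])
    nxt <- shiftNum(lev, -off)      # value at x + off
    same <- inm & !is.na(nxt) & lev == nxt
    # forward run length by fixed-point iteration: fwd(x) = 1 + fwd(x+off)
    # where the next voxel continues the run
    fwd <- array(NA_real_, dim(lev)); fwd[inm] <- 1
    repeat {
      fn <- shiftNum(fwd, -off)
      new <- fwd
      new[same] <- 1 + fn[same]
      if (identical(new, fwd)) break
      fwd <- new
    }
    prv <- shiftNum(lev, off)       # value at x - off
    samePrev <- inm & !is.na(prv) & lev == prv
    start <- inm & !samePrev
    g <- lev[start]; r <- fwd[start]
    tab <- tabulate((g - 1L) * maxLen + r, nbins = ng * maxLen)
    counts <- counts + matrix(tab, ng, maxLen, byrow = TRUE)
  }
  rmax <- max(which(colSums(counts) > 0))
  new("GLRLMatrix", counts = counts[, seq_len(rmax), drop = FALSE],
      nVoxels = as.integer(nvox), nDirections = nrow(directions))
}

#' Build the grey-level size-zone matrix
#'
#' Connected components of equal grey level within the mask under
#' 26-connectivity (which reduces to 8-connectivity for single-slice grids),
#' counted by (level, zone size). Component labelling runs on the voxel
#' adjacency graph via \pkg{igraph}.
#'
#' @inheritParams buildGLCM
#' @return a [GLSZMatrix-class] with \code{counts[g, s]} = number of zones of
#'   level g and size s.
#' @export
buildGLSZM <- function(voi, directions = NULL) {
  lev <- cropToMask(levelArray(voi))
  inm <- !is.na(lev)
  nvox <- sum(inm)
  if (nvox < 1L) stop("empty VOI")
  if (is.null(directions)) directions <- directions13()
  ng <- max(lev, na.rm = TRUE)
  d <- dim(lev)
  lin <- array(seq_len(prod(d)), d)
  edges <- list()
  for (k in seq_len(nrow(directions))) {
    off <- as.integer(directions[k, ])
    nxt <- shiftNum(lev, -off)
    nxtId <- shiftNum(lin, -off)
    ok <- inm & !is.na(nxt) & lev == nxt
    if (any(ok))
      edges[[length(edges) + 1L]] <- cbind(lin[ok], nxtId[ok])
  }
  em <- if (length(edges)) do.call(rbind, edges) else
    matrix(numeric(0), 0, 2)
  g <- igraph::make_undirected_graph(as.vector(t(em)), n = prod(d))
  memb <- igraph::components(g)$membership[lin[inm]]
  sizes <- tabulate(memb)
  firstOfZone <- !duplicated(memb)
  zl <- lev[inm][firstOfZone]
  zs <- sizes[memb[firstOfZone]]
  smax <- max(zs)
  tab <- tabulate((zl - 1L) * smax + zs, nbins = ng * smax)
  counts <- matrix(tab, ng, smax, byrow = TRUE)
  new("GLSZMatrix", counts = counts, nVoxels = as.integer(nvox),
      connectivity = 26L)
}
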