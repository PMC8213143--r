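# The 40 texture indices: 18 GLCM + 11 GLRLM + 11 GLSZM, IBSI-style
# definitions on the merged matrices. Entropies use log2 with 0*log(0) = 0.

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Texture indices from a grey-level co-occurrence matrix
#'
#' Evaluates the 18 co-occurrence features on the symmetric probability
#' matrix: joint maximum/average/variance/entropy, difference average
#' (dissimilarity), difference variance/entropy, sum
#' average/variance/entropy, angular second moment, contrast, correlation,
#' cluster tendency/shade/prominence, inverse difference and normalized
#' inverse difference.
#'
#' Degenerate single-level matrices get defined fallbacks instead of NaN:
#' entropies 0, \code{Correlation} 0 (zero marginal variance),
#' \code{NormInvDiff} 1.
#'
#' @param m a [GLCMatrix-class].
#' @return named numeric vector of length 18.
#' @export
glcmFeatures <- function(m) {
  p <- m@probabilities
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(i * p)
  sigma2 <- sum((seq_len(ng) - mu)^2 * px)
  # diagonal (difference) and cross-diagonal (sum) probabilities
  dIdx <- abs(i - j)
  pd <- vapply(0:(ng - 1), function(k) sum(p[dIdx == k]), numeric(1))
  kd <- 0:(ng - 1)
  sIdx <- i + j
  ps <- vapply(2:(2 * ng), function(k) sum(p[sIdx == k]), numeric(1))
  ks <- 2:(2 * ng)
  da <- sum(kd * pd)
  sa <- sum(ks * ps)
  corr <- if (sigma2 > 0) sum((i - mu) * (j - mu) * p) / sigma2 else 0
  c(JMax = max(p),
    JointAverage = mu,
    JVar = sum((i - mu)^2 * p),
    JEntropy = -sum(xlog2(p)),
    Dissim = da,
    DifferenceVariance = sum((kd - da)^2 * pd),
    DifferenceEntropy = -sum(xlog2(pd)),
    SumAverage = sa,
    SumVar = sum((ks - sa)^2 * ps),
    SumEntropy = -sum(xlog2(ps)),
    AngularSecondMoment = sum(p^2),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterProm = sum((i + j - 2 * mu)^4 * p),
    InverseDifference = sum(p / (1 + abs(i - j))),
    NormInvDiff = sum(p / (1 + abs(i - j) / ng)))
}

#' Texture indices from a grey-level run-length matrix
#'
#' The 11 run-length features. \code{RP} (run percentage) is the number of
#' runs divided by (number of directions x number of voxels), so it lies in
#' (0, 1] for the merged-direction matrix.
#'
#' @param m a [GLRLMatrix-class].
#' @return named numeric vector of length 11.
#' @export
glrlmFeatures <- function(m) {
  r <- m@counts
  ns <- sum(r)
  g <- seq_len(nrow(r))
  l <- seq_len(ncol(r))
  rg <- rowSums(r)   # per-level run counts
  rl <- colSums(r)   # per-length run counts
  c(SRE = sum(rl / l^2) / ns,
    LRE = sum(rl * l^2) / ns,
    LGRE = sum(rg / g^2) / ns,
    HGRE = sum(rg * g^2) / ns,
    SRLGE = sum(r / outer(g^2, l^2)) / ns,
    SRHGE = sum(r * outer(g^2, 1 / l^2)) / ns,
    LRLGE = sum(r * outer(1 / g^2, l^2)) / ns,
    LRHGE = sum(r * outer(g^2, l^2)) / ns,
    GLNU = sum(rg^2) / ns,
    RLNU = sum(rl^2) / ns,
    RP = ns / (m@nDirections * m@nVoxels))
}

#' Texture indices from a grey-level size-zone matrix
#'
#' The 11 size-zone features. \code{ZP} (zone percentage) is the number of
#' zones divided by the number of voxels.
#'
#' @param m a [GLSZMatrix-class].
#' @return named numeric vector of length 11.
#' @export
glszmFeatures <- function(m) {
  z <- m@counts
  nz <- sum(z)
  g <- seq_len(nrow(z))
  s <- seq_len(ncol(z))
  zg <- rowSums(z)
  zs <- colSums(z)
  c(SZE = sum(zs / s^2) / nz,
    LZE = sum(zs * s^2) / nz,
    LGZE = sum(zg / g^2) / nz,
    HGZE = sum(zg * g^2) / nz,
    SZLGE = sum(z / outer(g^2, s^2)) / nz,
    SZHGE = sum(z * outer(g^2, 1 / s^2)) / nz,
    LZLGE = sum(z * outer(1 / g^2, s^2)) / nz,
    LZHGE = sum(z * outer(g^2, s^2)) / nz,
    GLNUz = sum(zg^2) / nz,
    ZSNU = sum(zs^2) / nz,
    ZP = nz / m@nVoxels)
}

#' Extract all 40 texture indices from a discretized VOI
#'
#' Builds the GLCM (distance 1, 13 merged directions, symmetric), GLRLM and
#' GLSZM and evaluates all 40 features. Names are prefixed \code{glcm_},
#' \code{glrlm_}, \code{glszm_}; ordering is stable.
#'
#' @param voi a [DiscretizedVOI-class].
#' @param distance GLCM neighbor distance in voxels.
#' @return named numeric vector of length 40.
#' @examples
#' lev <- array(NA_real_, c(4, 4, 4))
#' lev[2:4, 2:4, 2:4] <- sample(1:3, 27, replace = TRUE)
#' f <- extractAll(discretizeLRR(lev * 10, D = 4))
#' length(f)  # 40
#' @export
extractAll <- function(voi, distance = 1) {
  fc <- glcmFeatures(buildGLCM(voi, distance = distance))
  fr <- glrlmFeatures(buildGLRLM(voi))
  fz <- glszmFeatures(buildGLSZM(voi))
  c(stats::setNames(fc, paste0("glcm_", names(fc))),
    stats::setNames(fr, paste0("glrlm_", names(fr))),
    stats::setNames(fz, paste0("glszm_", names(fz))))
}

#' Names of the 40 texture indices
#'
#' @return character vector of length 40 in the stable extraction order.
#' @export
featureNames <- function() {
  c(paste0("glcm_", c("JMax", "JointAverage", "JVar", "JEntropy", "Dissim",
                      "DifferenceVariance", "DifferenceEntropy",
                      "SumAverage", "SumVar", "SumEntropy",
                      "AngularSecondMoment", "Contrast", "Correlation",
                      "ClusterTendency", "ClusterShade", "ClusterProm",
                      "InverseDifference", "NormInvDiff")),
    paste0("glrlm_", c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE",
                       "LRLGE", "LRHGE", "GLNU", "RLNU", "RP")),
    paste0("glszm_", c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE",
                       "LZLGE", "LZHGE", "GLNUz", "ZSNU", "ZP")))
}
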