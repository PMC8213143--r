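# Independent brute-force oracles: plain-loop implementations of the texture
# matrices, the feature formulas and the rank-sum null enumeration. They
# share no code with the package internals.

oracleDirections <- function() {
  dirs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
      dirs[[length(dirs) + 1L]] <- c(dx, dy, dz)
  }
  dirs
}

inGrid <- function(p, d) all(p >= 1) && all(p <= d)

# symmetric merged GLCM probabilities, levels 1..max(lev)
oracleGLCM <- function(lev, distance = 1, dirs = oracleDirections()) {
  d <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  counts <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    for (dd in dirs) {
      q <- c(x, y, z) + dd * distance
      if (!inGrid(q, d)) next
      b <- lev[q[1], q[2], q[3]]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

# merged run-length counts, ng x maxlen
oracleGLRLM <- function(lev, dirs = oracleDirections()) {
  d <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  runs <- list()
  for (dd in dirs) {
    done <- array(FALSE, d)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      p <- c(x, y, z)
      a <- lev[x, y, z]
      if (is.na(a) || done[x, y, z]) next
      prev <- p - dd
      if (inGrid(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
          lev[prev[1], prev[2], prev[3]] == a)
        next  # not a run start
      len <- 0
      q <- p
      while (inGrid(q, d) && !is.na(lev[q[1], q[2], q[3]]) &&
             lev[q[1], q[2], q[3]] == a) {
        len <- len + 1
        done[q[1], q[2], q[3]] <- TRUE
        q <- q + dd
      }
      runs[[length(runs) + 1L]] <- c(a, len)
    }
    done[] <- FALSE
  }
  rmat <- do.call(rbind, runs)
  counts <- matrix(0, ng, max(rmat[, 2]))
  for (k in seq_len(nrow(rmat)))
    counts[rmat[k, 1], rmat[k, 2]] <- counts[rmat[k, 1], rmat[k, 2]] + 1
  counts
}

# size-zone counts by BFS flood fill over the 26-neighborhood
oracleGLSZM <- function(lev) {
  d <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  seen <- array(FALSE, d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || is.na(lev[x, y, z])) next
    a <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (!inGrid(q, d)) next
        if (seen[q[1], q[2], q[3]]) next
        b <- lev[q[1], q[2], q[3]]
        if (is.na(b) || b != a) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
    zones[[length(zones) + 1L]] <- c(a, size)
  }
  zmat <- do.call(rbind, zones)
  counts <- matrix(0, ng, max(zmat[, 2]))
  for (k in seq_len(nrow(zmat)))
    counts[zmat[k, 1], zmat[k, 2]] <- counts[zmat[k, 1], zmat[k, 2]] + 1
  counts
}

# naive double-loop feature formulas -------------------------------------

oracleGLCMFeatures <- function(p) {
  ng <- nrow(p)
  jmax <- 0; mu <- 0
  for (i in 1:ng) for (j in 1:ng) {
    jmax <- max(jmax, p[i, j]); mu <- mu + i * p[i, j]
  }
  jvar <- 0; jent <- 0; asm <- 0; contrast <- 0; id <- 0; nid <- 0
  ct <- 0; cs <- 0; cp <- 0; covar <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    jvar <- jvar + (i - mu)^2 * pij
    if (pij > 0) jent <- jent - pij * log2(pij)
    asm <- asm + pij^2
    contrast <- contrast + (i - j)^2 * pij
    id <- id + pij / (1 + abs(i - j))
    nid <- nid + pij / (1 + abs(i - j) / ng)
    ct <- ct + (i + j - 2 * mu)^2 * pij
    cs <- cs + (i + j - 2 * mu)^3 * pij
    cp <- cp + (i + j - 2 * mu)^4 * pij
    covar <- covar + (i - mu) * (j - mu) * pij
  }
  sigma2 <- 0
  for (i in 1:ng) sigma2 <- sigma2 + (i - mu)^2 * sum(p[i, ])
  corr <- if (sigma2 > 0) covar / sigma2 else 0
  pd <- numeric(ng); ps <- numeric(2 * ng)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j] <- ps[i + j] + p[i, j]
  }
  da <- 0; for (k in 1:ng) da <- da + (k - 1) * pd[k]
  dv <- 0; de <- 0
  for (k in 1:ng) {
    dv <- dv + ((k - 1) - da)^2 * pd[k]
    if (pd[k] > 0) de <- de - pd[k] * log2(pd[k])
  }
  sa <- 0; for (k in 2:(2 * ng)) sa <- sa + k * ps[k]
  sv <- 0; se <- 0
  for (k in 2:(2 * ng)) {
    sv <- sv + (k - sa)^2 * ps[k]
    if (ps[k] > 0) se <- se - ps[k] * log2(ps[k])
  }
  c(JMax = jmax, JointAverage = mu, JVar = jvar, JEntropy = jent,
    Dissim = da, DifferenceVariance = dv, DifferenceEntropy = de,
    SumAverage = sa, SumVar = sv, SumEntropy = se,
    AngularSecondMoment = asm, Contrast = contrast, Correlation = corr,
    ClusterTendency = ct, ClusterShade = cs, ClusterProm = cp,
    InverseDifference = id, NormInvDiff = nid)
}

oracleRLFeatures <- function(counts, nVoxels, nDirections) {
  ng <- nrow(counts); rmax <- ncol(counts)
  ns <- sum(counts)
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- lrlge <- lrhge <- 0
  for (g in 1:ng) for (r in 1:rmax) {
    n <- counts[g, r]
    sre <- sre + n / r^2;       lre <- lre + n * r^2
    lgre <- lgre + n / g^2;     hgre <- hgre + n * g^2
    srlge <- srlge + n / (g^2 * r^2); srhge <- srhge + n * g^2 / r^2
    lrlge <- lrlge + n * r^2 / g^2;   lrhge <- lrhge + n * g^2 * r^2
  }
  glnu <- 0; for (g in 1:ng) glnu <- glnu + sum(counts[g, ])^2
  rlnu <- 0; for (r in 1:rmax) rlnu <- rlnu + sum(counts[, r])^2
  c(SRE = sre / ns, LRE = lre / ns, LGRE = lgre / ns, HGRE = hgre / ns,
    SRLGE = srlge / ns, SRHGE = srhge / ns, LRLGE = lrlge / ns,
    LRHGE = lrhge / ns, GLNU = glnu / ns, RLNU = rlnu / ns,
    RP = ns / (nDirections * nVoxels))
}

oracleSZFeatures <- function(counts, nVoxels) {
  f <- oracleRLFeatures(counts, nVoxels, 1)
  names(f) <- c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE", "LZLGE",
                "LZHGE", "GLNUz", "ZSNU", "ZP")
  f["ZP"] <- sum(counts) / nVoxels
  f
}

# two-sided exact rank-sum p by full enumeration of group assignments
oracleRanksumExact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n1 + n2, n1)
  ws <- apply(combos, 2, function(ix) sum(r[ix]))
  pLe <- mean(ws <= wObs)
  pGe <- mean(ws >= wObs)
  min(1, 2 * min(pLe, pGe))
}

# random masked level array on a grid up to `side`^3
randomLevelArray <- function(side = 4, nLevels = 3, pMask = 0.8) {
  d <- c(side, side, side)
  lev <- array(sample(seq_len(nLevels), prod(d), replace = TRUE), d)
  msk <- array(stats::runif(prod(d)) < pMask, d)
  if (!any(msk)) msk[1] <- TRUE
  lev[!msk] <- NA
  storage.mode(lev) <- "double"
  lev
}

# wrap a bare level array in a DiscretizedVOI (levels >= 1 expected)
asDVOI <- function(lev, method = "LRR", param = max(lev, na.rm = TRUE)) {
  mritexture:::newDiscretizedVOI(lev, min(lev, na.rm = TRUE),
                                 max(lev, na.rm = TRUE), method, param,
                                 c(1, 1, 1))
}
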