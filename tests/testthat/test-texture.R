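# Texture matrices and features: worked examples, structural identities,
# and brute-force oracle agreement on small random grids.

mat2lev <- function(m) {
  a <- array(NA_real_, c(nrow(m), ncol(m), 1))
  a[, , 1] <- m
  a
}

test_that("GLCM matches the hand-counted 2x2 example", {
  lev <- mat2lev(matrix(c(1, 1, 1, 2), 2, byrow = TRUE))
  g <- buildGLCM(lev, directions = matrix(c(0, 1, 0), 1))
  expect_equal(g@probabilities,
               matrix(c(0.5, 0.25, 0.25, 0), 2, byrow = TRUE))
  f <- glcmFeatures(g)
  expect_equal(unname(f["JMax"]), 0.5)
  expect_equal(unname(f["Dissim"]), 0.5)
  expect_equal(unname(f["Contrast"]), 0.5)
})

test_that("constant VOI gives the degenerate point-mass GLCM features", {
  lev <- array(1, c(3, 3, 3))
  f <- glcmFeatures(buildGLCM(lev))
  expect_equal(unname(f["JMax"]), 1)
  expect_equal(unname(f["JEntropy"]), 0)
  expect_equal(unname(f["Dissim"]), 0)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["AngularSecondMoment"]), 1)
  expect_equal(unname(f["Correlation"]), 0)   # zero-variance fallback
  expect_equal(unname(f["NormInvDiff"]), 1)
  expect_error(buildGLCM(array(c(1, rep(NA, 7)), c(2, 2, 2))), "degenerate")
})

test_that("GLCM is symmetric, normalized, with empty unobserved rows kept", {
  set.seed(1)
  lev <- randomLevelArray(5, nLevels = 4)
  lev[!is.na(lev) & lev == 2] <- 4   # level 2 unobserved, level 4 present
  g <- buildGLCM(lev)
  p <- g@probabilities
  expect_equal(sum(p), 1)
  expect_equal(p, t(p))
  expect_equal(nrow(p), 4)           # Ng = max level, not #distinct
  expect_true(all(p[2, ] == 0))
  expect_equal(rowSums(p), colSums(p))
})

test_that("GLRLM matches hand run-length decompositions", {
  along <- matrix(c(1, 0, 0), 1)
  rl <- buildGLRLM(array(c(1, 1, 1, 2), c(4, 1, 1)), directions = along)
  expect_equal(rl@counts[1, 3], 1)
  expect_equal(rl@counts[2, 1], 1)
  expect_equal(sum(rl@counts), 2)
  expect_equal(unname(glrlmFeatures(rl)["RP"]), 2 / 4)

  cons <- buildGLRLM(array(2, c(6, 1, 1)), directions = along)
  expect_equal(unname(glrlmFeatures(cons)["RP"]), 1 / 6)

  alt <- buildGLRLM(array(c(1, 2, 1, 2), c(4, 1, 1)), directions = along)
  expect_equal(unname(glrlmFeatures(alt)["RP"]), 1)
})

test_that("GLSZM matches hand zone labelling", {
  lev <- mat2lev(matrix(c(1, 1, 2, 1), 2, byrow = TRUE))
  z <- buildGLSZM(lev)
  expect_equal(z@counts[1, 3], 1)
  expect_equal(z@counts[2, 1], 1)
  expect_equal(unname(glszmFeatures(z)["ZP"]), 2 / 4)
  zc <- buildGLSZM(array(3, c(2, 2, 2)))
  expect_equal(unname(glszmFeatures(zc)["ZP"]), 1 / 8)
})

test_that("partition identities hold on random grids", {
  set.seed(23)
  for (rep in 1:25) {
    lev <- randomLevelArray(sample(3:6, 1), nLevels = sample(2:5, 1))
    nvox <- sum(!is.na(lev))
    rl <- buildGLRLM(lev)
    # each voxel lies in exactly one run per direction
    expect_equal(sum(sweep(rl@counts, 2, seq_len(ncol(rl@counts)), "*")),
                 13 * nvox)
    z <- buildGLSZM(lev)
    expect_equal(sum(sweep(z@counts, 2, seq_len(ncol(z@counts)), "*")),
                 nvox)
  }
})

test_that("matrices and all 40 features agree with the brute-force oracle", {
  set.seed(99)
  nCases <- 40
  for (rep in seq_len(nCases)) {
    lev <- randomLevelArray(sample(3:4, 1), nLevels = sample(2:4, 1),
                            pMask = runif(1, 0.7, 1))
    g <- buildGLCM(lev)
    expect_equal(g@probabilities, oracleGLCM(lev), tolerance = 1e-12)
    expect_equal(glcmFeatures(g),
                 oracleGLCMFeatures(oracleGLCM(lev)), tolerance = 1e-12)
    rl <- buildGLRLM(lev)
    o <- oracleGLRLM(lev)
    expect_equal(unname(rl@counts), unname(o), tolerance = 0)
    expect_equal(glrlmFeatures(rl),
                 oracleRLFeatures(o, sum(!is.na(lev)), 13),
                 tolerance = 1e-12)
    z <- buildGLSZM(lev)
    oz <- oracleGLSZM(lev)
    expect_equal(unname(z@counts), unname(oz), tolerance = 0)
    expect_equal(glszmFeatures(z),
                 oracleSZFeatures(oz, sum(!is.na(lev))), tolerance = 1e-12)
  }
})

test_that("extractAll returns 40 stably named features", {
  set.seed(12)
  lev <- randomLevelArray(4, nLevels = 3)
  f <- extractAll(asDVOI(lev))
  expect_length(f, 40)
  expect_identical(names(f), featureNames())
  expect_equal(sum(startsWith(names(f), "glcm_")), 18)
  expect_equal(sum(startsWith(names(f), "glrlm_")), 11)
  expect_equal(sum(startsWith(names(f), "glszm_")), 11)
  expect_true(all(is.finite(f)))
})

test_that("features are invariant under lattice-preserving reorientation", {
  set.seed(31)
  lev <- randomLevelArray(4, nLevels = 3)
  f <- extractAll(asDVOI(lev))
  flipped <- lev[dim(lev)[1]:1, , , drop = FALSE]
  expect_equal(extractAll(asDVOI(flipped)), f, tolerance = 1e-12)
  flipped2 <- lev[, , dim(lev)[3]:1, drop = FALSE]
  expect_equal(extractAll(asDVOI(flipped2)), f, tolerance = 1e-12)
})

test_that("AR level arrays enter matrices shifted to start at 1", {
  x <- array(c(4.5, 9.1, 14.2, 19.9), c(4, 1, 1))
  dv <- discretizeAR(x, 5)            # levels 0,1,2,3
  expect_equal(greyLevels(dv), 0:3)
  g <- buildGLCM(dv, directions = matrix(c(1, 0, 0), 1))
  expect_equal(nrow(g@probabilities), 4)  # shifted grey values 1..4
})
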