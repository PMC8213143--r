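# Synthetic cohort generator: determinism, field statistics, geometry.

tinySpec <- function(seed = 5, sdLes = 10, sdBg = 10, blur = 0,
                     meanLes = 200, meanBg = 100) {
  subjectSpec("S1", "TU", list(c(6, 6, 6)),
              backgroundParams = textureParams(meanBg, sdBg, 0, blur),
              lesionParams = list(T1 = textureParams(meanLes, sdLes, 0,
                                                     blur)),
              seed = seed, lesionCenters = list(c(10, 16, 16)))
}

test_that("generation is a pure function of its inputs", {
  g1 <- generateSubjectVolume(tinySpec(), "T1", c(33, 33, 33), c(1, 1, 1))
  g2 <- generateSubjectVolume(tinySpec(), "T1", c(33, 33, 33), c(1, 1, 1))
  expect_identical(voxelData(g1$volume), voxelData(g2$volume))
  g3 <- generateSubjectVolume(tinySpec(seed = 6), "T1", c(33, 33, 33),
                              c(1, 1, 1))
  expect_false(identical(voxelData(g1$volume), voxelData(g3$volume)))
})

test_that("zero-variance fields give a piecewise-constant volume", {
  g <- generateSubjectVolume(tinySpec(sdLes = 0, sdBg = 0), "T1",
                             c(33, 33, 33), c(1, 1, 1))
  v <- voxelData(g$volume)
  m <- g$lesions[[1]]$mask
  expect_true(all(v[m] == 200))
  expect_true(all(v[!m] == 100))
})

test_that("lesion-interior mean matches the target within 3 SE", {
  g <- generateSubjectVolume(tinySpec(blur = 0), "T1", c(33, 33, 33),
                             c(1, 1, 1))
  v <- voxelData(g$volume)
  m <- g$lesions[[1]]$mask
  n <- sum(m)
  se <- 10 / sqrt(n)   # intensity sd 10; correlation length 0
  expect_lt(abs(mean(v[m]) - 200), 3 * se)
})

test_that("stationary fields converge to their target moments", {
  # empirical mean/sd over many independent fields converge to the targets;
  # per-field tolerance accounts for the reduced effective sample size of a
  # correlated field
  means <- sds <- numeric(12)
  for (s in seq_along(means)) {
    f <- mritexture:::correlatedField(c(24, 24, 24), c(1, 1, 1),
                                      textureParams(100, 10, 2),
                                      seed = 8800 + s)
    means[s] <- mean(f); sds[s] <- sd(f)
  }
  expect_lt(abs(mean(means) - 100), 3 * sd(means) / sqrt(length(means)))
  expect_lt(abs(mean(sds) - 10), 1)
  # white noise case is exact in distribution: tight tolerance on moments
  w <- mritexture:::correlatedField(c(24, 24, 24), c(1, 1, 1),
                                    textureParams(100, 10, 0), seed = 42)
  expect_lt(abs(mean(w) - 100), 3 * 10 / sqrt(24^3))
  expect_lt(abs(sd(w) - 10), 0.3)
  # correlated field is smoother than white noise at lag 1
  f <- mritexture:::correlatedField(c(24, 24, 24), c(1, 1, 1),
                                    textureParams(100, 10, 2), seed = 42)
  lag1 <- function(a) cor(as.vector(a[-1, , ]), as.vector(a[-24, , ]))
  expect_gt(lag1(f), 0.5)
  expect_lt(abs(lag1(w)), 0.1)
})

test_that("cohorts are reproducible and geometry is contrast-invariant", {
  des <- cohortDesign(1, 1, 1, gridShape = c(64, 64, 64), masterSeed = 21)
  c1 <- generateCohort(des)
  c2 <- generateCohort(des)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  expect_length(c1, 3)
  expect_setequal(vapply(c1, function(s) s$spec$diseaseGroup, ""),
                  c("IS", "MS", "TU"))
  for (subj in c1) {
    expect_named(subj$volumes, c("T1", "T2"))
    expect_false(identical(voxelData(subj$volumes$T1),
                           voxelData(subj$volumes$T2)))
  }
})

test_that("group sizes do not perturb other subjects' streams", {
  d1 <- cohortDesign(2, 1, 1, gridShape = c(64, 64, 64), masterSeed = 13)
  d2 <- cohortDesign(1, 1, 1, gridShape = c(64, 64, 64), masterSeed = 13)
  c1 <- generateCohort(d1)
  c2 <- generateCohort(d2)
  ids1 <- vapply(c1, function(s) s$spec$subjectId, "")
  ids2 <- vapply(c2, function(s) s$spec$subjectId, "")
  for (id in ids2) {
    s1 <- c1[[match(id, ids1)]]
    s2 <- c2[[match(id, ids2)]]
    expect_identical(voxelData(s1$volumes$T1), voxelData(s2$volumes$T1))
  }
})

test_that("all intensities stay strictly positive", {
  # background mean near zero forces the clamp to engage
  sp <- tinySpec(meanBg = 5, sdBg = 8, blur = 1)
  g <- generateSubjectVolume(sp, "T1", c(33, 33, 33), c(1, 1, 1))
  expect_true(all(voxelData(g$volume) >= 1))
  expect_error(generateSubjectVolume(tinySpec(), "T1", c(33, 33, 33),
                                     c(0, 1, 1)), "spacing")
})

test_that("misplaced lesions are rejected", {
  sp <- subjectSpec("S1", "TU", list(c(30, 30, 30)),
                    backgroundParams = textureParams(100, 10),
                    lesionParams = list(T1 = textureParams(150, 10)),
                    seed = 1)
  expect_error(generateSubjectVolume(sp, "T1", c(33, 33, 33), c(1, 1, 1)),
               "fit")
})

test_that("the default design describes the 71-subject three-group cohort", {
  des <- cohortDesign()
  expect_equal(des$nIS + des$nMS + des$nTU, 71L)
  expect_equal(c(des$nIS, des$nMS, des$nTU), c(22L, 22L, 27L))
  expect_identical(des$contrasts, c("T1", "T2"))
  expect_error(cohortDesign(nIS = 0), "nIS")
  expect_error(cohortDesign(spacing = c(1, 0, 1)), "spacing")
})

test_that("seed derivation is stable and stream-local", {
  expect_identical(deriveSeed(42, 1:5), deriveSeed(42, 1:5))
  expect_length(unique(deriveSeed(42, 1:100)), 100)
  expect_true(all(deriveSeed(7, 0:50) >= 0))
  expect_true(all(deriveSeed(7, 0:50) < 2^31))
  # withSeed restores the caller's RNG state
  set.seed(1); a <- runif(1)
  set.seed(1)
  mritexture:::withSeed(99, runif(10))
  expect_identical(runif(1), a)
})
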