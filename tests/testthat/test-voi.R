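# VOI construction: rasterization, dilation, mirroring, volume rule, and
# the plain-text voxel-list dialect.

test_that("ellipsoid rasterization approaches the analytic volume", {
  # brute-force recount of voxel centers inside the ball
  brute <- function(center, semi, shape, sp) {
    n <- 0
    for (x in 0:(shape[1] - 1)) for (y in 0:(shape[2] - 1))
      for (z in 0:(shape[3] - 1)) {
        q <- sum(((c(x, y, z) * sp - center) / semi)^2)
        if (q <= 1) n <- n + 1
      }
    n
  }
  v <- ellipsoidVOI(c(15, 15, 15), c(10, 10, 10), c(31, 31, 31), c(1, 1, 1))
  n1 <- sum(voiMaskArray(v))
  expect_equal(n1, brute(c(15, 15, 15), c(10, 10, 10), c(31, 31, 31),
                         c(1, 1, 1)))
  expect_lt(abs(n1 - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
  expect_identical(voiStyle(v), "elliptical")

  # sub-voxel ellipsoid centered on a voxel center: exactly 1 voxel
  tiny <- ellipsoidVOI(c(5, 5, 5), c(0.4, 0.4, 0.4), c(11, 11, 11),
                       c(1, 1, 1))
  expect_equal(sum(voiMaskArray(tiny)), 1)

  # doubling the spacing with fixed mm axes shrinks the count ~8x
  v2 <- ellipsoidVOI(c(16, 16, 16), c(10, 10, 10), c(17, 17, 17),
                     c(2, 2, 2))
  n2 <- sum(voiMaskArray(v2))
  expect_equal(n2, brute(c(16, 16, 16), c(10, 10, 10), c(17, 17, 17),
                         c(2, 2, 2)))
  expect_lt(abs(n1 / n2 - 8), 8 * 0.1)

  expect_error(ellipsoidVOI(c(2, 15, 15), c(10, 10, 10), c(31, 31, 31),
                            c(1, 1, 1)), "bounds")
})

test_that("ellipsoid membership is monotone in the semi-axes", {
  base <- ellipsoidVOI(c(10, 10, 10), c(4, 5, 6), c(21, 21, 21), c(1, 1, 1))
  for (k in 1:3) {
    semi <- c(4, 5, 6); semi[k] <- semi[k] + 2
    grown <- ellipsoidVOI(c(10, 10, 10), semi, c(21, 21, 21), c(1, 1, 1))
    expect_true(all(voiMaskArray(grown)[voiMaskArray(base)]))
  }
})

test_that("manual-like VOI dilates by a physical ball", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  d0 <- manualLikeVOI(m, 0, spacing = c(1, 1, 1))
  expect_identical(voiMaskArray(d0), m)
  d1 <- manualLikeVOI(m, 1, spacing = c(1, 1, 1))
  expect_equal(sum(voiMaskArray(d1)), 7)   # 6-neighborhood ball
  expect_identical(voiStyle(d1), "manual")
  # superset property on random masks
  set.seed(2)
  for (rep in 1:5) {
    m <- array(runif(9^3) < 0.1, c(9, 9, 9)); m[5, 5, 5] <- TRUE
    d <- suppressWarnings(manualLikeVOI(m, 1.5, spacing = c(1, 1, 1)))
    expect_true(all(voiMaskArray(d)[m]))
  }
  # anisotropic spacing: 1 mm margin cannot cross a 2 mm slice
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  da <- manualLikeVOI(m, 1, spacing = c(1, 1, 2))
  expect_equal(sum(voiMaskArray(da)), 5)
  expect_warning(manualLikeVOI(array(TRUE, c(3, 3, 3)), 2,
                               spacing = c(1, 1, 1)), "truncated")
})

test_that("mirroring reflects across the midsagittal plane", {
  m <- array(FALSE, c(64, 8, 8)); m[21, 4, 4] <- TRUE   # 0-based x = 20
  v <- voiMask(m, c(1, 1, 1))
  mv <- mirrorVOI(v, 32)
  expect_equal(unname(which(voiMaskArray(mv), arr.ind = TRUE)[1, "dim1"]),
               45L)
  expect_identical(voiRole(mv), "control")
  # involution, volume and pairwise-distance preservation on a random blob
  set.seed(4)
  blob <- array(FALSE, c(24, 24, 24))
  pts <- cbind(sample(3:11, 30, TRUE), sample(1:24, 30, TRUE),
               sample(1:24, 30, TRUE))
  blob[pts] <- TRUE
  bv <- voiMask(blob, c(1, 2, 1))
  mb <- mirrorVOI(bv, 11.5)
  expect_equal(voiVolume(mb), voiVolume(bv))
  back <- mirrorVOI(mb, 11.5, role = "pathological")
  expect_identical(voiMaskArray(back), blob)
  scale <- diag(c(1, 2, 1))
  dOrig <- sort(as.vector(dist(which(blob, arr.ind = TRUE) %*% scale)))
  dMirr <- sort(as.vector(dist(which(voiMaskArray(mb),
                                     arr.ind = TRUE) %*% scale)))
  expect_equal(dMirr, dOrig)
  expect_error(mirrorVOI(v, 5), "outside")
  expect_error(mirrorVOI(v, 10.25), "integer")
})

test_that("minimum-volume filter keeps exactly the >= 1 cm^3 VOIs", {
  mk <- function(n) {
    m <- array(FALSE, c(12, 12, 12)); m[sample.int(12^3, n)] <- TRUE
    voiMask(m, c(1, 1, 1))
  }
  set.seed(9)
  v999 <- mk(999); v1000 <- mk(1000)
  expect_length(filterMinVolume(list(v999)), 0)
  expect_length(filterMinVolume(list(v1000)), 1)
  expect_length(filterMinVolume(list()), 0)
  sizes <- c(10, 500, 999, 1000, 1200, 40)
  batch <- lapply(sizes, mk)
  kept <- filterMinVolume(batch)
  expect_length(kept, sum(sizes * 1 >= 1000))
  # anisotropic voxels count physically
  m <- array(FALSE, c(10, 10, 10)); m[1:5, 1:10, 1:10] <- TRUE  # 500 voxels
  expect_length(filterMinVolume(list(voiMask(m, c(1, 1, 2)))), 1)
})

test_that("voxel-list dialect round-trips exactly", {
  tmp <- tempfile(fileext = ".txt")
  coords <- matrix(as.integer(c(0, 0, 0, 3, 1, 2, 10, 0, 7)), ncol = 3,
                   byrow = TRUE)
  vals <- c(1.5, 100.25, 3.141592653589793)
  writeVoxelList(tmp, coords, vals, header = "three voxels")
  rt <- readVoxelList(tmp)
  expect_equal(unname(rt$coords), unname(coords))
  expect_identical(rt$intensities, vals)
  # LF endings, comment line present
  raw <- readBin(tmp, "raw", file.size(tmp))
  expect_false(any(raw == charToRaw("\r")))

  writeLines(c("# only", "# comments"), tmp)
  empty <- readVoxelList(tmp)
  expect_equal(nrow(empty$coords), 0)
  expect_length(empty$intensities, 0)

  writeLines(c("1 2 3 4.5", "1 2 oops"), tmp)
  expect_error(readVoxelList(tmp), "line 2")
  writeLines(c("# c", "1 2 3 abc"), tmp)
  expect_error(readVoxelList(tmp), "intensity at line 2")
  writeLines("1 -2 3 4.5", tmp)
  expect_error(readVoxelList(tmp), "negative")
})
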