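test_that("static binning sums clipped square windows", {
  ta <- TimeAxis(16, 48.8, 12.5)
  set.seed(2)
  a <- array(rpois(5 * 5 * 16, 8), c(5, 5, 16))
  cube <- TCSPCCube(a, ta)
  # f = 0 is the identity
  expect_identical(counts(staticBin(cube, 0)), a)
  # uniform cube, 100 photons/pixel, f = 1, interior pixel: 900 photons
  u <- TCSPCCube(array(rep(100 / 16, 5 * 5 * 16), c(5, 5, 16)), ta)
  expect_equal(sum(counts(staticBin(u, 1))[3, 3, ]), 900)
  # f = 2 at the center sums all 25 pixels
  b2 <- staticBin(cube, 2)
  expect_equal(b2@counts[3, 3, ], apply(a, 3, sum))
  expect_error(staticBin(cube, -1), "f must be")
})

test_that("static binning matches the brute-force oracle with borders", {
  ta <- TimeAxis(8, 48.8, 12.5)
  set.seed(3)
  a <- array(rpois(16 * 16 * 8, 5), c(16, 16, 8))
  cube <- TCSPCCube(a, ta)
  for (f in 1:2)
    expect_equal(counts(staticBin(cube, f)), bruteStaticBin(a, f))
  # photon totals per pixel are non-decreasing in f
  t0 <- apply(a, c(1, 2), sum)
  t1 <- apply(counts(staticBin(cube, 1)), c(1, 2), sum)
  t2 <- apply(counts(staticBin(cube, 2)), c(1, 2), sum)
  expect_true(all(t1 >= t0) && all(t2 >= t1))
})

test_that("adaptive binning grows lattice disks shell by shell", {
  ta <- TimeAxis(8, 48.8, 12.5)
  perChan <- 100 / 8
  u <- TCSPCCube(array(rep(perChan, 9 * 9 * 8), c(9, 9, 8)), ta)
  # threshold met by the pixel itself: identity, r = 0
  ab0 <- adaptiveBin(u, 100)
  expect_equal(ab0$radius, matrix(0, 9, 9))
  expect_equal(counts(ab0$cube), counts(u))
  # threshold 500: 5-pixel disk at r = 1
  ab1 <- adaptiveBin(u, 500)
  expect_equal(ab1$radius[5, 5], 1)
  expect_equal(sum(counts(ab1$cube)[5, 5, ]), 500)
  # threshold 1000: the r = sqrt(2) disk has only 9 pixels (900), so the
  # 13-pixel disk at r = 2 is needed (1300 photons)
  ab2 <- adaptiveBin(u, 1000)
  expect_equal(ab2$radius[5, 5], 2)
  expect_equal(sum(counts(ab2$cube)[5, 5, ]), 1300)
})

test_that("adaptive binning matches the brute-force disk oracle exactly", {
  ta <- TimeAxis(8, 48.8, 12.5)
  set.seed(4)
  a <- array(rpois(16 * 16 * 8, 5), c(16, 16, 8))
  cube <- TCSPCCube(a, ta)
  ab <- adaptiveBin(cube, threshold = 600, maxRadius = 16)
  tot <- apply(counts(ab$cube), c(1, 2), sum)
  expect_true(all(tot >= 600 | ab$capped))
  expect_false(any(ab$capped))
  for (px in list(c(1, 1), c(1, 16), c(8, 8), c(16, 5), c(3, 12))) {
    expect_equal(counts(ab$cube)[px[1], px[2], ],
                 bruteDiskSum(a, px[1], px[2], ab$radius[px[1], px[2]]))
    # the next-smaller shell radius must not reach the threshold
    r <- ab$radius[px[1], px[2]]
    if (r > 0) {
      smaller <- sqrt(max(0, r^2 - 1))
      expect_lt(sum(bruteDiskSum(a, px[1], px[2], smaller)), 600)
    }
  }
})

test_that("unreachable thresholds hit the radius cap and are flagged", {
  ta <- TimeAxis(8, 48.8, 12.5)
  cube <- TCSPCCube(array(1, c(4, 4, 8)), ta)   # 128 photons in total
  expect_warning(ab <- adaptiveBin(cube, 1e6, maxRadius = 8), "threshold")
  expect_true(all(ab$capped))
  expect_true(all(ab$radius == max(ab$radius)))
})

test_that("adaptive radius is monotone in neighborhood intensity", {
  ta <- TimeAxis(8, 48.8, 12.5)
  set.seed(5)
  a <- array(rpois(9 * 9 * 8, 10), c(9, 9, 8))
  bright <- TCSPCCube(a, ta)
  dim3 <- a
  dim3[1:9, 1:4, ] <- 0                     # darken part of the neighborhood
  dark <- TCSPCCube(dim3, ta)
  rB <- adaptiveBin(bright, 300, maxRadius = 12)$radius
  rD <- adaptiveBin(dark, 300, maxRadius = 12)$radius
  expect_true(all(rD >= rB))
})

test_that("disk membership is invariant under 90-degree rotation", {
  ta <- TimeAxis(4, 48.8, 12.5)
  set.seed(6)
  a <- array(rpois(9 * 9 * 4, 6), c(9, 9, 4))
  rot <- function(m) t(m[nrow(m):1, ])            # rotate 90 degrees
  arot <- array(0, dim(a))
  for (k in 1:4) arot[, , k] <- rot(a[, , k])
  r1 <- adaptiveBin(TCSPCCube(a, ta), 200)$radius
  r2 <- adaptiveBin(TCSPCCube(arot, ta), 200)$radius
  expect_equal(rot(r1), r2)
})

test_that("sumAllPixels conserves photons", {
  ta <- TimeAxis(8, 48.8, 12.5)
  h <- c(1, 5, 9, 4, 2, 1, 0, 0)
  a <- array(rep(h, each = 4), c(2, 2, 8))
  cube <- TCSPCCube(a, ta)
  expect_equal(sumAllPixels(cube), 4 * h)
  set.seed(7)
  a2 <- array(rpois(3 * 4 * 8, 3), c(3, 4, 8))
  expect_equal(sum(sumAllPixels(TCSPCCube(a2, ta))), sum(a2))
  one <- TCSPCCube(array(h, c(1, 1, 8)), ta)
  expect_equal(sumAllPixels(one), h)
})
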