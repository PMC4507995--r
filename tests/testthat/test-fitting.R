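test_that("Neyman and Pearson weights follow their definitions", {
  expect_equal(computeWeights(c(4, 9, 0)), c(4, 9, 1))
  expect_equal(computeWeights(c(4, 9, 0), "pearson", model = c(2, 8, 0.5)),
               c(2, 8, 0.5))
  # Neyman weights depend only on the measurement
  expect_identical(computeWeights(c(4, 9, 0)), computeWeights(c(4, 9, 0)))
  expect_error(computeWeights(c(1, 2), "pearson"), "model")
})

test_that("reduced chi-square evaluates Eq-level hand examples", {
  expect_equal(reducedChi2(c(5, 5), c(5, 5), c(5, 5), p = 1), 0)
  expect_equal(reducedChi2(c(10, 10), c(8, 12),
                           computeWeights(c(10, 10)), p = 1), 0.8)
  m <- c(10, 10, 100); mod <- c(8, 12, 10)
  w <- computeWeights(m)
  full <- reducedChi2(m, mod, w, p = 1)
  masked <- reducedChi2(m, mod, w, p = 1, mask = c(TRUE, TRUE, FALSE))
  expect_lt(masked, full)
  expect_error(reducedChi2(c(1, 2), c(1, 2), c(1, 1), p = 2), "degenerate")
})

test_that("neighborhood figure of merit squares only the central term", {
  expect_equal(neighborhoodChi2(0, c(2, 4)), 3)
  expect_equal(neighborhoodChi2(1, c(1, 1, 1, 1)), 2)
  expect_equal(neighborhoodChi2(2, 0), 4)
  expect_error(neighborhoodChi2(1, numeric(0)), "adjacent")
})

test_that("variable projection recovers linear parameters exactly", {
  ta <- shortAxis(128)
  tms <- channelCenters(ta)
  b1 <- exp(-tms / 500); b2 <- exp(-tms / 2500)
  w <- rep(1, 128)
  s <- solveAmplitudes(cbind(b1, b2), 2 * b1 + 3 * b2, w)
  expect_equal(unname(s$coef), c(2, 3), tolerance = 1e-9)
  expect_equal(s$b, 0, tolerance = 1e-9)
  # with a true background
  s2 <- solveAmplitudes(cbind(b1, b2), 2 * b1 + 3 * b2 + 4, w)
  expect_equal(unname(c(s2$coef, s2$b)), c(2, 3, 4), tolerance = 1e-7)
  # non-negativity clamps a negative direction at zero
  s3 <- solveAmplitudes(cbind(b1), -b1, w, background = FALSE)
  expect_equal(unname(s3$coef), 0)
  expect_error(solveAmplitudes(cbind(numeric(128)), b1, w), "all-zero")
})

test_that("no non-negative linear combination beats the projected solution", {
  ta <- shortAxis(64)
  tms <- channelCenters(ta)
  b1 <- exp(-tms / 400); b2 <- exp(-tms / 3000)
  set.seed(8)
  y <- 1.5 * b1 + 0.7 * b2 + rnorm(64, 0, 0.05)
  w <- rep(1, 64) + runif(64)
  s <- solveAmplitudes(cbind(b1, b2), y, w, background = FALSE)
  rss <- function(a1, a2) sum((y - a1 * b1 - a2 * b2)^2 / w)
  best <- min(outer(seq(0, 3, by = 0.02), seq(0, 3, by = 0.02),
                    Vectorize(rss)))
  expect_lte(rss(s$coef[1], s$coef[2]), best + 1e-9)
})

test_that("a noiseless single-exponential pixel is recovered to 0.1%", {
  ta <- shortAxis()
  irf <- deltaIRF(ta)
  hist1 <- 1000 * exp(-channelCenters(ta) / 2000)
  cfg <- fitConfig(artifactRemoval = FALSE, outlierIterations = 0L)
  r <- minimizePixel(hist1, modelSpec("multiexp"), cfg,
                     paramVector(tau = 1000), irf, ta)
  expect_equal(r$params@tau, 2000, tolerance = 1e-3)
  expect_lt(r$chi2r, 1e-8)
  expect_true(r$converged)
  # parameters respect their declared bounds
  cfg2 <- fitConfig(constraints = list(tau1 = c(100, 1500)))
  r2 <- minimizePixel(hist1, modelSpec("multiexp"), cfg2,
                      paramVector(tau = 1000), irf, ta)
  expect_gte(r2$params@tau, 100)
  expect_lte(r2$params@tau, 1500)
})

test_that("the stochastic stage is reproducible and respects bounds", {
  ta <- shortAxis(128)
  irf <- gaussIRF(ta)
  spec <- modelSpec("multiexp", 2)
  p <- paramVector(alpha = c(0.6, 0.4), tau = c(500, 2500))
  gt <- uniformGroundTruth(c(4, 4), p, 62500, spec, irf, ta, seed = 11L)
  total <- sumAllPixels(simulateCube(gt))      # ~1e6 photons
  cfg <- fitConfig(dePopulation = 15L, deGenerations = 40L, seed = 21L)
  i1 <- globalInit(total, spec, cfg, irf, ta)
  i2 <- globalInit(total, spec, cfg, irf, ta)
  expect_identical(i1@tau, i2@tau)
  taus <- sort(i1@tau)
  expect_equal(taus[1], 500, tolerance = 0.1)
  expect_equal(taus[2], 2500, tolerance = 0.1)
  layout_hi <- 0.6 * nChannels(ta) * channelWidth(ta)
  expect_true(all(i1@tau >= 5 & i1@tau <= layout_hi))
})

test_that("reflection artifacts are detected by the 3x rise rule", {
  # strictly monotone decay: nothing detected
  clean <- round(4000 * exp(-(1:512) / 150))
  expect_equal(nrow(detectReflectionArtifacts(clean)), 0)
  # bump rising at channel 100, peaking at 110: interval [100, 130)
  iv <- detectReflectionArtifacts(bumpDecay(riseStart = 100, riseLen = 10))
  expect_equal(nrow(iv), 1)
  expect_equal(unname(iv[1, ]), c(100L, 130L))
  # two disjoint bumps: two sorted, non-overlapping intervals
  y <- bumpDecay(riseStart = 100, riseLen = 10) +
    bumpDecay(riseStart = 300, riseLen = 6) -
    round(5000 * exp(-((1:512) - 10) / 120))
  y <- pmax(y, 0)
  iv2 <- detectReflectionArtifacts(y + round(5000 * exp(-((1:512) - 10) / 120)))
  expect_equal(nrow(iv2), 2)
  expect_true(iv2[1, 2] <= iv2[2, 1])
  expect_true(all(diff(iv2[, 1]) > 0))
})

test_that("fitting a small simulated image recovers truth deterministically", {
  ta <- shortAxis(128)
  irf <- gaussIRF(ta, center = 500)
  spec <- modelSpec("multiexp", 1)
  p <- paramVector(alpha = 1, tau = 1500, b = 0.2)
  gt <- uniformGroundTruth(c(6, 6), p, 4000, spec, irf, ta, seed = 13L)
  cube <- simulateCube(gt)
  cfg <- fitConfig(dePopulation = 10L, deGenerations = 25L,
                   outlierIterations = 0L, seed = 31L)
  res <- fitImage(cube, spec, cfg, irf)
  tau1 <- resultMap(res, "tau1")
  expect_lt(abs(median(tau1) - 1500) / 1500, 0.10)
  # mean-lifetime map is the amplitude-weighted mean, pixel-wise
  tm <- resultMap(res, "tauM")
  expect_equal(tm, tau1)                     # single component: tauM = tau1
  # re-running with the same seed reproduces the maps exactly
  res2 <- fitImage(cube, spec, cfg, irf)
  expect_identical(resultMap(res2, "tau1"), tau1)
  expect_identical(res2@chi2, res@chi2)
})

test_that("tauM from a two-component fit respects the weighted-mean bounds", {
  maps <- list(alpha1 = matrix(3, 2, 2), tau1 = matrix(100, 2, 2),
               alpha2 = matrix(1, 2, 2), tau2 = matrix(500, 2, 2))
  tm <- ocufit:::.tauMFromMaps(maps, 2)
  expect_equal(tm, matrix(200, 2, 2))
})

test_that("outlier treatment flags by window-median rule and only improves", {
  ta <- shortAxis(128)
  irf <- gaussIRF(ta, center = 500)
  spec <- modelSpec("multiexp", 1)
  p <- paramVector(alpha = 1, tau = 1500, b = 0.2)
  gt <- uniformGroundTruth(c(5, 5), p, 4000, spec, irf, ta, seed = 17L)
  cube <- simulateCube(gt)
  cfg <- fitConfig(dePopulation = 10L, deGenerations = 25L,
                   outlierWindow = 5L, outlierIterations = 1L, seed = 33L)
  # constant maps: nothing flagged
  maps <- list(alpha1 = matrix(1, 5, 5), tau1 = matrix(1500, 5, 5),
               b = matrix(0.2, 5, 5))
  res <- FitResultMaps(maps, chi2 = matrix(1, 5, 5))
  out <- treatOutliers(res, cube, spec, cfg, irf)
  expect_equal(out$nDetected, 0)
  expect_equal(out$nImproved, 0)
  # a pixel at 1.4x the constant level exceeds the 30% threshold ...
  maps2 <- maps; maps2$tau1[3, 3] <- 1.4 * 1500
  chi2 <- matrix(1, 5, 5); chi2[3, 3] <- 50
  res2 <- FitResultMaps(maps2, chi2 = chi2)
  out2 <- treatOutliers(res2, cube, spec, cfg, irf)
  expect_gte(out2$nDetected, 1)
  # accepted refits never worsen the figure of merit
  expect_true(all(out2$results@chi2 <= chi2))
  # ... while 1.2x stays under it
  maps3 <- maps; maps3$tau1[3, 3] <- 1.2 * 1500
  res3 <- FitResultMaps(maps3, chi2 = matrix(1, 5, 5))
  out3 <- treatOutliers(res3, cube, spec, cfg, irf)
  expect_equal(out3$nDetected, 0)
})
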