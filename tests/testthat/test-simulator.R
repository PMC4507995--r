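test_that("expected curves conserve the requested photon number", {
  ta <- shortAxis()
  irf <- deltaIRF(ta)
  spec <- modelSpec("multiexp")
  gt <- uniformGroundTruth(c(2, 2), paramVector(alpha = 1, tau = 1500),
                           photons = 1000, spec, irf, ta)
  cur <- expectedCurve(gt, 1, 1)
  expect_true(all(cur >= 0))
  expect_equal(sum(cur), 1000, tolerance = 0.5 / 1000)
  expect_equal(cur / cur[1], exp(-(channelCenters(ta) - channelCenters(ta)[1]) / 1500),
               tolerance = 1e-10)
  # background is an additive per-channel rate on top of the decay photons
  gtb <- uniformGroundTruth(c(1, 1), paramVector(alpha = 1, tau = 1500,
                                                 b = 0.5),
                            photons = 1000, spec, irf, ta)
  expect_equal(sum(expectedCurve(gtb, 1, 1)), 1000 + 0.5 * nChannels(ta),
               tolerance = 1e-6)
})

test_that("two components with equal integrated photons contribute N/2 each", {
  ta <- shortAxis()
  irf <- deltaIRF(ta)
  spec <- modelSpec("multiexp", 2)
  # weight the amplitudes by the inverse integral of each component
  b <- modelBasis(spec, paramVector(alpha = c(1, 1), tau = c(500, 2500)),
                  irf, ta)
  al <- 1 / colSums(b)
  gt <- uniformGroundTruth(c(1, 1), paramVector(alpha = al,
                                                tau = c(500, 2500)),
                           photons = 1000, spec, irf, ta)
  part1 <- al[1] * b[, 1] * 1000 / sum(al[1] * b[, 1] + al[2] * b[, 2])
  expect_equal(sum(part1), 500, tolerance = 1e-9)
  expect_equal(sum(expectedCurve(gt, 1, 1)), 1000, tolerance = 1e-6)
})

test_that("rep-period folding raises the pre-excitation expectation", {
  ta <- shortAxis()
  irf <- gaussIRF(ta, center = 2000)
  p <- paramVector(alpha = 1, tau = 2000)
  g0 <- uniformGroundTruth(c(1, 1), p, 1000, modelSpec("multiexp"), irf, ta)
  g1 <- uniformGroundTruth(c(1, 1), p, 1000,
                           modelSpec("multiexp", incompleteDecay = 1),
                           irf, ta)
  expect_gt(expectedCurve(g1, 1, 1)[1], expectedCurve(g0, 1, 1)[1] * 1.5)
})

test_that("Poisson sampling is seeded, reproducible and unbiased", {
  expect_identical(sampleHistogram(numeric(32), seed = 1),
                   rep(0L, 32))
  h1 <- sampleHistogram(rep(50, 64), seed = 9)
  h2 <- sampleHistogram(rep(50, 64), seed = 9)
  expect_identical(h1, h2)
  draws <- sampleHistogram(rep(50, 10000), seed = 3)
  expect_gt(mean(draws), 49)
  expect_lt(mean(draws), 51)
})

test_that("simulated cubes match their ground truth statistically", {
  ta <- shortAxis(128)
  irf <- deltaIRF(ta)
  spec <- modelSpec("multiexp")
  gt <- uniformGroundTruth(c(8, 8), paramVector(alpha = 1, tau = 1500),
                           photons = 1000, spec, irf, ta, seed = 5L)
  cube <- simulateCube(gt)
  tot <- sum(counts(cube))
  expect_lt(abs(tot - 64000), 3 * sqrt(64000))
  # same seed, same cube
  expect_identical(counts(simulateCube(gt)), counts(cube))
  # zero photons yields an all-zero cube
  gt0 <- uniformGroundTruth(c(4, 4), paramVector(alpha = 1, tau = 1500),
                            photons = 0, spec, irf, ta)
  expect_true(all(counts(simulateCube(gt0)) == 0))
})

test_that("a lens term adds early-time counts to the expectation", {
  ta <- shortAxis()
  irf <- gaussIRF(ta, center = 1500)
  lens <- LensDecay(shiftCurve(exp(-channelCenters(ta) / 400), 1000, ta), ta)
  spec0 <- modelSpec("multiexp", 2)
  specL <- modelSpec("lens_corrected", 2, lens = lens)
  p0 <- paramVector(alpha = c(1, .5), tau = c(500, 2500), alphaLens = 0)
  pL <- methods::initialize(p0, alphaLens = 0.5)
  mk <- function(spec, p) uniformGroundTruth(c(1, 1), p, 1000, spec, irf, ta)
  e0 <- expectedCurve(mk(spec0, p0), 1, 1)
  eL <- expectedCurve(mk(specL, pL), 1, 1)
  rising <- seq_len(which.max(e0))
  # with the total normalized, the lens shoulder redistributes photons
  # toward the rising edge
  expect_gt(sum(eL[rising]), sum(e0[rising]))
})

test_that("group studies are deterministic and carry the designed effect", {
  s1 <- simulateGroupStudy(5, effect = 200, nPixels = 400, seed = 3L)
  s2 <- simulateGroupStudy(5, effect = 200, nPixels = 400, seed = 3L)
  expect_identical(subjects(s1), subjects(s2))
  g <- groupLabels(s1)
  meanTau <- vapply(subjects(s1),
                    function(s) mean(s$maps$tau1[s$roi]), 0)
  expect_gt(mean(meanTau[g == "B"]), mean(meanTau[g == "A"]))
  # no effect: group means within the between-subject noise
  s0 <- simulateGroupStudy(10, effect = 0, nPixels = 400, seed = 4L)
  m0 <- vapply(subjects(s0), function(s) mean(s$maps$tau1[s$roi]), 0)
  g0 <- groupLabels(s0)
  expect_lt(abs(mean(m0[g0 == "B"]) - mean(m0[g0 == "A"])), 50)
})
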