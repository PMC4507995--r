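test_that("lens-retina time shift follows tc = 2 d n / c", {
  expect_equal(lensTimeShift(22.2, 1.3668), 202.3, tolerance = 0.1 / 202.3)
  expect_equal(lensTimeShift(0, 1.3668), 0)
  expect_equal(lensTimeShift(44.4, 1.3668), 2 * lensTimeShift(22.2, 1.3668))
  expect_error(lensTimeShift(-1, 1.3668), "non-negative")
})

test_that("repetition period is the reciprocal of the repetition rate", {
  expect_identical(repetitionPeriod(80e6), 12.5)
  expect_equal(repetitionPeriod(40e6), 25)
})

test_that("shiftCurve delays by interpolation with zero- or wrap-fill", {
  ta <- TimeAxis(8, 10, 12.5)
  d <- c(0, 0, 1, 0, 0, 0, 0, 0)
  expect_identical(shiftCurve(d, 0, ta), d)
  expect_equal(shiftCurve(d, 10, ta), c(0, 0, 0, 1, 0, 0, 0, 0))
  expect_equal(shiftCurve(d, 5, ta), c(0, 0, 0.5, 0.5, 0, 0, 0, 0))
  # zero-fill from before t = 0 vs wrap-around
  expect_equal(shiftCurve(c(1, rep(0, 7)), 10, ta)[1], 0)
  expect_equal(shiftCurve(c(0, rep(0, 6), 1), 10, ta, wrap = TRUE)[1], 1)
})

test_that("the convolved model reproduces closed forms under a delta IRF", {
  ta <- shortAxis()
  irf <- deltaIRF(ta)
  tms <- channelCenters(ta)
  p <- paramVector(alpha = 2, tau = 2000)
  cur <- evaluateModel(modelSpec("multiexp"), p, irf, ta)
  expect_equal(cur, 2 * exp(-tms / 2000), tolerance = 1e-12)
  # value at t = tau ln 2 is alpha / 2 (interpolated between channels)
  at <- approx(tms, cur, xout = 2000 * log(2))$y
  expect_equal(at, 1, tolerance = 1e-3)
  # monotone decay after the peak
  expect_true(all(diff(cur) < 0))
})

test_that("stretched model with beta = 1 equals the multi-exponential", {
  ta <- shortAxis()
  irf <- gaussIRF(ta)
  p <- paramVector(alpha = c(1, 0.5), tau = c(500, 2500), beta = 1, b = 2)
  a <- evaluateModel(modelSpec("multiexp", 2), p, irf, ta)
  b <- evaluateModel(modelSpec("stretched", 2), p, irf, ta)
  expect_lt(max(abs(a - b)), 1e-12)
})

test_that("the lens-corrected model degenerates to the multi-exponential", {
  ta <- shortAxis()
  irf <- gaussIRF(ta)
  lens <- LensDecay(exp(-channelCenters(ta) / 800), ta)
  p <- paramVector(alpha = c(1, 0.5), tau = c(500, 2500), beta = 1,
                   alphaLens = 0, tcLens = 100, b = 1)
  a <- evaluateModel(modelSpec("multiexp", 2), p, irf, ta)
  b <- evaluateModel(modelSpec("lens_corrected", 2, lens = lens), p, irf, ta)
  expect_lt(max(abs(a - b)), 1e-12)
  # a positive lens amplitude adds signal
  p2 <- methods::initialize(p, alphaLens = 0.3)
  c2 <- evaluateModel(modelSpec("lens_corrected", 2, lens = lens), p2, irf, ta)
  expect_true(all(c2 >= b))
  expect_gt(sum(c2 - b), 0)
})

test_that("the model is linear in each amplitude and the background", {
  ta <- shortAxis(128)
  irf <- gaussIRF(ta)
  spec <- modelSpec("multiexp", 2)
  base <- paramVector(alpha = c(1, 1), tau = c(500, 2500), b = 1)
  f <- function(a1, a2, b)
    evaluateModel(spec, paramVector(alpha = c(a1, a2), tau = c(500, 2500),
                                    b = b), irf, ta)
  expect_equal(f(2, 1, 1), 2 * f(1, 0, 0) + f(0, 1, 0) + f(0, 0, 1),
               tolerance = 1e-10)
})

test_that("integer-channel time shifts commute with shiftCurve", {
  ta <- shortAxis(128)
  irf <- gaussIRF(ta)
  s <- 2 * channelWidth(ta)
  spec <- modelSpec("layered", 1)
  p0 <- paramVector(alpha = 1, tau = 1500, tc = 0)
  ps <- paramVector(alpha = 1, tau = 1500, tc = s)
  a <- evaluateModel(spec, ps, irf, ta)
  b <- shiftCurve(evaluateModel(spec, p0, irf, ta), s, ta)
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("unit-sum IRF convolution conserves the decay integral", {
  ta <- shortAxis()
  irf <- gaussIRF(ta, center = 500)
  p <- paramVector(alpha = 1, tau = 800)
  cur <- evaluateModel(modelSpec("multiexp"), p, irf, ta)
  raw <- exp(-channelCenters(ta) / 800)
  # tolerance: the tail mass pushed beyond the grid by the convolution
  expect_equal(sum(cur), sum(raw), tolerance = 0.02)
})

test_that("incomplete-decay folding matches Eq-level closed forms", {
  ta <- shortAxis()
  irf <- deltaIRF(ta)
  tms <- channelCenters(ta)
  tR <- repPeriod(ta) * 1000
  p <- paramVector(alpha = 1, tau = 2000)
  # j = 0 is the identity
  f0 <- applyIncompleteDecay(function(t) exp(-t / 2000), 0, ta)
  expect_identical(f0(tms), exp(-tms / 2000))
  # j = 1: F(t) = alpha (e^{-t/tau} + e^{-(t+tR)/tau})
  c1 <- evaluateModel(modelSpec("multiexp", incompleteDecay = 1), p, irf, ta)
  expect_equal(c1, exp(-tms / 2000) + exp(-(tms + tR) / 2000),
               tolerance = 1e-12)
  # channel 1 gains wrapped tail relative to the unfolded model
  c0 <- evaluateModel(modelSpec("multiexp"), p, irf, ta)
  expect_gt(c1[1], c0[1])
  # large j approaches the geometric closed form 1 / (1 - e^{-tR/tau})
  fj <- applyIncompleteDecay(function(t) exp(-t / 2000), 12, ta)
  ratio <- fj(tms) / exp(-tms / 2000)
  expect_lt(max(abs(ratio - 1 / (1 - exp(-tR / 2000)))), 1e-6)
})

test_that("spectral-global evaluation ties lifetimes across channels", {
  ta <- shortAxis(128)
  irfs <- list(gaussIRF(ta), gaussIRF(ta))
  specs <- list(modelSpec("multiexp", 2), modelSpec("multiexp", 2))
  p1 <- paramVector(alpha = c(1, 0.5), tau = c(500, 2500), b = 1)
  # all lifetimes shared, identical alpha/b/IRF: identical curves
  out <- evaluateSpectralGlobal(specs, c(1, 2), list(p1, p1), irfs, ta)
  expect_equal(out[[1]], out[[2]])
  # one shared lifetime: perturbing it in channel 1 changes both curves
  p2 <- methods::initialize(p1, tau = c(700, 2500))
  out2 <- evaluateSpectralGlobal(specs, 1, list(p2, p1), irfs, ta)
  expect_false(isTRUE(all.equal(out2[[1]], out[[1]])))
  expect_false(isTRUE(all.equal(out2[[2]], out[[2]])))
  # empty shared set reduces to independent evaluations
  out3 <- evaluateSpectralGlobal(specs, integer(0), list(p2, p1), irfs, ta)
  expect_equal(out3[[2]], out[[2]])
  expect_error(
    evaluateSpectralGlobal(list(modelSpec("multiexp", 1), specs[[2]]),
                           2, list(p1, p1), irfs, ta),
    "shared lifetime")
})

test_that("parameter invariants are enforced", {
  expect_error(paramVector(alpha = 1, tau = -5), "lifetimes")
  expect_error(paramVector(alpha = -1, tau = 5), "amplitudes")
  expect_error(paramVector(beta = 1.5), "beta")
  expect_error(modelSpec("multiexp", 4), "nComponents")
  expect_error(modelSpec("lens_corrected", 1), "LensDecay")
})
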