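#' @include AllClasses.R decay_models.R
NULL

#' Ground truth for synthetic TCSPC data
#'
#' Per-pixel true model parameters, a target photon-number map and the
#' model ingredients needed to construct expected decay curves and sample
#' Poisson photon-count histograms from them. The default configuration
#' mirrors a typical ophthalmic acquisition: 1,000-10,000 photons per
#' pixel on a 12.5 ns repetition period.
#'
#' @slot spec the \code{\link{ModelSpec}} generating the data.
#' @slot maps named list of parameter matrices (\code{alpha1..},
#'   \code{tau1..} in ps, optional \code{tc1..}, \code{beta},
#'   \code{alphaLens}, \code{tcLens}, \code{b} as a per-channel rate).
#' @slot photons matrix of target photon numbers per pixel (decay part;
#'   background is an additive per-channel rate on top).
#' @slot irf the \code{\link{IRFCurve}}.
#' @slot time the \code{\link{TimeAxis}}.
#' @slot seed integer RNG seed recorded in provenance.
#'
#' @export
setClass("GroundTruth",
  representation(spec = "ModelSpec", maps = "list", photons = "matrix",
                 irf = "IRFCurve", time = "TimeAxis", seed = "integer"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  dims <- unique(lapply(object@maps, dim))
  if (length(dims) != 1 || !identical(dims[[1]], dim(object@photons)))
    msg <- c(msg, "all parameter maps and the photon map must share one dimension")
  need <- c(paste0("alpha", seq_len(object@spec@nComponents)),
            paste0("tau", seq_len(object@spec@nComponents)))
  if (!all(need %in% names(object@maps)))
    msg <- c(msg, paste("maps must contain:", paste(need, collapse = ", ")))
  for (i in seq_len(object@spec@nComponents)) {
    if (any(object@maps[[paste0("tau", i)]] <= 0))
      msg <- c(msg, "true lifetimes must be > 0")
    if (any(object@maps[[paste0("alpha", i)]] < 0))
      msg <- c(msg, "true amplitudes must be >= 0")
  }
  aSum <- Reduce(`+`, object@maps[paste0("alpha",
                                         seq_len(object@spec@nComponents))])
  if (any(aSum <= 0))
    msg <- c(msg, "per-pixel amplitudes must not be all zero")
  if (any(object@photons < 0))
    msg <- c(msg, "photon numbers must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param spec,maps,photons,irf,time,seed see slots.
#' @rdname GroundTruth-class
#' @export
groundTruth <- function(spec, maps, photons, irf, time, seed = 1L) {
  new("GroundTruth", spec = spec, maps = maps, photons = photons,
      irf = irf, time = time, seed = as.integer(seed))
}

#' Spatially uniform ground truth
#'
#' Convenience constructor: every pixel carries the same parameters.
#'
#' @param shape integer length-2, image rows and columns.
#' @param params a \code{\link{ParamVector}} with the true parameters.
#' @param photons target photon number per pixel (decay part).
#' @param spec a \code{\link{ModelSpec}}.
#' @param irf an \code{\link{IRFCurve}}.
#' @param time a \code{\link{TimeAxis}}.
#' @param seed integer seed.
#' @return a \code{\link{GroundTruth}}.
#' @export
uniformGroundTruth <- function(shape, params, photons, spec, irf, time,
                               seed = 1L) {
  cm <- function(v) matrix(v, shape[1], shape[2])
  n <- spec@nComponents
  maps <- list()
  for (i in seq_len(n)) {
    maps[[paste0("alpha", i)]] <- cm(params@alpha[i])
    maps[[paste0("tau", i)]] <- cm(params@tau[i])
    if (hasShifts(spec)) maps[[paste0("tc", i)]] <- cm(params@tc[i])
  }
  if (hasBeta(spec)) maps$beta <- cm(params@beta)
  if (hasLens(spec)) {
    maps$alphaLens <- cm(params@alphaLens)
    maps$tcLens <- cm(params@tcLens)
  }
  maps$b <- cm(params@b)
  groundTruth(spec, maps, cm(photons), irf, time, seed)
}

.truthParams <- function(truth, r, c) {
  n <- truth@spec@nComponents
  g <- function(nm, default = 0)
    if (nm %in% names(truth@maps)) truth@maps[[nm]][r, c] else default
  paramVector(
    alpha = vapply(seq_len(n), function(i) g(paste0("alpha", i)), 0),
    tau = vapply(seq_len(n), function(i) g(paste0("tau", i), 1000), 0),
    tc = vapply(seq_len(n), function(i) g(paste0("tc", i)), 0),
    beta = g("beta", 1), alphaLens = g("alphaLens"),
    tcLens = g("tcLens"), b = g("b"))
}

#' Expected photon-count curve for one ground-truth pixel
#'
#' Forward-evaluates the model for the pixel's true parameters and scales
#' the decay part (components plus lens term) so that it sums to the
#' pixel's target photon number; the background rate \code{b} is then
#' added per channel on top.
#'
#' @param truth a \code{\link{GroundTruth}}.
#' @param row,col pixel indices (1-based).
#' @return non-negative expected counts, one per time channel.
#' @export
expectedCurve <- function(truth, row = 1L, col = 1L) {
  p <- .truthParams(truth, row, col)
  noB <- methods::initialize(p, b = 0)
  decay <- evaluateModel(truth@spec, noB, truth@irf, truth@time)
  s <- sum(decay)
  n <- truth@photons[row, col]
  if (s > 0 && n > 0) decay <- decay * (n / s) else decay <- decay * 0
  decay + p@b
}

#' Sample a Poisson photon-count histogram
#'
#' Independent Poisson draw per time channel (standard TCSPC counting
#' statistics), reproducible for a given seed (Mersenne-Twister).
#'
#' @param expected non-negative expected counts per channel.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return integer histogram of the same length.
#' @export
sampleHistogram <- function(expected, seed = NULL) {
  stopifnot(all(expected >= 0))
  if (!is.null(seed)) set.seed(as.integer(seed), kind = "Mersenne-Twister")
  stats::rpois(length(expected), expected)
}

#' Simulate a TCSPC cube from ground truth
#'
#' Builds the expected curve for every pixel and draws the photon-count
#' histograms. The ground truth is attached to the returned cube (attribute
#' \code{"truth"}) so recovery can be scored in tests.
#'
#' @param truth a \code{\link{GroundTruth}}.
#' @param pixelPitch micrometers per pixel for the cube metadata.
#' @return a \code{\link{TCSPCCube}}.
#' @export
simulateCube <- function(truth, pixelPitch = 34) {
  methods::validObject(truth)
  d <- dim(truth@photons)
  m <- truth@time@nChannels
  set.seed(truth@seed, kind = "Mersenne-Twister")
  arr <- array(0L, c(d[1], d[2], m))
  for (r in seq_len(d[1]))
    for (c in seq_len(d[2]))
      arr[r, c, ] <- stats::rpois(m, expectedCurve(truth, r, c))
  cube <- TCSPCCube(arr, truth@time, pixelPitch = pixelPitch)
  attr(cube, "truth") <- truth
  cube
}

#' Simulate a two-group study with a known lifetime effect
#'
#' Generates per-subject true parameter maps for two groups. Each subject
#' draws its mean lifetimes from a normal between-subject distribution
#' around the base truth; pixels add independent within-subject variation.
#' Group B's designated lifetime is shifted by \code{effect} picoseconds.
#' Per-subject seeds are derived deterministically from the master seed.
#'
#' @param nPerGroup subjects per group (>= 2).
#' @param effect additive shift (ps) applied to \code{parameter} in group B.
#' @param base a \code{\link{ParamVector}} with the base true parameters.
#' @param nPixels pixels per subject map (a square-ish map is built).
#' @param parameter name of the shifted map, e.g. \code{"tau1"}.
#' @param betweenSd between-subject standard deviation of the lifetime, ps.
#' @param withinSd pixel-to-pixel standard deviation within a subject, ps.
#' @param seed master seed.
#' @return a \code{\link{StudySet}} with groups \code{"A"} and \code{"B"}.
#' @export
simulateGroupStudy <- function(nPerGroup, effect, base = paramVector(
                                 alpha = c(0.6, 0.4), tau = c(300, 2200)),
                               nPixels = 2500, parameter = "tau1",
                               betweenSd = 30, withinSd = 60, seed = 1L) {
  stopifnot(nPerGroup >= 2)
  comp <- as.integer(sub("tau", "", parameter))
  nr <- floor(sqrt(nPixels)); nc <- ceiling(nPixels / nr)
  subjectsList <- list()
  k <- 0L
  for (grp in c("A", "B")) {
    for (s in seq_len(nPerGroup)) {
      k <- k + 1L
      set.seed((as.integer(seed) * 1009L + k * 97L) %% .Machine$integer.max,
               kind = "Mersenne-Twister")
      maps <- list()
      for (i in seq_along(base@tau)) {
        mu <- base@tau[i] + if (grp == "B" && i == comp) effect else 0
        subjMean <- stats::rnorm(1, mu, betweenSd)
        vals <- pmax(stats::rnorm(nr * nc, subjMean, withinSd), 1)
        maps[[paste0("tau", i)]] <- matrix(vals, nr, nc)
        maps[[paste0("alpha", i)]] <- matrix(base@alpha[i], nr, nc)
      }
      subjectsList[[k]] <- list(id = sprintf("%s%02d", grp, s), group = grp,
                                maps = maps,
                                roi = matrix(TRUE, nr, nc))
    }
  }
  StudySet(subjectsList)
}
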