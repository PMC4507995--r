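#' @include AllClasses.R
NULL

#' Lens-to-retina photon travel time shift
#'
#' Fluorescence excited in the crystalline lens reaches the detector
#' earlier than retinal fluorescence: the excitation pulse and the emitted
#' photons both traverse the vitreous, so the retinal signal lags by
#' \code{tc = 2 d n / c}. For the average schematic eye
#' (d = 22.2 mm lens-to-retina, vitreous refractive index 1.3668) this is
#' 202.3 ps, resolvable at a 12.2 ps channel width.
#'
#' @param d_mm distance between the crystalline lens and the retina, mm.
#' @param refractiveIndex refractive index of the medium (>= 1).
#' @param c_mps speed of light in m/s.
#' @return time shift in picoseconds.
#' @examples
#' lensTimeShift(22.2, 1.3668)   # 202.3 ps
#' @export
lensTimeShift <- function(d_mm, refractiveIndex, c_mps = 3e8) {
  if (any(d_mm < 0)) stop("distance must be non-negative")
  if (any(refractiveIndex < 1)) stop("refractive index must be >= 1")
  2 * (d_mm * 1e-3) * refractiveIndex / c_mps * 1e12
}

#' Repetition period from pulse repetition rate
#'
#' @param rate_hz laser pulse repetition rate in Hz.
#' @return repetition period t_R in nanoseconds.
#' @examples
#' repetitionPeriod(80e6)   # 12.5 ns
#' @export
repetitionPeriod <- function(rate_hz) {
  if (any(rate_hz <= 0)) stop("repetition rate must be > 0")
  1 / rate_hz * 1e9
}

#' Shift a sampled curve along the time axis
#'
#' Delays a curve by \code{shift} picoseconds using linear interpolation
#' between channels. Samples shifted in from before t = 0 are zero, or the
#' wrapped end of the curve when \code{wrap = TRUE} (used when periodic
#' excitation makes the signal wrap around the repetition period).
#'
#' @param values numeric curve sampled at the channel centers of \code{time}.
#' @param shift time shift in picoseconds (positive delays the curve).
#' @param time a \code{\link{TimeAxis}}.
#' @param wrap logical; wrap around instead of zero-filling.
#' @return the shifted curve, same length.
#' @examples
#' ta <- TimeAxis(8, 10)
#' shiftCurve(c(0, 1, 0, 0, 0, 0, 0, 0), 10, ta)  # delta moves one channel
#' @export
shiftCurve <- function(values, shift, time, wrap = FALSE) {
  m <- time@nChannels
  stopifnot(length(values) == m)
  if (abs(shift) >= time@repPeriod * 1000)
    stop("|shift| must be smaller than the repetition period")
  if (shift == 0) return(values)
  s <- shift / time@channelWidth        # shift in channels
  idx <- seq_len(m) - s                 # fractional source index
  if (wrap) idx <- ((idx - 1) %% m) + 1
  lo <- floor(idx); frac <- idx - lo
  hi <- lo + 1
  if (wrap) {
    lo <- ((lo - 1) %% m) + 1
    hi <- ((hi - 1) %% m) + 1
    values[lo] * (1 - frac) + values[hi] * frac
  } else {
    get0 <- function(i) ifelse(i >= 1 & i <= m, values[pmin(pmax(i, 1), m)], 0)
    get0(lo) * (1 - frac) + get0(hi) * frac
  }
}

# Unconvolved decay of one component at arbitrary times (ps).
# Zero before its onset tc; stretched when beta < 1.
.componentAtTimes <- function(tms, tau, tc, beta) {
  u <- (tms - tc) / tau
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- if (beta == 1) exp(-u[pos]) else exp(-(u[pos]^beta))
  out
}

# Sum of unit-free components (no amplitudes) with incomplete-decay
# folding, sampled on a doubled grid that extends one full span before
# t = 0: periodic excitation adds the tails of the j preceding pulses,
# I(t) = IC(t) + sum_q IC(t + q tR), which is nonzero at (slightly)
# negative times. Evaluating the analytic components at the shifted times
# makes the folding itself exact; the pre-zero samples let the causal IRF
# convolution place preceding-pulse tails into the pre-excitation
# channels.
.componentBasisExtended <- function(spec, params, time) {
  m <- time@nChannels
  tms <- (seq_len(2 * m) - m - 0.5) * time@channelWidth   # (1-m)..m centers
  tR <- time@repPeriod * 1000
  j <- spec@incompleteDecay
  n <- spec@nComponents
  basis <- matrix(0, nrow = 2 * m, ncol = n)
  for (i in seq_len(n)) {
    v <- .componentAtTimes(tms, params@tau[i], params@tc[i], params@beta)
    if (j > 0)
      for (q in seq_len(j))
        v <- v + .componentAtTimes(tms + q * tR, params@tau[i],
                                   params@tc[i], params@beta)
    basis[, i] <- v
  }
  basis
}

# Discrete linear convolution of the unit-sum IRF with a decay sampled on
# the doubled grid (one span before t = 0, one after); the slice k + m of
# the full convolution is output channel k. The FFT can leave values a few
# ulp below zero; the model is non-negative by construction, so those are
# clamped.
.convolveIRF <- function(dExt, irfValues) {
  m <- length(irfValues)
  full <- stats::convolve(c(dExt, numeric(m)),
                          rev(c(irfValues, numeric(2 * m))),
                          type = "open")
  pmax(full[m + seq_len(m)], 0)
}

#' Convolved per-component basis curves
#'
#' Unit-amplitude model curves for each exponential component (convolved
#' with the IRF, incomplete-decay folded) plus, for the lens-corrected
#' model, the shifted lens curve. These are the columns against which the
#' linear parameters (amplitudes, background) are solved.
#'
#' @param spec a \code{\link{ModelSpec}}.
#' @param params a \code{\link{ParamVector}} (only nonlinear entries used).
#' @param irf an \code{\link{IRFCurve}} (normalized to unit sum internally).
#' @param time a \code{\link{TimeAxis}}.
#' @return numeric matrix, one column per component (plus a lens column
#'   named \code{"lens"} when present).
#' @export
modelBasis <- function(spec, params, irf, time) {
  irfv <- curveValues(normalizeCurve(irf))
  basis <- .componentBasisExtended(spec, params, time)
  basis <- apply(basis, 2, .convolveIRF, irfValues = irfv)
  basis <- matrix(basis, nrow = time@nChannels)
  colnames(basis) <- paste0("comp", seq_len(ncol(basis)))
  if (hasLens(spec)) {
    lensv <- shiftCurve(curveValues(spec@lens), params@tcLens, time,
                        wrap = spec@incompleteDecay > 0)
    basis <- cbind(basis, lens = lensv)
  }
  basis
}

#' Evaluate a fluorescence decay model on the time grid
#'
#' Forward model of the expected photon counts per channel: the sum of
#' (possibly stretched, possibly time-shifted) exponential components,
#' folded over \code{incompleteDecay} preceding repetition periods,
#' convolved with the unit-sum IRF, plus the lens term (a measured,
#' already instrument-broadened signal, scaled and shifted, added after
#' the convolution) and a constant background.
#'
#' @inheritParams modelBasis
#' @return non-negative expected-counts curve of length \code{nChannels}.
#' @examples
#' ta <- TimeAxis(256, 48.8)
#' irf <- IRFCurve(c(1, numeric(255)), ta)      # delta IRF
#' p <- paramVector(alpha = 1, tau = 2000)
#' curve <- evaluateModel(modelSpec("multiexp"), p, irf, ta)
#' @export
evaluateModel <- function(spec, params, irf, time) {
  methods::validObject(params)
  methods::validObject(spec)
  basis <- modelBasis(spec, params, irf, time)
  amps <- params@alpha[seq_len(spec@nComponents)]
  if (hasLens(spec)) amps <- c(amps, params@alphaLens)
  as.numeric(basis %*% amps) + params@b
}

#' Spectrally global model evaluation across channels
#'
#' Evaluates one model per spectral channel while forcing the lifetimes in
#' \code{sharedIdx} to take identical values in every channel (a
#' fluorophore's lifetime does not depend on the detection band, so tying
#' lifetimes across channels pools their photons). The shared values are
#' taken from the first channel's parameters; all other parameters stay
#' channel specific.
#'
#' @param specs list of \code{\link{ModelSpec}}, one per spectral channel.
#' @param sharedIdx integer vector of component indices whose lifetimes
#'   are common to all channels (may be empty).
#' @param paramsList list of \code{\link{ParamVector}}, one per channel.
#' @param irfs list of \code{\link{IRFCurve}}, one per channel.
#' @param time a \code{\link{TimeAxis}}.
#' @return list of expected curves, one per channel.
#' @export
evaluateSpectralGlobal <- function(specs, sharedIdx, paramsList, irfs, time) {
  nc <- length(specs)
  stopifnot(length(paramsList) == nc, length(irfs) == nc)
  if (length(sharedIdx)) {
    for (k in seq_len(nc))
      if (any(sharedIdx > specs[[k]]@nComponents))
        stop("shared lifetime indices must exist in every channel's model")
    for (k in seq_len(nc)[-1]) {
      tau <- paramsList[[k]]@tau
      tau[sharedIdx] <- paramsList[[1]]@tau[sharedIdx]
      paramsList[[k]] <- methods::initialize(paramsList[[k]], tau = tau)
    }
  }
  lapply(seq_len(nc), function(k)
    evaluateModel(specs[[k]], paramsList[[k]], irfs[[k]], time))
}

#' Fold an arbitrary decay evaluator over preceding pulses
#'
#' Incomplete-decay correction for a generic model evaluator: when the
#' fluorescence has not decayed fully within one repetition period, each
#' recorded histogram also contains the tails of preceding pulses,
#' \code{F(t) = I(t) + sum_{q=1..j} I(t + q tR)}. Because excitation is
#' periodic this also fills the pre-excitation channels with preceding
#' tails. The evaluator is called at the shifted continuous times, so the
#' folding itself introduces no discretization error.
#'
#' @param evalFun function(times_ps) returning model intensity at
#'   arbitrary times in picoseconds.
#' @param j integer >= 0, number of preceding periods to fold in.
#' @param time a \code{\link{TimeAxis}}.
#' @return function(times_ps) returning the folded intensity.
#' @examples
#' ta <- TimeAxis(64, 195, 12.5)
#' f <- applyIncompleteDecay(function(t) exp(-t / 2000), 10, ta)
#' f(100) / exp(-100 / 2000)        # ~ 1 / (1 - exp(-12500/2000))
#' @export
applyIncompleteDecay <- function(evalFun, j, time) {
  stopifnot(j >= 0)
  if (j == 0) return(evalFun)
  tR <- time@repPeriod * 1000
  function(tms) {
    out <- evalFun(tms)
    for (q in seq_len(j)) out <- out + evalFun(tms + q * tR)
    out
  }
}
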