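#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------- TimeAxis

#' Discrete TCSPC time axis
#'
#' The time grid on which photon-arrival histograms live. Channel \code{j}
#' covers \code{[(j-1)*dt, j*dt)} picoseconds; model curves are evaluated at
#' channel centers. The repetition period is the reciprocal of the laser
#' pulse repetition rate and bounds the observable time span.
#'
#' @slot nChannels integer, number of time channels (m).
#' @slot channelWidth numeric, channel width in picoseconds.
#' @slot repPeriod numeric, laser repetition period in nanoseconds.
#'
#' @examples
#' ta <- TimeAxis()                  # 1024 channels of 12.2 ps, 12.5 ns period
#' head(channelCenters(ta))
#' @export
setClass("TimeAxis",
  representation(nChannels = "integer", channelWidth = "numeric",
                 repPeriod = "numeric"),
  prototype(nChannels = 1024L, channelWidth = 12.2, repPeriod = 12.5))

setValidity("TimeAxis", function(object) {
  msg <- character()
  if (length(object@nChannels) != 1L || is.na(object@nChannels) ||
      object@nChannels < 1L)
    msg <- c(msg, "nChannels must be a positive integer")
  if (length(object@channelWidth) != 1L || !is.finite(object@channelWidth) ||
      object@channelWidth <= 0)
    msg <- c(msg, "channelWidth must be > 0")
  if (length(object@repPeriod) != 1L || !is.finite(object@repPeriod) ||
      object@repPeriod <= 0)
    msg <- c(msg, "repPeriod must be > 0")
  if (length(msg) == 0 &&
      object@nChannels * object@channelWidth >
        object@repPeriod * 1000 + object@channelWidth / 2)
    msg <- c(msg, "time span exceeds the repetition period")
  if (length(msg)) msg else TRUE
})

#' @param nChannels,channelWidth,repPeriod see slots.
#' @rdname TimeAxis-class
#' @export
TimeAxis <- function(nChannels = 1024L, channelWidth = 12.2,
                     repPeriod = 12.5) {
  new("TimeAxis", nChannels = as.integer(nChannels),
      channelWidth = as.numeric(channelWidth),
      repPeriod = as.numeric(repPeriod))
}

#' @param time a \code{TimeAxis}.
#' @return \code{channelCenters}: channel-center times in picoseconds.
#' @rdname TimeAxis-class
#' @export
channelCenters <- function(time) {
  (seq_len(time@nChannels) - 0.5) * time@channelWidth
}

#' @rdname accessors
#' @export
nChannels <- function(x) x@nChannels

#' @rdname accessors
#' @export
channelWidth <- function(x) x@channelWidth

#' @rdname accessors
#' @export
repPeriod <- function(x) x@repPeriod

setMethod("show", "TimeAxis", function(object) {
  cat(sprintf("TimeAxis: %d channels x %.3g ps (span %.4g ns, period %.4g ns)\n",
              object@nChannels, object@channelWidth,
              object@nChannels * object@channelWidth / 1000,
              object@repPeriod))
})

# --------------------------------------------------------------- TCSPCCube

#' Three-dimensional TCSPC photon-count cube
#'
#' Per-pixel photon arrival histograms for one spectral channel:
#' a non-negative integer array indexed (row, column, time channel),
#' with the time axis and acquisition metadata.
#'
#' @slot counts 3-D array of non-negative counts, dim (rows, cols, channels).
#' @slot time the \code{\link{TimeAxis}}.
#' @slot spectralRange numeric length-2, detection band in nm.
#' @slot pixelPitch numeric, micrometers per pixel.
#' @slot channelId integer label of the spectral channel.
#'
#' @examples
#' cube <- TCSPCCube(array(0L, c(2, 2, 16)), TimeAxis(16, 12.2))
#' dim(counts(cube))
#' @export
setClass("TCSPCCube",
  representation(counts = "array", time = "TimeAxis",
                 spectralRange = "numeric", pixelPitch = "numeric",
                 channelId = "integer"),
  prototype(spectralRange = c(498, 560), pixelPitch = 34, channelId = 1L))

setValidity("TCSPCCube", function(object) {
  msg <- character()
  if (length(dim(object@counts)) != 3L)
    msg <- c(msg, "counts must be a 3-D array (rows, cols, time channels)")
  else if (dim(object@counts)[3] != object@time@nChannels)
    msg <- c(msg, "third dimension of counts must equal nChannels(time)")
  if (any(object@counts < 0, na.rm = TRUE) || anyNA(object@counts))
    msg <- c(msg, "counts must be non-negative and finite")
  if (object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be > 0")
  if (length(object@spectralRange) != 2L)
    msg <- c(msg, "spectralRange must have length 2")
  if (length(msg)) msg else TRUE
})

#' @param counts,time,spectralRange,pixelPitch,channelId see slots.
#' @rdname TCSPCCube-class
#' @export
TCSPCCube <- function(counts, time, spectralRange = c(498, 560),
                      pixelPitch = 34, channelId = 1L) {
  new("TCSPCCube", counts = counts, time = time,
      spectralRange = as.numeric(spectralRange),
      pixelPitch = as.numeric(pixelPitch), channelId = as.integer(channelId))
}

#' @rdname accessors
#' @export
setMethod("counts", "TCSPCCube", function(x, ...) x@counts)

#' @rdname accessors
#' @export
setMethod("timeAxis", "TCSPCCube", function(x, ...) x@time)

#' @rdname accessors
#' @export
setMethod("pixelPitch", "TCSPCCube", function(x, ...) x@pixelPitch)

#' @rdname accessors
#' @export
spectralRange <- function(x) x@spectralRange

setMethod("show", "TCSPCCube", function(object) {
  d <- dim(object@counts)
  cat(sprintf("TCSPCCube: %d x %d pixels, %d time channels, %.3g photons total\n",
              d[1], d[2], d[3], sum(object@counts)))
  cat(sprintf("  spectral channel %d (%g-%g nm), pitch %g um/pixel\n",
              object@channelId, object@spectralRange[1],
              object@spectralRange[2], object@pixelPitch))
  show(object@time)
})

# ---------------------------------------------------- IRFCurve / LensDecay

#' Measured one-dimensional curves on the TCSPC time grid
#'
#' \code{IRFCurve} holds the measured instrument response function; model
#' decays are convolved with it (after unit-sum normalization).
#' \code{LensDecay} holds a separately measured crystalline-lens
#' fluorescence decay used by the lens-corrected model; it is a measured,
#' already instrument-broadened signal and therefore enters the model as-is
#' (scaled and time shifted), not convolved again.
#'
#' @slot values numeric non-negative values, one per time channel.
#' @slot time the \code{\link{TimeAxis}}.
#'
#' @examples
#' ta <- TimeAxis(64, 12.2)
#' irf <- IRFCurve(dnorm(1:64, 10, 3), ta)
#' sum(curveValues(normalizeCurve(irf)))
#' @export
setClass("IRFCurve",
  representation(values = "numeric", time = "TimeAxis"))

setValidity("IRFCurve", function(object) {
  msg <- character()
  if (length(object@values) != object@time@nChannels)
    msg <- c(msg, "values length must equal nChannels(time)")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and non-negative")
  if (all(object@values == 0))
    msg <- c(msg, "degenerate IRF: all values are zero")
  if (length(msg)) msg else TRUE
})

#' @param values,time see slots.
#' @rdname IRFCurve-class
#' @export
IRFCurve <- function(values, time) {
  new("IRFCurve", values = as.numeric(values), time = time)
}

#' @rdname IRFCurve-class
#' @export
setClass("LensDecay",
  representation(values = "numeric", time = "TimeAxis"))

setValidity("LensDecay", function(object) {
  msg <- character()
  if (length(object@values) != object@time@nChannels)
    msg <- c(msg, "values length must equal nChannels(time)")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname IRFCurve-class
#' @export
LensDecay <- function(values, time) {
  new("LensDecay", values = as.numeric(values), time = time)
}

#' @rdname accessors
#' @export
setMethod("curveValues", "IRFCurve", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("curveValues", "LensDecay", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("timeAxis", "IRFCurve", function(x, ...) x@time)

#' @rdname accessors
#' @export
setMethod("timeAxis", "LensDecay", function(x, ...) x@time)

#' Normalize a measured curve to unit sum
#'
#' @param x an \code{IRFCurve} or \code{LensDecay}.
#' @return The same class with values scaled to sum to one.
#' @export
normalizeCurve <- function(x) {
  s <- sum(x@values)
  if (s <= 0) stop("degenerate IRF: curve sums to zero")
  methods::initialize(x, values = x@values / s)
}

setMethod("show", "IRFCurve", function(object) {
  cat(sprintf("IRFCurve: %d channels, peak at channel %d, sum %.4g\n",
              length(object@values), which.max(object@values),
              sum(object@values)))
})

setMethod("show", "LensDecay", function(object) {
  cat(sprintf("LensDecay: %d channels, peak at channel %d, sum %.4g\n",
              length(object@values), which.max(object@values),
              sum(object@values)))
})

# --------------------------------------------------------------- ModelSpec

.modelKinds <- c("multiexp", "stretched", "spectral_global", "layered",
                 "layered_stretched", "lens_corrected")

#' Declarative description of a fluorescence decay model
#'
#' Selects one of the implemented decay models and its structure: the
#' number of exponential components (at most three; more is not practical
#' given achievable photon numbers), whether a stretching exponent beta is
#' present, whether per-component time shifts are free, the number of
#' preceding-pulse periods folded in for incomplete-decay correction, and,
#' for the lens-corrected model, the measured lens decay curve.
#'
#' @slot kind one of \code{"multiexp"}, \code{"stretched"},
#'   \code{"spectral_global"}, \code{"layered"}, \code{"layered_stretched"},
#'   \code{"lens_corrected"}.
#' @slot nComponents integer in 1..3.
#' @slot incompleteDecay integer >= 0; number of repetition periods folded
#'   in (0 disables the correction).
#' @slot lens a \code{LensDecay} or \code{NULL} (required iff kind is
#'   \code{"lens_corrected"}).
#'
#' @examples
#' modelSpec("multiexp", nComponents = 2, incompleteDecay = 1)
#' @export
setClass("ModelSpec",
  representation(kind = "character", nComponents = "integer",
                 incompleteDecay = "integer", lens = "ANY"),
  prototype(kind = "multiexp", nComponents = 1L, incompleteDecay = 0L,
            lens = NULL))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!(object@kind %in% .modelKinds))
    msg <- c(msg, paste("kind must be one of:",
                        paste(.modelKinds, collapse = ", ")))
  if (object@nComponents < 1L || object@nComponents > 3L)
    msg <- c(msg, "nComponents must be 1, 2 or 3")
  if (object@incompleteDecay < 0L)
    msg <- c(msg, "incompleteDecay must be >= 0")
  if (object@kind == "lens_corrected" && !methods::is(object@lens, "LensDecay"))
    msg <- c(msg, "lens_corrected model requires a LensDecay in `lens`")
  if (object@kind != "lens_corrected" && !is.null(object@lens))
    msg <- c(msg, "`lens` is only allowed for kind = lens_corrected")
  if (length(msg)) msg else TRUE
})

#' @param kind,nComponents,incompleteDecay,lens see slots.
#' @rdname ModelSpec-class
#' @export
modelSpec <- function(kind = "multiexp", nComponents = 1L,
                      incompleteDecay = 0L, lens = NULL) {
  new("ModelSpec", kind = kind, nComponents = as.integer(nComponents),
      incompleteDecay = as.integer(incompleteDecay), lens = lens)
}

#' Does a model kind include a stretching exponent / time shifts / lens term?
#' @param spec a \code{ModelSpec}.
#' @return logical.
#' @rdname ModelSpec-class
#' @export
hasBeta <- function(spec)
  spec@kind %in% c("stretched", "layered_stretched", "lens_corrected")

#' @rdname ModelSpec-class
#' @export
hasShifts <- function(spec)
  spec@kind %in% c("layered", "layered_stretched", "lens_corrected")

#' @rdname ModelSpec-class
#' @export
hasLens <- function(spec) spec@kind == "lens_corrected"

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s, %d component(s), incomplete-decay j = %d%s\n",
              object@kind, object@nComponents, object@incompleteDecay,
              if (hasLens(object)) ", with lens curve" else ""))
})

# ------------------------------------------------------------- ParamVector

#' Decay-model parameter vector
#'
#' All parameters of the decay models in one object. Amplitudes and
#' background are the linear parameters solved in closed form during
#' fitting (variable projection); lifetimes, time shifts, the stretching
#' exponent and the lens shift are the nonlinear parameters. Lifetimes and
#' shifts are in picoseconds throughout.
#'
#' @slot alpha non-negative amplitudes, one per component.
#' @slot tau strictly positive lifetimes (ps), one per component.
#' @slot tc per-component time shifts (ps); zeros when the model has none.
#' @slot beta stretching exponent in (0, 1]; 1 reduces a stretched model
#'   to plain exponentials. A single beta is shared across components.
#' @slot alphaLens non-negative amplitude of the lens term.
#' @slot tcLens time shift of the lens term (ps).
#' @slot b non-negative constant background per channel.
#'
#' @examples
#' paramVector(alpha = c(1, 0.5), tau = c(500, 2500))
#' @export
setClass("ParamVector",
  representation(alpha = "numeric", tau = "numeric", tc = "numeric",
                 beta = "numeric", alphaLens = "numeric", tcLens = "numeric",
                 b = "numeric"),
  prototype(alpha = 1, tau = 1000, tc = 0, beta = 1, alphaLens = 0,
            tcLens = 0, b = 0))

setValidity("ParamVector", function(object) {
  msg <- character()
  if (length(object@alpha) != length(object@tau))
    msg <- c(msg, "alpha and tau must have the same length")
  if (length(object@tc) != length(object@tau))
    msg <- c(msg, "tc must have one entry per component")
  if (any(object@alpha < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (any(object@tau <= 0)) msg <- c(msg, "lifetimes must be > 0")
  if (object@beta <= 0 || object@beta > 1)
    msg <- c(msg, "beta must lie in (0, 1]")
  if (object@alphaLens < 0) msg <- c(msg, "alphaLens must be >= 0")
  if (object@b < 0) msg <- c(msg, "background must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param alpha,tau,tc,beta,alphaLens,tcLens,b see slots.
#' @rdname ParamVector-class
#' @export
paramVector <- function(alpha = 1, tau = 1000, tc = NULL, beta = 1,
                        alphaLens = 0, tcLens = 0, b = 0) {
  if (is.null(tc)) tc <- rep(0, length(tau))
  new("ParamVector", alpha = as.numeric(alpha), tau = as.numeric(tau),
      tc = as.numeric(tc), beta = as.numeric(beta),
      alphaLens = as.numeric(alphaLens), tcLens = as.numeric(tcLens),
      b = as.numeric(b))
}

setMethod("show", "ParamVector", function(object) {
  cat("ParamVector:\n")
  cat("  alpha:", signif(object@alpha, 4), "\n")
  cat("  tau (ps):", signif(object@tau, 5), "\n")
  if (any(object@tc != 0)) cat("  tc (ps):", signif(object@tc, 4), "\n")
  if (object@beta != 1) cat("  beta:", signif(object@beta, 4), "\n")
  if (object@alphaLens != 0)
    cat("  lens: alpha", signif(object@alphaLens, 4),
        "tc", signif(object@tcLens, 4), "ps\n")
  cat("  background b:", signif(object@b, 4), "\n")
})

# ------------------------------------------------------------ FitResultMaps

#' Per-pixel fit results for one image
#'
#' Named matrices with one entry per pixel for every fitted parameter
#' (amplitudes \code{alpha1..}, lifetimes \code{tau1..}, shifts
#' \code{tc1..}, \code{beta}, \code{alphaLens}, \code{tcLens},
#' background \code{b}), the reduced chi-square map, the amplitude-weighted
#' mean lifetime \code{tauM}, the adaptive binning radius map (if binning
#' was adaptive), the reflection-artifact channel intervals, and the fit
#' provenance (model, configuration, seed).
#'
#' @slot maps named list of numeric matrices of identical dimension.
#' @slot chi2 reduced chi-square matrix.
#' @slot radius adaptive-binning radius matrix or NULL.
#' @slot artifacts integer matrix with columns \code{start}, \code{end}:
#'   half-open masked channel intervals \code{[start, end)} (1-based).
#' @slot provenance named list (model kind, configuration, seed, ...).
#'
#' @export
setClass("FitResultMaps",
  representation(maps = "list", chi2 = "matrix", radius = "ANY",
                 artifacts = "matrix", provenance = "list"),
  prototype(radius = NULL,
            artifacts = matrix(integer(), ncol = 2,
                               dimnames = list(NULL, c("start", "end"))),
            provenance = list()))

setValidity("FitResultMaps", function(object) {
  msg <- character()
  if (length(object@maps) == 0 || is.null(names(object@maps)))
    msg <- c(msg, "maps must be a nonempty named list")
  dims <- lapply(object@maps, dim)
  if (length(unique(dims)) > 1)
    msg <- c(msg, "all maps must share one dimension")
  if (length(dims) && !identical(dim(object@chi2), dims[[1]]))
    msg <- c(msg, "chi2 map dimension must match parameter maps")
  tauMaps <- object@maps[grep("^tau[0-9]+$", names(object@maps))]
  for (tm in tauMaps)
    if (any(tm[is.finite(tm)] <= 0))
      msg <- c(msg, "fitted lifetimes must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' @param maps,chi2,radius,artifacts,provenance see slots.
#' @rdname FitResultMaps-class
#' @export
FitResultMaps <- function(maps, chi2, radius = NULL,
                          artifacts = NULL, provenance = list()) {
  if (is.null(artifacts))
    artifacts <- matrix(integer(), ncol = 2,
                        dimnames = list(NULL, c("start", "end")))
  new("FitResultMaps", maps = maps, chi2 = chi2, radius = radius,
      artifacts = artifacts, provenance = provenance)
}

#' @rdname accessors
#' @export
setMethod("resultMap", "FitResultMaps", function(x, name, ...) {
  if (name == "chi2") return(x@chi2)
  if (!name %in% names(x@maps))
    stop("no map named '", name, "'; available: ",
         paste(c(names(x@maps), "chi2"), collapse = ", "))
  x@maps[[name]]
})

#' @rdname accessors
#' @export
setMethod("mapNames", "FitResultMaps", function(x, ...)
  c(names(x@maps), "chi2"))

#' @rdname accessors
#' @export
setMethod("provenance", "FitResultMaps", function(x, ...) x@provenance)

setMethod("show", "FitResultMaps", function(object) {
  d <- dim(object@chi2)
  cat(sprintf("FitResultMaps: %d x %d pixels, maps: %s\n", d[1], d[2],
              paste(names(object@maps), collapse = ", ")))
  cat(sprintf("  median chi2r: %.4g; %d artifact interval(s)\n",
              stats::median(object@chi2, na.rm = TRUE),
              nrow(object@artifacts)))
})

# ----------------------------------------------------------------- StudySet

#' A two-group study of fitted subjects
#'
#' A collection of subjects, each carrying an identifier, a group label,
#' its \code{FitResultMaps} (or a plain named list of parameter matrices)
#' and a logical region-of-interest mask of matching dimension.
#'
#' @slot subjects list of lists with elements \code{id}, \code{group},
#'   \code{maps}, \code{roi}.
#'
#' @export
setClass("StudySet", representation(subjects = "list"))

setValidity("StudySet", function(object) {
  msg <- character()
  for (s in object@subjects) {
    if (!all(c("id", "group", "maps", "roi") %in% names(s))) {
      msg <- c(msg, "each subject needs id, group, maps, roi")
      break
    }
    m <- if (methods::is(s$maps, "FitResultMaps")) s$maps@maps else s$maps
    if (!identical(dim(s$roi), dim(m[[1]]))) {
      msg <- c(msg, "roi mask dimension must match the maps")
      break
    }
  }
  groups <- vapply(object@subjects, function(s) s$group, character(1))
  if (length(unique(groups)) > 2)
    msg <- c(msg, "at most two group labels are supported")
  if (length(msg)) msg else TRUE
})

#' @param subjects see slot.
#' @rdname StudySet-class
#' @export
StudySet <- function(subjects) new("StudySet", subjects = subjects)

#' @rdname accessors
#' @export
setMethod("subjects", "StudySet", function(x, ...) x@subjects)

#' @param x a \code{StudySet}.
#' @return \code{groupLabels}: the group label of each subject.
#' @rdname StudySet-class
#' @export
groupLabels <- function(x)
  vapply(x@subjects, function(s) s$group, character(1))

setMethod("show", "StudySet", function(object) {
  g <- table(groupLabels(object))
  cat("StudySet:", length(object@subjects), "subjects (",
      paste(sprintf("%s: %d", names(g), g), collapse = ", "), ")\n")
})
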