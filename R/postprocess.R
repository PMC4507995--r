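#' @include AllClasses.R
NULL

#' Amplitude-weighted mean fluorescence lifetime
#'
#' \code{tauM = sum(alpha_i * tau_i) / sum(alpha_i)} — the standard
#' overview parameter combining the component lifetimes weighted by their
#' amplitudes. Always lies between the smallest and largest component
#' lifetime, and is invariant to rescaling all amplitudes.
#'
#' @param alpha non-negative amplitudes (at least one positive).
#' @param tau positive lifetimes (ps), same length.
#' @return the mean lifetime in ps.
#' @examples
#' meanLifetime(c(1, 1), c(1000, 3000))   # 2000
#' meanLifetime(c(3, 1), c(100, 500))     # 200
#' @export
meanLifetime <- function(alpha, tau) {
  stopifnot(length(alpha) == length(tau))
  if (any(alpha < 0) || any(tau <= 0))
    stop("amplitudes must be >= 0 and lifetimes > 0")
  s <- sum(alpha)
  if (s <= 0) stop("amplitude sum must be positive")
  sum(alpha * tau) / s
}

#' Spatial mean or median filtering of a parameter map
#'
#' Replaces each pixel by the mean or median over an odd square window
#' clipped at the image border. Used to reduce noise in the fitted
#' parameter maps before computing region statistics.
#'
#' @param map numeric matrix.
#' @param size odd kernel size (3 or 5 are typical).
#' @param method \code{"median"} or \code{"mean"}.
#' @return the filtered matrix.
#' @export
spatialFilter <- function(map, size = 3, method = c("median", "mean")) {
  method <- match.arg(method)
  if (size %% 2 == 0 || size < 1) stop("kernel size must be odd")
  half <- (size - 1) %/% 2
  d <- dim(map)
  out <- map
  fun <- if (method == "median") stats::median else mean
  for (r in seq_len(d[1])) {
    rs <- max(1, r - half):min(d[1], r + half)
    for (c in seq_len(d[2])) {
      cs <- max(1, c - half):min(d[2], c + half)
      out[r, c] <- fun(map[rs, cs], na.rm = TRUE)
    }
  }
  out
}

.etdrsLabels <- c("central",
                  "inner_superior", "inner_nasal", "inner_inferior",
                  "inner_temporal",
                  "outer_superior", "outer_nasal", "outer_inferior",
                  "outer_temporal")

#' ETDRS macular grid
#'
#' Standardized region-of-interest grid for the macula: three concentric
#' circles of 500, 1500 and 3000 um radius around the fovea, with the two
#' rings split into quadrants by the diagonals at 45, 135, 225 and 315
#' degrees, giving nine subfields (central plus inner/outer superior,
#' inferior, nasal and temporal). Pixels exactly on a circle belong to the
#' inner region; pixels on a diagonal belong to the counter-clockwise
#' sector. Superior is up in the image; for a right eye in standard
#' orientation nasal is image-left, for a left eye image-right.
#'
#' @slot labels integer matrix, 0 outside the grid, otherwise 1..9
#'   indexing \code{labelNames}.
#' @slot labelNames the nine subfield names.
#' @slot center numeric (row, col) of the fovea.
#' @slot pixelPitch micrometers per pixel.
#' @slot radii the three circle radii in micrometers.
#' @slot eyeSide \code{"left"} or \code{"right"}.
#'
#' @export
setClass("EtdrsGrid",
  representation(labels = "matrix", labelNames = "character",
                 center = "numeric", pixelPitch = "numeric",
                 radii = "numeric", eyeSide = "character"))

setValidity("EtdrsGrid", function(object) {
  msg <- character()
  if (!all(diff(object@radii) > 0))
    msg <- c(msg, "radii must be strictly increasing")
  if (!object@eyeSide %in% c("left", "right"))
    msg <- c(msg, "eyeSide must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' Build the ETDRS grid label map
#'
#' @param center numeric (row, col) pixel coordinates of the fovea.
#' @param pixelPitch micrometers per pixel.
#' @param shape integer (rows, cols) of the image.
#' @param eyeSide \code{"left"} or \code{"right"} (decides which side is
#'   nasal).
#' @param radii circle radii in micrometers.
#' @return an \code{\link{EtdrsGrid}}.
#' @examples
#' g <- buildEtdrsGrid(c(50, 50), pixelPitch = 50, shape = c(99, 99))
#' table(g@labels)[["1"]]     # pixels of the central subfield
#' @export
buildEtdrsGrid <- function(center, pixelPitch, shape, eyeSide = "right",
                           radii = c(500, 1500, 3000)) {
  if (center[1] < 1 || center[1] > shape[1] ||
      center[2] < 1 || center[2] > shape[2])
    stop("grid center must lie inside the image")
  if (pixelPitch <= 0) stop("pixelPitch must be > 0")
  labels <- matrix(0L, shape[1], shape[2])
  rowIdx <- matrix(seq_len(shape[1]), shape[1], shape[2])
  colIdx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dy <- (center[1] - rowIdx) * pixelPitch     # up is positive
  dx <- (colIdx - center[2]) * pixelPitch     # image-right is positive
  dist <- sqrt(dx^2 + dy^2)
  ring <- ifelse(dist <= radii[1], 1L,
          ifelse(dist <= radii[2], 2L,
          ifelse(dist <= radii[3], 3L, 0L)))
  # sector index counter-clockwise from the 45-degree diagonal:
  # 0 = superior [45,135), 1 = left [135,225), 2 = inferior [225,315),
  # 3 = right [315,45); a boundary angle belongs to the sector it opens.
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  sector <- floor(((theta - 45) %% 360) / 90)
  # map left/right to nasal/temporal per eye side
  leftName <- if (eyeSide == "right") "nasal" else "temporal"
  rightName <- if (eyeSide == "right") "temporal" else "nasal"
  sectorName <- character(4)
  sectorName[1] <- "superior"; sectorName[2] <- leftName
  sectorName[3] <- "inferior"; sectorName[4] <- rightName
  labels[ring == 1L] <- 1L
  for (rg in 2:3) {
    prefix <- if (rg == 2L) "inner_" else "outer_"
    for (sc in 0:3) {
      nm <- paste0(prefix, sectorName[sc + 1])
      idx <- which(ring == rg & sector == sc)
      labels[idx] <- match(nm, .etdrsLabels)
    }
  }
  new("EtdrsGrid", labels = labels, labelNames = .etdrsLabels,
      center = as.numeric(center), pixelPitch = as.numeric(pixelPitch),
      radii = as.numeric(radii), eyeSide = eyeSide)
}

#' Logical mask of one ETDRS subfield
#'
#' @param grid an \code{\link{EtdrsGrid}}.
#' @param subfield one of the nine subfield names (see
#'   \code{grid@labelNames}).
#' @return logical matrix.
#' @export
subfieldMask <- function(grid, subfield) {
  i <- match(subfield, grid@labelNames)
  if (is.na(i)) stop("unknown subfield '", subfield, "'")
  grid@labels == i
}

setMethod("show", "EtdrsGrid", function(object) {
  cat(sprintf("EtdrsGrid: center (%g, %g), pitch %g um/px, %s eye\n",
              object@center[1], object@center[2], object@pixelPitch,
              object@eyeSide))
  print(table(factor(object@labels, levels = 0:9,
                     labels = c("outside", object@labelNames))))
})

#' Descriptive statistics over a region of interest
#'
#' Mean, median, mode, standard deviation, variance, a confidence
#' interval for the mean and the pixel count over the unmasked finite
#' pixels of a map. The mode is the center of the most frequent histogram
#' class at the given class width (continuous data has no exact mode).
#' The confidence interval is either normal-theory (t-based, default) or
#' a percentile bootstrap.
#'
#' @param map numeric matrix.
#' @param mask logical matrix (TRUE = in ROI).
#' @param classWidth histogram class width for the mode.
#' @param level confidence level.
#' @param ci \code{"normal"} or \code{"bootstrap"}.
#' @param nBoot bootstrap replicates.
#' @return list with \code{mean}, \code{median}, \code{mode}, \code{sd},
#'   \code{variance}, \code{ci} (level, lower, upper), \code{n}.
#' @export
roiStatistics <- function(map, mask, classWidth = NULL, level = 0.95,
                          ci = c("normal", "bootstrap"), nBoot = 1000) {
  ci <- match.arg(ci)
  v <- map[mask]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("empty ROI")
  n <- length(v)
  mu <- mean(v); sdev <- stats::sd(v)
  if (n == 1) sdev <- 0
  if (is.null(classWidth)) {
    rng <- diff(range(v))
    classWidth <- if (rng > 0) rng / 20 else 1
  }
  h <- roiHistogram(map, mask, classWidth)
  modeClass <- which.max(h$counts)
  modeVal <- (h$edges[modeClass] + h$edges[modeClass + 1]) / 2
  if (ci == "normal") {
    se <- sdev / sqrt(n)
    q <- if (n > 1) stats::qt((1 + level) / 2, n - 1) else 0
    lo <- mu - q * se; hi <- mu + q * se
  } else {
    bm <- vapply(seq_len(nBoot),
                 function(i) mean(v[sample.int(n, n, replace = TRUE)]), 0)
    qs <- stats::quantile(bm, c((1 - level) / 2, (1 + level) / 2),
                          names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  list(mean = mu, median = stats::median(v), mode = modeVal, sd = sdev,
       variance = sdev^2, ci = list(level = level, lower = lo, upper = hi),
       n = n)
}

#' Histogram of a region of interest
#'
#' Left-closed classes \code{[k*w, (k+1)*w)} aligned to multiples of the
#' class width, spanning the ROI's finite values; counts sum to the
#' number of pixels binned.
#'
#' @param map numeric matrix.
#' @param mask logical matrix (TRUE = in ROI).
#' @param classWidth class width (> 0).
#' @return list with \code{edges} (length k+1) and \code{counts}
#'   (length k).
#' @examples
#' m <- matrix(c(2, 7, 12, 3), 2)
#' roiHistogram(m, matrix(c(TRUE, TRUE, TRUE, FALSE), 2), 5)
#' @export
roiHistogram <- function(map, mask, classWidth) {
  if (classWidth <= 0) stop("class width must be > 0")
  v <- map[mask]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("empty ROI")
  k <- floor(v / classWidth)
  lo <- min(k); hi <- max(k)
  edges <- (lo:(hi + 1)) * classWidth
  counts <- tabulate(k - lo + 1L, nbins = hi - lo + 1L)
  list(edges = edges, counts = counts)
}
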