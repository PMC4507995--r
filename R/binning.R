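#' @include AllClasses.R
NULL

#' Static square-window photon binning
#'
#' Sums the photon histograms over a square window of edge length
#' \code{l = 2 f + 1} centered on each pixel (a spatial moving sum). The
#' window is clipped at the image borders, so border pixels sum over their
#' in-image part only. \code{f = 0} is the identity.
#'
#' @param cube a \code{\link{TCSPCCube}}.
#' @param f integer binning factor >= 0.
#' @return a \code{\link{TCSPCCube}} of binned (summed) histograms.
#' @examples
#' ta <- TimeAxis(8, 12.2)
#' cube <- TCSPCCube(array(1L, c(5, 5, 8)), ta)
#' sum(counts(staticBin(cube, 1))[3, 3, ])   # 3x3 window: 72 photons
#' @export
staticBin <- function(cube, f) {
  if (f < 0) stop("binning factor f must be >= 0")
  f <- as.integer(f)
  if (f == 0L) return(cube)
  a <- cube@counts
  d <- dim(a)
  out <- array(0, d)
  # separable moving sum with border clipping, via padded cumulative sums
  for (k in seq_len(d[3])) {
    M <- a[, , k]
    cs <- rbind(0, apply(M, 2, cumsum))
    lo <- pmax(seq_len(d[1]) - f, 1); hi <- pmin(seq_len(d[1]) + f, d[1])
    M2 <- cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]
    cs2 <- cbind(0, t(apply(M2, 1, cumsum)))
    lo2 <- pmax(seq_len(d[2]) - f, 1); hi2 <- pmin(seq_len(d[2]) + f, d[2])
    out[, , k] <- cs2[, hi2 + 1, drop = FALSE] - cs2[, lo2, drop = FALSE]
  }
  methods::initialize(cube, counts = out)
}

# Integer lattice offsets grouped by Euclidean norm: shells at the sorted
# distinct distances 0, 1, sqrt(2), 2, sqrt(5), ... up to maxRadius.
.diskShells <- function(maxRadius) {
  r <- ceiling(maxRadius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  d2 <- g$dr^2 + g$dc^2
  keep <- d2 <= maxRadius^2 + 1e-9
  g <- g[keep, ]; d2 <- d2[keep]
  ord <- order(d2)
  g <- g[ord, ]; d2 <- d2[ord]
  split(g, factor(d2, levels = unique(d2)))
}

#' Adaptive circular-window photon binning
#'
#' For each pixel the radius of a closed circular window (center-to-center
#' Euclidean distance) is increased shell by shell over the distinct
#' lattice distances (0, 1, sqrt(2), 2, ...) until the summed in-image
#' photon count reaches \code{threshold}; the pixel's output histogram is
#' the raw channel-wise sum over that disk. This guarantees the photon
#' minimum at the highest possible spatial resolution, and removes the
#' border intensity drop-off since only in-image pixels contribute. Pixels
#' that cannot reach the threshold even at \code{maxRadius} keep that cap
#' radius and are flagged (with one warning for the image).
#'
#' @param cube a \code{\link{TCSPCCube}}.
#' @param threshold integer >= 1, minimum photons per binned pixel.
#' @param maxRadius safety cap on the radius, in pixels.
#' @return list with elements \code{cube} (binned \code{TCSPCCube}),
#'   \code{radius} (per-pixel radius map) and \code{capped} (logical map,
#'   TRUE where the threshold was not reached at \code{maxRadius}).
#' @examples
#' ta <- TimeAxis(8, 12.2)
#' cube <- TCSPCCube(array(2L, c(9, 9, 8)), ta)      # 16 photons/pixel
#' ab <- adaptiveBin(cube, threshold = 80)           # needs a 5-pixel disk
#' ab$radius[5, 5]
#' @export
adaptiveBin <- function(cube, threshold, maxRadius = 32) {
  if (threshold < 1) stop("threshold must be >= 1")
  a <- cube@counts
  d <- dim(a)
  total <- rowSums(a, dims = 2)
  shells <- .diskShells(maxRadius)
  radii <- sqrt(as.numeric(names(shells)))
  out <- array(0, d)
  radius <- matrix(NA_real_, d[1], d[2])
  capped <- matrix(FALSE, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      acc <- 0
      rows <- integer(0); cols <- integer(0)
      chosen <- radii[length(radii)]
      reached <- FALSE
      for (si in seq_along(shells)) {
        sh <- shells[[si]]
        rr <- r + sh$dr; cc <- c + sh$dc
        ok <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
        rr <- rr[ok]; cc <- cc[ok]
        if (length(rr)) {
          acc <- acc + sum(total[cbind(rr, cc)])
          rows <- c(rows, rr); cols <- c(cols, cc)
        }
        if (acc >= threshold) {
          chosen <- radii[si]
          reached <- TRUE
          break
        }
      }
      radius[r, c] <- chosen
      capped[r, c] <- !reached
      h <- numeric(d[3])
      for (i in seq_along(rows)) h <- h + a[rows[i], cols[i], ]
      out[r, c, ] <- h
    }
  }
  if (any(capped))
    warning(sum(capped), " pixel(s) could not reach the photon threshold ",
            "at maxRadius = ", maxRadius)
  list(cube = methods::initialize(cube, counts = out),
       radius = radius, capped = capped)
}

#' Sum all pixels into a single decay
#'
#' Channel-wise sum of every pixel's histogram — the best-SNR decay of the
#' whole image, used for reflection-artifact detection and for the global
#' initial solution.
#'
#' @param cube a \code{\link{TCSPCCube}}.
#' @return numeric vector of length \code{nChannels}.
#' @export
sumAllPixels <- function(cube) {
  d <- dim(cube@counts)
  if (prod(d[1:2]) == 0) stop("empty cube")
  apply(cube@counts, 3, sum)
}
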