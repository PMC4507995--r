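# Shared fixtures, built in code at test time.

# short time axis: m channels of 48.8 ps-equivalent spanning one 12.5 ns period
shortAxis <- function(m = 256L) TimeAxis(m, 48.8 * 256 / m, 12.5)

deltaIRF <- function(time) {
  v <- numeric(time@nChannels); v[1] <- 1
  IRFCurve(v, time)
}

# Gaussian IRF with a given FWHM (ps), centered at `center` ps
gaussIRF <- function(time, fwhm = 172, center = 1000) {
  tms <- channelCenters(time)
  IRFCurve(exp(-((tms - center) / (fwhm / 2.355))^2 / 2), time)
}

# image-integrated decay with an injected reflection bump rising at
# channel `riseStart` and peaking at `riseStart + riseLen`
bumpDecay <- function(m = 512, riseStart = 100, riseLen = 10) {
  t <- seq_len(m)
  decay <- 5000 * exp(-(t - 10) / 120)
  decay[t < 10] <- 0.1
  bump <- numeric(m)
  pk <- riseStart + riseLen
  bump[riseStart:pk] <- decay[riseStart] * 0.8 * (0:riseLen) / riseLen
  dk <- seq_len(min(50, m - pk))
  bump[pk + dk] <- decay[riseStart] * 0.8 * exp(-dk / 15)
  round(decay + bump)
}

# brute-force oracles -------------------------------------------------------

# O(n^2) static-binning oracle: clipped square window sum per pixel
bruteStaticBin <- function(a, f) {
  d <- dim(a)
  out <- array(0, d)
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    rs <- max(1, r - f):min(d[1], r + f)
    cs <- max(1, c - f):min(d[2], c + f)
    h <- numeric(d[3])
    for (rr in rs) for (cc in cs) h <- h + a[rr, cc, ]
    out[r, c, ] <- h
  }
  out
}

# brute-force closed-disk sum for one pixel at a given radius
bruteDiskSum <- function(a, r0, c0, radius) {
  d <- dim(a)
  h <- numeric(d[3])
  for (rr in seq_len(d[1])) for (cc in seq_len(d[2]))
    if ((rr - r0)^2 + (cc - c0)^2 <= radius^2 + 1e-9)
      h <- h + a[rr, cc, ]
  h
}

# exact two-sided rank-sum p by full enumeration of rank assignments
enumRanksumP <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  uObs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, function(idx) sum(ranks[idx]) - na * (na + 1) / 2)
  mu <- na * nb / 2
  # two-sided: mass at least as far from the mean as observed
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}

# Mann-Whitney AUC by pair counting (ties count one half)
pairCountAUC <- function(x, y) {
  gt <- outer(x, y, ">"); eq <- outer(x, y, "==")
  a <- (sum(gt) + 0.5 * sum(eq)) / (length(x) * length(y))
  max(a, 1 - a)
}
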