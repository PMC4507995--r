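#' @include AllClasses.R decay_models.R binning.R
NULL

#' Fit configuration
#'
#' Settings for the two-stage image fit and its post-processing. Defaults
#' follow common ophthalmic practice: Neyman weighting, a stochastic
#' global stage (differential evolution) on the image-integrated decay,
#' a bound-constrained Nelder-Mead per pixel, artifact removal on, one
#' outlier-treatment iteration with a 7x7 window and a 30% relative
#' threshold.
#'
#' @param weighting \code{"neyman"} (w = measured counts, floored at 1) or
#'   \code{"pearson"} (w = model counts, recomputed per evaluation).
#' @param fitInterval \code{"decay_only"} (channels from the measured peak
#'   onward; appropriate when the model has no time-shift parameters) or
#'   \code{"full_signal"} (all channels, including pre-excitation and
#'   rising edge; required for layered and lens-corrected models).
#' @param constraints named list of \code{c(lower, upper)} bounds for the
#'   nonlinear parameters (\code{tau}, \code{tc}, \code{beta},
#'   \code{tcLens}); a length-1 value fixes the parameter.
#' @param dePopulation,deGenerations differential-evolution settings.
#' @param nmMaxIter,nmTol Nelder-Mead iteration cap and tolerance.
#' @param neighborhood integer >= 0: number of adjacent pixels entering
#'   the neighborhood figure of merit (0 disables it).
#' @param artifactRemoval logical; detect and mask reflection artifacts.
#' @param outlierWindow odd window size for outlier detection (pixels).
#' @param outlierThreshold relative deviation from the window median above
#'   which a pixel counts as an outlier.
#' @param outlierIterations number of outlier-treatment passes.
#' @param seed integer seed for the stochastic stage.
#' @return a list of class \code{"FitConfig"}.
#' @export
fitConfig <- function(weighting = c("neyman", "pearson"),
                      fitInterval = c("decay_only", "full_signal"),
                      constraints = list(),
                      dePopulation = 20L, deGenerations = 60L,
                      nmMaxIter = 400L, nmTol = 1e-8,
                      neighborhood = 0L, artifactRemoval = TRUE,
                      outlierWindow = 7L, outlierThreshold = 0.30,
                      outlierIterations = 1L, seed = 1L) {
  weighting <- match.arg(weighting)
  fitInterval <- match.arg(fitInterval)
  if (outlierWindow %% 2 == 0 || outlierWindow < 3)
    stop("outlierWindow must be odd and >= 3")
  if (outlierThreshold <= 0) stop("outlierThreshold must be > 0")
  if (dePopulation < 5) stop("dePopulation must be >= 5")
  structure(list(weighting = weighting, fitInterval = fitInterval,
                 constraints = constraints, dePopulation = as.integer(dePopulation),
                 deGenerations = as.integer(deGenerations),
                 nmMaxIter = as.integer(nmMaxIter), nmTol = nmTol,
                 neighborhood = as.integer(neighborhood),
                 artifactRemoval = isTRUE(artifactRemoval),
                 outlierWindow = as.integer(outlierWindow),
                 outlierThreshold = outlierThreshold,
                 outlierIterations = as.integer(outlierIterations),
                 seed = as.integer(seed)),
            class = "FitConfig")
}

#' Residual weights for the figure of merit
#'
#' Neyman weighting sets the weight of each channel to the measured count
#' (the Poisson variance estimate), floored at 1 so empty channels do not
#' divide by zero. Pearson weighting uses the model counts instead and is
#' recomputed at every model evaluation.
#'
#' @param measured integer histogram (Neyman).
#' @param method \code{"neyman"} or \code{"pearson"}.
#' @param model model curve (required for Pearson).
#' @param eps floor for Pearson weights.
#' @return weight vector w(t_j).
#' @export
computeWeights <- function(measured, method = c("neyman", "pearson"),
                           model = NULL, eps = 1e-3) {
  method <- match.arg(method)
  if (method == "neyman") {
    pmax(measured, 1)
  } else {
    if (is.null(model)) stop("Pearson weighting needs the model curve")
    pmax(model, eps)
  }
}

#' Reduced chi-square figure of merit
#'
#' Weighted sum of squared residuals over the unmasked channels divided by
#' the degrees of freedom (channels used minus free parameters):
#' \code{chi2r = 1/(m - p) * sum (IM - IC)^2 / w}.
#'
#' @param measured measured counts per channel.
#' @param modeled model counts per channel.
#' @param weights channel weights (see \code{\link{computeWeights}}).
#' @param p number of free model parameters.
#' @param mask logical vector of channels to use (TRUE = use); NULL uses
#'   all channels. Reflection-artifact intervals are excluded this way —
#'   masking affects only the figure of merit, never the model curve.
#' @return the reduced chi-square.
#' @examples
#' reducedChi2(c(10, 10), c(8, 12), computeWeights(c(10, 10)), p = 1) # 0.8
#' @export
reducedChi2 <- function(measured, modeled, weights, p, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(measured))
  mUsed <- sum(mask)
  if (mUsed <= p)
    stop("degenerate degrees of freedom: channels used (", mUsed,
         ") must exceed free parameters (", p, ")")
  sum((measured[mask] - modeled[mask])^2 / weights[mask]) / (mUsed - p)
}

#' Neighborhood figure of merit
#'
#' Combines the central pixel's reduced chi-square with that of its
#' adjacent pixels evaluated under the central pixel's parameters:
#' \code{chi2rN = (chi2r_center)^2 + mean(chi2r_adjacent)}. Minimizing it
#' rewards parameters that also describe the neighborhood, yielding
#' spatially smoother lifetime maps.
#'
#' @param center reduced chi-square of the central pixel.
#' @param adjacent numeric vector of the adjacent pixels' reduced
#'   chi-squares (computed with the center's parameters).
#' @return the combined figure of merit.
#' @examples
#' neighborhoodChi2(1, c(1, 1, 1, 1))   # 2
#' @export
neighborhoodChi2 <- function(center, adjacent) {
  if (length(adjacent) < 1) stop("at least one adjacent pixel is required")
  center^2 + mean(adjacent)
}

#' Solve the linear parameters by weighted non-negative least squares
#'
#' For fixed nonlinear parameters the model is linear in the amplitudes,
#' the lens amplitude and the background, so they are solved in closed
#' form (variable projection): minimize
#' \code{sum w_j^-1 (measured_j - [basis %*% coef]_j)^2} subject to
#' non-negative coefficients. A constant column for the background is
#' appended to the basis.
#'
#' @param basis matrix of component (and lens) curves, one per column.
#' @param measured measured histogram.
#' @param weights channel weights.
#' @param mask logical channel mask (TRUE = use) or NULL.
#' @param background logical; include a constant background column.
#' @return named list: \code{coef} (per basis column), \code{b}, and
#'   \code{model} (full-length fitted curve).
#' @export
solveAmplitudes <- function(basis, measured, weights, mask = NULL,
                            background = TRUE) {
  basis <- as.matrix(basis)
  if (all(basis == 0)) stop("all-zero basis")
  if (is.null(mask)) mask <- rep(TRUE, length(measured))
  A <- basis
  if (background) A <- cbind(A, bg = 1)
  sw <- 1 / sqrt(weights[mask])
  Aw <- A[mask, , drop = FALSE] * sw
  yw <- measured[mask] * sw
  coef <- tryCatch(pracma::lsqnonneg(Aw, yw)$x,
                   error = function(e) NULL)
  if (is.null(coef)) {
    # collinear basis (e.g. two lifetimes proposed equal): fall back to a
    # ridge-regularized non-negative projection
    AtA <- crossprod(Aw)
    coef <- pmax(as.numeric(solve(AtA + diag(1e-8 * max(diag(AtA)),
                                             ncol(Aw)),
                                  crossprod(Aw, yw))), 0)
  }
  nb <- ncol(basis)
  list(coef = coef[seq_len(nb)],
       b = if (background) coef[nb + 1] else 0,
       model = as.numeric(A %*% coef))
}

# ---------------------------------------------------------------- optimizers

# Bound-constrained Nelder-Mead simplex: the standard reflect / expand /
# contract / shrink moves with every candidate vertex projected onto the
# box. Deterministic; returns the best vertex.
.nelderMeadBox <- function(fn, x0, lower, upper, maxIter = 400, tol = 1e-8) {
  n <- length(x0)
  proj <- function(x) pmin(pmax(x, lower), upper)
  x0 <- proj(x0)
  if (n == 0) return(list(par = x0, value = fn(x0), iterations = 0L,
                          converged = TRUE))
  step <- 0.05 * (upper - lower)
  step[step == 0] <- 1e-3
  simplex <- matrix(rep(x0, n + 1), nrow = n + 1, byrow = TRUE)
  for (i in seq_len(n)) {
    cand <- x0
    cand[i] <- if (x0[i] + step[i] <= upper[i]) x0[i] + step[i] else
      x0[i] - step[i]
    simplex[i + 1, ] <- proj(cand)
  }
  fv <- apply(simplex, 1, fn)
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]; fv <- fv[ord]
    if (diff(range(fv)) < tol * (abs(fv[1]) + tol)) { converged <- TRUE; break }
    centroid <- colMeans(simplex[seq_len(n), , drop = FALSE])
    worst <- simplex[n + 1, ]
    xr <- proj(centroid + (centroid - worst)); fr <- fn(xr)
    if (fr < fv[1]) {
      xe <- proj(centroid + 2 * (centroid - worst)); fe <- fn(xe)
      if (fe < fr) { simplex[n + 1, ] <- xe; fv[n + 1] <- fe }
      else { simplex[n + 1, ] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1, ] <- xr; fv[n + 1] <- fr
    } else {
      xc <- proj(centroid + 0.5 * (worst - centroid)); fc <- fn(xc)
      if (fc < fv[n + 1]) { simplex[n + 1, ] <- xc; fv[n + 1] <- fc }
      else {
        for (i in 2:(n + 1)) {
          simplex[i, ] <- proj(simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ]))
          fv[i] <- fn(simplex[i, ])
        }
      }
    }
  }
  best <- which.min(fv)
  list(par = simplex[best, ], value = fv[best], iterations = iter,
       converged = converged)
}

# Differential evolution (rand/1/bin) with box constraints by projection.
# Deterministic given the seed.
.diffEvolution <- function(fn, lower, upper, population = 20, generations = 60,
                           F = 0.8, CR = 0.9, seed = 1L) {
  n <- length(lower)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  pop <- matrix(stats::runif(population * n, rep(lower, each = population),
                             rep(upper, each = population)),
                nrow = population)
  fv <- apply(pop, 1, fn)
  for (g in seq_len(generations)) {
    for (i in seq_len(population)) {
      idx <- sample(setdiff(seq_len(population), i), 3)
      mutant <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
      cross <- stats::runif(n) < CR
      cross[sample.int(n, 1)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      ft <- fn(trial)
      if (ft <= fv[i]) { pop[i, ] <- trial; fv[i] <- ft }
    }
  }
  best <- which.min(fv)
  list(par = pop[best, ], value = fv[best])
}

# ------------------------------------------------------- parameter plumbing

# Free nonlinear parameters of a model: names, bounds, and packing between
# a flat vector theta and a ParamVector. Defaults give lifetimes a wide
# positive range; shifts a window around zero; beta in (0, 1].
.nonlinearLayout <- function(spec, constraints = list(), time = NULL) {
  dtSpan <- if (is.null(time)) 12500 else time@nChannels * time@channelWidth
  nm <- character(); lo <- numeric(); hi <- numeric()
  add <- function(name, dlo, dhi) {
    b <- constraints[[name]]
    if (is.null(b)) b <- c(dlo, dhi)
    if (length(b) == 1) b <- c(b, b)        # fixed value
    nm <<- c(nm, name); lo <<- c(lo, b[1]); hi <<- c(hi, b[2])
  }
  for (i in seq_len(spec@nComponents))
    add(paste0("tau", i), 5, 0.6 * dtSpan)
  if (hasShifts(spec))
    for (i in seq_len(spec@nComponents))
      add(paste0("tc", i), -500, 500)
  if (hasBeta(spec)) add("beta", 0.05, 1)
  if (hasLens(spec)) add("tcLens", -500, 500)
  free <- lo < hi
  list(names = nm, lower = lo, upper = hi, free = free)
}

.thetaToParams <- function(theta, layout, spec) {
  full <- ifelse(layout$free, NA, layout$lower)
  full[layout$free] <- theta
  names(full) <- layout$names
  g <- function(pat, default) {
    v <- full[grep(pat, names(full))]
    if (length(v)) unname(v) else default
  }
  n <- spec@nComponents
  paramVector(alpha = rep(1, n), tau = g("^tau[0-9]+$", 1000),
              tc = if (hasShifts(spec)) g("^tc[0-9]+$", 0) else rep(0, n),
              beta = g("^beta$", 1),
              tcLens = g("^tcLens$", 0))
}

# ----------------------------------------------------------- per-pixel fit

#' Fit one photon histogram
#'
#' Variable-projection fit of a decay model to a single histogram: the
#' nonlinear parameters (lifetimes, shifts, stretching exponent, lens
#' shift) are optimized by a bound-constrained minimizer, and at every
#' objective evaluation the linear parameters (amplitudes, lens amplitude,
#' background) are re-solved by weighted non-negative least squares. The
#' figure of merit is the reduced chi-square with the configured
#' weighting, over the configured fit interval minus any artifact
#' channels.
#'
#' @param histogram integer photon counts per channel.
#' @param spec a \code{\link{ModelSpec}}.
#' @param config a \code{\link{fitConfig}}.
#' @param init a \code{\link{ParamVector}} with starting nonlinear values.
#' @param irf an \code{\link{IRFCurve}}.
#' @param time a \code{\link{TimeAxis}}.
#' @param mask logical channel mask (TRUE = use) or NULL; combined with
#'   the fit-interval rule.
#' @param optimizer \code{"nelder_mead"} (deterministic, default) or
#'   \code{"de"} (differential evolution, seeded from \code{config$seed}).
#' @param adjacent optional list of adjacent pixels' histograms; when
#'   \code{config$neighborhood > 0} the objective becomes the neighborhood
#'   figure of merit (\code{\link{neighborhoodChi2}}).
#' @return list: \code{params} (full \code{\link{ParamVector}}),
#'   \code{chi2r}, \code{iterations}, \code{converged}, \code{mask},
#'   \code{p} (free-parameter count).
#' @export
minimizePixel <- function(histogram, spec, config, init, irf, time,
                          mask = NULL, optimizer = c("nelder_mead", "de"),
                          adjacent = NULL) {
  optimizer <- match.arg(optimizer)
  m <- time@nChannels
  useMask <- if (is.null(mask)) rep(TRUE, m) else mask
  if (config$fitInterval == "decay_only") {
    pk <- which.max(histogram)
    useMask <- useMask & (seq_len(m) >= pk)
  }
  layout <- .nonlinearLayout(spec, config$constraints, time)
  nLin <- spec@nComponents + 1L + (if (hasLens(spec)) 1L else 0L)
  p <- sum(layout$free) + nLin
  if (sum(useMask) <= p)
    stop("histogram has too few usable channels for ", p, " free parameters")
  wNey <- computeWeights(histogram, "neyman")
  useAdj <- config$neighborhood > 0 && length(adjacent) > 0
  if (useAdj) adjW <- lapply(adjacent, computeWeights, method = "neyman")

  evalTheta <- function(theta) {
    par <- .thetaToParams(theta, layout, spec)
    basis <- modelBasis(spec, par, irf, time)
    sol <- solveAmplitudes(basis, histogram, wNey, useMask)
    w <- wNey
    if (config$weighting == "pearson") {
      w <- computeWeights(histogram, "pearson", model = sol$model)
      sol <- solveAmplitudes(basis, histogram, w, useMask)
      w <- computeWeights(histogram, "pearson", model = sol$model)
    }
    chi <- reducedChi2(histogram, sol$model, w, p, useMask)
    list(par = par, sol = sol, basis = basis, chi = chi)
  }
  objective <- function(theta) {
    ev <- evalTheta(theta)
    if (!is.finite(ev$chi)) return(1e30)
    if (!useAdj) return(ev$chi)
    adjChi <- vapply(seq_along(adjacent), function(k) {
      solA <- solveAmplitudes(ev$basis, adjacent[[k]], adjW[[k]], useMask)
      reducedChi2(adjacent[[k]], solA$model, adjW[[k]], p, useMask)
    }, 0)
    neighborhoodChi2(ev$chi, adjChi)
  }

  theta0 <- c(init@tau[seq_len(spec@nComponents)],
              if (hasShifts(spec)) init@tc[seq_len(spec@nComponents)],
              if (hasBeta(spec)) init@beta,
              if (hasLens(spec)) init@tcLens)[layout$free]
  lower <- layout$lower[layout$free]; upper <- layout$upper[layout$free]
  if (optimizer == "nelder_mead") {
    opt <- .nelderMeadBox(objective, theta0, lower, upper,
                          maxIter = config$nmMaxIter, tol = config$nmTol)
  } else {
    opt <- .diffEvolution(objective, lower, upper,
                          population = config$dePopulation,
                          generations = config$deGenerations,
                          seed = config$seed)
    opt$iterations <- config$deGenerations
    opt$converged <- TRUE
  }
  ev <- evalTheta(opt$par)
  params <- methods::initialize(ev$par,
    alpha = ev$sol$coef[seq_len(spec@nComponents)],
    alphaLens = if (hasLens(spec)) ev$sol$coef[spec@nComponents + 1L] else 0,
    b = ev$sol$b)
  list(params = params, chi2r = ev$chi, iterations = opt$iterations,
       converged = isTRUE(opt$converged), mask = useMask, p = p)
}

#' Global initial solution from the image-integrated decay
#'
#' Runs the stochastic stage (differential evolution) on the sum of all
#' pixels' histograms — the stochastic minimizer is robust to the choice
#' of starting point but slow, so it is used once per image to provide the
#' starting point for the fast deterministic per-pixel fits.
#'
#' @param total the image-integrated histogram (see
#'   \code{\link{sumAllPixels}}).
#' @inheritParams minimizePixel
#' @param seed seed for the differential evolution (defaults to
#'   \code{config$seed}).
#' @return a full \code{\link{ParamVector}} fitted to the total decay.
#' @export
globalInit <- function(total, spec, config, irf, time, mask = NULL,
                       seed = config$seed) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  cfg$neighborhood <- 0L
  res <- minimizePixel(total, spec, cfg, paramVector(
    alpha = rep(1, spec@nComponents),
    tau = rep(1000, spec@nComponents)), irf, time, mask = mask,
    optimizer = "de")
  res$params
}

#' Detect reflection artifacts in the image-integrated decay
#'
#' Reflections in the optical pathway re-inject delayed photons, producing
#' bumps in the otherwise monotonically decreasing decay. The gradient of
#' the (moving-average smoothed) total decay is searched for sustained
#' rising sections strictly after the main fluorescence peak. For each
#' rise the start channel is refined on the raw curve (the local minimum
#' preceding the bump peak) and the artifact end is estimated as
#' \code{start + 3 * (peak - start)}; overlapping intervals are merged.
#' The intervals are meant to be excluded from the figure of merit only.
#'
#' @param total image-integrated histogram.
#' @param smooth moving-average window (channels) for the gradient search.
#' @param minRun minimum number of consecutive rising gradient channels.
#' @param minRise minimum rise amplitude in units of the Poisson standard
#'   deviation at the rise start; smaller fluctuations are counting
#'   noise, not reflections.
#' @return integer matrix with columns \code{start}, \code{end}: half-open
#'   channel intervals \code{[start, end)}, 1-based; zero rows when the
#'   decay is clean.
#' @export
detectReflectionArtifacts <- function(total, smooth = 5, minRun = 2,
                                      minRise = 3) {
  m <- length(total)
  s <- stats::filter(total, rep(1 / smooth, smooth), sides = 2)
  s[is.na(s)] <- total[is.na(s)]
  s <- as.numeric(s)
  peakMain <- which.max(s)
  g <- diff(s)
  # binned decays are over-dispersed (each photon enters several windows);
  # estimate the dispersion factor from successive differences after the
  # peak, where the decay slope is small relative to the noise
  tail <- seq(min(peakMain + 1, m), m - 1)
  phi <- 1
  if (length(tail) > 10) {
    dsq <- diff(total)[tail]^2
    expv <- total[tail] + total[tail + 1]
    phi <- max(1, stats::median(dsq / pmax(expv, 1)))
  }
  rising <- which(g > 0)
  rising <- rising[rising > peakMain]
  ivals <- NULL
  if (length(rising)) {
    runs <- split(rising, cumsum(c(1, diff(rising) != 1)))
    for (run in runs) {
      if (length(run) < minRun) next
      a <- run[1]; bEnd <- run[length(run)] + 1
      # refine the bump peak on the raw curve around the smoothed rise end
      pk <- min(bEnd, m)
      while (pk < m && total[pk + 1] > total[pk]) pk <- pk + 1
      while (pk > a && total[pk - 1] > total[pk]) pk <- pk - 1
      st <- pk
      while (st > peakMain + 1 && total[st - 1] < total[st]) st <- st - 1
      if (pk <= st) next
      if (total[pk] - total[st] <= minRise * sqrt(phi * max(total[st], 1)))
        next
      en <- min(st + 3L * (pk - st), m + 1L)
      ivals <- rbind(ivals, c(st, en))
    }
  }
  if (is.null(ivals))
    return(matrix(integer(), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  ivals <- ivals[order(ivals[, 1]), , drop = FALSE]
  merged <- ivals[1, , drop = FALSE]
  for (i in seq_len(nrow(ivals))[-1]) {
    last <- nrow(merged)
    if (ivals[i, 1] <= merged[last, 2])
      merged[last, 2] <- max(merged[last, 2], ivals[i, 2])
    else merged <- rbind(merged, ivals[i, ])
  }
  storage.mode(merged) <- "integer"
  dimnames(merged) <- list(NULL, c("start", "end"))
  merged
}

# Logical channel mask from artifact intervals (TRUE = keep).
.artifactMask <- function(intervals, m) {
  mask <- rep(TRUE, m)
  if (nrow(intervals))
    for (i in seq_len(nrow(intervals)))
      mask[seq(intervals[i, 1], min(intervals[i, 2] - 1L, m))] <- FALSE
  mask
}

.paramsToMaps <- function(spec) {
  n <- spec@nComponents
  c(paste0("alpha", seq_len(n)), paste0("tau", seq_len(n)),
    if (hasShifts(spec)) paste0("tc", seq_len(n)),
    if (hasBeta(spec)) "beta",
    if (hasLens(spec)) c("alphaLens", "tcLens"),
    "b")
}

.paramValue <- function(params, name) {
  if (grepl("^alpha[0-9]+$", name))
    params@alpha[as.integer(sub("alpha", "", name))]
  else if (grepl("^tau[0-9]+$", name))
    params@tau[as.integer(sub("tau", "", name))]
  else if (grepl("^tc[0-9]+$", name))
    params@tc[as.integer(sub("tc", "", name))]
  else slot(params, name)
}

.mapsToParams <- function(maps, spec, r, c) {
  n <- spec@nComponents
  g <- function(nm, default) if (nm %in% names(maps)) maps[[nm]][r, c] else default
  paramVector(
    alpha = vapply(seq_len(n), function(i) g(paste0("alpha", i), 1), 0),
    tau = pmax(vapply(seq_len(n), function(i) g(paste0("tau", i), 1000), 0), 1e-3),
    tc = vapply(seq_len(n), function(i) g(paste0("tc", i), 0), 0),
    beta = g("beta", 1), alphaLens = g("alphaLens", 0),
    tcLens = g("tcLens", 0), b = g("b", 0))
}

#' Two-stage fluorescence-lifetime fit of a whole image
#'
#' The canonical analysis chain for one (already binned) cube:
#' \enumerate{
#'   \item sum all pixels into a single best-SNR decay;
#'   \item detect reflection artifacts on it and build the channel mask;
#'   \item differential evolution on the total decay gives the global
#'     initial solution;
#'   \item every pixel is fit by bound-constrained Nelder-Mead starting
#'     from that solution (optionally with the neighborhood figure of
#'     merit);
#'   \item the iterative outlier treatment re-fits pixels that deviate
#'     from their window median.
#' }
#'
#' @param cube a \code{\link{TCSPCCube}} (typically after binning).
#' @param spec a \code{\link{ModelSpec}}.
#' @param config a \code{\link{fitConfig}}.
#' @param irf an \code{\link{IRFCurve}}.
#' @param radius optional adaptive-binning radius map to carry along.
#' @return a \code{\link{FitResultMaps}}.
#' @export
fitImage <- function(cube, spec, config = fitConfig(), irf, radius = NULL) {
  time <- cube@time
  d <- dim(cube@counts)
  total <- sumAllPixels(cube)
  artifacts <- if (config$artifactRemoval)
    detectReflectionArtifacts(total)
  else matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))
  chanMask <- .artifactMask(artifacts, time@nChannels)
  init <- globalInit(total, spec, config, irf, time, mask = chanMask)
  mapNamesAll <- .paramsToMaps(spec)
  maps <- stats::setNames(
    replicate(length(mapNamesAll), matrix(NA_real_, d[1], d[2]),
              simplify = FALSE), mapNamesAll)
  chi2 <- matrix(NA_real_, d[1], d[2])
  conv <- matrix(FALSE, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      adj <- NULL
      if (config$neighborhood > 0) {
        offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                      c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
        offs <- offs[seq_len(min(config$neighborhood, 8)), , drop = FALSE]
        adj <- list()
        for (i in seq_len(nrow(offs))) {
          rr <- r + offs[i, 1]; cc <- c + offs[i, 2]
          if (rr >= 1 && rr <= d[1] && cc >= 1 && cc <= d[2])
            adj[[length(adj) + 1]] <- cube@counts[rr, cc, ]
        }
      }
      res <- tryCatch(
        minimizePixel(cube@counts[r, c, ], spec, config, init, irf, time,
                      mask = chanMask, adjacent = adj),
        error = function(e) NULL)
      if (is.null(res)) next
      conv[r, c] <- res$converged
      chi2[r, c] <- res$chi2r
      for (nm in mapNamesAll)
        maps[[nm]][r, c] <- .paramValue(res$params, nm)
    }
  }
  maps$tauM <- .tauMFromMaps(maps, spec@nComponents)
  out <- FitResultMaps(maps, chi2, radius = radius, artifacts = artifacts,
                       provenance = list(model = spec@kind,
                                         nComponents = spec@nComponents,
                                         incompleteDecay = spec@incompleteDecay,
                                         config = unclass(config),
                                         seed = config$seed,
                                         converged = conv,
                                         init = init))
  if (config$outlierIterations > 0) {
    out <- treatOutliers(out, cube, spec, config, irf)$results
  }
  out
}

.tauMFromMaps <- function(maps, n) {
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    num <- num + maps[[paste0("alpha", i)]] * maps[[paste0("tau", i)]]
    den <- den + maps[[paste0("alpha", i)]]
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Iterative treatment of outlier pixels
#'
#' Slides a window over the lifetime maps and the reduced chi-square map;
#' a pixel whose value deviates from the window median by more than the
#' relative threshold in any inspected map is flagged. Flagged pixels are
#' re-fit starting from the parameters of the window's best
#' (lowest chi-square) pixel; the re-fit is kept only when its figure of
#' merit strictly improves, so the accepted chi-square never increases.
#'
#' @param results a \code{\link{FitResultMaps}} from \code{\link{fitImage}}.
#' @param cube the cube the results were fitted on.
#' @param spec,config,irf as in \code{\link{fitImage}}.
#' @return list: \code{results} (updated maps), \code{nDetected},
#'   \code{nImproved}.
#' @export
treatOutliers <- function(results, cube, spec, config, irf) {
  time <- cube@time
  d <- dim(results@chi2)
  half <- (config$outlierWindow - 1L) %/% 2L
  chanMask <- .artifactMask(results@artifacts, time@nChannels)
  inspect <- c(grep("^tau[0-9]+$", names(results@maps), value = TRUE))
  nDetTotal <- 0L; nImpTotal <- 0L
  maps <- results@maps; chi2 <- results@chi2
  for (it in seq_len(max(config$outlierIterations, 1L))) {
    flagged <- matrix(FALSE, d[1], d[2])
    for (r in seq_len(d[1])) {
      for (c in seq_len(d[2])) {
        rs <- max(1, r - half):min(d[1], r + half)
        cs <- max(1, c - half):min(d[2], c + half)
        for (nm in c(inspect, "chi2")) {
          M <- if (nm == "chi2") chi2 else maps[[nm]]
          win <- M[rs, cs]
          med <- stats::median(win, na.rm = TRUE)
          v <- M[r, c]
          if (is.finite(v) && is.finite(med) && med != 0 &&
              abs(v - med) / abs(med) > config$outlierThreshold) {
            flagged[r, c] <- TRUE
            break
          }
        }
      }
    }
    nDet <- sum(flagged)
    nImp <- 0L
    if (nDet > 0) {
      for (r in seq_len(d[1])) {
        for (c in seq_len(d[2])) {
          if (!flagged[r, c]) next
          rs <- max(1, r - half):min(d[1], r + half)
          cs <- max(1, c - half):min(d[2], c + half)
          winChi <- chi2[rs, cs]
          if (all(!is.finite(winChi))) next
          best <- which(winChi == min(winChi, na.rm = TRUE),
                        arr.ind = TRUE)[1, ]
          initP <- .mapsToParams(maps, spec, rs[best[1]], cs[best[2]])
          res <- tryCatch(
            minimizePixel(cube@counts[r, c, ], spec, config, initP, irf,
                          time, mask = chanMask),
            error = function(e) NULL)
          if (!is.null(res) && is.finite(res$chi2r) &&
              (!is.finite(chi2[r, c]) || res$chi2r < chi2[r, c])) {
            nImp <- nImp + 1L
            chi2[r, c] <- res$chi2r
            for (nm in names(maps))
              if (nm != "tauM")
                maps[[nm]][r, c] <- .paramValue(res$params, nm)
          }
        }
      }
    }
    nDetTotal <- nDetTotal + nDet
    nImpTotal <- nImpTotal + nImp
    if (nDet == 0) break
  }
  maps$tauM <- .tauMFromMaps(maps, spec@nComponents)
  prov <- results@provenance
  prov$outliersDetected <- nDetTotal
  prov$outliersImproved <- nImpTotal
  results <- methods::initialize(results, maps = maps, chi2 = chi2,
                                 provenance = prov)
  list(results = results, nDetected = nDetTotal, nImproved = nImpTotal)
}
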