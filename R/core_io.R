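#' @include AllClasses.R
NULL

# TIFF stores 32-bit float samples in [0, 1]; values are therefore written
# as (v - offset) / scale with offset and scale kept in the JSON sidecar.
.packRange <- function(v) {
  fin <- v[is.finite(v)]
  offset <- if (length(fin)) min(fin, 0) else 0
  scale <- if (length(fin)) max(fin - offset, 1) else 1
  list(offset = offset, scale = scale)
}

.writeMapTiff <- function(values, path, offset, scale) {
  w <- (values - offset) / scale
  w[!is.finite(w)] <- 0
  tiff::writeTIFF(w, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
}

#' Save a TCSPC cube to a multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float page per time channel; the acquisition metadata
#' (channel width, repetition period, pixel pitch, spectral band, count
#' scale) goes to \code{<path>.json}.
#'
#' @param cube a \code{\link{TCSPCCube}}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
saveCube <- function(cube, path) {
  a <- cube@counts
  scale <- max(a, 1)
  pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(n_channels = cube@time@nChannels,
               channel_width_ps = cube@time@channelWidth,
               rep_period_ns = cube@time@repPeriod,
               pixel_pitch_um = cube@pixelPitch,
               spectral_nm = cube@spectralRange,
               channel_id = cube@channelId,
               count_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a TCSPC cube
#'
#' Reads either the native container (multi-page 32-bit TIFF stack with a
#' \code{<path>.json} metadata sidecar, as written by
#' \code{\link{saveCube}}) or a toy CSV with one row per pixel
#' (columns \code{row}, \code{col}, then one column per time channel).
#' For CSV input the time axis must be supplied. Any cube violating a
#' class invariant (negative counts, inconsistent dimensions) is rejected
#' with an error, never silently clamped.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"tiff"} or
#'   \code{"csv"}.
#' @param time a \code{\link{TimeAxis}}, required for CSV input.
#' @return a \code{\link{TCSPCCube}}.
#' @export
loadCube <- function(path, format = c("auto", "tiff", "csv"), time = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tiff"
  if (format == "tiff") {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("metadata error: sidecar ", sidecar, " not found")
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    need <- c("n_channels", "channel_width_ps", "rep_period_ns",
              "pixel_pitch_um", "count_scale")
    miss <- setdiff(need, names(meta))
    if (length(miss))
      stop("metadata error: sidecar lacks ", paste(miss, collapse = ", "))
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != meta$n_channels)
      stop("format error: page count does not match n_channels")
    a <- array(0, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages))
      a[, , k] <- round(pages[[k]] * meta$count_scale)
    if (any(a < 0)) stop("format error: negative counts")
    ta <- TimeAxis(meta$n_channels, meta$channel_width_ps,
                   meta$rep_period_ns)
    TCSPCCube(a, ta,
              spectralRange = if (!is.null(meta$spectral_nm))
                meta$spectral_nm else c(NA_real_, NA_real_),
              pixelPitch = meta$pixel_pitch_um,
              channelId = if (!is.null(meta$channel_id))
                meta$channel_id else 1L)
  } else {
    if (is.null(time))
      stop("metadata error: CSV input needs an explicit TimeAxis")
    tab <- utils::read.csv(path)
    if (ncol(tab) != 2 + time@nChannels)
      stop("format error: expected columns row, col and one per channel")
    cnt <- as.matrix(tab[, -(1:2), drop = FALSE])
    if (any(cnt < 0)) stop("format error: negative counts")
    nr <- max(tab$row); nc <- max(tab$col)
    a <- array(0, c(nr, nc, time@nChannels))
    for (i in seq_len(nrow(tab)))
      a[tab$row[i], tab$col[i], ] <- cnt[i, ]
    TCSPCCube(a, time)
  }
}

#' Load a measured 1-D curve (IRF or lens decay)
#'
#' Reads a two-column text file (\code{time_ps}, \code{counts}) and
#' resamples it onto the channel centers of the stated time axis by
#' linear interpolation (zero outside the measured range). A curve whose
#' values are all zero is rejected.
#'
#' @param path input file (comma- or whitespace-separated, optional
#'   header).
#' @param time the target \code{\link{TimeAxis}}.
#' @param type \code{"irf"} or \code{"lens"}.
#' @param normalize logical; scale an IRF to unit sum on load.
#' @return an \code{\link{IRFCurve}} or \code{\link{LensDecay}}.
#' @export
loadCurve <- function(path, time, type = c("irf", "lens"),
                      normalize = FALSE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, sep = sep, header = header)
  if (ncol(tab) < 2) stop("format error: expected two columns")
  v <- stats::approx(tab[[1]], tab[[2]], xout = channelCenters(time),
                     rule = 1)$y
  v[is.na(v)] <- 0
  v[v < 0] <- 0
  if (all(v == 0)) stop("degenerate IRF: curve is all zero on the time axis")
  out <- if (type == "irf") IRFCurve(v, time) else LensDecay(v, time)
  if (normalize) out <- normalizeCurve(out)
  out
}

#' Save fit results to a directory
#'
#' Writes every parameter map (plus the chi-square and, if present, the
#' adaptive-radius map) as a single-page 32-bit float TIFF, a CSV of
#' per-map descriptive statistics, and a JSON provenance file holding the
#' model, configuration, seed, artifact intervals and the per-map
#' offset/scale (and non-finite cells) needed to reload the maps exactly.
#'
#' @param results a \code{\link{FitResultMaps}}.
#' @param outDir output directory (created if needed).
#' @return the manifest (named list of written files), invisibly.
#' @export
saveResults <- function(results, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  allMaps <- c(results@maps, list(chi2 = results@chi2))
  if (!is.null(results@radius)) allMaps$radius <- results@radius
  manifest <- list()
  mapMeta <- list()
  statRows <- list()
  for (nm in names(allMaps)) {
    M <- allMaps[[nm]]
    pk <- .packRange(M)
    f <- file.path(outDir, paste0(nm, ".tif"))
    .writeMapTiff(M, f, pk$offset, pk$scale)
    manifest[[nm]] <- f
    mapMeta[[nm]] <- list(offset = pk$offset, scale = pk$scale,
                          na_cells = which(!is.finite(M)))
    fin <- M[is.finite(M)]
    statRows[[nm]] <- data.frame(
      map = nm, mean = mean(fin), median = stats::median(fin),
      sd = if (length(fin) > 1) stats::sd(fin) else 0,
      min = min(fin), max = max(fin), n = length(fin))
  }
  statsFile <- file.path(outDir, "summary.csv")
  utils::write.csv(do.call(rbind, statRows), statsFile, row.names = FALSE)
  manifest$summary <- statsFile
  prov <- results@provenance
  prov$converged <- NULL                      # matrices do not belong in JSON
  prov$init <- NULL
  provFile <- file.path(outDir, "provenance.json")
  jsonlite::write_json(
    list(provenance = prov,
         artifacts = as.data.frame(results@artifacts),
         maps = mapMeta),
    provFile, auto_unbox = TRUE, digits = NA, null = "null")
  manifest$provenance <- provFile
  invisible(manifest)
}

#' Reload one map written by \code{\link{saveResults}}
#'
#' @param outDir the results directory.
#' @param name map name (e.g. \code{"tau1"}, \code{"chi2"}).
#' @return the numeric matrix, with non-finite cells restored to NA.
#' @export
loadResultMap <- function(outDir, name) {
  prov <- jsonlite::read_json(file.path(outDir, "provenance.json"),
                              simplifyVector = TRUE)
  meta <- prov$maps[[name]]
  if (is.null(meta)) stop("no map named '", name, "' in ", outDir)
  w <- tiff::readTIFF(file.path(outDir, paste0(name, ".tif")))
  M <- w * meta$scale + meta$offset
  if (length(meta$na_cells)) M[meta$na_cells] <- NA_real_
  M
}
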