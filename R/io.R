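# File formats: trace matrices (CSV), movies (multi-page TIFF + JSON
# sidecar), and run manifests.

#' Read a per-condition trace matrix
#'
#' Reads the cells x frames layout used for deposited single-cell trace
#' data: one row per cell, one column per frame, with a leading `trackId`
#' column and frame times encoded in the column headers (`t<hours>`).
#' Missing values mark invalid frames.
#'
#' @param file CSV path.
#' @param what Which series the matrix holds: `"cn"` or `"p53"`.
#' @param condition Condition label attached to the traces.
#' @param span Smoothing span applied on load.
#' @return A [KtrTraceSet-class].
#' @export
readTraceMatrix <- function(file, what = c("cn", "p53"),
                            condition = "cohort", span = 3) {
  what <- match.arg(what)
  df <- utils::read.csv(file, check.names = FALSE)
  if (!"trackId" %in% names(df)) .stopf("trace matrix needs a trackId column")
  tcols <- setdiff(names(df), "trackId")
  timeH <- suppressWarnings(as.numeric(sub("^t", "", tcols)))
  if (any(is.na(timeH)))
    .stopf("frame columns must be named t<hours>, e.g. t0, t0.133")
  m <- as.matrix(df[, tcols, drop = FALSE])
  if (!is.numeric(m)) .stopf("trace matrix must be numeric")
  dimnames(m) <- NULL
  args <- list(timeH = timeH, trackId = df$trackId, condition = condition,
               span = span)
  args[[if (what == "cn") "cnRaw" else "p53Raw"]] <- m
  do.call(ktrTraceSet, args)
}

#' Write a trace matrix
#'
#' Inverse of [readTraceMatrix()]; values are written at full precision
#' (15 significant digits) so a write/read round trip preserves traces.
#'
#' @param ts A [KtrTraceSet-class].
#' @param file Output CSV path.
#' @param assay Assay to write (default the raw C/N series).
#' @return `file`, invisibly.
#' @export
writeTraceMatrix <- function(ts, file, assay = "cnRaw") {
  m <- SummarizedExperiment::assay(ts, assay)
  df <- data.frame(trackId = trackId(ts),
                   signif(m, 15), check.names = FALSE)
  names(df)[-1] <- paste0("t", format(traceTimeH(ts), digits = 15,
                                      trim = TRUE, scientific = FALSE))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a movie as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered frame-major then channel ((f1,c1), (f1,c2), ...),
#' stored as 16-bit unsigned; the sidecar (`<file>.json`) records channel
#' roles, frame interval, page order, and the intensity scale used, so
#' [readMovieTiff()] can reconstruct the stack.
#'
#' @param movie A [MovieStack-class].
#' @param file Output TIFF path.
#' @return `file`, invisibly.
#' @export
writeMovieTiff <- function(movie, file) {
  d <- movie@data
  lo <- min(d); hi <- max(d)
  scale <- if (hi > lo) 65535 / (hi - lo) else 1
  pages <- list()
  for (f in seq_len(dim(d)[1])) for (ch in seq_len(dim(d)[2]))
    pages[[length(pages) + 1L]] <-
      round((d[f, ch, , ] - lo) * scale) / 65535
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  side <- list(channels = movie@channels,
               frameIntervalMin = movie@frameIntervalMin,
               nFrames = dim(d)[1], pageOrder = "frame-major",
               intensityOffset = lo, intensityScale = scale)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read a movie written by [writeMovieTiff()]
#'
#' @param file TIFF path (sidecar `<file>.json` must exist).
#' @return A [MovieStack-class] with intensities restored to their
#'   original scale.
#' @export
readMovieTiff <- function(file) {
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(file, all = TRUE)
  nc <- length(side$channels)
  nf <- side$nFrames
  shp <- dim(pages[[1]])
  d <- array(0, dim = c(nf, nc, shp[1], shp[2]))
  k <- 1L
  for (f in seq_len(nf)) for (ch in seq_len(nc)) {
    d[f, ch, , ] <- pages[[k]] * 65535 / side$intensityScale +
      side$intensityOffset
    k <- k + 1L
  }
  movieStack(d, channels = side$channels,
             frameIntervalMin = side$frameIntervalMin)
}

#' Write a run manifest
#'
#' Records package version, seed, configuration, and an MD5 of the
#' serialized configuration, so every output of a run is regenerable from
#' the manifest alone.
#'
#' @param config Configuration list.
#' @param seed Integer seed.
#' @param outDir Output directory.
#' @return Manifest path, invisibly.
#' @export
writeManifest <- function(config, seed, outDir) {
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE)
  tmp <- tempfile(); writeLines(cfgJson, tmp)
  manifest <- list(
    package = "ktrdyn",
    version = as.character(utils::packageVersion("ktrdyn")),
    seed = seed,
    configMd5 = unname(tools::md5sum(tmp)),
    config = jsonlite::fromJSON(cfgJson, simplifyVector = TRUE))
  unlink(tmp)
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
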