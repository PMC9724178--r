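#' Container for single-cell traces (cells x frames)
#'
#' `KtrTraceSet` extends [SummarizedExperiment::SummarizedExperiment] with
#' cells as rows and frames as columns. Assays hold raw and smoothed nuclear
#' p53 mean intensity (`p53Raw`, `p53Smooth`), raw and smoothed KTR C/N
#' ratio (`cnRaw`, `cnSmooth`), and a logical `valid` mask. Invalid frames
#' (empty ring, lost track, frames at or after a flagged death) carry `NA`
#' in the value assays. `rowData` stores `trackId`, `deathFrame` (1-based
#' frame of death, `NA` for survivors), `fate`, and `condition`; `colData`
#' stores `frame` and `timeH` (hours post-treatment, frame 1 at 0).
#'
#' @slot int_elementMetadata,int_colData,int_metadata Inherited.
#' @name KtrTraceSet-class
#' @aliases KtrTraceSet
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("KtrTraceSet", contains = "SummarizedExperiment")

#' Build a KtrTraceSet from trace matrices
#'
#' Smoothed assays are computed with [smoothTrace()] at `span` (the
#' three-window moving mean by default). Frames at or after a cell's
#' `deathFrame` are marked invalid.
#'
#' @param cnRaw,p53Raw Cells x frames numeric matrices (either may be
#'   omitted; missing values are treated as invalid frames).
#' @param timeH Frame times in hours (length = ncol).
#' @param trackId Integer/character ids, one per row.
#' @param deathFrame Integer death frame per cell (`NA` = survivor).
#' @param fate Optional fate labels; defaults to `"dying"` where
#'   `deathFrame` is set, `"surviving"` otherwise.
#' @param condition Condition label (recycled).
#' @param valid Optional logical matrix; defaults to finite values.
#' @param span Smoothing span (odd, >= 1).
#' @return A [KtrTraceSet-class].
#' @examples
#' cn <- rbind(c(1, 2, 3, 2), c(1, 1, 1, 1))
#' ts <- ktrTraceSet(cnRaw = cn, timeH = c(0, 1, 2, 3), trackId = 1:2)
#' cnSmooth(ts)
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
ktrTraceSet <- function(cnRaw = NULL, p53Raw = NULL, timeH,
                        trackId = NULL, deathFrame = NULL, fate = NULL,
                        condition = "cohort", valid = NULL, span = 3) {
  template <- if (!is.null(cnRaw)) cnRaw else p53Raw
  if (is.null(template)) .stopf("need at least one of cnRaw, p53Raw")
  nc <- nrow(template); nf <- ncol(template)
  if (length(timeH) != nf) .stopf("timeH must have one entry per frame")
  if (is.null(cnRaw)) cnRaw <- matrix(NA_real_, nc, nf)
  if (is.null(p53Raw)) p53Raw <- matrix(NA_real_, nc, nf)
  if (is.null(trackId)) trackId <- seq_len(nc)
  if (is.null(deathFrame)) deathFrame <- rep(NA_integer_, nc)
  if (is.null(fate))
    fate <- ifelse(is.na(deathFrame), "surviving", "dying")
  if (is.null(valid)) valid <- is.finite(cnRaw) | is.finite(p53Raw)

  # death truncation: frames at/after death are invalid
  for (i in seq_len(nc)) {
    if (!is.na(deathFrame[i]) && deathFrame[i] <= nf)
      valid[i, deathFrame[i]:nf] <- FALSE
  }
  cnRaw[!valid] <- NA_real_
  p53Raw[!valid] <- NA_real_

  cnSm <- t(apply(cnRaw, 1L, smoothTrace, span = span))
  p53Sm <- t(apply(p53Raw, 1L, smoothTrace, span = span))
  dim(cnSm) <- dim(p53Sm) <- c(nc, nf)

  rd <- S4Vectors::DataFrame(trackId = trackId,
                             deathFrame = as.integer(deathFrame),
                             fate = fate,
                             condition = rep_len(condition, nc))
  cd <- S4Vectors::DataFrame(frame = seq_len(nf), timeH = as.numeric(timeH))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cnRaw = cnRaw, cnSmooth = cnSm,
                  p53Raw = p53Raw, p53Smooth = p53Sm, valid = valid),
    rowData = rd, colData = cd)
  S4Vectors::metadata(se)$smoothingSpan <- span
  new("KtrTraceSet", se)
}

#' @param x A `KtrTraceSet`.
#' @return Accessors return the corresponding assay matrix or annotation
#'   vector.
#' @rdname KtrTraceSet-class
#' @export
cnRaw <- function(x) SummarizedExperiment::assay(x, "cnRaw")

#' @rdname KtrTraceSet-class
#' @export
cnSmooth <- function(x) SummarizedExperiment::assay(x, "cnSmooth")

#' @rdname KtrTraceSet-class
#' @export
p53Raw <- function(x) SummarizedExperiment::assay(x, "p53Raw")

#' @rdname KtrTraceSet-class
#' @export
p53Smooth <- function(x) SummarizedExperiment::assay(x, "p53Smooth")

#' @rdname KtrTraceSet-class
#' @export
traceValid <- function(x) SummarizedExperiment::assay(x, "valid")

#' @rdname KtrTraceSet-class
#' @export
traceTimeH <- function(x) SummarizedExperiment::colData(x)$timeH

#' @rdname KtrTraceSet-class
#' @export
deathFrame <- function(x) SummarizedExperiment::rowData(x)$deathFrame

#' @rdname KtrTraceSet-class
#' @export
fate <- function(x) SummarizedExperiment::rowData(x)$fate

#' @param value Replacement fate vector.
#' @rdname KtrTraceSet-class
#' @export
`fate<-` <- function(x, value) {
  SummarizedExperiment::rowData(x)$fate <- value
  x
}

#' @rdname KtrTraceSet-class
#' @export
trackId <- function(x) SummarizedExperiment::rowData(x)$trackId

setMethod("show", "KtrTraceSet", function(object) {
  cat("KtrTraceSet:", nrow(object), "cells x", ncol(object), "frames (",
      sum(fate(object) == "dying"), "dying ).",
      "Assays:", paste(SummarizedExperiment::assayNames(object),
                       collapse = ", "), "\n")
})
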