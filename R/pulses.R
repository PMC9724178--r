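# Pulse detection with a cohort-calibrated prominence threshold, and
# per-cell dynamic feature extraction.

#' Cohort-calibrated minimum peak prominence
#'
#' To avoid calling noise excursions pulses, the minimum prominence is set
#' per condition to half the span between the cohort's median basal value
#' (the frame-1, pre-treatment value of each cell) and its median peak
#' value (each cell's trace maximum): `theta = 0.5 * (medianPeak -
#' medianBasal)`, floored at zero. `peakSummary = "global_max"` replaces
#' the median of per-cell maxima by the single largest maximum across the
#' cohort (an alternative reading of "peak expression of all cells").
#'
#' @param traces Cells x frames numeric matrix (NA = invalid frame), or a
#'   [KtrTraceSet-class] (then `assay` selects the series).
#' @param condition Label recorded in the result.
#' @param peakSummary `"median"` (default) or `"global_max"`.
#' @param assay Assay name when `traces` is a `KtrTraceSet`.
#' @return A [ProminenceThreshold-class].
#' @examples
#' m <- rbind(c(1, 3, 1), c(1, 3, 1))
#' cohortProminenceThreshold(m)  # theta = 1
#' @export
cohortProminenceThreshold <- function(traces, condition = "cohort",
                                      peakSummary = c("median", "global_max"),
                                      assay = "cnSmooth") {
  peakSummary <- match.arg(peakSummary)
  if (is(traces, "KtrTraceSet"))
    traces <- SummarizedExperiment::assay(traces, assay)
  if (!is.matrix(traces)) traces <- matrix(traces, nrow = 1)
  basal <- traces[, 1]
  peaks <- suppressWarnings(apply(traces, 1, max, na.rm = TRUE))
  ok <- is.finite(basal) & is.finite(peaks)
  if (!any(ok)) .stopf("no valid traces (finite basal and peak required)")
  mb <- stats::median(basal[ok])
  mp <- if (peakSummary == "median") stats::median(peaks[ok])
        else max(peaks[ok])
  new("ProminenceThreshold", condition = condition,
      theta = max(0, 0.5 * (mp - mb)), medianBasal = mb, medianPeak = mp,
      nCellsUsed = sum(ok))
}

# Interior local maxima of a numeric vector, with plateau handling: a run
# of equal values is a maximum iff the values immediately before and after
# the run are strictly lower; its representative index is the run middle.
# Endpoints are never maxima (a monotone rise ending at the final frame is
# not a pulse).
.localMaxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  runEnds <- c(which(diff(v) != 0), n)
  runStarts <- c(1L, head(runEnds, -1L) + 1L)
  out <- integer()
  for (r in seq_along(runStarts)) {
    s <- runStarts[r]; e <- runEnds[r]
    if (s == 1L || e == n) next
    if (v[s - 1L] < v[s] && v[e + 1L] < v[e])
      out <- c(out, s + (e - s) %/% 2L)
  }
  out
}

# Topographic prominence of the local maximum at index p: walk outward in
# each direction until a strictly higher point (or the trace end), taking
# the minimum en route; prominence is the peak height above the higher of
# the two valley minima.
.prominence <- function(v, p) {
  h <- v[p]
  left <- Inf
  j <- p - 1L
  while (j >= 1L && v[j] <= h) { left <- min(left, v[j]); j <- j - 1L }
  if (!is.finite(left)) left <- h
  right <- Inf
  j <- p + 1L
  while (j <= length(v) && v[j] <= h) { right <- min(right, v[j]); j <- j + 1L }
  if (!is.finite(right)) right <- h
  h - max(left, right)
}

# Full width at half prominence, linearly interpolated; clipped at the
# trace ends.
.fwhp <- function(v, timeH, p, prom) {
  level <- v[p] - prom / 2
  tl <- timeH[1]
  j <- p - 1L
  while (j >= 1L && v[j] > level) j <- j - 1L
  if (j >= 1L) tl <- .crossTime(timeH[j], v[j], timeH[j + 1L], v[j + 1L],
                                level)
  tr <- timeH[length(v)]
  j <- p + 1L
  while (j <= length(v) && v[j] > level) j <- j + 1L
  if (j <= length(v)) tr <- .crossTime(timeH[j - 1L], v[j - 1L], timeH[j],
                                       v[j], level)
  tr - tl
}

#' Detect activity pulses in one trace
#'
#' Finds interior local maxima whose topographic prominence (peak value
#' minus the higher of the two minimal valleys separating it from higher
#' terrain or the trace ends) reaches the threshold. Pulse duration is the
#' full width at half prominence, linearly interpolated between frames.
#' Invalid (`NA`) frames are dropped and detection runs on the remaining
#' series with its original time stamps.
#'
#' @param values Numeric trace (NA = invalid frame).
#' @param timeH Frame times in hours (same length).
#' @param theta Minimum prominence — a number or a
#'   [ProminenceThreshold-class].
#' @return `data.frame` of pulse records ordered by time: `peakFrame`
#'   (index into `values`), `peakTimeH`, `amplitude` (trace value at the
#'   peak), `prominence`, `durationH`. Zero rows when nothing qualifies.
#' @examples
#' t <- seq(0, 24, by = 8 / 60)
#' v <- 1 + 2 * exp(-4 * log(2) * ((t - 6) / 1)^2)
#' detectPulses(v, t, theta = 0.5)
#' @export
detectPulses <- function(values, timeH, theta) {
  if (is(theta, "ProminenceThreshold")) theta <- theta@theta
  if (!.isScalarNum(theta) || theta < 0) .stopf("theta must be >= 0")
  ok <- is.finite(values)
  empty <- data.frame(peakFrame = integer(), peakTimeH = numeric(),
                      amplitude = numeric(), prominence = numeric(),
                      durationH = numeric())
  if (sum(ok) < 3L) return(empty)
  v <- values[ok]; t <- timeH[ok]
  frameIdx <- which(ok)
  peaks <- .localMaxima(v)
  if (!length(peaks)) return(empty)
  prom <- vapply(peaks, function(p) .prominence(v, p), 0)
  sel <- prom >= theta & prom > 0
  if (!any(sel)) return(empty)
  peaks <- peaks[sel]; prom <- prom[sel]
  data.frame(peakFrame = frameIdx[peaks], peakTimeH = t[peaks],
             amplitude = v[peaks], prominence = prom,
             durationH = vapply(seq_along(peaks), function(i)
               .fwhp(v, t, peaks[i], prom[i]), 0))
}

#' Scalar dynamic features of one trace
#'
#' Maximum value and its timing over valid frames, pulse count within the
#' acquisition window, basal (frame-1) value, and the integrated level.
#'
#' @param values,timeH Trace and frame times.
#' @param pulses [detectPulses()] result for this trace.
#' @return One-row `data.frame`: `nPulses`, `maxValue`, `timeOfMaxH`,
#'   `integratedLevel`, `basal`, `nValidFrames`.
#' @export
summarizeFeatures <- function(values, timeH, pulses) {
  ok <- is.finite(values)
  if (sum(ok) < 2L)
    return(data.frame(nPulses = nrow(pulses), maxValue = NA_real_,
                      timeOfMaxH = NA_real_, integratedLevel = NA_real_,
                      basal = NA_real_, nValidFrames = sum(ok)))
  v <- values[ok]; t <- timeH[ok]
  imax <- which.max(v)
  data.frame(nPulses = nrow(pulses), maxValue = v[imax],
             timeOfMaxH = t[imax],
             integratedLevel = integrateTrace(values, timeH),
             basal = values[1], nValidFrames = sum(ok))
}

#' Trapezoidal integral of a trace over its valid frames
#'
#' @param values Numeric trace (NA = invalid frame).
#' @param timeH Frame times in hours.
#' @return The integral in value-hours, or `NA_real_` with a warning when
#'   fewer than 2 valid frames exist. Cells with invalid tails (e.g. early
#'   death) integrate over their valid window only.
#' @examples
#' t <- seq(0, 24, by = 8 / 60)
#' integrateTrace(rep(1, length(t)), t)  # 24
#' @export
integrateTrace <- function(values, timeH) {
  ok <- is.finite(values)
  if (sum(ok) < 2L) {
    warning("fewer than 2 valid frames: integral undefined")
    return(NA_real_)
  }
  pracma::trapz(timeH[ok], values[ok])
}

#' Pulse features for every cell of a trace set
#'
#' Applies the cohort prominence calibration and per-cell detection /
#' summarisation to one assay of a [KtrTraceSet-class].
#'
#' @param ts A [KtrTraceSet-class].
#' @param assay Assay to analyse (default `"cnSmooth"`; features are
#'   computed on the smoothed series by default so one canonical trace
#'   feeds both plots and features).
#' @param threshold Optional [ProminenceThreshold-class]; computed from
#'   the cohort if omitted.
#' @param peakSummary Passed to [cohortProminenceThreshold()].
#' @return List: `features` (one row per cell, with `trackId`, `fate`,
#'   `deathFrame`, `condition` merged in), `pulses` (one row per pulse,
#'   with `trackId`), and `threshold`.
#' @export
pulseFeatureTable <- function(ts, assay = "cnSmooth", threshold = NULL,
                              peakSummary = "median") {
  m <- SummarizedExperiment::assay(ts, assay)
  t <- traceTimeH(ts)
  if (is.null(threshold))
    threshold <- cohortProminenceThreshold(
      m, condition = SummarizedExperiment::rowData(ts)$condition[1],
      peakSummary = peakSummary)
  feats <- vector("list", nrow(m))
  puls <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    p <- detectPulses(m[i, ], t, threshold)
    f <- summarizeFeatures(m[i, ], t, p)
    f$trackId <- trackId(ts)[i]
    feats[[i]] <- f
    if (nrow(p)) puls[[i]] <- cbind(trackId = trackId(ts)[i], p)
  }
  features <- do.call(rbind, feats)
  features$fate <- fate(ts)
  features$deathFrame <- deathFrame(ts)
  features$condition <- SummarizedExperiment::rowData(ts)$condition
  pulses <- do.call(rbind, puls)
  if (is.null(pulses))
    pulses <- data.frame(trackId = integer(), peakFrame = integer(),
                         peakTimeH = numeric(), amplitude = numeric(),
                         prominence = numeric(), durationH = numeric())
  list(features = features, pulses = pulses, threshold = threshold)
}
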