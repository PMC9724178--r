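#' @import methods
NULL

# ---------------------------------------------------------------------------
# AcquisitionSpec
# ---------------------------------------------------------------------------

#' Acquisition geometry of a live-cell imaging run
#'
#' Captures the imaging schedule and field geometry: one frame every
#' `frameIntervalMin` minutes over `durationH` hours (frame 1 is the
#' pre-treatment baseline; the stimulus is added between frames 1 and 2),
#' on a field of `imageShape` pixels, aiming for at least `nCells` cells
#' per condition.
#'
#' @slot frameIntervalMin Minutes between frames (default 8).
#' @slot durationH Total imaging duration in hours (default 24).
#' @slot imageShape Integer `(height, width)` of the field in pixels.
#' @slot nCells Target number of cells per condition (default 40).
#'
#' @examples
#' acq <- acquisitionSpec()
#' nFrames(acq)      # 181 frames: 24 h at 8-min intervals plus frame 1
#' head(timePoints(acq))
#' @name AcquisitionSpec-class
#' @aliases AcquisitionSpec
#' @export
setClass("AcquisitionSpec",
  representation(
    frameIntervalMin = "numeric",
    durationH = "numeric",
    imageShape = "integer",
    nCells = "integer"
  )
)

setValidity("AcquisitionSpec", function(object) {
  msg <- character()
  if (!.isScalarNum(object@frameIntervalMin) || object@frameIntervalMin <= 0)
    msg <- c(msg, "frameIntervalMin must be a positive number")
  if (!.isScalarNum(object@durationH) || object@durationH <= 0)
    msg <- c(msg, "durationH must be a positive number")
  if (length(object@imageShape) != 2L || any(object@imageShape <= 0L))
    msg <- c(msg, "imageShape must be two positive integers (height, width)")
  if (length(object@nCells) != 1L || object@nCells < 1L)
    msg <- c(msg, "nCells must be a positive integer")
  if (length(msg) == 0L &&
      floor(object@durationH * 60 / object@frameIntervalMin) + 1 < 2)
    msg <- c(msg, "acquisition must span at least 2 frames")
  if (length(msg)) msg else TRUE
})

#' @param frameIntervalMin Minutes between frames.
#' @param durationH Total duration in hours.
#' @param imageShape Height and width of the field, pixels.
#' @param nCells Target cells per condition.
#' @rdname AcquisitionSpec-class
#' @export
acquisitionSpec <- function(frameIntervalMin = 8, durationH = 24,
                            imageShape = c(256L, 256L), nCells = 40L) {
  new("AcquisitionSpec",
      frameIntervalMin = as.numeric(frameIntervalMin),
      durationH = as.numeric(durationH),
      imageShape = as.integer(imageShape),
      nCells = as.integer(nCells))
}

#' @param acq,object An `AcquisitionSpec`.
#' @return `nFrames()` the number of frames; `timePoints()` the frame times
#'   in hours post-treatment (frame 1 at t = 0).
#' @rdname AcquisitionSpec-class
#' @export
nFrames <- function(acq) {
  as.integer(floor(acq@durationH * 60 / acq@frameIntervalMin) + 1)
}

#' @rdname AcquisitionSpec-class
#' @export
timePoints <- function(acq) {
  (seq_len(nFrames(acq)) - 1) * acq@frameIntervalMin / 60
}

setMethod("show", "AcquisitionSpec", function(object) {
  cat("AcquisitionSpec:", nFrames(object), "frames,",
      object@frameIntervalMin, "min interval,", object@durationH, "h,",
      paste(object@imageShape, collapse = "x"), "px field\n")
})

# ---------------------------------------------------------------------------
# TraceModel
# ---------------------------------------------------------------------------

#' Generative model for one single-cell activity or expression trace
#'
#' The noiseless trace is the sum of a constant baseline, Gaussian-shaped
#' pulses (parameterised by peak time, amplitude, and full width at half
#' maximum), and a linear ramp. The `kind` field selects the phenomenology
#' being emulated:
#' \describe{
#'   \item{flat}{baseline only.}
#'   \item{pulsatile}{baseline + the pulses in `pulses` (JNK/ERK-like
#'     repeated activation).}
#'   \item{sustained_single_peak}{one broad pulse (p38-like sustained
#'     activity).}
#'   \item{oscillatory}{a regular pulse train of period `periodH` and
#'     amplitude `oscAmplitude` (low-dose p53-like oscillations); the train
#'     is expanded into `pulses` at simulation time.}
#'   \item{rising}{baseline + `rampRate` * t (high-dose p53-like monotone
#'     accumulation).}
#' }
#' Noise is applied after the deterministic part: a multiplicative
#' lognormal factor with coefficient of variation `noiseCvMult`
#' (expression variability) followed by additive Gaussian noise with sd
#' `noiseSdAdd` (measurement noise).
#'
#' @slot kind One of `"flat"`, `"pulsatile"`, `"sustained_single_peak"`,
#'   `"oscillatory"`, `"rising"`.
#' @slot baseline Dimensionless baseline level, > 0.
#' @slot pulses `data.frame` with columns `peakTimeH`, `amplitude`, `fwhmH`.
#' @slot rampRate Level per hour added linearly (rising kind).
#' @slot noiseSdAdd Additive Gaussian noise sd, >= 0.
#' @slot noiseCvMult Multiplicative lognormal coefficient of variation, >= 0.
#' @slot periodH Oscillation period in hours (oscillatory kind).
#' @slot oscAmplitude Oscillation pulse amplitude (oscillatory kind).
#' @name TraceModel-class
#' @aliases TraceModel
#' @export
setClass("TraceModel",
  representation(
    kind = "character",
    baseline = "numeric",
    pulses = "data.frame",
    rampRate = "numeric",
    noiseSdAdd = "numeric",
    noiseCvMult = "numeric",
    periodH = "numeric",
    oscAmplitude = "numeric"
  )
)

.traceModelKinds <- c("flat", "pulsatile", "sustained_single_peak",
                      "oscillatory", "rising")

setValidity("TraceModel", function(object) {
  msg <- character()
  if (!object@kind %in% .traceModelKinds)
    msg <- c(msg, paste("kind must be one of:",
                        paste(.traceModelKinds, collapse = ", ")))
  if (!.isScalarNum(object@baseline) || object@baseline <= 0)
    msg <- c(msg, "baseline must be > 0")
  p <- object@pulses
  if (nrow(p)) {
    if (!all(c("peakTimeH", "amplitude", "fwhmH") %in% names(p)))
      msg <- c(msg, "pulses needs columns peakTimeH, amplitude, fwhmH")
    else {
      if (any(p$amplitude < 0)) msg <- c(msg, "pulse amplitudes must be >= 0")
      if (any(p$fwhmH <= 0)) msg <- c(msg, "pulse fwhmH must be > 0")
      if (any(p$peakTimeH < 0)) msg <- c(msg, "pulse peakTimeH must be >= 0")
    }
  }
  if (object@noiseSdAdd < 0 || object@noiseCvMult < 0)
    msg <- c(msg, "noise parameters must be >= 0")
  if (object@kind == "oscillatory" &&
      (!.isScalarNum(object@periodH) || object@periodH <= 0))
    msg <- c(msg, "oscillatory kind requires periodH > 0")
  if (length(msg)) msg else TRUE
})

#' @param kind,baseline,pulses,rampRate,noiseSdAdd,noiseCvMult,periodH,oscAmplitude
#'   See slots.
#' @rdname TraceModel-class
#' @export
traceModel <- function(kind = "flat", baseline = 1, pulses = NULL,
                       rampRate = 0, noiseSdAdd = 0, noiseCvMult = 0,
                       periodH = 5.5, oscAmplitude = 1) {
  if (is.null(pulses))
    pulses <- data.frame(peakTimeH = numeric(), amplitude = numeric(),
                         fwhmH = numeric())
  new("TraceModel", kind = kind, baseline = as.numeric(baseline),
      pulses = as.data.frame(pulses), rampRate = as.numeric(rampRate),
      noiseSdAdd = as.numeric(noiseSdAdd),
      noiseCvMult = as.numeric(noiseCvMult),
      periodH = as.numeric(periodH), oscAmplitude = as.numeric(oscAmplitude))
}

setMethod("show", "TraceModel", function(object) {
  cat("TraceModel<", object@kind, ">: baseline ", object@baseline,
      ", ", nrow(object@pulses), " pulse(s), ramp ", object@rampRate,
      "/h, noise (add ", object@noiseSdAdd, ", cv ", object@noiseCvMult,
      ")\n", sep = "")
})

# ---------------------------------------------------------------------------
# CellSimSpec
# ---------------------------------------------------------------------------

#' Specification of one simulated cell
#'
#' Geometry, motion, generative trace models, reporter level, and fate of a
#' single simulated cell. The rendered cell consists of a nuclear disk of
#' radius `nucleusRadiusPx` and a cytoplasmic annulus extending to
#' `cytoRadiusPx`; the annulus must extend beyond the downstream ring width
#' so that the measured cytoplasmic ring lies inside true cytoplasm. The
#' nucleus random-walks with per-frame step sd `motionSdPxPerFrame`,
#' reflected inside a home box of half-width `motionBoxPx` around the
#' initial position (adherent cells wander locally rather than diffusing
#' across the field). Dying cells (`fate == "dying"`) carry a `deathTimeH`
#' at which the rendered nucleus rounds up and loses fluorescence.
#'
#' @slot cellId Integer id, unique within a cohort.
#' @slot center Numeric `(y, x)` initial nucleus centre, pixels.
#' @slot nucleusRadiusPx,cytoRadiusPx Nuclear / outer cytoplasmic radius.
#' @slot motionSdPxPerFrame Random-walk step sd, px per frame.
#' @slot motionBoxPx Half-width of the home box for the walk, px.
#' @slot p53Model,kinaseModel `TraceModel`s for nuclear p53 and kinase
#'   activity.
#' @slot ktrTotalLevel Total KTR reporter amount (intensity x px).
#' @slot h2bLevel H2B nuclear marker intensity (per px).
#' @slot deathTimeH Hours post-treatment at which the cell dies, or `NA`.
#' @slot fate `"dying"` or `"surviving"`.
#' @name CellSimSpec-class
#' @aliases CellSimSpec
#' @export
setClass("CellSimSpec",
  representation(
    cellId = "integer",
    center = "numeric",
    nucleusRadiusPx = "numeric",
    cytoRadiusPx = "numeric",
    motionSdPxPerFrame = "numeric",
    motionBoxPx = "numeric",
    p53Model = "TraceModel",
    kinaseModel = "TraceModel",
    ktrTotalLevel = "numeric",
    h2bLevel = "numeric",
    deathTimeH = "numeric",
    fate = "character"
  )
)

setValidity("CellSimSpec", function(object) {
  msg <- character()
  if (object@cytoRadiusPx <= object@nucleusRadiusPx)
    msg <- c(msg, "cytoRadiusPx must exceed nucleusRadiusPx")
  if (!object@fate %in% c("dying", "surviving"))
    msg <- c(msg, "fate must be 'dying' or 'surviving'")
  dying <- identical(object@fate, "dying")
  if (dying != !is.na(object@deathTimeH))
    msg <- c(msg, "deathTimeH must be set iff fate is 'dying'")
  if (length(msg)) msg else TRUE
})

#' @param cellId,center,nucleusRadiusPx,cytoRadiusPx,motionSdPxPerFrame,motionBoxPx,p53Model,kinaseModel,ktrTotalLevel,h2bLevel,deathTimeH,fate
#'   See slots.
#' @rdname CellSimSpec-class
#' @export
cellSimSpec <- function(cellId, center, nucleusRadiusPx = 9,
                        cytoRadiusPx = 16, motionSdPxPerFrame = 2,
                        motionBoxPx = 5, p53Model = traceModel(),
                        kinaseModel = traceModel(), ktrTotalLevel = 5e4,
                        h2bLevel = 200, deathTimeH = NA_real_,
                        fate = if (is.na(deathTimeH)) "surviving" else "dying") {
  new("CellSimSpec", cellId = as.integer(cellId), center = as.numeric(center),
      nucleusRadiusPx = as.numeric(nucleusRadiusPx),
      cytoRadiusPx = as.numeric(cytoRadiusPx),
      motionSdPxPerFrame = as.numeric(motionSdPxPerFrame),
      motionBoxPx = as.numeric(motionBoxPx),
      p53Model = p53Model, kinaseModel = kinaseModel,
      ktrTotalLevel = as.numeric(ktrTotalLevel),
      h2bLevel = as.numeric(h2bLevel),
      deathTimeH = as.numeric(deathTimeH), fate = fate)
}

# ---------------------------------------------------------------------------
# SimCohort (ground truth)
# ---------------------------------------------------------------------------

#' A simulated cohort with full ground truth
#'
#' Returned by [simulateCohort()]. Holds the per-cell simulation specs and
#' everything the acceptance oracles need: true per-frame kinase activity,
#' analytic C/N ratio and nuclear p53 for every cell, the true pulse
#' records, fates and death frames, plus the seed and scenario parameters
#' that generated them (so any run is reproducible from this object alone).
#'
#' @slot acq The `AcquisitionSpec`.
#' @slot cells List of `CellSimSpec`.
#' @slot cellTable Per-cell `data.frame`: `cellId`, `fate`, `deathTimeH`,
#'   `deathFrame` (1-based, NA for survivors), `field`, `y0`, `x0`,
#'   `nucleusAreaPx`, `cytoAreaPx`.
#' @slot trueActivity,trueP53,trueCN Cells x frames matrices of noiseless
#'   truth (activity; nuclear p53 intensity; analytic C/N from the
#'   translocation map and the cell's pixel compartment areas).
#' @slot truePulses `data.frame` of true kinase pulse records: `cellId`,
#'   `pulse`, `peakTimeH`, `amplitude`, `fwhmH`.
#' @slot scenario List of scenario parameters used.
#' @slot seed Integer seed.
#' @name SimCohort-class
#' @aliases SimCohort
#' @export
setClass("SimCohort",
  representation(
    acq = "AcquisitionSpec",
    cells = "list",
    cellTable = "data.frame",
    trueActivity = "matrix",
    trueP53 = "matrix",
    trueCN = "matrix",
    truePulses = "data.frame",
    scenario = "list",
    seed = "integer"
  )
)

setMethod("show", "SimCohort", function(object) {
  tab <- table(object@cellTable$fate)
  cat("SimCohort:", length(object@cells), "cells (",
      paste(names(tab), tab, collapse = ", "), ") over",
      nFrames(object@acq), "frames in",
      max(object@cellTable$field), "field(s); seed", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# MovieStack
# ---------------------------------------------------------------------------

#' Multi-channel time-lapse image stack
#'
#' A T x C x Y x X intensity array with named channel roles and the frame
#' interval, the raw input of the analysis pipeline.
#'
#' @slot data Numeric array `(frame, channel, y, x)`.
#' @slot channels Character vector of channel roles, e.g.
#'   `c("h2b", "ktr", "p53")`, matching the second dimension.
#' @slot frameIntervalMin Minutes per frame.
#' @name MovieStack-class
#' @aliases MovieStack
#' @export
setClass("MovieStack",
  representation(
    data = "array",
    channels = "character",
    frameIntervalMin = "numeric"
  )
)

setValidity("MovieStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4-d array (frame, channel, y, x)")
  if (length(object@channels) != d[2L])
    return("channels must name every channel plane")
  if (object@frameIntervalMin <= 0)
    return("frameIntervalMin must be > 0")
  TRUE
})

#' @param data,channels,frameIntervalMin See slots.
#' @rdname MovieStack-class
#' @export
movieStack <- function(data, channels = c("h2b", "ktr", "p53"),
                       frameIntervalMin = 8) {
  new("MovieStack", data = data, channels = channels,
      frameIntervalMin = as.numeric(frameIntervalMin))
}

#' @param x A `MovieStack`.
#' @param channel Channel role name.
#' @param frame Frame index (1-based).
#' @return `channelFrame()` returns the Y x X matrix of one channel at one
#'   frame.
#' @rdname MovieStack-class
#' @export
channelFrame <- function(x, channel, frame) {
  ci <- match(channel, x@channels)
  if (is.na(ci)) .stopf("movie has no channel with role '%s'", channel)
  x@data[frame, ci, , ]
}

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@data)
  cat("MovieStack:", d[1], "frames x", d[2], "channels (",
      paste(object@channels, collapse = ", "), ") x", d[3], "x", d[4],
      "px;", object@frameIntervalMin, "min/frame\n")
})

#' @rdname MovieStack-class
#' @export
setMethod("dim", "MovieStack", function(x) dim(x@data))

# ---------------------------------------------------------------------------
# ProminenceThreshold
# ---------------------------------------------------------------------------

#' Cohort-calibrated minimum pulse prominence
#'
#' The detection threshold used by [detectPulses()]: half the difference
#' between the median basal (frame-1, pre-treatment) value and the median
#' per-cell peak value across all cells of a condition, floored at zero.
#'
#' @slot condition Condition label.
#' @slot theta The threshold.
#' @slot medianBasal,medianPeak The two cohort medians.
#' @slot nCellsUsed Number of cells entering the medians.
#' @name ProminenceThreshold-class
#' @aliases ProminenceThreshold
#' @export
setClass("ProminenceThreshold",
  representation(
    condition = "character",
    theta = "numeric",
    medianBasal = "numeric",
    medianPeak = "numeric",
    nCellsUsed = "integer"
  )
)

setMethod("show", "ProminenceThreshold", function(object) {
  cat("ProminenceThreshold [", object@condition, "]: theta = ",
      signif(object@theta, 4), " (median basal ",
      signif(object@medianBasal, 4), ", median peak ",
      signif(object@medianPeak, 4), ", n = ", object@nCellsUsed, ")\n",
      sep = "")
})
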