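# Synthetic trace generation and the reporter translocation map.

.gaussPulse <- function(t, peakTimeH, amplitude, fwhmH) {
  amplitude * exp(-4 * log(2) * ((t - peakTimeH) / fwhmH)^2)
}

# Expand an oscillatory model into an explicit Gaussian pulse train over
# the acquisition window: pulses every periodH starting at periodH/2, with
# FWHM periodH/2 (bumps just touching at half maximum).
.oscPulses <- function(model, durationH) {
  times <- seq(model@periodH / 2, durationH, by = model@periodH)
  data.frame(peakTimeH = times,
             amplitude = rep(model@oscAmplitude, length(times)),
             fwhmH = rep(model@periodH / 2, length(times)))
}

#' Simulate one single-cell trace from a generative model
#'
#' Evaluates the model's noiseless component (baseline + Gaussian pulses +
#' linear ramp) at every frame of the acquisition, then applies
#' multiplicative lognormal and additive Gaussian noise. The returned true
#' pulse records echo the model's pulses (expanded from the period for
#' oscillatory models), giving downstream detection something exact to be
#' scored against.
#'
#' @param model A [TraceModel-class].
#' @param acq An [AcquisitionSpec-class].
#' @param seed Integer seed for the noise draws, or `NULL` to use the
#'   current RNG stream.
#' @return List with `values` (length [nFrames()]), `timeH`, and `pulses`
#'   (`data.frame` of the true pulse records).
#' @examples
#' acq <- acquisitionSpec()
#' m <- traceModel("pulsatile", baseline = 1,
#'                 pulses = data.frame(peakTimeH = 2, amplitude = 2, fwhmH = 1))
#' tr <- simulateTrace(m, acq)
#' max(tr$values)  # 3 at the frame nearest 2 h
#' @export
simulateTrace <- function(model, acq, seed = NULL) {
  validObject(model); validObject(acq)
  t <- timePoints(acq)
  pulses <- switch(model@kind,
    flat = ,
    rising = model@pulses[0, , drop = FALSE],
    oscillatory = if (nrow(model@pulses)) model@pulses
                  else .oscPulses(model, acq@durationH),
    model@pulses)
  if (nrow(pulses) && any(pulses$fwhmH <= 0))
    .stopf("pulse fwhmH must be > 0")
  v <- rep(model@baseline, length(t))
  if (model@kind == "rising") v <- v + model@rampRate * t
  for (k in seq_len(nrow(pulses)))
    v <- v + .gaussPulse(t, pulses$peakTimeH[k], pulses$amplitude[k],
                         pulses$fwhmH[k])
  if (model@noiseCvMult > 0 || model@noiseSdAdd > 0) {
    v <- .withSeed(seed, {
      out <- v
      if (model@noiseCvMult > 0) {
        sdlog <- sqrt(log(1 + model@noiseCvMult^2))
        out <- out * exp(stats::rnorm(length(out), -sdlog^2 / 2, sdlog))
      }
      if (model@noiseSdAdd > 0)
        out <- out + stats::rnorm(length(out), 0, model@noiseSdAdd)
      out
    })
  }
  list(values = v, timeH = t, pulses = pulses)
}

#' Map kinase activity to reporter compartment occupancy
#'
#' The kinase translocation reporter shuttles out of the nucleus when
#' phosphorylated, so its cytoplasmic fraction grows monotonically with
#' kinase activity. The map used here is the saturating form
#' `f(a) = a / (1 + a)`: zero activity keeps the whole reporter nuclear,
#' unit activity splits it evenly, and high activity asymptotically
#' exports everything. The total reporter amount is conserved
#' (nuclear + cytoplasmic fractions sum to one at every activity).
#'
#' @param activity Non-negative kinase activity (vectorised).
#' @param ktrTotalLevel Total reporter amount per cell (intensity x px).
#' @return `data.frame` with `cytoFraction`, `nuclearFraction`,
#'   `cytoAmount`, `nuclearAmount`.
#' @seealso [analyticCN()] for the resulting C/N ratio given compartment
#'   areas.
#' @examples
#' translocationMap(c(0, 1, 4))
#' @export
translocationMap <- function(activity, ktrTotalLevel = 1) {
  if (any(!is.finite(activity)) || any(activity < 0))
    .stopf("activity must be finite and >= 0")
  f <- activity / (1 + activity)
  data.frame(cytoFraction = f, nuclearFraction = 1 - f,
             cytoAmount = ktrTotalLevel * f,
             nuclearAmount = ktrTotalLevel * (1 - f))
}

#' Analytic C/N ratio implied by the translocation map
#'
#' With cytoplasmic fraction `f(a) = a/(1+a)` and per-compartment mean
#' intensity proportional to fraction / area, the C/N ratio reduces to
#' `a * nuclearArea / cytoArea`. This is the ground-truth value the image
#' pipeline is checked against on noiseless renders.
#'
#' @param activity Non-negative activity (vectorised).
#' @param nuclearAreaPx,cytoAreaPx Compartment areas in pixels.
#' @return Numeric C/N ratio.
#' @export
analyticCN <- function(activity, nuclearAreaPx, cytoAreaPx) {
  if (any(activity < 0)) .stopf("activity must be >= 0")
  activity * nuclearAreaPx / cytoAreaPx
}

#' Preset trace models for the three MAPK reporters
#'
#' Convenience constructors emulating the qualitative activation profiles
#' seen under high-dose oxidative stress: ERK starts from an elevated
#' basal activity (growth-factor signalling keeps the reporter largely
#' cytoplasmic before treatment) with an early pulse; JNK is pulsatile
#' from a low baseline (1-3 pulses); p38 mounts a single sustained peak.
#'
#' @param kinase `"erk"`, `"jnk"`, or `"p38"`.
#' @param pulseTimesH,amplitude,fwhmH Pulse placement for pulsatile kinds.
#' @param noiseSdAdd,noiseCvMult Noise levels.
#' @return A [TraceModel-class].
#' @export
kinaseTraceModel <- function(kinase = c("jnk", "erk", "p38"),
                             pulseTimesH = c(0.6, 6), amplitude = 2,
                             fwhmH = 1, noiseSdAdd = 0.02,
                             noiseCvMult = 0.05) {
  kinase <- match.arg(kinase)
  pulses <- data.frame(peakTimeH = pulseTimesH,
                       amplitude = rep_len(amplitude, length(pulseTimesH)),
                       fwhmH = rep_len(fwhmH, length(pulseTimesH)))
  switch(kinase,
    jnk = traceModel("pulsatile", baseline = 0.2, pulses = pulses,
                     noiseSdAdd = noiseSdAdd, noiseCvMult = noiseCvMult),
    erk = traceModel("pulsatile", baseline = 1.5, pulses = pulses,
                     noiseSdAdd = noiseSdAdd, noiseCvMult = noiseCvMult),
    p38 = traceModel("sustained_single_peak", baseline = 0.2,
                     pulses = data.frame(peakTimeH = pulseTimesH[1] + 1,
                                         amplitude = amplitude, fwhmH = 6),
                     noiseSdAdd = noiseSdAdd, noiseCvMult = noiseCvMult))
}
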