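# Cohort-level simulation: two-fate scenario with ground truth.

#' Scenario parameters for a two-fate cohort
#'
#' Defaults emulate the high-dose oxidative-stress condition in which fate
#' divergence is driven by the timing of the second kinase pulse: every
#' cell mounts an early activation pulse shortly after treatment; dying
#' cells re-activate early (second pulse ~ N(6 h, 1.5 h)) and die shortly
#' after the second pulse, while surviving cells re-activate late
#' (~ N(10 h, 1.5 h)). Nuclear p53 rises monotonically in all cells, as at
#' lethal doses. All parameters are recorded verbatim in the resulting
#' [SimCohort-class].
#'
#' @param firstPulseMeanH,firstPulseSdH Timing of the first kinase pulse.
#' @param dyingSecondPulseMeanH,survivingSecondPulseMeanH,secondPulseSdH
#'   Second-pulse timing per fate group.
#' @param secondPulseMinGapH Minimum gap enforced between the two pulses
#'   (redraws below this are truncated up).
#' @param pulseAmplitude,pulseFwhmH Kinase pulse shape.
#' @param baselineActivity Kinase basal activity.
#' @param deathDelayRangeH Uniform delay between the second pulse and death.
#' @param p53Baseline,p53RampRate Rising p53 model (intensity units, per h).
#' @param noiseSdAdd,noiseCvMult Trace noise (activity units / cv).
#' @param nucleusRadiusPx,cytoRadiusPx,motionSdPxPerFrame,motionBoxPx,
#'   ktrTotalLevel,h2bLevel Cell geometry and reporter levels.
#' @param fieldSpacingPx Grid spacing between cells within a field.
#' @return Named list of scenario parameters.
#' @export
cohortScenario <- function(firstPulseMeanH = 0.6, firstPulseSdH = 0.1,
                           dyingSecondPulseMeanH = 6,
                           survivingSecondPulseMeanH = 10,
                           secondPulseSdH = 1.5, secondPulseMinGapH = 2,
                           pulseAmplitude = 2, pulseFwhmH = 1,
                           baselineActivity = 0.2,
                           deathDelayRangeH = c(1.5, 3),
                           p53Baseline = 60, p53RampRate = 6,
                           noiseSdAdd = 0.02, noiseCvMult = 0.05,
                           nucleusRadiusPx = 9, cytoRadiusPx = 16,
                           motionSdPxPerFrame = 2, motionBoxPx = 5,
                           ktrTotalLevel = 5e4, h2bLevel = 200,
                           fieldSpacingPx = 40) {
  as.list(environment())
}

# Grid of non-overlapping initial positions for one field. Margin keeps the
# whole cytoplasm plus motion box inside the image.
.fieldPositions <- function(imageShape, spacing, margin) {
  ys <- seq(margin, imageShape[1] - margin, by = spacing)
  xs <- seq(margin, imageShape[2] - margin, by = spacing)
  if (!length(ys) || !length(xs))
    .stopf("image of %dx%d px too small for cell layout",
           imageShape[1], imageShape[2])
  as.matrix(expand.grid(y = ys, x = xs))
}

#' Simulate a two-fate cohort with ground truth
#'
#' Draws per-cell kinase pulse timings from the scenario's fate-specific
#' distributions, assigns death times strictly after the last pulse for
#' dying cells, lays the cells out on non-overlapping grids across as many
#' fields of view as needed, and evaluates all true traces. The result is
#' a pure function of `(nDying, nSurviving, acq, scenario, seed)`.
#'
#' @param nDying,nSurviving Cell counts per fate group (sum >= 2).
#' @param acq An [AcquisitionSpec-class].
#' @param scenario A list from [cohortScenario()].
#' @param seed Integer seed.
#' @return A [SimCohort-class].
#' @examples
#' co <- simulateCohort(4, 4, acquisitionSpec(durationH = 6), seed = 1)
#' co@cellTable[, c("cellId", "fate", "deathFrame")]
#' @export
simulateCohort <- function(nDying, nSurviving, acq = acquisitionSpec(),
                           scenario = cohortScenario(), seed = 1) {
  if (nDying < 0 || nSurviving < 0) .stopf("cell counts must be >= 0")
  n <- nDying + nSurviving
  if (n < 2) .stopf("need at least 2 cells in the cohort")
  validObject(acq)
  sc <- scenario
  t <- timePoints(acq)
  nf <- nFrames(acq)

  margin <- ceiling(sc$cytoRadiusPx + sc$motionBoxPx + 2)
  pos <- .fieldPositions(acq@imageShape, sc$fieldSpacingPx, margin)
  perField <- nrow(pos)
  nFields <- ceiling(n / perField)

  .withSeed(seed, {
    fates <- c(rep("dying", nDying), rep("surviving", nSurviving))
    # interleave fates across fields so every field carries both groups
    ord <- sample.int(n)
    fates <- fates[ord]

    cells <- vector("list", n)
    truePulses <- vector("list", n)
    cellTab <- data.frame(cellId = seq_len(n), fate = fates,
                          deathTimeH = NA_real_, deathFrame = NA_integer_,
                          field = rep(seq_len(nFields),
                                      each = perField)[seq_len(n)],
                          y0 = NA_real_, x0 = NA_real_,
                          nucleusAreaPx = NA_real_, cytoAreaPx = NA_real_)
    slot <- 0L
    trueAct <- matrix(NA_real_, n, nf)
    trueP53 <- matrix(NA_real_, n, nf)

    for (i in seq_len(n)) {
      slot <- if (i %% perField == 1L || perField == 1L) 1L else slot + 1L
      center <- pos[slot, ]
      dying <- fates[i] == "dying"
      t1 <- stats::rnorm(1, sc$firstPulseMeanH, sc$firstPulseSdH)
      t1 <- max(t1, 0.3)
      mu2 <- if (dying) sc$dyingSecondPulseMeanH else sc$survivingSecondPulseMeanH
      t2 <- stats::rnorm(1, mu2, sc$secondPulseSdH)
      t2 <- max(t2, t1 + sc$secondPulseMinGapH)
      if (acq@durationH - 2 > t1 + sc$secondPulseMinGapH)
        t2 <- min(t2, acq@durationH - 2)
      pulses <- data.frame(peakTimeH = c(t1, t2),
                           amplitude = rep(sc$pulseAmplitude, 2),
                           fwhmH = rep(sc$pulseFwhmH, 2))
      deathTimeH <- NA_real_
      if (dying) {
        deathTimeH <- t2 + stats::runif(1, sc$deathDelayRangeH[1],
                                        sc$deathDelayRangeH[2])
        deathTimeH <- min(deathTimeH, acq@durationH - 0.2)
        if (deathTimeH <= t2)   # death strictly after the last fate pulse
          deathTimeH <- t2 + 0.2
      }
      kin <- traceModel("pulsatile", baseline = sc$baselineActivity,
                        pulses = pulses, noiseSdAdd = sc$noiseSdAdd,
                        noiseCvMult = sc$noiseCvMult)
      p53 <- traceModel("rising", baseline = sc$p53Baseline,
                        rampRate = sc$p53RampRate,
                        noiseCvMult = sc$noiseCvMult)
      cells[[i]] <- cellSimSpec(
        cellId = i, center = center,
        nucleusRadiusPx = sc$nucleusRadiusPx, cytoRadiusPx = sc$cytoRadiusPx,
        motionSdPxPerFrame = sc$motionSdPxPerFrame,
        motionBoxPx = sc$motionBoxPx,
        p53Model = p53, kinaseModel = kin,
        ktrTotalLevel = sc$ktrTotalLevel, h2bLevel = sc$h2bLevel,
        deathTimeH = deathTimeH)
      truePulses[[i]] <- cbind(cellId = i, pulse = seq_len(nrow(pulses)),
                               pulses)
      cellTab$deathTimeH[i] <- deathTimeH
      cellTab$deathFrame[i] <- if (is.na(deathTimeH)) NA_integer_
                               else as.integer(which(t >= deathTimeH)[1])
      cellTab$y0[i] <- center[1]; cellTab$x0[i] <- center[2]
      cellTab$nucleusAreaPx[i] <- .diskAreaPx(sc$nucleusRadiusPx)
      cellTab$cytoAreaPx[i] <- .annulusAreaPx(sc$nucleusRadiusPx,
                                              sc$cytoRadiusPx)
      trueAct[i, ] <- model_noiseless(kin, t)
      trueP53[i, ] <- model_noiseless(p53, t)
    }
    trueCN <- trueAct * cellTab$nucleusAreaPx / cellTab$cytoAreaPx
    new("SimCohort", acq = acq, cells = cells, cellTable = cellTab,
        trueActivity = trueAct, trueP53 = trueP53, trueCN = trueCN,
        truePulses = do.call(rbind, truePulses), scenario = sc,
        seed = as.integer(seed))
  })
}

# Noiseless evaluation of a trace model on an explicit time grid.
model_noiseless <- function(model, t) {
  v <- rep(model@baseline, length(t))
  if (model@kind == "rising") v <- v + model@rampRate * t
  pulses <- if (model@kind == "oscillatory" && !nrow(model@pulses))
    .oscPulses(model, max(t)) else model@pulses
  if (model@kind %in% c("flat", "rising")) pulses <- pulses[0, , drop = FALSE]
  for (k in seq_len(nrow(pulses)))
    v <- v + .gaussPulse(t, pulses$peakTimeH[k], pulses$amplitude[k],
                         pulses$fwhmH[k])
  v
}

#' Build a cohort object from explicit cell specifications
#'
#' For controlled experiments (fidelity sweeps, tracking benchmarks) where
#' the scenario machinery of [simulateCohort()] is too coarse: takes a
#' list of [CellSimSpec-class] objects, computes their ground truth, and
#' wraps them in a [SimCohort-class] that [renderMovie()] accepts.
#'
#' @param cells List of [CellSimSpec-class].
#' @param acq An [AcquisitionSpec-class].
#' @param seed Seed recorded (and used by default when rendering).
#' @param field Field assignment per cell (recycled; default all 1).
#' @return A [SimCohort-class].
#' @export
cohortFromCells <- function(cells, acq = acquisitionSpec(), seed = 1,
                            field = 1L) {
  n <- length(cells)
  if (!n) .stopf("need at least one cell")
  t <- timePoints(acq)
  nf <- nFrames(acq)
  trueAct <- trueP53 <- matrix(NA_real_, n, nf)
  pulsesL <- vector("list", n)
  tab <- data.frame(cellId = vapply(cells, function(c) c@cellId, 0L),
                    fate = vapply(cells, function(c) c@fate, ""),
                    deathTimeH = vapply(cells, function(c) c@deathTimeH, 0),
                    deathFrame = NA_integer_,
                    field = rep_len(as.integer(field), n),
                    y0 = vapply(cells, function(c) c@center[1], 0),
                    x0 = vapply(cells, function(c) c@center[2], 0),
                    nucleusAreaPx = NA_real_, cytoAreaPx = NA_real_)
  for (i in seq_len(n)) {
    cell <- cells[[i]]
    trueAct[i, ] <- model_noiseless(cell@kinaseModel, t)
    trueP53[i, ] <- model_noiseless(cell@p53Model, t)
    kin <- cell@kinaseModel
    p <- if (kin@kind == "oscillatory" && !nrow(kin@pulses))
      .oscPulses(kin, acq@durationH) else kin@pulses
    if (kin@kind %in% c("flat", "rising")) p <- p[0, , drop = FALSE]
    if (nrow(p)) pulsesL[[i]] <- cbind(cellId = cell@cellId,
                                       pulse = seq_len(nrow(p)), p)
    tab$deathFrame[i] <- if (is.na(cell@deathTimeH)) NA_integer_
                         else as.integer(which(t >= cell@deathTimeH)[1])
    tab$nucleusAreaPx[i] <- .diskAreaPx(cell@nucleusRadiusPx)
    tab$cytoAreaPx[i] <- .annulusAreaPx(cell@nucleusRadiusPx,
                                        cell@cytoRadiusPx)
  }
  truePulses <- do.call(rbind, pulsesL)
  if (is.null(truePulses))
    truePulses <- data.frame(cellId = integer(), pulse = integer(),
                             peakTimeH = numeric(), amplitude = numeric(),
                             fwhmH = numeric())
  new("SimCohort", acq = acq, cells = cells, cellTable = tab,
      trueActivity = trueAct, trueP53 = trueP53,
      trueCN = trueAct * tab$nucleusAreaPx / tab$cytoAreaPx,
      truePulses = truePulses, scenario = list(custom = TRUE),
      seed = as.integer(seed))
}
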