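# Rendering simulated cells into multi-channel image stacks.

# Factors applied to nucleus radius / channel intensities once a cell dies:
# at the death frame the nucleus has visibly rounded up (area < 50% of
# normal) and dimmed below half intensity; from the next frame on it has
# essentially vanished (<= 10% intensity, radius < half). This
# operationalises "rounded up and lost fluorescence at the time of death"
# while keeping the collapse frame itself detectable, so the automated
# death flag can place the event.
.deathRadiusFactor <- c(atDeath = 0.65, after = 0.45)
.deathIntensityFactor <- c(atDeath = 0.4, after = 0.05)

# Reflect a random-walk coordinate into [lo, hi].
.reflect <- function(x, lo, hi) {
  width <- hi - lo
  if (width <= 0) return(rep(lo, length(x)))
  y <- (x - lo) %% (2 * width)
  lo + ifelse(y > width, 2 * width - y, y)
}

# Add `value` to the pixels of `mat` within a disk (or annulus if
# rInner >= 0) centred at (cy, cx). Returns the modified matrix.
# rInner = -1 paints the full disk including the centre pixel.
.paintAnnulus <- function(mat, cy, cx, rOuter, value, rInner = -1) {
  ys <- max(1L, floor(cy - rOuter)):min(nrow(mat), ceiling(cy + rOuter))
  xs <- max(1L, floor(cx - rOuter)):min(ncol(mat), ceiling(cx + rOuter))
  if (!length(ys) || !length(xs)) return(mat)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  sel <- d2 <= rOuter^2
  if (rInner >= 0) sel <- sel & d2 > rInner^2
  mat[ys, xs][sel] <- mat[ys, xs][sel] + value
  mat
}

.paintLabel <- function(mat, cy, cx, r, label) {
  ys <- max(1L, floor(cy - r)):min(nrow(mat), ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(ncol(mat), ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(mat)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  sel <- d2 <= r^2
  mat[ys, xs][sel] <- label
  mat
}

#' Render simulated cells into a multi-channel movie
#'
#' Renders the cells of one field of a [SimCohort-class] into a
#' `(frame, channel, y, x)` stack with three channels:
#' \describe{
#'   \item{h2b}{uniform disk at `h2bLevel` inside the nucleus.}
#'   \item{ktr}{nuclear disk plus cytoplasmic annulus; per-pixel
#'     intensities follow [translocationMap()] — compartment amount divided
#'     by compartment pixel area — so the true C/N ratio is analytic.}
#'   \item{p53}{nuclear disk at the cell's p53 trace value.}
#' }
#' Nuclei random-walk inside their home boxes. After a cell's death frame
#' the nucleus shrinks and all its channels dim (see the death phenotype
#' constants in the source). Per-cell trace noise comes from the cells'
#' `TraceModel`s; optional per-pixel camera noise and Gaussian blur are
#' applied last.
#'
#' @param cohort A [SimCohort-class].
#' @param field Field-of-view index to render.
#' @param cameraNoiseSd Additive per-pixel Gaussian noise sd (0 = none).
#' @param blurSigmaPx Optional isotropic Gaussian blur sigma (0 = none).
#' @param traceNoise If `FALSE`, per-cell traces are rendered noiselessly
#'   regardless of their models (used by the fidelity oracles).
#' @param motion If `FALSE`, cells stay at their initial positions.
#' @param seed Seed for motion, trace noise, and camera noise; defaults to
#'   a value derived from the cohort seed and the field index.
#' @return List with `movie` ([MovieStack-class]), `trueLabels` (frame x y
#'   x x integer array of ground-truth nucleus masks, labelled by
#'   `cellId`; zero after death collapse), and `cellIds` (cells rendered in
#'   this field).
#' @examples
#' co <- simulateCohort(1, 3, acquisitionSpec(durationH = 2), seed = 7)
#' rm <- renderMovie(co, cameraNoiseSd = 0, motion = FALSE)
#' rm$movie
#' @export
renderMovie <- function(cohort, field = 1L, cameraNoiseSd = 2,
                        blurSigmaPx = 0, traceNoise = TRUE, motion = TRUE,
                        seed = NULL) {
  acq <- cohort@acq
  nf <- nFrames(acq)
  shp <- acq@imageShape
  idx <- which(cohort@cellTable$field == field)
  if (!length(idx)) .stopf("no cells in field %d", field)
  cells <- cohort@cells[idx]
  if (is.null(seed)) seed <- cohort@seed + 7907L * as.integer(field)

  # no initial overlap of nuclei (layout contract)
  ctr <- do.call(rbind, lapply(cells, function(c) c@center))
  if (length(cells) > 1) {
    dd <- as.matrix(stats::dist(ctr))
    diag(dd) <- Inf
    rr <- vapply(cells, function(c) c@nucleusRadiusPx, 0)
    if (any(dd < outer(rr, rr, `+`)))
      .stopf("initial nucleus overlap in layout")
  }

  .withSeed(seed, {
    data <- array(0, dim = c(nf, 3L, shp[1], shp[2]))
    labels <- array(0L, dim = c(nf, shp[1], shp[2]))
    t <- timePoints(acq)

    for (j in seq_along(cells)) {
      cell <- cells[[j]]
      kin <- cell@kinaseModel; p53m <- cell@p53Model
      if (!traceNoise) {
        act <- model_noiseless(kin, t)
        p53v <- model_noiseless(p53m, t)
      } else {
        act <- pmax(simulateTrace(kin, acq)$values, 0)
        p53v <- pmax(simulateTrace(p53m, acq)$values, 0)
      }
      # random walk, reflected into the home box
      if (motion && cell@motionSdPxPerFrame > 0) {
        stepY <- c(0, stats::rnorm(nf - 1, 0, cell@motionSdPxPerFrame))
        stepX <- c(0, stats::rnorm(nf - 1, 0, cell@motionSdPxPerFrame))
        cy <- .reflect(cell@center[1] + cumsum(stepY),
                       cell@center[1] - cell@motionBoxPx,
                       cell@center[1] + cell@motionBoxPx)
        cx <- .reflect(cell@center[2] + cumsum(stepX),
                       cell@center[2] - cell@motionBoxPx,
                       cell@center[2] + cell@motionBoxPx)
      } else {
        cy <- rep(cell@center[1], nf); cx <- rep(cell@center[2], nf)
      }
      deathFrame <- if (is.na(cell@deathTimeH)) NA_integer_
                    else which(t >= cell@deathTimeH)[1]
      rn <- cell@nucleusRadiusPx; rc <- cell@cytoRadiusPx

      for (f in seq_len(nf)) {
        rFac <- 1; iFac <- 1
        if (!is.na(deathFrame) && f >= deathFrame) {
          atDeath <- f == deathFrame
          rFac <- .deathRadiusFactor[[if (atDeath) "atDeath" else "after"]]
          iFac <- .deathIntensityFactor[[if (atDeath) "atDeath" else "after"]]
          cy[f] <- cy[deathFrame]; cx[f] <- cx[deathFrame]
        }
        rnf <- rn * rFac; rcf <- rc * rFac
        occ <- translocationMap(act[f], cell@ktrTotalLevel)
        areaN <- .diskAreaPx(rnf, cy[f], cx[f])
        areaC <- .annulusAreaPx(rnf, rcf, cy[f], cx[f])
        intN <- if (areaN > 0) occ$nuclearAmount / areaN else 0
        intC <- if (areaC > 0) occ$cytoAmount / areaC else 0

        data[f, 1, , ] <- .paintAnnulus(data[f, 1, , ], cy[f], cx[f], rnf,
                                        cell@h2bLevel * iFac)
        data[f, 2, , ] <- .paintAnnulus(data[f, 2, , ], cy[f], cx[f], rnf,
                                        intN * iFac)
        data[f, 2, , ] <- .paintAnnulus(data[f, 2, , ], cy[f], cx[f], rcf,
                                        intC * iFac, rInner = rnf)
        data[f, 3, , ] <- .paintAnnulus(data[f, 3, , ], cy[f], cx[f], rnf,
                                        p53v[f] * iFac)
        if (is.na(deathFrame) || f <= deathFrame)
          labels[f, , ] <- .paintLabel(labels[f, , ], cy[f], cx[f], rnf,
                                       cell@cellId)
      }
    }

    if (blurSigmaPx > 0) {
      for (f in seq_len(nf)) for (ch in 1:3)
        data[f, ch, , ] <- EBImage::imageData(
          EBImage::gblur(EBImage::Image(data[f, ch, , ]), blurSigmaPx))
    }
    if (cameraNoiseSd > 0)
      data <- data + stats::rnorm(length(data), 0, cameraNoiseSd)

    list(movie = movieStack(data, frameIntervalMin = acq@frameIntervalMin),
         trueLabels = labels,
         cellIds = cohort@cellTable$cellId[idx])
  })
}

#' Render every field of a cohort
#'
#' @inheritParams renderMovie
#' @return List of [renderMovie()] results, one per field.
#' @export
renderCohort <- function(cohort, cameraNoiseSd = 2, blurSigmaPx = 0,
                         traceNoise = TRUE, motion = TRUE) {
  fields <- sort(unique(cohort@cellTable$field))
  lapply(fields, function(f)
    renderMovie(cohort, field = f, cameraNoiseSd = cameraNoiseSd,
                blurSigmaPx = blurSigmaPx, traceNoise = traceNoise,
                motion = motion))
}
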