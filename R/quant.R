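# Per-cell quantification: cytoplasmic ring, C/N ratio, nuclear mean,
# smoothing, and assembly of tracked masks + channels into traces.

#' Cytoplasmic ring masks from a nuclear label mask
#'
#' Each nucleus is dilated by a Euclidean disk of radius `ringWidthPx` and
#' the nuclei are subtracted, yielding a perinuclear ring per cell. A ring
#' pixel never lies inside any nucleus; a pixel contested by two cells'
#' rings is assigned to the cell with the nearer nucleus centroid (no
#' pixel is double-counted). Rings are clipped at the image border.
#'
#' @param labelMask Integer nuclear label mask (0 = background).
#' @param ringWidthPx Ring width in pixels (default 5). A width of 0
#'   yields an empty ring mask (downstream C/N is then invalid).
#' @return Integer ring label mask with the same labels.
#' @examples
#' m <- matrix(0L, 40, 40); m[15:25, 15:25] <- 1L
#' sum(makeRing(m, 3) == 1)
#' @export
makeRing <- function(labelMask, ringWidthPx = 5) {
  if (!any(labelMask > 0L)) .stopf("label mask contains no nucleus")
  out <- matrix(0L, nrow(labelMask), ncol(labelMask))
  if (ringWidthPx <= 0) return(out)
  w <- as.integer(ringWidthPx)
  brush <- EBImage::makeBrush(2L * w + 1L, shape = "disc")
  st <- .labelStats(labelMask)
  nr <- nrow(labelMask); nc <- ncol(labelMask)

  candIdx <- integer(); candLab <- integer(); candD2 <- numeric()
  for (i in seq_len(nrow(st))) {
    lab <- st$label[i]
    sel <- which(labelMask == lab, arr.ind = TRUE)
    ys <- max(1L, min(sel[, 1]) - w):min(nr, max(sel[, 1]) + w)
    xs <- max(1L, min(sel[, 2]) - w):min(nc, max(sel[, 2]) + w)
    sub <- labelMask[ys, xs, drop = FALSE]
    dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(sub == lab),
                                              brush)) > 0
    ring <- dil & sub == 0L
    if (!any(ring)) next
    ridx <- which(ring, arr.ind = TRUE)
    gy <- ys[ridx[, 1]]; gx <- xs[ridx[, 2]]
    candIdx <- c(candIdx, (gx - 1L) * nr + gy)
    candLab <- c(candLab, rep(lab, nrow(ridx)))
    candD2 <- c(candD2, (gy - st$cy[i])^2 + (gx - st$cx[i])^2)
  }
  if (!length(candIdx)) return(out)
  ord <- order(candD2, candLab)   # nearest centroid wins; ties by label
  first <- !duplicated(candIdx[ord])
  out[candIdx[ord][first]] <- candLab[ord][first]
  out
}

#' Cytoplasmic-to-nuclear ratio of a reporter channel
#'
#' Mean reporter intensity over the cytoplasmic ring divided by the mean
#' over the nucleus. An empty ring or nucleus, or a non-positive nuclear
#' mean, marks the frame invalid (`NA`) rather than erroring.
#'
#' @param ktrFrame Y x X reporter intensity matrix.
#' @param nucMask,ringMask Logical or 0/1 masks of the two compartments.
#' @return The ratio, or `NA_real_` when undefined.
#' @examples
#' img <- matrix(7, 10, 10)
#' nuc <- ring <- matrix(FALSE, 10, 10); nuc[3:5, 3:5] <- TRUE
#' ring[7:9, 7:9] <- TRUE
#' cnRatio(img, nuc, ring)  # 1
#' @export
cnRatio <- function(ktrFrame, nucMask, ringMask) {
  nuc <- as.logical(nucMask); ring <- as.logical(ringMask)
  if (!any(nuc) || !any(ring)) return(NA_real_)
  mn <- mean(ktrFrame[nuc])
  if (!is.finite(mn) || mn <= 0) return(NA_real_)
  mean(ktrFrame[ring]) / mn
}

#' Mean intensity over the nuclear mask
#'
#' @param frame Y x X intensity matrix.
#' @param nucMask Logical or 0/1 nuclear mask.
#' @return Arithmetic mean over mask pixels; `NA_real_` if the mask is
#'   empty.
#' @export
nuclearMean <- function(frame, nucMask) {
  nuc <- as.logical(nucMask)
  if (!any(nuc)) return(NA_real_)
  mean(frame[nuc])
}

#' Centred moving-mean smoothing of a trace
#'
#' Moving mean with an odd window (`span = 3` averages frames n-1, n,
#' n+1). At the trace boundaries the window shrinks to the available
#' frames; invalid (`NA`) frames are excluded from every window and remain
#' invalid in the output.
#'
#' @param values Numeric trace (may contain `NA`).
#' @param span Odd window size >= 1 (1 = identity).
#' @return Smoothed trace, same length, `NA` where the input was `NA`.
#' @examples
#' smoothTrace(c(1, 2, 3, 4), span = 3)  # 1.5 2 3 3.5
#' @export
smoothTrace <- function(values, span = 3) {
  span <- as.integer(span)
  if (span < 1L || span %% 2L == 0L) .stopf("span must be odd and >= 1")
  n <- length(values)
  if (span == 1L || n == 0L) return(values)
  h <- span %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(values[i])) next
    win <- values[max(1L, i - h):min(n, i + h)]
    out[i] <- mean(win, na.rm = TRUE)
  }
  out
}

#' Assemble tracked masks and channels into per-cell traces
#'
#' For every frame, measures the nuclear mean of the p53 and H2B channels
#' and the KTR mean over nucleus and cytoplasmic ring for each label, then
#' joins the measurements along tracks. Death is flagged per track from
#' the area and H2B traces ([flagDeath()]); frames at or after death are
#' invalid. Tracks are kept if they span at least `minTrackFraction` of
#' the movie, or end in a flagged death having started near the beginning
#' (a dying cell is tracked "until death"). Both raw and smoothed series
#' are retained.
#'
#' @param movie A [MovieStack-class] with channels `h2b`, `ktr`, `p53`.
#' @param masks List of per-frame nuclear label masks (e.g. from
#'   [segmentNuclei()]).
#' @param tracks Track table from [buildTracks()].
#' @param ringWidthPx Ring width (default 5).
#' @param span Smoothing span (default 3).
#' @param minTrackFraction Minimum fraction of frames a surviving track
#'   must span (default 0.75).
#' @param deathAreaFrac,deathIntensityFrac Passed to [flagDeath()].
#' @param condition Condition label stored in the result.
#' @return A [KtrTraceSet-class].
#' @export
assembleTraces <- function(movie, masks, tracks, ringWidthPx = 5,
                           span = 3, minTrackFraction = 0.75,
                           deathAreaFrac = 0.5, deathIntensityFrac = 0.5,
                           condition = "cohort") {
  need <- c("h2b", "ktr", "p53")
  if (!all(need %in% movie@channels))
    .stopf("movie must declare channel roles: %s",
           paste(setdiff(need, movie@channels), collapse = ", "))
  nf <- dim(movie)[1]
  if (length(masks) != nf) .stopf("one mask per frame required")

  # per-frame, per-label measurements
  meas <- vector("list", nf)
  for (f in seq_len(nf)) {
    mask <- masks[[f]]
    if (!any(mask > 0L)) next
    ktr <- channelFrame(movie, "ktr", f)
    st <- .labelStats(mask, intensities = list(
      h2bMean = channelFrame(movie, "h2b", f),
      p53Mean = channelFrame(movie, "p53", f),
      ktrNucMean = ktr))
    rings <- makeRing(mask, ringWidthPx)
    rs <- .labelStats(rings, intensities = list(ktrRingMean = ktr))
    st$ktrRingMean <- rs$ktrRingMean[match(st$label, rs$label)]
    st$frame <- f
    meas[[f]] <- st
  }
  meas <- do.call(rbind, meas)
  tab <- merge(tracks, meas[, c("frame", "label", "h2bMean", "p53Mean",
                                "ktrNucMean", "ktrRingMean")],
               by = c("frame", "label"), all.x = TRUE, sort = FALSE)

  ids <- sort(unique(tab$trackId))
  n <- length(ids)
  cn <- p53 <- matrix(NA_real_, n, nf)
  death <- rep(NA_integer_, n)
  keep <- logical(n)
  for (k in seq_len(n)) {
    d <- tab[tab$trackId == ids[k], ]
    d <- d[order(d$frame), ]
    ratio <- ifelse(is.finite(d$ktrRingMean) & is.finite(d$ktrNucMean) &
                      d$ktrNucMean > 0, d$ktrRingMean / d$ktrNucMean,
                    NA_real_)
    cn[k, d$frame] <- ratio
    p53[k, d$frame] <- d$p53Mean
    if (nrow(d) >= 3L) {
      di <- flagDeath(d$area, d$h2bMean, deathAreaFrac, deathIntensityFrac)
      if (!is.na(di)) death[k] <- d$frame[di]
    }
    spanFrames <- max(d$frame) - min(d$frame) + 1L
    keep[k] <- spanFrames >= minTrackFraction * nf ||
      (!is.na(death[k]) && min(d$frame) <= ceiling(0.05 * nf))
  }

  ts <- ktrTraceSet(cnRaw = cn[keep, , drop = FALSE],
                    p53Raw = p53[keep, , drop = FALSE],
                    timeH = (seq_len(nf) - 1) * movie@frameIntervalMin / 60,
                    trackId = ids[keep], deathFrame = death[keep],
                    condition = condition, span = span)
  ts
}

#' Run segmentation + tracking + quantification on one movie
#'
#' Convenience wrapper chaining [segmentNuclei()], [buildTracks()], and
#' [assembleTraces()] for one field.
#'
#' @inheritParams assembleTraces
#' @param smoothSigmaPx,minAreaPx,splitTouching,thresholdCorrection Passed
#'   to [segmentNuclei()].
#' @param maxDistPx Passed to [buildTracks()].
#' @return List with `traces` ([KtrTraceSet-class]), `masks`, and `tracks`.
#' @export
quantifyMovie <- function(movie, smoothSigmaPx = 1, minAreaPx = 80,
                          splitTouching = TRUE, thresholdCorrection = 0.5,
                          maxDistPx = 50, ringWidthPx = 5, span = 3,
                          minTrackFraction = 0.75, deathAreaFrac = 0.5,
                          deathIntensityFrac = 0.5, condition = "cohort") {
  nf <- dim(movie)[1]
  masks <- lapply(seq_len(nf), function(f)
    segmentNuclei(channelFrame(movie, "h2b", f), smoothSigmaPx = smoothSigmaPx,
                  minAreaPx = minAreaPx, splitTouching = splitTouching,
                  thresholdCorrection = thresholdCorrection))
  tracks <- buildTracks(masks, maxDistPx = maxDistPx)
  traces <- assembleTraces(movie, masks, tracks, ringWidthPx = ringWidthPx,
                           span = span, minTrackFraction = minTrackFraction,
                           deathAreaFrac = deathAreaFrac,
                           deathIntensityFrac = deathIntensityFrac,
                           condition = condition)
  list(traces = traces, masks = masks, tracks = tracks)
}
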