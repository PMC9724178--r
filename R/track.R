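# Frame-to-frame linking and track assembly ("overlap method with a
# 50-pixel maximum distance").

#' Link nucleus labels between two consecutive frames
#'
#' Candidate pairs are label pairs with any pixel overlap, or with centroid
#' distance at most `maxDistPx` (the overlap rule with a distance cap;
#' both routes are admitted so a fast-moving nucleus that loses overlap can
#' still be matched within the cap). Assignment is greedy and
#' deterministic: by descending overlap, ties broken by ascending centroid
#' distance, then by ascending label numbers; each label is matched at most
#' once.
#'
#' @param maskT,maskT1 Integer label masks of frames t and t+1 (same shape).
#' @param maxDistPx Maximum centroid distance for a match (default 50).
#' @return `data.frame` with `labelT`, `labelT1`, `overlapPx`, `distPx` —
#'   one row per accepted match.
#' @export
linkFrames <- function(maskT, maskT1, maxDistPx = 50) {
  if (!identical(dim(maskT), dim(maskT1)))
    .stopf("masks must share the same shape")
  sT <- .labelStats(maskT)
  sT1 <- .labelStats(maskT1)
  empty <- data.frame(labelT = integer(), labelT1 = integer(),
                      overlapPx = integer(), distPx = numeric())
  if (!nrow(sT) || !nrow(sT1)) return(empty)

  both <- maskT > 0L & maskT1 > 0L
  ov <- if (any(both)) {
    tab <- table(labelT = maskT[both], labelT1 = maskT1[both])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0L, ]
    data.frame(labelT = as.integer(df$labelT),
               labelT1 = as.integer(df$labelT1),
               overlapPx = as.integer(df$Freq))
  } else {
    data.frame(labelT = integer(), labelT1 = integer(),
               overlapPx = integer())
  }

  # centroid-distance candidates within the cap
  d <- sqrt(outer(sT$cy, sT1$cy, `-`)^2 + outer(sT$cx, sT1$cx, `-`)^2)
  near <- which(d <= maxDistPx, arr.ind = TRUE)
  cand <- data.frame(labelT = sT$label[near[, 1]],
                     labelT1 = sT1$label[near[, 2]],
                     overlapPx = rep(0L, nrow(near)),
                     distPx = d[near])
  if (nrow(ov)) {
    ov$distPx <- d[cbind(match(ov$labelT, sT$label),
                         match(ov$labelT1, sT1$label))]
    key <- paste(cand$labelT, cand$labelT1)
    cand <- rbind(ov, cand[!key %in% paste(ov$labelT, ov$labelT1), ])
  }
  if (!nrow(cand)) return(empty)

  cand <- cand[order(-cand$overlapPx, cand$distPx, cand$labelT,
                     cand$labelT1), ]
  usedT <- usedT1 <- integer()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$labelT[i] %in% usedT || cand$labelT1[i] %in% usedT1) next
    keep[i] <- TRUE
    usedT <- c(usedT, cand$labelT[i])
    usedT1 <- c(usedT1, cand$labelT1[i])
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble per-frame labels into persistent tracks
#'
#' Opens a new track for every unmatched label; a track whose label finds
#' no match in the next frame is closed with status `"lost"` (there is no
#' gap closing — the overlap method has none). A division split keeps the
#' track on the matched daughter and opens a new track for the other.
#'
#' @param masks List of per-frame integer label masks.
#' @param links Optional list of [linkFrames()] results (length
#'   `length(masks) - 1`); computed if omitted.
#' @param maxDistPx Passed to [linkFrames()] when links are computed here.
#' @return `data.frame` (one row per track-frame): `trackId`, `frame`,
#'   `label`, `cy`, `cx`, `area`, plus attribute `"trackStatus"` — a
#'   per-track `data.frame` with `trackId`, `firstFrame`, `lastFrame`,
#'   `status` (`"active"` at movie end or `"lost"`).
#' @export
buildTracks <- function(masks, links = NULL, maxDistPx = 50) {
  nT <- length(masks)
  if (is.null(links)) {
    links <- vector("list", max(nT - 1L, 0L))
    for (f in seq_len(nT - 1L))
      links[[f]] <- linkFrames(masks[[f]], masks[[f + 1L]], maxDistPx)
  }
  stats <- lapply(masks, .labelStats)
  rows <- vector("list", nT)
  nextTrack <- 1L
  current <- integer()   # current[label at frame f] -> trackId

  for (f in seq_len(nT)) {
    st <- stats[[f]]
    assign <- integer(nrow(st))
    if (f == 1L) {
      assign <- seq_len(nrow(st))
      nextTrack <- nrow(st) + 1L
    } else {
      lk <- links[[f - 1L]]
      for (i in seq_len(nrow(st))) {
        hit <- lk$labelT[match(st$label[i], lk$labelT1)]
        if (!is.na(hit) && as.character(hit) %in% names(current)) {
          assign[i] <- current[[as.character(hit)]]
        } else {
          assign[i] <- nextTrack
          nextTrack <- nextTrack + 1L
        }
      }
    }
    current <- stats::setNames(assign, st$label)
    if (nrow(st))
      rows[[f]] <- data.frame(trackId = assign, frame = f,
                              label = st$label, cy = st$cy, cx = st$cx,
                              area = st$area)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(trackId = integer(), frame = integer(),
                      label = integer(), cy = numeric(), cx = numeric(),
                      area = integer())
  rownames(tab) <- NULL
  status <- do.call(rbind, lapply(split(tab, tab$trackId), function(d) {
    data.frame(trackId = d$trackId[1], firstFrame = min(d$frame),
               lastFrame = max(d$frame),
               status = if (max(d$frame) == nT) "active" else "lost")
  }))
  rownames(status) <- NULL
  attr(tab, "trackStatus") <- status
  tab
}

#' Flag a death event within one track
#'
#' Automates the visual call that a dying cell "rounds up and loses
#' fluorescence": the death frame is the first frame at which the nuclear
#' area drops below `areaFrac` of the track's median area AND the H2B mean
#' drops below `intensityFrac` of the track's median H2B mean, with both
#' conditions sustained through the end of the track. A transient
#' single-frame dip that recovers is not a death.
#'
#' @param area Nuclear area per tracked frame (px).
#' @param h2bMean H2B mean intensity per tracked frame.
#' @param areaFrac,intensityFrac Collapse thresholds (defaults 0.5).
#' @return Index into the track's frames of the death event, or
#'   `NA_integer_` if none.
#' @export
flagDeath <- function(area, h2bMean, areaFrac = 0.5, intensityFrac = 0.5) {
  n <- length(area)
  if (n < 3L || n != length(h2bMean))
    .stopf("need area and h2bMean traces of equal length >= 3")
  collapsed <- area < areaFrac * stats::median(area) &
    h2bMean < intensityFrac * stats::median(h2bMean)
  # sustained to track end: suffix of all-TRUE
  sustained <- rev(cumall(rev(collapsed)))
  if (!any(sustained)) NA_integer_ else which(sustained)[1]
}

cumall <- function(x) cumprod(as.logical(x)) > 0
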