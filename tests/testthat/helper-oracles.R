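# Independent brute-force oracles. These deliberately re-derive each
# quantity with the most literal algorithm available (nested loops,
# exhaustive scans) and share no code path with the package functions
# they check.

# --- pulse detection ------------------------------------------------------

# Every interior local maximum (plateaus represented by their middle
# index), by direct scanning.
oracleLocalMaxima <- function(v) {
  n <- length(v)
  out <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) out <- c(out, i + (j - i) %/% 2L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Topographic prominence by scanning both directions from the peak.
oracleProminence <- function(v, p) {
  h <- v[p]
  leftVals <- v[seq_len(p - 1L)]
  higher <- which(leftVals > h)
  lo <- if (length(higher)) (max(higher) + 1L) else 1L
  leftValley <- if (lo <= p - 1L) min(v[lo:(p - 1L)]) else h
  rightVals <- v[(p + 1L):length(v)]
  higher <- which(rightVals > h)
  hi <- if (length(higher)) (p + min(higher) - 1L) else length(v)
  rightValley <- if (p + 1L <= hi) min(v[(p + 1L):hi]) else h
  h - max(leftValley, rightValley)
}

# Full pulse table for comparison against detectPulses (peak indices and
# prominences only; durations are checked separately on analytic pulses).
oraclePulses <- function(v, theta) {
  peaks <- oracleLocalMaxima(v)
  prom <- vapply(peaks, function(p) oracleProminence(v, p), 0)
  keep <- prom >= theta & prom > 0
  data.frame(peak = peaks[keep], prominence = prom[keep])
}

# --- smoothing / integration ---------------------------------------------

oracleMovingMean <- function(v, span) {
  h <- span %/% 2L
  n <- length(v)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    acc <- 0; cnt <- 0L
    for (j in max(1L, i - h):min(n, i + h)) {
      if (!is.na(v[j])) { acc <- acc + v[j]; cnt <- cnt + 1L }
    }
    out[i] <- acc / cnt
  }
  out
}

oracleTrapz <- function(t, v) {
  s <- 0
  for (i in seq_len(length(t) - 1L))
    s <- s + (t[i + 1L] - t[i]) * (v[i] + v[i + 1L]) / 2
  s
}

# --- statistics -----------------------------------------------------------

# Two-sided permutation p-value for a difference in group means.
oraclePermutationP <- function(x, y, nPerm = 10000, seed = 99) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  n1 <- length(x)
  withr::with_seed(seed, {
    hits <- 0L
    for (k in seq_len(nPerm)) {
      idx <- sample.int(length(pool), n1)
      d <- abs(mean(pool[idx]) - mean(pool[-idx]))
      if (d >= obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (nPerm + 1)
  })
}

# --- morphology -----------------------------------------------------------

# Binary dilation by explicit translate-and-OR over the brush support.
oracleDilate <- function(mask, brush) {
  nr <- nrow(mask); nc <- ncol(mask)
  br <- nrow(brush); bc <- ncol(brush)
  oy <- (br + 1L) %/% 2L; ox <- (bc + 1L) %/% 2L
  out <- matrix(FALSE, nr, nc)
  offs <- which(brush > 0, arr.ind = TRUE)
  sel <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(sel))) {
    ys <- sel[k, 1] + offs[, 1] - oy
    xs <- sel[k, 2] + offs[, 2] - ox
    ok <- ys >= 1L & ys <= nr & xs >= 1L & xs <= nc
    out[cbind(ys[ok], xs[ok])] <- TRUE
  }
  out
}

# --- geometry -------------------------------------------------------------

diskMask <- function(nr, nc, cy, cx, r) {
  outer(seq_len(nr), seq_len(nc),
        function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}
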