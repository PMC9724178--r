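# Internal helpers shared across modules.

.isScalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic generators in the package funnel their randomness through
#' this helper so that every simulation is a pure function of (parameters,
#' seed) and never perturbs the session RNG.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

# Linear interpolation of the time at which a trace crosses `level` between
# two consecutive samples (t1,v1) -> (t2,v2), v1 and v2 on opposite sides.
.crossTime <- function(t1, v1, t2, v2, level) {
  if (v2 == v1) return(t2)
  t1 + (level - v1) * (t2 - t1) / (v2 - v1)
}

# Number of pixel centres inside a disk of radius r centred on (cy, cx)
# within an (optionally unbounded) image; used for analytic compartment
# areas of rendered cells.
.diskAreaPx <- function(r, cy = 0, cx = 0) {
  ys <- seq(floor(cy - r), ceiling(cy + r))
  xs <- seq(floor(cx - r), ceiling(cx + r))
  g <- expand.grid(y = ys, x = xs)
  sum((g$y - cy)^2 + (g$x - cx)^2 <= r^2)
}

# Pixel area of the annulus rInner < d <= rOuter around (cy, cx).
.annulusAreaPx <- function(rInner, rOuter, cy = 0, cx = 0) {
  .diskAreaPx(rOuter, cy, cx) - .diskAreaPx(rInner, cy, cx)
}
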