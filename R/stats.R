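# Fate stratification and group statistics.

#' Split a feature table by cell fate
#'
#' Partitions cells into surviving and dying groups by the presence of a
#' death annotation (automated death flag or ground truth). A death in the
#' last frame still counts as dying.
#'
#' @param features Feature `data.frame` with a `deathFrame` column (and
#'   optionally `fate`); one row per cell.
#' @return List with `surviving` and `dying` data frames and `n` (named
#'   group sizes). An empty group triggers a warning (downstream
#'   comparisons will be skipped).
#' @export
splitByFate <- function(features) {
  dying <- !is.na(features$deathFrame)
  out <- list(surviving = features[!dying, , drop = FALSE],
              dying = features[dying, , drop = FALSE],
              n = c(surviving = sum(!dying), dying = sum(dying)))
  if (any(out$n == 0))
    warning("empty fate group: group comparisons will be skipped")
  out
}

# Second-pulse peak time per qualifying cell (>= 2 detected pulses).
.secondPulseTimes <- function(pulses) {
  if (!nrow(pulses)) return(numeric())
  byCell <- split(pulses$peakTimeH, pulses$trackId)
  vapply(byCell[lengths(byCell) >= 2L],
         function(tt) sort(tt)[2L], 0)
}

#' Compare second-pulse timing between surviving and dying cells
#'
#' For each group, takes the second detected pulse time of every cell with
#' at least two pulses and compares the groups with a two-tailed t-test
#' (Welch by default; `pooled = TRUE` for the equal-variance variant).
#'
#' @param pulses Pulse table (from [pulseFeatureTable()]`$pulses`) with
#'   `trackId` and `peakTimeH`.
#' @param features Feature table carrying `trackId` and `deathFrame`.
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return One-row `data.frame`: `feature`, `test`, `statistic`,
#'   `pValue`, `meanDying`, `meanSurviving`, `nDying`, `nSurviving`; or
#'   `NULL` (with a warning) when a group has fewer than 2 qualifying
#'   cells.
#' @export
secondPulseTiming <- function(pulses, features, pooled = FALSE) {
  t2 <- .secondPulseTimes(pulses)
  fate <- ifelse(is.na(features$deathFrame), "surviving", "dying")
  names(fate) <- features$trackId
  grp <- fate[names(t2)]
  dyingT <- t2[grp == "dying"]
  survT <- t2[grp == "surviving"]
  if (length(dyingT) < 2L || length(survT) < 2L) {
    warning("fewer than 2 qualifying cells in a group: comparison skipped")
    return(NULL)
  }
  # zero-variance degenerate groups: report the mean difference with an
  # undefined test statistic instead of failing
  tt <- tryCatch(stats::t.test(dyingT, survT, var.equal = pooled),
                 error = function(e)
                   list(statistic = NA_real_, p.value = NA_real_))
  data.frame(feature = "secondPulseTimeH",
             test = if (pooled) "t-test (pooled, 2-tailed)"
                    else "Welch t-test (2-tailed)",
             statistic = unname(tt$statistic), pValue = tt$p.value,
             meanDying = mean(dyingT), meanSurviving = mean(survT),
             nDying = length(dyingT), nSurviving = length(survT))
}

#' One-way fixed-effects ANOVA on a per-cell feature
#'
#' @param values Numeric feature values.
#' @param groups Grouping factor (>= 2 levels, each n >= 2).
#' @param feature Label recorded in the output.
#' @return One-row `data.frame` with the F statistic, p-value, and group
#'   sizes. When the data carry no variance at all, F is reported as 0
#'   with p = 1.
#' @examples
#' compareFeatureAnova(c(rnorm(10), rnorm(10, 3)), rep(c("a", "b"), each = 10))
#' @export
compareFeatureAnova <- function(values, groups, feature = "feature") {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) .stopf("need >= 2 groups")
  if (any(table(groups) < 2L)) .stopf("every group needs n >= 2")
  if (stats::var(values) == 0) {
    f <- 0; p <- 1
  } else {
    fit <- stats::aov(values ~ groups)
    s <- summary(fit)[[1]]
    f <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
  }
  data.frame(feature = feature, test = "one-way ANOVA",
             statistic = f, pValue = p,
             nGroups = nlevels(groups), nTotal = length(values))
}

#' Z-score standardisation across samples
#'
#' `z = (x - mean) / sd` with the sample (n-1) standard deviation; across
#' the input set the z-scores have mean 0 and sd 1.
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric z-scores; all-`NA` with a warning when the sd is 0.
#' @examples
#' zscoreStandardize(c(1, 3, 5))
#' @export
zscoreStandardize <- function(x) {
  if (length(x) < 2L) .stopf("need >= 2 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warning("zero standard deviation: z-scores undefined")
    return(rep(NA_real_, length(x)))
  }
  (x - mean(x)) / s
}

#' Per-frame population mean and SD of a trace set
#'
#' Mean and sample SD over valid cells at each frame, as plotted as the
#' thick line with a shaded SD envelope in population-average figures.
#' Frames with fewer than 2 valid cells report `NA` SD.
#'
#' @param ts A [KtrTraceSet-class] or a cells x frames matrix.
#' @param assay Assay to summarise when `ts` is a `KtrTraceSet`.
#' @return `data.frame` per frame: `frame`, `timeH`, `mean`, `sd`,
#'   `nValid`.
#' @export
populationSummary <- function(ts, assay = "cnSmooth") {
  if (is(ts, "KtrTraceSet")) {
    m <- SummarizedExperiment::assay(ts, assay)
    t <- traceTimeH(ts)
  } else {
    m <- ts
    t <- seq_len(ncol(m)) - 1
  }
  nValid <- as.integer(colSums(is.finite(m)))
  data.frame(
    frame = seq_len(ncol(m)), timeH = t,
    mean = ifelse(nValid >= 1, colMeans(m, na.rm = TRUE), NA_real_),
    sd = ifelse(nValid >= 2, apply(m, 2, stats::sd, na.rm = TRUE),
                NA_real_),
    nValid = nValid)
}
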