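# Prominence calibration, pulse detection, feature summaries, integration.

test_that("cohort prominence threshold is half the basal-to-peak span", {
  m <- rbind(c(1, 2, 3, 1), c(1, 1.5, 3, 1), c(1, 3, 2, 1))
  th <- cohortProminenceThreshold(m)
  expect_equal(th@theta, 1)          # 0.5 * (3 - 1)
  expect_equal(th@medianBasal, 1)
  expect_equal(th@medianPeak, 3)
  expect_identical(th@nCellsUsed, 3L)

  flat <- matrix(1, 4, 10)
  expect_equal(cohortProminenceThreshold(flat)@theta, 0)

  withr::with_seed(31, {
    r <- matrix(rnorm(200, 5), 10, 20)
    th <- cohortProminenceThreshold(r)
    expect_equal(th@medianBasal, median(r[, 1]))
    expect_equal(th@medianPeak, median(apply(r, 1, max)))
    expect_equal(th@theta, max(0, 0.5 * (th@medianPeak - th@medianBasal)))
  })

  # global-max alternative reading
  thG <- cohortProminenceThreshold(m, peakSummary = "global_max")
  expect_equal(thG@medianPeak, 3)
  expect_error(cohortProminenceThreshold(matrix(NA_real_, 2, 3)), "valid")
})

test_that("single Gaussian pulses are detected with FWHM-accurate duration", {
  t <- seq(0, 24, by = 8 / 60)
  v <- 1 + 2 * exp(-4 * log(2) * ((t - 6) / 1.5)^2)
  p <- detectPulses(v, t, theta = 0.5)
  expect_identical(nrow(p), 1L)
  expect_equal(p$peakTimeH, 6, tolerance = 8 / 60)
  expect_equal(p$amplitude, 3, tolerance = 1e-6)
  expect_equal(p$prominence, 2, tolerance = 1e-6)
  # full width at half prominence of an isolated Gaussian = its FWHM
  expect_equal(p$durationH, 1.5, tolerance = 2 * 8 / 60)

  expect_identical(nrow(detectPulses(rep(1, 30), t[1:30], 0.1)), 0L)
  # monotone rise terminating at the last frame is not a pulse
  expect_identical(nrow(detectPulses(seq(1, 3, length.out = 50),
                                     t[1:50], 0)), 0L)
})

test_that("sub-threshold bumps are rejected", {
  t <- seq(0, 24, by = 8 / 60)
  theta <- 1
  v <- 1 + 0.9 * theta * exp(-4 * log(2) * ((t - 5) / 1)^2) +
    1.5 * theta * exp(-4 * log(2) * ((t - 15) / 1)^2)
  p <- detectPulses(v, t, theta)
  expect_identical(nrow(p), 1L)
  expect_equal(p$peakTimeH, 15, tolerance = 8 / 60)
})

test_that("detection agrees with the exhaustive prominence oracle", {
  withr::with_seed(41, {
    for (rep in 1:300) {
      n <- sample(5:50, 1)
      v <- rnorm(n)
      theta <- runif(1, 0, 1.5)
      got <- detectPulses(v, seq_len(n) - 1, theta)
      want <- oraclePulses(v, theta)
      expect_identical(got$peakFrame, want$peak)
      expect_equal(got$prominence, want$prominence)
    }
  })
})

test_that("pulse sets are invariant to adding a constant", {
  withr::with_seed(43, {
    m <- matrix(rnorm(10 * 60, 2), 10, 60)
    t <- seq_len(60) - 1
    th1 <- cohortProminenceThreshold(m)
    th2 <- cohortProminenceThreshold(m + 7)
    expect_equal(th2@theta, th1@theta)
    for (i in 1:10) {
      a <- detectPulses(m[i, ], t, th1)
      b <- detectPulses(m[i, ] + 7, t, th2)
      expect_identical(a$peakFrame, b$peakFrame)
      expect_equal(a$prominence, b$prominence)
    }
  })
})

test_that("detection skips invalid frames but keeps true time stamps", {
  t <- seq(0, 10, by = 0.5)
  v <- 1 + 2 * exp(-4 * log(2) * ((t - 5) / 1)^2)
  v[c(3, 15)] <- NA
  p <- detectPulses(v, t, 0.5)
  expect_identical(nrow(p), 1L)
  expect_equal(p$peakTimeH, 5)
  expect_identical(nrow(detectPulses(c(NA, 1, NA, 2, NA), 1:5, 0)), 0L)
})

test_that("feature summaries report max, timing, basal, and truncation", {
  t <- seq(0, 24, by = 8 / 60)
  rising <- 1 + 0.1 * t
  f <- summarizeFeatures(rising, t, detectPulses(rising, t, 0.2))
  expect_identical(f$nPulses, 0L)
  expect_equal(f$timeOfMaxH, 24)
  expect_equal(f$maxValue, 3.4)
  expect_equal(f$basal, 1)

  # death truncation: only frames before death contribute
  v <- 1 + 2 * exp(-4 * log(2) * ((t - 4) / 1)^2)
  v[t >= 12] <- NA
  f <- summarizeFeatures(v, t, detectPulses(v, t, 0.5))
  expect_identical(f$nPulses, 1L)
  expect_equal(f$timeOfMaxH, 4)
  expect_identical(f$nValidFrames, sum(t < 12))
})

test_that("trapezoidal integration matches closed forms and the oracle", {
  t <- seq(0, 24, by = 8 / 60)
  expect_equal(integrateTrace(rep(1, length(t)), t), 24, tolerance = 1e-9)
  expect_equal(integrateTrace(2 * t / 24, t), 24, tolerance = 1e-9)

  withr::with_seed(47, {
    v <- rnorm(length(t), 5)
    expect_equal(integrateTrace(v, t), oracleTrapz(t, v),
                 tolerance = 1e-12)
    # linearity on identical validity patterns
    x <- rnorm(length(t)); y <- rnorm(length(t))
    expect_equal(integrateTrace(3 * x + 2 * y, t),
                 3 * integrateTrace(x, t) + 2 * integrateTrace(y, t),
                 tolerance = 1e-9)
  })
  expect_warning(out <- integrateTrace(c(1, NA, NA), c(0, 1, 2)), "valid")
  expect_true(is.na(out))
})

test_that("well-separated pulses are recovered from noisy traces", {
  acq <- acquisitionSpec()
  t <- timePoints(acq)
  withr::with_seed(53, {
    nTraces <- 60
    exact <- 0; timeOK <- 0; pulsesTotal <- 0
    traces <- matrix(NA_real_, nTraces, length(t))
    truth <- vector("list", nTraces)
    for (i in seq_len(nTraces)) {
      k <- sample(1:3, 1)
      times <- sort(1.5 + (22 - 1.5) * ((seq_len(k) - 0.5) / k +
                                          runif(k, -0.1, 0.1)))
      model <- traceModel("pulsatile", baseline = 1,
                          pulses = data.frame(peakTimeH = times,
                                              amplitude = 2,
                                              fwhmH = runif(k, 0.7, 1.2)),
                          noiseSdAdd = 0.15)
      traces[i, ] <- smoothTrace(simulateTrace(model, acq)$values, 3)
      truth[[i]] <- times
    }
    theta <- cohortProminenceThreshold(traces)
    for (i in seq_len(nTraces)) {
      p <- detectPulses(traces[i, ], t, theta)
      if (nrow(p) == length(truth[[i]])) exact <- exact + 1
      for (tt in truth[[i]]) {
        pulsesTotal <- pulsesTotal + 1
        if (any(abs(p$peakTimeH - tt) <= 8 / 60 + 1e-9))
          timeOK <- timeOK + 1
      }
    }
    expect_gte(exact / nTraces, 0.95)
    expect_gte(timeOK / pulsesTotal, 0.90)
  })
})
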