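# Synthetic trace and cohort generation.

test_that("flat and single-pulse traces evaluate exactly", {
  acq <- acquisitionSpec()
  flat <- simulateTrace(traceModel("flat", baseline = 1), acq)
  expect_identical(flat$values, rep(1, nFrames(acq)))
  expect_identical(nrow(flat$pulses), 0L)

  m <- traceModel("pulsatile", baseline = 1,
                  pulses = data.frame(peakTimeH = 2, amplitude = 2,
                                      fwhmH = 1))
  tr <- simulateTrace(m, acq)
  expect_equal(max(tr$values), 3)                 # apex hit exactly at 2 h
  expect_equal(tr$timeH[which.max(tr$values)], 2)
  expect_equal(tr$pulses$peakTimeH, 2)

  bad <- traceModel("pulsatile",
                    pulses = data.frame(peakTimeH = 2, amplitude = 1,
                                        fwhmH = 1))
  bad@pulses$fwhmH <- 0
  expect_error(simulateTrace(bad, acq), "fwhm")
})

test_that("noisy traces are pure functions of the seed", {
  acq <- acquisitionSpec(durationH = 6)
  m <- traceModel("pulsatile", baseline = 1,
                  pulses = data.frame(peakTimeH = 3, amplitude = 2,
                                      fwhmH = 1),
                  noiseSdAdd = 0.2, noiseCvMult = 0.1)
  a <- simulateTrace(m, acq, seed = 5)
  b <- simulateTrace(m, acq, seed = 5)
  expect_identical(a$values, b$values)
  c <- simulateTrace(m, acq, seed = 6)
  expect_false(identical(a$values, c$values))
})

test_that("oscillatory models expand into a regular pulse train", {
  acq <- acquisitionSpec()
  m <- traceModel("oscillatory", baseline = 1, periodH = 6,
                  oscAmplitude = 2)
  tr <- simulateTrace(m, acq)
  expect_equal(tr$pulses$peakTimeH, c(3, 9, 15, 21))
  # bump apex reached (to within frame discretisation and tail overlap)
  expect_equal(max(tr$values), 3, tolerance = 0.01)
  i3 <- which.min(abs(tr$timeH - 3))
  expect_equal(tr$values[i3], 3, tolerance = 0.01)
})

test_that("translocation map conserves reporter and is monotone in C/N", {
  m <- translocationMap(c(0, 1, 4))
  expect_equal(m$cytoFraction, c(0, 0.5, 0.8))
  expect_true(all(abs(m$cytoFraction + m$nuclearFraction - 1) < 1e-12))
  expect_error(translocationMap(-0.1), "activity")

  grid <- seq(0.05, 5, by = 0.05)
  cn <- analyticCN(grid, nuclearAreaPx = 250, cytoAreaPx = 550)
  expect_true(all(diff(cn) > 0))
})

test_that("cohort simulation honours fate structure and determinism", {
  acq <- acquisitionSpec(durationH = 24)
  co <- simulateCohort(0, 5, acq, seed = 3)
  expect_true(all(is.na(co@cellTable$deathTimeH)))

  co <- simulateCohort(40, 40, acq, seed = 3)
  t2 <- co@truePulses[co@truePulses$pulse == 2, ]
  fateOf <- co@cellTable$fate[match(t2$cellId, co@cellTable$cellId)]
  expect_lt(mean(t2$peakTimeH[fateOf == "dying"]),
            mean(t2$peakTimeH[fateOf == "surviving"]))

  # death strictly after the cell's last fate-construction pulse
  lastPulse <- tapply(co@truePulses$peakTimeH, co@truePulses$cellId, max)
  dying <- co@cellTable[co@cellTable$fate == "dying", ]
  expect_true(all(dying$deathTimeH >
                    lastPulse[as.character(dying$cellId)]))

  co2 <- simulateCohort(40, 40, acq, seed = 3)
  expect_identical(co@cellTable, co2@cellTable)
  expect_identical(co@trueActivity, co2@trueActivity)
  expect_identical(co@truePulses, co2@truePulses)
  expect_error(simulateCohort(-1, 5, acq), "counts")
})

test_that("rendered static noiseless cells match configured intensities", {
  acq <- acquisitionSpec(durationH = 0.5, imageShape = c(96L, 96L))
  cell <- cellSimSpec(1L, center = c(48, 48), nucleusRadiusPx = 10,
                      cytoRadiusPx = 17,
                      kinaseModel = traceModel("flat", baseline = 1),
                      p53Model = traceModel("flat", baseline = 80))
  co <- cohortFromCells(list(cell), acq)
  rm <- renderMovie(co, cameraNoiseSd = 0, traceNoise = FALSE,
                    motion = FALSE)
  nuc <- diskMask(96, 96, 48, 48, 10)
  cyto <- diskMask(96, 96, 48, 48, 17) & !nuc

  h2b <- channelFrame(rm$movie, "h2b", 1)
  expect_equal(unique(h2b[nuc]), cell@h2bLevel)     # exact, uniform disk
  p53 <- channelFrame(rm$movie, "p53", 1)
  expect_equal(mean(p53[nuc]), 80)

  # measured C/N over true masks equals the analytic value to rounding
  ktr <- channelFrame(rm$movie, "ktr", 1)
  measured <- mean(ktr[cyto]) / mean(ktr[nuc])
  expect_equal(measured, analyticCN(1, sum(nuc), sum(cyto)),
               tolerance = 1e-12)
})

test_that("reporter is conserved in rendered frames", {
  acq <- acquisitionSpec(durationH = 0.5, imageShape = c(96L, 96L))
  cell <- cellSimSpec(1L, center = c(48, 48),
                      kinaseModel = traceModel(
                        "pulsatile", baseline = 0.3,
                        pulses = data.frame(peakTimeH = 0.25,
                                            amplitude = 2, fwhmH = 0.2)))
  co <- cohortFromCells(list(cell), acq)
  rm <- renderMovie(co, cameraNoiseSd = 0, traceNoise = FALSE,
                    motion = FALSE)
  for (f in seq_len(nFrames(acq))) {
    total <- sum(channelFrame(rm$movie, "ktr", f))
    expect_equal(total, cell@ktrTotalLevel, tolerance = 1e-9)
  }
})

test_that("death rendering collapses the nucleus within two frames", {
  acq <- acquisitionSpec(durationH = 2, imageShape = c(96L, 96L))
  cell <- cellSimSpec(1L, center = c(48, 48), deathTimeH = 1)
  co <- cohortFromCells(list(cell), acq)
  rm <- renderMovie(co, cameraNoiseSd = 0, traceNoise = FALSE,
                    motion = FALSE)
  d <- co@cellTable$deathFrame[1]
  areaBefore <- sum(rm$trueLabels[d - 1, , ] == 1)
  h2bBefore <- sum(channelFrame(rm$movie, "h2b", d - 1))
  areaAfter2 <- sum(channelFrame(rm$movie, "h2b", d + 2) > 0)
  h2bAfter2 <- sum(channelFrame(rm$movie, "h2b", d + 2))
  expect_lt(areaAfter2, 0.5 * areaBefore)     # radius shrink >= 50%
  expect_lt(h2bAfter2, 0.1 * h2bBefore)       # fluorescence loss <= 10%
})

test_that("rendering is deterministic and rejects overlapping layouts", {
  acq <- acquisitionSpec(durationH = 1, imageShape = c(96L, 96L))
  co <- simulateCohort(1, 2, acq, seed = 9,
                       scenario = cohortScenario(fieldSpacingPx = 34))
  a <- renderMovie(co, seed = 4)
  b <- renderMovie(co, seed = 4)
  expect_identical(a$movie@data, b$movie@data)
  expect_identical(a$trueLabels, b$trueLabels)

  cells <- list(cellSimSpec(1L, c(40, 40)), cellSimSpec(2L, c(40, 50)))
  bad <- cohortFromCells(cells, acq)
  expect_error(renderMovie(bad), "overlap")
})
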