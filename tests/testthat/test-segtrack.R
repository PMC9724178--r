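# Nuclear segmentation, frame linking, track assembly, death flagging.

test_that("segmentation handles blank frames and separates disks", {
  expect_warning(m0 <- segmentNuclei(matrix(0, 64, 64)), "constant")
  expect_identical(max(m0), 0L)

  # two disjoint disks at SNR 10
  img <- matrix(0, 128, 128)
  img[diskMask(128, 128, 40, 40, 10)] <- 100
  img[diskMask(128, 128, 90, 85, 10)] <- 100
  img <- img + withr::with_seed(1, matrix(rnorm(128 * 128, 0, 10), 128))
  m <- segmentNuclei(img, minAreaPx = 80)
  st <- ktrdyn:::.labelStats(m)
  expect_identical(nrow(st), 2L)
  st <- st[order(st$cy), ]
  expect_lt(abs(st$cy[1] - 40) + abs(st$cx[1] - 40), 2)
  expect_lt(abs(st$cy[2] - 90) + abs(st$cx[2] - 85), 2)
})

test_that("watershed splitting separates touching nuclei", {
  img <- matrix(0, 128, 128)
  img[diskMask(128, 128, 60, 50, 10)] <- 100
  img[diskMask(128, 128, 60, 69, 10)] <- 100    # centres 19 px apart: fused
  mSplit <- segmentNuclei(img, smoothSigmaPx = 0, minAreaPx = 50,
                          splitTouching = TRUE)
  mFused <- segmentNuclei(img, smoothSigmaPx = 0, minAreaPx = 50,
                          splitTouching = FALSE)
  expect_identical(max(mSplit), 2L)
  expect_identical(max(mFused), 1L)
})

test_that("frame linking obeys overlap, distance cap, and determinism", {
  m1 <- matrix(0L, 128, 128)
  m1[diskMask(128, 128, 40, 40, 10)] <- 1L
  m1[diskMask(128, 128, 90, 90, 10)] <- 2L

  # identical masks -> identity mapping
  lk <- linkFrames(m1, m1)
  expect_identical(lk$labelT, lk$labelT1)
  expect_identical(nrow(lk), 2L)

  # 10-px translation keeps the pairing
  m2 <- matrix(0L, 128, 128)
  m2[diskMask(128, 128, 50, 40, 10)] <- 5L
  m2[diskMask(128, 128, 100, 90, 10)] <- 9L
  lk <- linkFrames(m1, m2)
  expect_identical(lk$labelT1[match(1:2, lk$labelT)], c(5L, 9L))

  # 60-px jump with no overlap exceeds the 50-px cap -> no match
  m3 <- matrix(0L, 128, 128)
  m3[diskMask(128, 128, 40, 100, 10)] <- 1L
  one <- matrix(0L, 128, 128)
  one[diskMask(128, 128, 40, 40, 10)] <- 1L
  expect_identical(nrow(linkFrames(one, m3)), 0L)
  # ... but a 30-px jump without overlap still matches via the cap
  m4 <- matrix(0L, 128, 128)
  m4[diskMask(128, 128, 40, 70, 10)] <- 1L
  expect_identical(nrow(linkFrames(one, m4)), 1L)

  expect_error(linkFrames(m1, matrix(0L, 64, 64)), "shape")
})

test_that("greedy assignment agrees with brute-force optimum on a hard case", {
  # two nuclei drifting toward each other's previous position: the
  # assignment maximising total overlap keeps identities straight
  mA <- matrix(0L, 128, 128)
  mA[diskMask(128, 128, 60, 40, 10)] <- 1L
  mA[diskMask(128, 128, 60, 64, 10)] <- 2L
  mB <- matrix(0L, 128, 128)
  mB[diskMask(128, 128, 60, 46, 10)] <- 1L
  mB[diskMask(128, 128, 60, 70, 10)] <- 2L
  lk <- linkFrames(mA, mB)

  # brute force over all one-to-one assignments of {1,2} -> {1,2}
  ov <- function(a, b) sum(mA == a & mB == b)
  best <- if (ov(1, 1) + ov(2, 2) >= ov(1, 2) + ov(2, 1))
    cbind(1:2, 1:2) else cbind(1:2, 2:1)
  expect_identical(lk$labelT1[match(best[, 1], lk$labelT)],
                   as.integer(best[, 2]))
})

test_that("tracks open, persist, and close as lost", {
  disk <- function(cy, cx) {
    m <- matrix(0L, 96, 96); m[diskMask(96, 96, cy, cx, 8)] <- 1L; m
  }
  masks <- lapply(seq(30, 60, by = 5), function(cx) disk(40, cx))
  tab <- buildTracks(masks)
  expect_identical(unique(tab$trackId), 1L)
  expect_identical(nrow(tab), length(masks))
  expect_identical(attr(tab, "trackStatus")$status, "active")

  # cell disappears at frame 5 of 7
  masks2 <- masks
  for (f in 5:7) masks2[[f]] <- matrix(0L, 96, 96)
  tab2 <- buildTracks(masks2)
  expect_identical(max(tab2$frame), 4L)
  expect_identical(attr(tab2, "trackStatus")$status, "lost")
})

test_that("track partition is invariant under label permutation", {
  withr::with_seed(21, {
    disk2 <- function(c1, c2, swap) {
      m <- matrix(0L, 96, 96)
      m[diskMask(96, 96, c1[1], c1[2], 8)] <- if (swap) 2L else 1L
      m[diskMask(96, 96, c2[1], c2[2], 8)] <- if (swap) 1L else 2L
      m
    }
    pos1 <- cbind(30 + cumsum(rnorm(6, 0, 2)), 30 + cumsum(rnorm(6, 0, 2)))
    pos2 <- cbind(65 + cumsum(rnorm(6, 0, 2)), 65 + cumsum(rnorm(6, 0, 2)))
    masksA <- lapply(1:6, function(f) disk2(pos1[f, ], pos2[f, ], FALSE))
    masksB <- lapply(1:6, function(f) disk2(pos1[f, ], pos2[f, ],
                                            f %% 2 == 0))
    part <- function(tab) {
      key <- paste(tab$frame, round(tab$cy, 6), round(tab$cx, 6), sep = "/")
      unname(lapply(split(key, tab$trackId), sort))
    }
    pa <- part(buildTracks(masksA))
    pb <- part(buildTracks(masksB))
    expect_setequal(pa, pb)
  })
})

test_that("death flagging requires a sustained collapse", {
  expect_identical(flagDeath(rep(100, 10), rep(50, 10)), NA_integer_)

  # single-frame dip that recovers is not a death
  area <- c(100, 100, 30, 100, 100)
  h2b <- c(50, 50, 10, 50, 50)
  expect_identical(flagDeath(area, h2b), NA_integer_)

  # sustained collapse from frame 7
  area <- c(rep(100, 6), rep(30, 3))
  h2b <- c(rep(50, 6), rep(15, 3))
  expect_identical(flagDeath(area, h2b), 7L)

  # both conditions must hold: area collapse alone is not enough
  expect_identical(flagDeath(c(rep(100, 6), rep(30, 3)), rep(50, 9)),
                   NA_integer_)
  expect_error(flagDeath(1:2, 1:2), "length")
})

test_that("rendered dying cells are flagged near the true death frame", {
  acq <- acquisitionSpec(durationH = 3, imageShape = c(96L, 96L))
  cell <- cellSimSpec(1L, center = c(48, 48), deathTimeH = 1.5,
                      kinaseModel = traceModel("flat", baseline = 0.5),
                      p53Model = traceModel("flat", baseline = 50))
  co <- cohortFromCells(list(cell), acq)
  rm <- renderMovie(co, cameraNoiseSd = 2, traceNoise = FALSE, seed = 2)
  q <- quantifyMovie(rm$movie, minTrackFraction = 0.3)
  expect_identical(nrow(q$traces), 1L)
  expect_lte(abs(deathFrame(q$traces) - co@cellTable$deathFrame[1]), 2)
})
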