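test_that("proximity stimuli have two collinear segments separated by the gap", {
  for (gap in 0:4) {
    s <- generateProximityStimulus(gap)
    lab <- segmentLabels(s)
    expect_equal(sort(unique(lab[lab > 0])), c(1L, 2L))
    rows <- which(rowSums(lab > 0) > 0)
    expect_length(rows, 1)  # a single horizontal row
    cols1 <- which(lab[rows, ] == 1)
    cols2 <- which(lab[rows, ] == 2)
    expect_true(max(cols1) < min(cols2))
    # exactly `gap` background columns between the inner endpoints
    expect_equal(min(cols2) - max(cols1) - 1L, gap)
    # fixed total extent: joint pixel count shrinks by exactly the gap
    expect_equal(sum(pixels(s) > 0), 16 - gap)
    # labels only on lit pixels
    expect_true(all(pixels(s)[lab > 0] > 0))
  }
})

test_that("gap 0 yields one unbroken line of two labelled halves", {
  s <- generateProximityStimulus(0)
  lab <- segmentLabels(s)
  row <- which(rowSums(lab > 0) > 0)
  cols <- which(lab[row, ] > 0)
  expect_equal(cols, seq(min(cols), max(cols)))  # contiguous
  expect_equal(sum(lab == 1), sum(lab == 2))
})

test_that("an oversized gap is rejected", {
  expect_error(generateProximityStimulus(15), "gap too large")
  expect_error(generateProximityStimulus(-1), "nonnegative")
})

test_that("similarity stimuli meet at a contact point with the stated angle", {
  for (lv in c(0, 23, 45, 68, 90)) {
    s <- generateSimilarityStimulus(lv)
    lab <- segmentLabels(s)
    expect_equal(sort(unique(lab[lab > 0])), c(1L, 2L))
    px1 <- which(lab == 1, arr.ind = TRUE)
    px2 <- which(lab == 2, arr.ind = TRUE)
    # segments touch: minimal Chebyshev distance between them is 1
    d <- outer(seq_len(nrow(px1)), seq_len(nrow(px2)), function(i, j)
      pmax(abs(px1[i, 1] - px2[j, 1]), abs(px1[i, 2] - px2[j, 2])))
    expect_equal(min(d), 1)
    # measured orientation difference matches the level (rasterization slack)
    fit <- function(px) {  # orientation of the best-fit line, degrees in [0,180)
      if (stats::sd(px[, 2]) == 0) return(90)
      b <- stats::coef(stats::lm(I(-px[, 1]) ~ px[, 2]))[2]
      (atan2(b, 1) * 180 / pi) %% 180
    }
    meas <- abs(fit(px1) - fit(px2))
    meas <- 90 - abs(meas %% 180 - 90)
    expect_lt(abs(meas - levelToAngle(lv)), 8)
  }
  expect_error(generateSimilarityStimulus(30), "must be one of")
})

test_that("similarity level 0 forms one straight line", {
  s <- generateSimilarityStimulus(0)
  lab <- segmentLabels(s)
  expect_equal(length(unique(which(lab > 0, arr.ind = TRUE)[, 1])), 1)
})

test_that("continuity stimuli have four segments with collinear opposite pairs", {
  for (lv in c(23, 45, 68, 90)) {
    s <- generateContinuityStimulus(lv)
    lab <- segmentLabels(s)
    expect_equal(sort(unique(lab[lab > 0])), 1:4)
    # segments 1 and 3 lie on the same horizontal row
    r1 <- unique(which(lab == 1, arr.ind = TRUE)[, 1])
    r3 <- unique(which(lab == 3, arr.ind = TRUE)[, 1])
    expect_equal(r1, r3)
    expect_length(r1, 1)
    # segments 2 and 4 are collinear: least-squares slopes agree
    slope <- function(id) {
      px <- which(lab == id, arr.ind = TRUE)
      if (stats::sd(px[, 2]) == 0) return(Inf)
      stats::coef(stats::lm(I(-px[, 1]) ~ px[, 2]))[2]
    }
    s2 <- slope(2); s4 <- slope(4)
    if (is.finite(s2) && is.finite(s4)) {
      expect_lt(abs(atan(s2) - atan(s4)) * 180 / pi, 10)
    } else {
      expect_true(!is.finite(s2) && !is.finite(s4))
    }
  }
  expect_error(generateContinuityStimulus(0), "invalid")
})

test_that("background noise preserves signal pixels and labels, fresh per seed", {
  s <- generateProximityStimulus(1)
  n1 <- addBackgroundNoise(s, 0.4, seed = 1)
  n2 <- addBackgroundNoise(s, 0.4, seed = 2)
  expect_identical(segmentLabels(n1), segmentLabels(s))
  expect_true(all(pixels(n1) >= pixels(s)))
  expect_false(identical(pixels(n1), pixels(n2)))
  expect_identical(addBackgroundNoise(s, 0), s)  # snr 0 is a no-op
})

test_that("noise level matches the documented amplitude rule (Monte Carlo)", {
  s <- generateProximityStimulus(0)
  bg <- segmentLabels(s) == 0
  ratios <- replicate(200, {
    n <- addBackgroundNoise(s, 0.4)
    mean(pixels(n)[bg]) / mean(pixels(s)[!bg])
  })
  # uniform noise on [0, snr]: mean background level = snr/2 of the signal
  expect_lt(abs(mean(ratios) - 0.2), 0.01)
  expect_true(all(pixels(addBackgroundNoise(s, 0.4)) <= 1.4))
})

test_that("orientation decomposition yields 5 selective nonnegative channels", {
  oris <- channelOrientations()
  expect_equal(oris, c(0, 22.5, 45, 67.5, 90))
  blank <- new("StimulusImage", pixels = matrix(0, 20, 20),
               segmentLabels = matrix(0L, 20, 20), principle = "proximity",
               level = 0)
  expect_true(all(decomposeOrientations(blank)@channels == 0))
  # a line at each channel orientation responds maximally, along its own
  # pixels, in its own channel (normalized kernels conserve total mass, so
  # selectivity must be read off the line pixels, not the image sum)
  for (lv in c(0, 23, 45, 68, 90)) {
    img <- matrix(0, 20, 20)
    th <- levelToAngle(lv) * pi / 180
    for (k in -7:7) {
      r <- 10 - round(k * sin(th)); c <- 10 + round(k * cos(th))
      img[r, c] <- 1
    }
    ch <- decomposeOrientations(img)@channels
    expect_true(all(ch >= 0))
    resp <- apply(ch, 3, function(x) sum(x[img > 0]))
    expect_equal(which.max(resp), which(oris == levelToAngle(lv)))
  }
})

test_that("each similarity segment activates primarily its own channel", {
  for (lv in c(0, 45, 90)) {
    s <- generateSimilarityStimulus(lv)
    ch <- decomposeOrientations(s)@channels
    lab <- segmentLabels(s)
    oris <- channelOrientations()
    for (seg in 1:2) {
      m <- lab == seg
      resp <- apply(ch, 3, function(x) sum(x[m]))
      want <- if (seg == 1) 0 else levelToAngle(lv)
      expect_equal(oris[which.max(resp)], want)
    }
  }
})

test_that("Poisson encoding is seeded, rate-faithful and bounded", {
  s <- generateProximityStimulus(0)
  ch <- decomposeOrientations(s)
  e1 <- encodePoisson(ch, rateHz = 40, durationMs = 1000, seed = 5)
  e2 <- encodePoisson(ch, rateHz = 40, durationMs = 1000, seed = 5)
  expect_identical(e1@spikes, e2@spikes)
  expect_error(encodePoisson(ch, rateHz = 4000, binMs = 0.5), "below one")
  # driven neurons: expected 40 spikes over 1 s, within +-3 sqrt(40)
  drv <- drivenNeurons(s)
  full <- drv$neuron[sapply(seq_len(nrow(drv)), function(i)
    ch@channels[drv$row[i], drv$col[i], drv$channel[i]] >= 1)]
  counts <- rowSums(e1@spikes[full, , drop = FALSE])
  expect_true(all(abs(counts - 40) <= 3 * sqrt(40)))
  # zero rate: empty train
  e0 <- encodePoisson(ch, rateHz = 0, durationMs = 100)
  expect_equal(sum(e0@spikes), 0)
})

test_that("stimulus generators are monotone in their Gestalt parameter", {
  # gap: minimal inter-segment Chebyshev distance strictly increases
  dmin <- sapply(0:4, function(g) {
    lab <- segmentLabels(generateProximityStimulus(g))
    p1 <- which(lab == 1, arr.ind = TRUE); p2 <- which(lab == 2, arr.ind = TRUE)
    min(outer(seq_len(nrow(p1)), seq_len(nrow(p2)), function(i, j)
      pmax(abs(p1[i, 1] - p2[j, 1]), abs(p1[i, 2] - p2[j, 2]))))
  })
  expect_true(all(diff(dmin) > 0))
  # angle: measured orientation difference strictly increases
  ang <- sapply(c(0, 23, 45, 68, 90), function(a) {
    lab <- segmentLabels(generateSimilarityStimulus(a))
    fit <- function(px) {
      if (stats::sd(px[, 2]) == 0) return(90)
      b <- stats::coef(stats::lm(I(-px[, 1]) ~ px[, 2]))[2]
      (atan2(b, 1) * 180 / pi) %% 180
    }
    d <- abs(fit(which(lab == 1, arr.ind = TRUE)) -
             fit(which(lab == 2, arr.ind = TRUE)))
    90 - abs(d %% 180 - 90)
  })
  expect_true(all(diff(ang) > 0))
})

test_that("segment labels partition the clean stimulus pixels", {
  stims <- c(generateStimulusSeries("proximity"),
             generateStimulusSeries("similarity"),
             generateStimulusSeries("continuity"))
  for (s in stims) {
    lab <- segmentLabels(s)
    expect_true(all(pixels(s)[lab > 0] > 0))
    nseg <- if (principle(s) == "continuity") 4 else 2
    expect_equal(max(lab), nseg)
  }
})

test_that("stimuli round-trip through the plain-text format", {
  s <- generateContinuityStimulus(45)
  path <- tempfile(fileext = ".txt")
  writeStimulusText(s, path)
  r <- readStimulusText(path)
  expect_equal(pixels(r), pixels(s))
  expect_identical(segmentLabels(r), segmentLabels(s))
  expect_equal(principle(r), principle(s))
  expect_equal(gestaltLevel(r), gestaltLevel(s))
})

test_that("neuron indexing is a bijection with grid position and channel", {
  gd <- c(7L, 9L)
  ids <- seq_len(prod(gd) * 5L)
  pos <- neuronPosition(ids, gd)
  back <- neuronIndex(pos$row, pos$col, pos$channel, gd)
  expect_equal(back, ids)
})

test_that("encoding drives the stimulus fully, the halo partially, the rest not", {
  s <- generateProximityStimulus(0)
  ch <- decomposeOrientations(s)
  e <- encodePoisson(ch, durationMs = 2000, seed = 9)
  rate <- rowSums(e@spikes) / 2
  drv <- drivenNeurons(s)$neuron
  expect_true(all(rate[drv] > 25))            # full 40 Hz within Poisson error
  resp <- as.vector(ch@channels)
  far <- resp + 0.4 < 0.7                    # unreachable by the noise
  expect_equal(sum(e@spikes[far, ]), 0)
  halo <- !far & resp < 0.7
  expect_gte(sum(rate[halo] > 1), 5)          # a populated halo
  expect_true(any(rate[halo] > 1 & rate[halo] < 30))  # with graded members
  # snr = 0 reduces to a hard threshold on the clean response
  e0 <- encodePoisson(ch, durationMs = 500, seed = 9, snr = 0)
  expect_equal(sum(e0@spikes[resp < 0.7, ]), 0)
})

test_that("YAML stimulus configs read with defaults filled in", {
  path <- tempfile(fileext = ".yml")
  writeLines(c("principle: proximity", "levels: [0, 2, 4]"), path)
  cfg <- readStimulusConfig(path)
  expect_equal(cfg$principle, "proximity")
  expect_equal(cfg$levels, c(0, 2, 4))
  expect_equal(cfg$snr, 0.4)
  expect_equal(cfg$rateHz, 40)
  writeLines("gridSize: 20", path)
  expect_error(readStimulusConfig(path), "principle")
})

test_that("stimuli export to grayscale PNG", {
  s <- generateSimilarityStimulus(45)
  path <- tempfile(fileext = ".png")
  writeStimulusPNG(s, path)
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], dim(pixels(s)))
  expect_equal(round(img[10, 10] * 255), 255)  # lit contact-line pixel
})
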