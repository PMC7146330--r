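streamOf <- function(rows, fps = 1.6, nFrames = NULL,
                     classes = jellyfishClasses()) {
  dets <- do.call(rbind, rows)
  if (is.null(nFrames)) nFrames <- max(dets$frame) + 1L
  DetectionStream(dets, fps = fps, frameIds = 0:(nFrames - 1L),
                  classes = classes)
}

detAt <- function(frame, conf, class = SP1, x = 0) {
  data.frame(frame = frame, class = class, confidence = conf,
             xmin = x, ymin = 0, xmax = x + 10, ymax = 10,
             stringsAsFactors = FALSE)
}

test_that("information points apply Cthr2 and cover empty frames", {
  st <- streamOf(list(
    detAt(0, 0.9), detAt(0, 0.8, x = 20),
    detAt(0, 0.3, class = "Rhizostoma_pulmo", x = 40)
  ), nFrames = 2)
  pts <- streamToInformationPoints(st, cthr2 = 50)
  expect_equal(unname(countMatrix(pts)[1, "Pelagia_noctiluca"]), 2L)
  expect_equal(unname(countMatrix(pts)[1, "Rhizostoma_pulmo"]), 0L)
  expect_equal(unname(countMatrix(pts)[2, ]), rep(0L, 3))  # empty frame
  expect_equal(pointTimes(pts), c(0, 1) / 1.6)

  raw <- streamToInformationPoints(st, cthr2 = 0)
  expect_equal(sum(countMatrix(raw)), 3)
})

test_that("windowed-mode reduction reproduces the hand-enumerated example", {
  ip <- ipointsOf(c(1, 1, 1, 2, 1, 1, 1, 1))
  out <- windowReduce(ip, wSize = 4, wOverlap = 0.5)
  ## windows {1,1,1,2}, {1,2,1,1}, {1,1,1,1} -> modes 1, 1, 1
  expect_equal(unname(countMatrix(out)[, 1]), c(1L, 1L, 1L))
  ## stamped at each window's final frame
  expect_identical(frameIds(out), c(3L, 5L, 7L))

  const <- windowReduce(ipointsOf(rep(2, 20)), 4, 0.25)
  expect_true(all(countMatrix(const) == 2L))

  expect_warning(short <- windowReduce(ipointsOf(c(1, 1)), 4, 0.25), "fewer")
  expect_length(frameIds(short), 0)
})

test_that("resulting-point count matches the window-enumeration oracle", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(12:120, 1)
    counts <- sample(0:3, n, replace = TRUE)
    wSize <- sample(c(4L, 8L, 12L), 1)
    wOverlap <- sample(c(0.25, 0.5, 0.75), 1)
    stride <- as.integer(wSize * (1 - wOverlap))
    out <- windowReduce(ipointsOf(counts), wSize, wOverlap)
    expect_length(frameIds(out), floor((n - wSize) / stride) + 1)
    oracle <- windowOracle(matrix(as.integer(counts), ncol = 1,
                                  dimnames = list(NULL, SP1)),
                           wSize, stride)
    expect_equal(unname(countMatrix(out)[, 1]), unname(oracle$counts[, 1]))
    expect_identical(frameIds(out), as.integer(oracle$ends - 1L))
  }
})

test_that("mode ties prefer the previous resulting value, then the lower count", {
  ## window {1,1,2,2}: tie with no previous value -> lower count 1
  out <- windowReduce(ipointsOf(c(1, 1, 2, 2)), 4, 0)
  expect_equal(unname(countMatrix(out)[, 1]), 1L)
  ## previous resulting point is 2 -> tie in the second window goes to 2
  out <- windowReduce(ipointsOf(c(2, 2, 2, 1, 1, 2, 2, 1)), 4, 0)
  expect_equal(unname(countMatrix(out)[, 1]), c(2L, 2L))
})

test_that("stride timing follows wSize * (1 - wOverlap) / fps", {
  expect_equal(tRIPoint(8, 0.25, 1.6), 3.75)
  expect_equal(tRIPoint(12, 0.25, 1.6), 5.625)
  expect_equal(tRIPoint(10, 0, 2.5), 4)  # zero-overlap limit: wSize / fps
  expect_error(tRIPoint(8, 0.25, 0), "fps")
  expect_error(tRIPoint(8, 1, 1.6), "wOverlap")
})

test_that("equivalent window sizes invert the stride-timing relation", {
  expect_identical(equivalentWindowSize(25.2, tRIPoint(4, 0.25, 1.6), 0.25), 63L)
  expect_identical(equivalentWindowSize(10, tRIPoint(4, 0.25, 1.6), 0.25), 25L)
  expect_identical(equivalentWindowSize(1.6, tRIPoint(7, 0, 1.6), 0), 7L)
  expect_error(equivalentWindowSize(3, tRIPoint(4, 0.25, 1.6), 0.25),
               "between 7 and 8")
})

test_that("emitted resulting points are spaced by exactly the stride time", {
  set.seed(32)
  st <- streamOf(list(detAt(0, 0.9)), nFrames = 100)
  for (w in c(4L, 8L, 12L)) {
    res <- quantify(st, w, 0.25, 0)
    fid <- frameIds(resultingPoints(res))
    expect_true(all(abs(diff(fid) / fps(st) - strideSeconds(res)) < 1e-12))
  }
})

test_that("similarity counts exact count-vector matches, in percent", {
  truth <- timelineOf(c(1, 1, 2, 2))
  exact <- InformationPoints(0:3, countMatrix(truth), (0:3) / 1.6)
  expect_equal(similarity(exact, truth), 100)

  offByOne <- countMatrix(truth)
  offByOne[4, 1] <- 3L
  expect_equal(similarity(InformationPoints(0:3, offByOne, (0:3) / 1.6), truth), 75)

  expect_error(similarity(InformationPoints(integer(),
                                            countMatrix(truth)[0, , drop = FALSE],
                                            numeric()), truth),
               "undefined")
  expect_error(similarity(InformationPoints(9L, offByOne[1, , drop = FALSE], 0),
                          truth), "lacks frame")

  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    truthCounts <- sample(0:2, n, replace = TRUE)
    predCounts <- truthCounts
    flip <- sample(n, sample(0:n, 1))
    predCounts[flip] <- predCounts[flip] + 1L
    tl <- timelineOf(truthCounts)
    ip <- ipointsOf(predCounts)
    expect_equal(
      similarity(ip, tl),
      similarityOracle(frameIds(ip), countMatrix(ip),
                       frameIds(tl), countMatrix(tl))
    )
  }
})

test_that("sporadic minority errors never corrupt a resulting point", {
  ## fewer than ceiling(wSize/2) deviating points inside every window
  for (wSize in c(4L, 8L, 12L)) {
    for (wOverlap in c(0.25, 0.5, 0.75)) {
      counts <- rep(1L, 96)
      ## corruptions spaced wSize apart: exactly one per window, always a
      ## strict minority (1 < ceiling(wSize / 2) for wSize >= 4)
      counts[seq(1, 96, by = wSize)] <- 0L
      out <- windowReduce(ipointsOf(counts), wSize, wOverlap)
      expect_true(all(countMatrix(out) == 1L),
                  label = sprintf("wSize=%d wOverlap=%g", wSize, wOverlap))
    }
  }
})

test_that("larger windows never hurt average similarity under i.i.d. errors", {
  set.seed(34)
  reps <- 200
  n <- 96
  sims <- sapply(seq_len(reps), function(r) {
    truth <- rep(1L, n)
    noisy <- truth
    bad <- which(stats::runif(n) < 0.15)
    noisy[bad] <- noisy[bad] + sample(c(-1L, 1L), length(bad), replace = TRUE)
    noisy <- pmax(noisy, 0L)
    tl <- timelineOf(truth)
    vapply(c(4L, 8L, 12L), function(w) {
      similarity(windowReduce(ipointsOf(noisy), w, 0.25), tl)
    }, numeric(1))
  })
  means <- rowMeans(sims)
  expect_true(all(diff(means) >= 0))
})

test_that("wSize 1 with Cthr2 0 reproduces the raw per-frame counts", {
  set.seed(35)
  rows <- lapply(0:30, function(f) {
    k <- sample(0:2, 1)
    if (k == 0) return(NULL)
    do.call(rbind, lapply(seq_len(k), function(j) {
      detAt(f, stats::runif(1, 0.2, 1), x = 40 * j)  # disjoint boxes
    }))
  })
  st <- streamOf(rows[!vapply(rows, is.null, logical(1))], nFrames = 31)
  res <- quantify(st, 1, 0, cthr2 = 0)
  raw <- streamToInformationPoints(st, 0)
  expect_identical(countMatrix(resultingPoints(res)), countMatrix(raw))
  expect_identical(frameIds(resultingPoints(res)), frameIds(raw))
})

test_that("quantify composes the stages it is defined from", {
  set.seed(36)
  sc <- generateScene(sceneParams(duration = 120, species = SP1,
                                  arrivalRate = 1 / 60, dwellMean = 60),
                      seed = 9)
  st <- corruptToDetections(sc$annotations, detectorModel(), fps = 1.6,
                            seed = 10, classes = SP1)
  res <- quantify(st, 12, 0.25, cthr2 = 20, truth = sc$timeline)
  manual <- windowReduce(
    streamToInformationPoints(nmsStream(st, 0.4), cthr2 = 20), 12, 0.25)
  expect_identical(countMatrix(resultingPoints(res)), countMatrix(manual))
  expect_equal(similarityScore(res), similarity(manual, sc$timeline))
  expect_equal(strideSeconds(res), tRIPoint(12, 0.25, 1.6))
})

test_that("the Cthr2 sweep grid reports stride times and oracle optima", {
  set.seed(37)
  sc <- constantScene(duration = 75)
  st <- corruptToDetections(sc$annotations,
                            detectorModel(pMiss = 0.05, fpRate = 0.1),
                            fps = 1.6, seed = 38, classes = SP1)
  grid <- data.frame(wSize = c(4L, 8L), wOverlap = c(0.25, 0.5))
  res <- cthr2Sweep(st, sc$timeline, windowConfigs = grid)
  expect_equal(res$tRIPoint, c(tRIPoint(4, 0.25, 1.6), tRIPoint(8, 0.5, 1.6)))
  ## exhaustive independent re-run of the 101-threshold loop
  for (i in seq_len(nrow(grid))) {
    sims <- vapply(0:100, function(thr) {
      similarity(windowReduce(streamToInformationPoints(st, thr),
                              grid$wSize[i], grid$wOverlap[i]),
                 sc$timeline)
    }, numeric(1))
    expect_equal(res$bestSimilarity[i], max(sims))
    expect_equal(res$bestCthr2[i], which.max(sims) - 1L)
  }
})

test_that("window configurations with fractional strides are rejected", {
  expect_error(WindowConfig(4, 0.3), "stride")
  expect_error(windowReduce(ipointsOf(rep(1, 20)), 10, 0.33), "stride")
  ## every parameter combination of the standard grid is valid
  for (w in c(4L, 8L, 12L)) {
    for (ov in c(0.25, 0.5, 0.75)) {
      expect_s4_class(WindowConfig(w, ov), "WindowConfig")
    }
  }
})
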