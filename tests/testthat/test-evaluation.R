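oneBoxAnn <- function(class = SP1, box = c(10, 10, 30, 30), frame = 0L) {
  FrameAnnotation(frame, 64, 64, data.frame(
    class = class, xmin = box[1], ymin = box[2], xmax = box[3], ymax = box[4]
  ))
}

detRow <- function(conf, class = SP1, box = c(10, 10, 30, 30), frame = 0L) {
  data.frame(frame = frame, class = class, confidence = conf,
             xmin = box[1], ymin = box[2], xmax = box[3], ymax = box[4],
             stringsAsFactors = FALSE)
}

test_that("matching classifies exact, cross-class and duplicate predictions", {
  gt <- oneBoxAnn()

  m <- matchPredictions(detRow(0.9), gt)
  expect_equal(nrow(truePositives(m)), 1)
  expect_equal(nrow(falsePositives(m)), 0)
  expect_equal(sum(falseNegativeCounts(m)), 0)

  ## perfect overlap but wrong species: FP, and the animal stays undetected
  m <- matchPredictions(detRow(0.9, class = "Rhizostoma_pulmo"), gt)
  expect_equal(nrow(truePositives(m)), 0)
  expect_equal(nrow(falsePositives(m)), 1)
  expect_equal(sum(falseNegativeCounts(m)), 1)

  ## two detections of one animal: the more confident one wins
  m <- matchPredictions(rbind(detRow(0.9), detRow(0.8)), gt)
  expect_equal(nrow(truePositives(m)), 1)
  expect_equal(truePositives(m)$confidence, 0.9)
  expect_equal(nrow(falsePositives(m)), 1)
  expect_equal(sum(falseNegativeCounts(m)), 0)

  expect_error(matchPredictions(detRow(0.9), gt, thrIoU = 1.5), "thrIoU")
})

test_that("IoU exactly at the threshold counts as a true positive", {
  ## shifted box with IoU exactly 0.5 against (0,0,20,10): (0,5,20,15)
  gt <- oneBoxAnn(box = c(0, 0, 20, 10))
  d <- detRow(0.9, box = c(0, 5, 20, 15))
  expect_equal(boxIoU(c(0, 0, 20, 10), c(0, 5, 20, 15)), 1 / 3)
  d2 <- detRow(0.9, box = c(0, 0, 20, 20))  # IoU = 200/400 = 0.5
  m <- matchPredictions(d2, gt, thrIoU = 0.5)
  expect_equal(nrow(truePositives(m)), 1)
})

test_that("precision, recall and F1 follow their definitions and conventions", {
  fakeMatch <- function(tp, fp, fn) {
    new("MatchResult",
      tp = cbind(do.call(rbind, rep(list(detRow(0.9)), tp)),
                 data.frame(gtFrame = rep(0L, tp), gtIndex = seq_len(tp)))[
                   seq_len(tp), , drop = FALSE],
      fp = do.call(rbind, c(rep(list(detRow(0.1)), fp), list(emptyDetectionTable()))),
      fnCounts = c(Pelagia_noctiluca = as.integer(fn)),
      gtCounts = c(Pelagia_noctiluca = as.integer(tp + fn))
    )
  }
  pr <- precisionRecall(fakeMatch(9, 1, 2))
  expect_equal(unname(pr), c(0.9, 9 / 11))
  expect_equal(unname(precisionRecall(fakeMatch(0, 0, 5))), c(0, 0))
  expect_equal(unname(precisionRecall(fakeMatch(4, 0, 0))), c(1, 1))

  expect_equal(f1Score(1, 1), 1)
  expect_equal(f1Score(0.7, 0), 0)
  expect_equal(f1Score(0, 0), 0)
  expect_equal(f1Score(0.8, 0.6), 2 * 0.8 * 0.6 / 1.4)
  pr <- c(0.62, 0.62)
  expect_equal(f1Score(pr[1], pr[2]), pr[1])  # F1 = P = R when P = R
})

test_that("average precision: degenerate rankings and the staircase oracle", {
  gt <- oneBoxAnn()
  expect_equal(averagePrecision(detRow(0.9), gt, SP1), 1)

  ## FP ranked above the TP with one ground truth: AP = 0.5
  preds <- rbind(detRow(0.9, box = c(40, 40, 60, 60)), detRow(0.8))
  expect_equal(averagePrecision(preds, gt, SP1), 0.5)

  expect_error(averagePrecision(detRow(0.9), gt, "Rhizostoma_pulmo"),
               "no ground-truth")

  set.seed(21)
  for (i in 1:40) {
    anns <- lapply(0:2, function(f) randomAnnotation(sample(1:3, 1), frame = f))
    preds <- do.call(rbind, lapply(0:2, function(f) {
      randomDetFrame(sample(1:4, 1), frame = f)
    }))
    expect_equal(
      averagePrecision(preds, anns, SP1),
      apOracle(preds, gtTableOf(anns), SP1)
    )
  }
})

test_that("11-point interpolated AP is available and close to all-point AP", {
  gt <- oneBoxAnn()
  preds <- rbind(detRow(0.9, box = c(40, 40, 60, 60)), detRow(0.8))
  ## the envelope is flat at 1/2 over all recall levels here
  expect_equal(averagePrecision(preds, gt, SP1, interpolation = "11point"), 0.5)
})

test_that("mAP is the unweighted mean of per-class APs", {
  anns <- list(
    oneBoxAnn(SP1, frame = 0L),
    oneBoxAnn("Rhizostoma_pulmo", frame = 1L)
  )
  preds <- rbind(
    detRow(0.9, SP1, frame = 0L),
    detRow(0.9, "Rhizostoma_pulmo", box = c(40, 40, 60, 60), frame = 1L),
    detRow(0.8, "Rhizostoma_pulmo", frame = 1L)
  )
  expect_equal(
    meanAveragePrecision(preds, anns, c(SP1, "Rhizostoma_pulmo")),
    mean(c(1, 0.5))
  )
  expect_error(
    meanAveragePrecision(preds, anns, jellyfishClasses()),
    "no ground-truth"
  )
})

test_that("matching invariants hold on fuzzed instances", {
  set.seed(22)
  for (i in 1:100) {
    classes <- jellyfishClasses()
    anns <- lapply(0:1, function(f) {
      randomAnnotation(sample(0:4, 1), frame = f, classes = classes)
    })
    preds <- do.call(rbind, lapply(0:1, function(f) {
      randomDetFrame(sample(1:6, 1), frame = f, classes = classes)
    }))
    m <- matchPredictions(preds, anns, classes = classes)
    expect_equal(nrow(truePositives(m)) + nrow(falsePositives(m)), nrow(preds))
    gtdf <- gtTableOf(anns)
    for (cl in classes) {
      nGt <- if (is.null(gtdf)) 0L else sum(gtdf$class == cl)
      expect_equal(
        sum(truePositives(m)$class == cl) + falseNegativeCounts(m)[[cl]],
        nGt
      )
    }
    tp <- truePositives(m)
    expect_false(any(duplicated(tp[, c("gtFrame", "gtIndex", "class")])))
    ## totals agree with the independent loop matcher
    om <- matchOracle(preds, gtdf)
    expect_equal(nrow(truePositives(m)), unname(om["tp"]))
  }
})

test_that("the Cthr1 sweep covers 101 thresholds and finds the oracle optimum", {
  set.seed(23)
  anns <- lapply(0:4, function(f) randomAnnotation(2, frame = f))
  tps <- do.call(rbind, lapply(anns, function(a) {
    ob <- annotationObjects(a)
    data.frame(frame = frameIds(a), class = ob$class,
               confidence = seq(0.90, 0.99, length.out = nrow(ob)),
               xmin = ob$xmin, ymin = ob$ymin, xmax = ob$xmax, ymax = ob$ymax)
  }))
  fps_ <- do.call(rbind, lapply(0:4, function(f) {
    d <- randomDetFrame(2, frame = f)
    d$confidence <- c(0.03, 0.08)
    d$xmin <- d$xmin + 100; d$xmax <- d$xmax + 100  # guaranteed FP
    d
  }))
  report <- confidenceSweep(rbind(tps, fps_), anns)
  sw <- sweepTable(report)
  expect_equal(nrow(sw), 101)
  expect_identical(sw$threshold, 0:100)
  ## all TPs at >= 90%, the last FP survives threshold 8%: F1 hits 1 first at 9%
  expect_equal(bestF1(report), 1)
  expect_equal(optimalCthr1(report), 9)
  oracle <- sweepOracle(rbind(tps, fps_), gtTableOf(anns))
  expect_equal(sw$f1, oracle$f1)
  expect_equal(optimalCthr1(report), oracle$best)
})

test_that("sweep at threshold 0 reproduces the unfiltered match", {
  set.seed(24)
  anns <- lapply(0:2, function(f) randomAnnotation(2, frame = f))
  preds <- do.call(rbind, lapply(0:2, function(f) randomDetFrame(3, frame = f)))
  report <- confidenceSweep(preds, anns)
  pr <- precisionRecall(matchPredictions(preds, anns))
  sw <- sweepTable(report)
  expect_equal(sw$precision[1], unname(pr["precision"]))
  expect_equal(sw$recall[1], unname(pr["recall"]))
})

test_that("empty predictions give an all-zero sweep with optimum 0", {
  anns <- list(oneBoxAnn())
  report <- confidenceSweep(emptyDetectionTable(), anns)
  expect_true(all(sweepTable(report)$f1 == 0))
  expect_equal(optimalCthr1(report), 0)
  expect_equal(meanAP(report), 0)
})

test_that("k-fold splits pair consecutive test folds and are reproducible", {
  folds <- kfoldSplit(1:10, k = 10, seed = 5)
  for (i in 1:10) {
    expect_length(folds[[i]]$test, 2)
    expect_length(folds[[i]]$train, 8)
    expect_setequal(c(folds[[i]]$train, folds[[i]]$test), 1:10)
  }
  expect_identical(kfoldSplit(1:10, k = 10, seed = 5), folds)
  expect_false(identical(kfoldSplit(1:10, k = 10, seed = 6), folds))

  ## uneven sizes differ by at most one and runs wrap around
  folds <- kfoldSplit(letters[1:13], k = 5, seed = 1)
  sizes <- lengths(lapply(folds, `[[`, "test"))
  expect_true(all(sizes >= 4 & sizes <= 6))
  for (f in folds) expect_setequal(c(f$train, f$test), letters[1:13])

  expect_error(kfoldSplit(1:10, k = 1), "at least 2")
  expect_error(kfoldSplit(1:3, k = 5), "at least k")
})
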