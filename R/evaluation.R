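## flatten a list of FrameAnnotation into one ground-truth table
.gtTable <- function(gts) {
  if (is(gts, "FrameAnnotation")) gts <- list(gts)
  rows <- lapply(gts, function(a) {
    ob <- a@objects
    if (!nrow(ob)) return(NULL)
    cbind(data.frame(frame = a@frameId, gtIndex = seq_len(nrow(ob))), ob)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(cbind(data.frame(frame = integer(), gtIndex = integer()),
                 emptyObjectTable()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match predictions to ground truth by IoU
#'
#' Classifies every prediction as a true positive or false positive
#' following the PASCAL VOC protocol: within each frame and class,
#' predictions are visited in order of descending confidence and greedily
#' assigned to the not-yet-matched ground-truth box of the same class with
#' the highest IoU, provided that IoU is at least `thrIoU`. Assigned
#' predictions are TPs; the rest (including duplicate detections of an
#' already-matched box and cross-class overlaps) are FPs. Ground-truth
#' objects left unmatched are false negatives.
#'
#' @param preds Detection `data.frame` of predictions (may span frames).
#' @param gts A [FrameAnnotation-class] or list thereof, indexed by the
#'   same frame ids as `preds`.
#' @param thrIoU IoU threshold in `(0, 1)`; default 0.5, the PASCAL VOC
#'   convention.
#' @param classes Classes over which FN counts are reported; defaults to
#'   the union of classes present in `preds` and `gts`.
#' @return A [MatchResult-class] object.
#' @export
matchPredictions <- function(preds, gts, thrIoU = 0.5, classes = NULL) {
  if (thrIoU <= 0 || thrIoU >= 1) stop("thrIoU must lie in (0, 1)")
  err <- .checkDetectionFrame(preds)
  if (!is.null(err)) stop(err)
  gt <- .gtTable(gts)
  if (is.null(classes)) {
    classes <- sort(unique(c(preds$class, gt$class)))
  }

  gtMatched <- rep(FALSE, nrow(gt))
  isTP <- rep(FALSE, nrow(preds))
  tpGtRow <- rep(NA_integer_, nrow(preds))

  ord <- order(preds$frame, preds$class, -preds$confidence, preds$xmin)
  for (i in ord) {
    cand <- which(!gtMatched &
                  gt$frame == preds$frame[i] &
                  gt$class == preds$class[i])
    if (!length(cand)) next
    ious <- .boxOverlap(.asBoxMatrix(preds[i, , drop = FALSE]),
                        .asBoxMatrix(gt[cand, , drop = FALSE]))
    j <- which.max(ious)
    if (ious[j] >= thrIoU) {
      isTP[i] <- TRUE
      tpGtRow[i] <- cand[j]
      gtMatched[cand[j]] <- TRUE
    }
  }

  tp <- preds[isTP, , drop = FALSE]
  if (nrow(tp)) {
    tp$gtFrame <- gt$frame[tpGtRow[isTP]]
    tp$gtIndex <- gt$gtIndex[tpGtRow[isTP]]
  } else {
    tp <- cbind(preds[isTP, , drop = FALSE],
                data.frame(gtFrame = integer(), gtIndex = integer()))
  }
  fp <- preds[!isTP, , drop = FALSE]
  rownames(tp) <- rownames(fp) <- NULL

  gtCounts <- vapply(classes, function(cl) sum(gt$class == cl), integer(1))
  tpCounts <- vapply(classes, function(cl) sum(tp$class == cl), integer(1))
  new("MatchResult",
    tp = tp, fp = fp,
    fnCounts = gtCounts - tpCounts, gtCounts = gtCounts
  )
}

#' Precision and recall from a match result
#'
#' `Precision = TP / (TP + FP)` and `Recall = TP / (TP + FN)`, each
#' defined as 0 when its denominator is 0.
#'
#' @param m A [MatchResult-class] object.
#' @return Named numeric vector `c(precision = , recall = )`.
#' @export
precisionRecall <- function(m) {
  stopifnot(is(m, "MatchResult"))
  tp <- nrow(m@tp)
  fp <- nrow(m@fp)
  fn <- sum(m@fnCounts)
  c(
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0
  )
}

#' F1 score
#'
#' Harmonic mean of precision and recall,
#' `2 * precision * recall / (precision + recall)`, 0 when both are 0.
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @return The F1 score as a fraction.
#' @examples
#' f1Score(0.8, 0.6)
#' @export
f1Score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Average precision of one class
#'
#' Ranks all detections of `classLabel` by descending confidence, matches
#' them greedily in rank order to the unmatched ground-truth box of the
#' class with the highest IoU at least `thrIoU` (in the detection's
#' frame), and integrates the precision--recall staircase. The default
#' interpolation is the all-point monotone precision envelope (VOC2010+);
#' the classic 11-point interpolation is available.
#'
#' @param preds Detection `data.frame` of predictions.
#' @param gts A [FrameAnnotation-class] or list thereof.
#' @param classLabel Class to evaluate; must have at least one
#'   ground-truth object, otherwise AP is undefined and an error is
#'   signalled.
#' @param thrIoU IoU threshold; default 0.5.
#' @param interpolation `"all"` (default) or `"11point"`.
#' @return AP as a fraction in `[0, 1]`.
#' @export
averagePrecision <- function(preds, gts, classLabel, thrIoU = 0.5,
                             interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  if (thrIoU <= 0 || thrIoU >= 1) stop("thrIoU must lie in (0, 1)")
  gt <- .gtTable(gts)
  gt <- gt[gt$class == classLabel, , drop = FALSE]
  nGt <- nrow(gt)
  if (nGt == 0L) {
    stop("AP undefined: no ground-truth object of class '", classLabel, "'")
  }
  d <- preds[preds$class == classLabel, , drop = FALSE]
  if (!nrow(d)) return(0)
  d <- d[order(-d$confidence, d$frame, d$xmin), , drop = FALSE]

  gtMatched <- rep(FALSE, nGt)
  isTP <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    cand <- which(!gtMatched & gt$frame == d$frame[i])
    if (!length(cand)) next
    ious <- .boxOverlap(.asBoxMatrix(d[i, , drop = FALSE]),
                        .asBoxMatrix(gt[cand, , drop = FALSE]))
    j <- which.max(ious)
    if (ious[j] >= thrIoU) {
      isTP[i] <- TRUE
      gtMatched[cand[j]] <- TRUE
    }
  }
  cumTP <- cumsum(isTP)
  cumFP <- cumsum(!isTP)
  recall <- cumTP / nGt
  precision <- cumTP / (cumTP + cumFP)

  if (interpolation == "all") {
    env <- rev(cummax(rev(precision)))
    sum(diff(c(0, recall)) * env)
  } else {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      p <- precision[recall >= r]
      if (length(p)) max(p) else 0
    }, numeric(1)))
  }
}

#' Mean average precision over classes
#'
#' Unweighted mean of [averagePrecision()] over the class vocabulary.
#' Errors if any class has no ground-truth objects (its AP is undefined).
#'
#' @inheritParams averagePrecision
#' @param classes Classes to average over.
#' @return mAP as a fraction.
#' @export
meanAveragePrecision <- function(preds, gts, classes, thrIoU = 0.5,
                                 interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  aps <- vapply(classes, function(cl) {
    averagePrecision(preds, gts, cl, thrIoU = thrIoU,
                     interpolation = interpolation)
  }, numeric(1))
  mean(aps)
}

#' Confidence-threshold sweep and full evaluation report
#'
#' Sweeps the prediction confidence threshold `Cthr1` from 0\% to 100\% in
#' 1\% steps (101 thresholds). At each step, predictions below the
#' threshold are deleted and precision, recall and F1 are recomputed from
#' the resulting TP/FP/FN classification (true positives removed by the
#' filter become false negatives). The optimal `Cthr1` is the threshold
#' with the highest F1, ties broken toward the lowest threshold (retaining
#' more detections at equal F1). Per-class AP and mAP are computed from
#' the unfiltered, ranked predictions.
#'
#' @inheritParams averagePrecision
#' @param classes Class vocabulary; defaults to classes present in the
#'   ground truth.
#' @return An [EvaluationReport-class] object.
#' @export
confidenceSweep <- function(preds, gts, thrIoU = 0.5, classes = NULL,
                            interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  gt <- .gtTable(gts)
  if (is.null(classes)) classes <- sort(unique(gt$class))

  thresholds <- 0:100
  prf <- vapply(thresholds, function(thr) {
    m <- matchPredictions(filterByConfidence(preds, thr), gts,
                          thrIoU = thrIoU, classes = classes)
    pr <- precisionRecall(m)
    c(pr, f1 = f1Score(pr[["precision"]], pr[["recall"]]))
  }, numeric(3))
  sweep <- data.frame(
    threshold = thresholds,
    precision = prf["precision", ],
    recall = prf["recall", ],
    f1 = prf["f1", ]
  )
  best <- which.max(sweep$f1)  # first maximum = lowest threshold

  aps <- vapply(classes, function(cl) {
    averagePrecision(preds, gts, cl, thrIoU = thrIoU,
                     interpolation = interpolation)
  }, numeric(1))

  new("EvaluationReport",
    perClassAP = aps, mAP = mean(aps), sweep = sweep,
    optimalCthr1 = sweep$threshold[best], bestF1 = sweep$f1[best]
  )
}

#' k-fold cross-validation splits with paired test folds
#'
#' Splits item ids into `k` equally sized folds (sizes differing by at
#' most one) and builds `k` train/test runs where run `i` uses folds `i`
#' and `i + 1` (mod `k`) as the test set — two folds (20\% of the data for
#' `k = 10`) — and the remaining folds as training data.
#'
#' @param itemIds Vector of item identifiers, `length(itemIds) >= k`.
#' @param k Number of folds (>= 2); default 10.
#' @param seed Optional integer seed for the shuffle; same seed, same
#'   split.
#' @return List of `k` lists with elements `train` and `test`.
#' @export
kfoldSplit <- function(itemIds, k = 10, seed = NULL) {
  if (k < 2) stop("k must be at least 2")
  n <- length(itemIds)
  if (n < k) stop("need at least k items")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(itemIds)
  assign <- rep(seq_len(k), length.out = n)
  folds <- split(perm, assign)
  lapply(seq_len(k), function(i) {
    testFolds <- c(i, i %% k + 1L)
    list(
      train = unname(unlist(folds[-testFolds])),
      test = unname(unlist(folds[testFolds]))
    )
  })
}
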