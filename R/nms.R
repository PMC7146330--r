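#' Non-maxima suppression of one frame's detections
#'
#' Greedy suppression of overlapping detections: detections are visited in
#' order of descending confidence (ties broken toward the lower `xmin`,
#' then lower `ymin`, for determinism); each kept detection suppresses
#' every remaining detection whose overlap with it exceeds `overlapThr`.
#' The default threshold of 0.40 is deliberately restrictive, reflecting
#' that two jellyfish rarely appear superimposed in the frame; suppression
#' is class-agnostic for the same geometric reason.
#'
#' The overlap measure defaults to IoU and can be switched to
#' intersection-over-minimum-area (`"iomin"`).
#'
#' @param dets Detection `data.frame` from a single frame.
#' @param overlapThr Overlap threshold in `(0, 1)`; default 0.40.
#' @param measure `"iou"` (default) or `"iomin"`.
#' @return The surviving subset of `dets`, input order preserved.
#' @examples
#' d <- data.frame(frame = 0L, class = "Pelagia_noctiluca",
#'                 confidence = c(0.9, 0.8),
#'                 xmin = 0, ymin = 0, xmax = 10, ymax = 10)
#' nonMaximaSuppression(d)  # only the 0.9 detection survives
#' @export
nonMaximaSuppression <- function(dets, overlapThr = 0.40,
                                 measure = c("iou", "iomin")) {
  measure <- match.arg(measure)
  if (overlapThr <= 0 || overlapThr >= 1) {
    stop("overlapThr must lie in (0, 1)")
  }
  err <- .checkDetectionFrame(dets)
  if (!is.null(err)) stop(err)
  n <- nrow(dets)
  if (n == 0L) return(dets)
  if (length(unique(dets$frame)) > 1L) {
    stop("nonMaximaSuppression expects detections from a single frame; ",
         "use nmsStream() for whole streams")
  }
  boxes <- .asBoxMatrix(dets)
  ord <- order(-dets$confidence, dets$xmin, dets$ymin)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive)
    if (length(cand)) {
      ov <- .boxOverlap(boxes[i, , drop = FALSE],
                        boxes[cand, , drop = FALSE], measure = measure)
      alive[cand[ov > overlapThr]] <- FALSE
    }
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Non-maxima suppression over a whole detection stream
#'
#' Applies [nonMaximaSuppression()] frame by frame.
#'
#' @param stream A [DetectionStream-class] object.
#' @inheritParams nonMaximaSuppression
#' @return A [DetectionStream-class] with suppressed detections removed.
#' @export
nmsStream <- function(stream, overlapThr = 0.40, measure = c("iou", "iomin")) {
  stopifnot(is(stream, "DetectionStream"))
  measure <- match.arg(measure)
  d <- stream@detections
  if (nrow(d)) {
    kept <- lapply(split(d, d$frame), nonMaximaSuppression,
                   overlapThr = overlapThr, measure = measure)
    d <- do.call(rbind, kept)
    rownames(d) <- NULL
  }
  DetectionStream(d, fps = stream@fps, frameIds = stream@frameIds,
                  classes = stream@classes)
}

#' Confidence-threshold filtering of detections
#'
#' Deletes detections whose confidence, expressed in percent, is strictly
#' lower than `threshold` (survivors satisfy `confidence * 100 >=
#' threshold`), preserving order. This is the `Cthr1`/`Cthr2` filtering
#' step of the prediction and quantification branches.
#'
#' @param dets Detection `data.frame` (any mix of frames) or a
#'   [DetectionStream-class].
#' @param threshold Confidence threshold in percent, `[0, 100]`.
#' @return Object of the same type as `dets` with only survivors.
#' @examples
#' d <- data.frame(frame = 0L, class = "Pelagia_noctiluca",
#'                 confidence = c(0.11, 0.10),
#'                 xmin = 0, ymin = 0, xmax = 10, ymax = 10)
#' filterByConfidence(d, 11)  # the 0.11 detection survives
#' @export
filterByConfidence <- function(dets, threshold) {
  if (threshold < 0 || threshold > 100) {
    stop("threshold must be a percentage in [0, 100]")
  }
  if (is(dets, "DetectionStream")) {
    d <- dets@detections
    d <- d[d$confidence * 100 >= threshold, , drop = FALSE]
    rownames(d) <- NULL
    return(DetectionStream(d, fps = dets@fps, frameIds = dets@frameIds,
                           classes = dets@classes))
  }
  err <- .checkDetectionFrame(dets)
  if (!is.null(err)) stop(err)
  out <- dets[dets$confidence * 100 >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
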