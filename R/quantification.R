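#' Per-frame information points from a detection stream
#'
#' First step of the quantification branch: detections with confidence
#' below `cthr2` (percent) are deleted, then each analyzed frame —
#' including frames with no surviving detection — yields one information
#' point: the vector of per-species detection counts, timestamped at
#' `frame / fps`.
#'
#' @param stream A [DetectionStream-class] object.
#' @param cthr2 Quantification confidence threshold in percent; default 0
#'   (raw counts).
#' @return An [InformationPoints-class] object with one point per
#'   analyzed frame, species columns in `stream`'s class order.
#' @export
streamToInformationPoints <- function(stream, cthr2 = 0) {
  stopifnot(is(stream, "DetectionStream"))
  if (cthr2 < 0 || cthr2 > 100) stop("cthr2 must be a percentage in [0, 100]")
  d <- stream@detections
  d <- d[d$confidence * 100 >= cthr2, , drop = FALSE]
  fids <- stream@frameIds
  classes <- stream@classes
  counts <- matrix(0L, nrow = length(fids), ncol = length(classes),
                   dimnames = list(NULL, classes))
  if (nrow(d)) {
    fi <- match(d$frame, fids)
    ci <- match(d$class, classes)
    tab <- table(factor(fi, levels = seq_along(fids)),
                 factor(ci, levels = seq_along(classes)))
    counts[] <- as.integer(tab)
  }
  InformationPoints(fids, counts, fids / stream@fps)
}

## modal count of a window column with deterministic tie-breaks:
## ties go to the previous resulting value if it is among the tied
## candidates, otherwise to the lower count
.windowMode <- function(v, prev) {
  tab <- tabulate(v + 1L)
  m <- max(tab)
  cand <- which(tab == m) - 1L
  if (length(cand) == 1L) return(cand)
  if (!is.na(prev) && prev %in% cand) return(prev)
  min(cand)
}

#' Windowed-mode reduction of information points
#'
#' Core of the quantification algorithm: sliding windows of `wSize`
#' consecutive information points, advancing by a stride of
#' `wSize * (1 - wOverlap)` points, are each reduced to one resulting
#' information point whose count, per species independently, is the most
#' occurring count within the window. This suppresses sporadic detection
#' errors (missed animals, spurious boxes) that flip individual frames.
#'
#' Modal ties are broken toward the previous resulting point's value for
#' that species (temporal continuity), then toward the lower count
#' (conservative against false alarms). Each resulting point is stamped at
#' the window's final contributing frame — the causal, real-time choice.
#'
#' @param points An [InformationPoints-class] object.
#' @param wSize Window length in information points.
#' @param wOverlap Fractional overlap between consecutive windows in
#'   `[0, 1)`; the stride must come out as a whole number of points.
#' @return An [InformationPoints-class] object of resulting points; empty
#'   (with a warning) when fewer than `wSize` points are available.
#' @examples
#' ip <- InformationPoints(0:7, matrix(c(1, 1, 1, 2, 1, 1, 1, 1),
#'   dimnames = list(NULL, "Pelagia_noctiluca")), (0:7) / 1.6)
#' countMatrix(windowReduce(ip, wSize = 4, wOverlap = 0.5))  # 1, 1, 1
#' @export
windowReduce <- function(points, wSize, wOverlap = 0.25) {
  stopifnot(is(points, "InformationPoints"))
  cfg <- WindowConfig(wSize, wOverlap)  # validates stride
  wSize <- cfg@wSize
  stride <- as.integer(round(wSize * (1 - cfg@wOverlap)))
  n <- length(points@frameIds)
  classes <- colnames(points@counts)
  if (n < wSize) {
    warning("fewer information points (", n, ") than wSize (", wSize,
            "); no resulting points")
    return(InformationPoints(integer(),
                             matrix(integer(), 0, length(classes),
                                    dimnames = list(NULL, classes)),
                             numeric()))
  }
  starts <- seq.int(1L, n - wSize + 1L, by = stride)
  ends <- starts + wSize - 1L
  out <- matrix(0L, nrow = length(starts), ncol = length(classes),
                dimnames = list(NULL, classes))
  for (j in seq_along(classes)) {
    col <- points@counts[, j]
    prev <- NA_integer_
    for (w in seq_along(starts)) {
      prev <- .windowMode(col[starts[w]:ends[w]], prev)
      out[w, j] <- prev
    }
  }
  InformationPoints(points@frameIds[ends], out, points@times[ends])
}

#' Time between resulting information points
#'
#' The stride duration of the windowed reduction:
#' `wSize * (1 - wOverlap) / fps` seconds. This is the effective temporal
#' resolution of the quantification output and can be tuned to the
#' monitoring target — lower `wSize` or higher `wOverlap` for a finer
#' timeline, the other way around for stronger smoothing.
#'
#' @param wSize Window length in information points.
#' @param wOverlap Fractional window overlap in `[0, 1)`.
#' @param fps Analysis rate in frames per second.
#' @return Stride duration in seconds.
#' @examples
#' tRIPoint(12, 0.25, 1.6)  # 5.625 s
#' @export
tRIPoint <- function(wSize, wOverlap, fps) {
  if (fps <= 0) stop("fps must be positive")
  if (wOverlap < 0 || wOverlap >= 1) stop("wOverlap must lie in [0, 1)")
  wSize * (1 - wOverlap) / fps
}

#' Window size preserving a stride duration at another frame rate
#'
#' Inverts [tRIPoint()]: given a detector analyzing at `fpsNew` frames per
#' second, returns the window size that keeps the time between resulting
#' information points equal to `targetTr` at overlap `wOverlap`. Used to
#' compare detectors of different speeds on an equal temporal-resolution
#' footing: faster detectors get proportionally larger windows, folding
#' more points into each mode.
#'
#' @param fpsNew Frame rate of the new detector.
#' @param targetTr Target stride duration in seconds.
#' @param wOverlap Fractional window overlap in `[0, 1)`.
#' @return Integer window size. Errors, reporting the neighbouring
#'   integers, when the exact inversion is not a whole number of points.
#' @examples
#' equivalentWindowSize(25.2, tRIPoint(4, 0.25, 1.6), 0.25)  # 63
#' @export
equivalentWindowSize <- function(fpsNew, targetTr, wOverlap = 0.25) {
  if (fpsNew <= 0) stop("fpsNew must be positive")
  if (wOverlap < 0 || wOverlap >= 1) stop("wOverlap must lie in [0, 1)")
  w <- targetTr * fpsNew / (1 - wOverlap)
  if (abs(w - round(w)) > 1e-6) {
    stop(sprintf(
      "no integer window size preserves %.6g s at %.6g fps (between %d and %d)",
      targetTr, fpsNew, floor(w), ceiling(w)))
  }
  as.integer(round(w))
}

#' Similarity between predicted and manual quantification
#'
#' The percentage of correct resulting information points over the total
#' number of resulting information points. A point is correct when its
#' full species-count vector equals the manual ground-truth counts at the
#' same frame (the frame at which the point is stamped).
#'
#' @param predicted An [InformationPoints-class] object (typically the
#'   output of [windowReduce()]).
#' @param truth A [CountTimeline-class] with an entry for every predicted
#'   frame and the same species columns.
#' @param ... Unused.
#' @return Similarity in percent.
#' @export
setMethod("similarity", signature("InformationPoints", "CountTimeline"),
  function(predicted, truth, ...) {
    n <- length(predicted@frameIds)
    if (n == 0L) stop("similarity undefined: no resulting information points")
    classes <- colnames(predicted@counts)
    if (!setequal(classes, colnames(truth@counts))) {
      stop("predicted and truth cover different species")
    }
    rows <- match(predicted@frameIds, truth@frameIds)
    if (anyNA(rows)) {
      stop("truth timeline lacks frame(s): ",
           paste(utils::head(predicted@frameIds[is.na(rows)], 5), collapse = ", "))
    }
    tc <- truth@counts[rows, classes, drop = FALSE]
    correct <- rowSums(predicted@counts != tc) == 0L
    100 * sum(correct) / n
  }
)

#' Quantification confidence-threshold sweep
#'
#' For each windowing configuration, sweeps the quantification confidence
#' threshold `Cthr2` from 0\% to 100\% in 1\% steps; at each threshold the
#' full pipeline (confidence filtering, per-frame information points,
#' windowed-mode reduction) is run and the Similarity against the manual
#' timeline computed. The reported optimum is the threshold with maximal
#' Similarity, ties broken toward the lowest threshold.
#'
#' @param stream A [DetectionStream-class] object.
#' @param truth A [CountTimeline-class] ground truth.
#' @param windowConfigs `data.frame` with columns `wSize` and `wOverlap`
#'   (one row per combination), or a list of [WindowConfig-class]
#'   objects. Default: the nine combinations of `wSize` 4/8/12 and
#'   `wOverlap` 25/50/75\%.
#' @return `data.frame` with columns `wSize`, `wOverlap`, `tRIPoint`
#'   (seconds), `bestCthr2` (percent) and `bestSimilarity` (percent).
#' @export
cthr2Sweep <- function(stream, truth,
                       windowConfigs = expand.grid(
                         wOverlap = c(0.25, 0.5, 0.75),
                         wSize = c(4L, 8L, 12L))[, 2:1]) {
  stopifnot(is(stream, "DetectionStream"), is(truth, "CountTimeline"))
  if (is.list(windowConfigs) && !is.data.frame(windowConfigs)) {
    windowConfigs <- data.frame(
      wSize = vapply(windowConfigs, function(c) c@wSize, integer(1)),
      wOverlap = vapply(windowConfigs, function(c) c@wOverlap, numeric(1))
    )
  }
  thresholds <- 0:100
  pointsByThr <- lapply(thresholds, function(thr) {
    streamToInformationPoints(stream, cthr2 = thr)
  })
  res <- lapply(seq_len(nrow(windowConfigs)), function(i) {
    wSize <- windowConfigs$wSize[i]
    wOverlap <- windowConfigs$wOverlap[i]
    sims <- vapply(pointsByThr, function(pts) {
      similarity(windowReduce(pts, wSize, wOverlap), truth)
    }, numeric(1))
    best <- which.max(sims)  # first maximum = lowest threshold
    data.frame(
      wSize = wSize, wOverlap = wOverlap,
      tRIPoint = tRIPoint(wSize, wOverlap, stream@fps),
      bestCthr2 = thresholds[best], bestSimilarity = sims[best]
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Run the full quantification algorithm
#'
#' Composition of the quantification pipeline: optional class-agnostic
#' non-maxima suppression, `Cthr2` confidence filtering, per-frame
#' information points, and windowed-mode reduction. When a manual count
#' timeline is supplied the Similarity of the result is computed.
#'
#' @param stream A [DetectionStream-class] object.
#' @param wSize Window length in information points.
#' @param wOverlap Fractional window overlap.
#' @param cthr2 Quantification confidence threshold in percent.
#' @param truth Optional [CountTimeline-class] ground truth.
#' @param applyNms Apply [nmsStream()] before quantification (default
#'   `TRUE`, matching the treatment of the prediction branch).
#' @param nmsOverlapThr NMS overlap threshold; default 0.40.
#' @return A [QuantificationResult-class] object.
#' @export
quantify <- function(stream, wSize, wOverlap = 0.25, cthr2 = 0,
                     truth = NULL, applyNms = TRUE, nmsOverlapThr = 0.40) {
  stopifnot(is(stream, "DetectionStream"))
  cfg <- WindowConfig(wSize, wOverlap, cthr2)
  if (applyNms) stream <- nmsStream(stream, overlapThr = nmsOverlapThr)
  pts <- streamToInformationPoints(stream, cthr2 = cthr2)
  rp <- windowReduce(pts, cfg@wSize, cfg@wOverlap)
  sim <- if (is.null(truth)) NA_real_ else similarity(rp, truth)
  new("QuantificationResult",
    points = rp,
    tRIPointSeconds = tRIPoint(cfg@wSize, cfg@wOverlap, stream@fps),
    similarityPct = sim, config = cfg
  )
}
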