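## reflect positions into [lo, hi] (degenerate interval collapses to lo)
.reflect <- function(x, lo, hi) {
  if (hi <= lo) return(rep(lo, length(x)))
  period <- 2 * (hi - lo)
  y <- (x - lo) %% period
  y <- ifelse(y > (hi - lo), period - y, y)
  lo + y
}

#' Generate a synthetic ground-truth scene
#'
#' Simulates a fixed-camera underwater scene as an immigration--death
#' process per species: individuals enter the field of view as a Poisson
#' process with the configured arrival rate, stay for an exponentially
#' distributed dwell time, and drift as a reflected Gaussian random walk
#' that keeps their bounding box inside the image. The scene starts in the
#' stationary regime (initial occupancy is Poisson with mean
#' `arrivalRate * dwellMean`), so the long-run mean simultaneous count per
#' species equals `arrivalRate * dwellMean` (Little's law).
#'
#' @param params A [SceneParams-class] object.
#' @param seed Integer seed; the whole scene is reproducible from it.
#' @return List with `annotations` (list of [FrameAnnotation-class], one
#'   per frame) and `timeline` (a [CountTimeline-class] whose counts equal
#'   the per-frame box counts exactly).
#' @examples
#' sc <- generateScene(sceneParams(duration = 30), seed = 1)
#' length(sc$annotations)
#' @export
generateScene <- function(params, seed) {
  stopifnot(is(params, "SceneParams"))
  set.seed(as.integer(seed))
  nFrames <- max(1L, as.integer(round(params@duration * params@fps)))
  times <- (seq_len(nFrames) - 1L) / params@fps
  W <- params@imageWidth
  H <- params@imageHeight

  rows <- vector("list", 0L)
  counts <- matrix(0L, nrow = nFrames, ncol = length(params@species),
                   dimnames = list(NULL, params@species))

  for (s in seq_along(params@species)) {
    rate <- params@arrivalRate[s]
    dwell <- params@dwellMean[s]
    ## stationary initial occupancy, then fresh arrivals over the scene
    n0 <- stats::rpois(1L, rate * dwell)
    births <- rep(0, n0)
    lifetimes <- stats::rexp(n0, rate = 1 / dwell)  # memoryless residual
    nA <- stats::rpois(1L, rate * params@duration)
    births <- c(births, sort(stats::runif(nA, 0, params@duration)))
    lifetimes <- c(lifetimes, stats::rexp(nA, rate = 1 / dwell))

    for (ind in seq_along(births)) {
      active <- which(times >= births[ind] & times < births[ind] + lifetimes[ind])
      if (!length(active)) next
      w <- stats::runif(1, params@boxSizeRange[1], params@boxSizeRange[2])
      h <- stats::runif(1, params@boxSizeRange[1], params@boxSizeRange[2])
      cx0 <- stats::runif(1, w / 2, W - w / 2)
      cy0 <- stats::runif(1, h / 2, H - h / 2)
      nAct <- length(active)
      cx <- .reflect(cx0 + c(0, cumsum(stats::rnorm(nAct - 1, 0, params@motionStep))),
                     w / 2, W - w / 2)
      cy <- .reflect(cy0 + c(0, cumsum(stats::rnorm(nAct - 1, 0, params@motionStep))),
                     h / 2, H - h / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = active - 1L, class = params@species[s],
        xmin = cx - w / 2, ymin = cy - h / 2,
        xmax = cx + w / 2, ymax = cy + h / 2,
        stringsAsFactors = FALSE
      )
      counts[active, s] <- counts[active, s] + 1L
    }
  }

  boxes <- if (length(rows)) do.call(rbind, rows) else {
    cbind(data.frame(frame = integer()), emptyObjectTable())
  }
  byFrame <- split(boxes[, c("class", .BOX_COLS)], factor(boxes$frame, levels = 0:(nFrames - 1L)))
  annotations <- lapply(seq_len(nFrames), function(f) {
    ob <- byFrame[[f]]
    rownames(ob) <- NULL
    FrameAnnotation(f - 1L, W, H, ob)
  })
  list(
    annotations = annotations,
    timeline = CountTimeline(0:(nFrames - 1L), counts)
  )
}

#' Corrupt ground truth into an imperfect detection stream
#'
#' Applies a [DetectorModel-class] to a list of annotated frames,
#' emulating a real detector: each ground-truth box is independently
#' missed with probability `pMiss`, otherwise emitted with Gaussian
#' corner jitter, its class swapped with probability `pConfuse` (when
#' more than one class is configured), and a confidence drawn from the
#' true-positive Beta law. Independently, `Poisson(fpRate)` spurious
#' detections per frame are added with uniformly placed random boxes,
#' uniformly drawn classes and confidences from the false-positive Beta
#' law. Fully reproducible given the seed.
#'
#' @param annotations List of [FrameAnnotation-class] objects (ground
#'   truth), e.g. from [generateScene()].
#' @param model A [DetectorModel-class] object.
#' @param fps Analysis rate recorded in the output stream.
#' @param seed Integer seed.
#' @param classes Class vocabulary of the stream; defaults to the labels
#'   present in the annotations.
#' @return A [DetectionStream-class] object covering every annotated
#'   frame.
#' @export
corruptToDetections <- function(annotations, model, fps, seed,
                                classes = NULL) {
  stopifnot(is(model, "DetectorModel"))
  if (is(annotations, "FrameAnnotation")) annotations <- list(annotations)
  set.seed(as.integer(seed))
  if (is.null(classes)) {
    classes <- sort(unique(unlist(lapply(annotations, function(a) a@objects$class))))
    if (!length(classes)) classes <- jellyfishClasses()
  }
  rows <- vector("list", 0L)
  for (ann in annotations) {
    ob <- ann@objects
    W <- ann@imageWidth
    H <- ann@imageHeight
    for (i in seq_len(nrow(ob))) {
      if (stats::runif(1) < model@pMiss) next
      box <- as.numeric(ob[i, .BOX_COLS])
      if (model@boxJitter > 0) {
        box <- box + stats::rnorm(4, 0, model@boxJitter)
        box[c(1, 3)] <- pmin(pmax(box[c(1, 3)], 0), W)
        box[c(2, 4)] <- pmin(pmax(box[c(2, 4)], 0), H)
        if (box[3] <= box[1]) box[3] <- min(box[1] + 1, W)
        if (box[4] <= box[2]) box[4] <- min(box[2] + 1, H)
      }
      cls <- ob$class[i]
      if (stats::runif(1) < model@pConfuse && length(classes) > 1L) {
        cls <- sample(setdiff(classes, cls), 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        frame = ann@frameId, class = cls,
        confidence = stats::rbeta(1, model@tpShape[1], model@tpShape[2]),
        xmin = box[1], ymin = box[2], xmax = box[3], ymax = box[4],
        stringsAsFactors = FALSE
      )
    }
    nFp <- stats::rpois(1L, model@fpRate)
    for (k in seq_len(nFp)) {
      w <- stats::runif(1, model@fpBoxSizeRange[1],
                        min(model@fpBoxSizeRange[2], W))
      h <- stats::runif(1, model@fpBoxSizeRange[1],
                        min(model@fpBoxSizeRange[2], H))
      cx <- stats::runif(1, w / 2, W - w / 2)
      cy <- stats::runif(1, h / 2, H - h / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = ann@frameId,
        class = sample(classes, 1L),
        confidence = stats::rbeta(1, model@fpShape[1], model@fpShape[2]),
        xmin = cx - w / 2, ymin = cy - h / 2,
        xmax = cx + w / 2, ymax = cy + h / 2,
        stringsAsFactors = FALSE
      )
    }
  }
  dets <- if (length(rows)) do.call(rbind, rows) else emptyDetectionTable()
  fids <- vapply(annotations, function(a) a@frameId, integer(1))
  DetectionStream(dets, fps = fps, frameIds = sort(fids), classes = classes)
}

#' Write a scene/detections fixture bundle to disk
#'
#' Serializes a synthetic scene and its detector output in the package's
#' on-disk formats: one VOC XML per frame under `annotations/`, the
#' detection stream as `detections.jsonl` and the ground-truth counts as
#' `truth.csv`, all re-readable by the corresponding readers.
#'
#' @param scene List with `annotations` and `timeline`, as returned by
#'   [generateScene()].
#' @param detections A [DetectionStream-class] object.
#' @param outDir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
writeFixtureBundle <- function(scene, detections, outDir) {
  annDir <- file.path(outDir, "annotations")
  dir.create(annDir, recursive = TRUE, showWarnings = FALSE)
  for (ann in scene$annotations) {
    writeVocAnnotation(ann, file.path(annDir,
                                      sprintf("frame_%06d.xml", ann@frameId)))
  }
  detPath <- file.path(outDir, "detections.jsonl")
  writeDetections(detections, detPath)
  truthPath <- file.path(outDir, "truth.csv")
  writeCountTimeline(scene$timeline, truthPath)
  invisible(list(annotations = annDir, detections = detPath,
                 truth = truthPath))
}
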