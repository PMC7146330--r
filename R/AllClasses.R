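#' @import methods
NULL

#' Default jellyfish class vocabulary
#'
#' The three Mediterranean scyphozoan species used as default class labels
#' throughout the package: \emph{Pelagia noctiluca}, \emph{Rhizostoma pulmo}
#' and \emph{Cotylorhiza tuberculata}.
#'
#' @return Character vector of three species labels.
#' @examples
#' jellyfishClasses()
#' @export
jellyfishClasses <- function() {
  c("Pelagia_noctiluca", "Rhizostoma_pulmo", "Cotylorhiza_tuberculata")
}

## columns every detection table must carry, in canonical order
.DET_COLS <- c("frame", "class", "confidence", "xmin", "ymin", "xmax", "ymax")
.BOX_COLS <- c("xmin", "ymin", "xmax", "ymax")

.checkDetectionFrame <- function(df) {
  if (!is.data.frame(df)) {
    return("detections must be a data.frame")
  }
  missing <- setdiff(.DET_COLS, names(df))
  if (length(missing)) {
    return(paste0("detections lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    return(NULL)
  }
  if (any(df$confidence < 0 | df$confidence > 1)) {
    return("confidence values must lie in [0, 1]")
  }
  if (any(df$frame < 0)) {
    return("frame indices must be non-negative")
  }
  if (any(df$xmax <= df$xmin) || any(df$ymax <= df$ymin)) {
    return("degenerate bounding box: xmax > xmin and ymax > ymin required")
  }
  NULL
}

.checkObjectFrame <- function(df) {
  if (!is.data.frame(df)) {
    return("objects must be a data.frame")
  }
  missing <- setdiff(c("class", .BOX_COLS), names(df))
  if (length(missing)) {
    return(paste0("objects lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(df) > 0L && (any(df$xmax <= df$xmin) || any(df$ymax <= df$ymin))) {
    return("degenerate bounding box: xmax > xmin and ymax > ymin required")
  }
  NULL
}

#' FrameAnnotation: ground-truth objects of one image or video frame
#'
#' Holds the manually annotated bounding boxes of a single frame, i.e. the
#' content of one LabelImg PASCAL VOC XML file. Boxes use the internal
#' half-open continuous convention with the origin at the top-left pixel
#' corner; conversion from the 1-based inclusive integer VOC convention
#' happens in [readVocAnnotation()].
#'
#' @slot frameId Non-negative integer frame/image index.
#' @slot imageWidth,imageHeight Image dimensions in pixels.
#' @slot objects `data.frame` with columns `class`, `xmin`, `ymin`,
#'   `xmax`, `ymax` (one row per annotated animal).
#' @aliases FrameAnnotation-class
#' @exportClass FrameAnnotation
setClass("FrameAnnotation",
  representation(
    frameId = "integer",
    imageWidth = "numeric",
    imageHeight = "numeric",
    objects = "data.frame"
  )
)

setValidity("FrameAnnotation", function(object) {
  msg <- character()
  if (length(object@frameId) != 1L || is.na(object@frameId) || object@frameId < 0L) {
    msg <- c(msg, "frameId must be a single non-negative integer")
  }
  if (object@imageWidth <= 0 || object@imageHeight <= 0) {
    msg <- c(msg, "image dimensions must be positive")
  }
  err <- .checkObjectFrame(object@objects)
  if (!is.null(err)) msg <- c(msg, err)
  if (is.null(err) && nrow(object@objects) > 0L) {
    ob <- object@objects
    if (any(ob$xmin < 0 | ob$ymin < 0 |
            ob$xmax > object@imageWidth | ob$ymax > object@imageHeight)) {
      msg <- c(msg, "annotated boxes must lie within the image bounds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FrameAnnotation
#'
#' @param frameId Non-negative integer frame index.
#' @param imageWidth,imageHeight Image dimensions in pixels.
#' @param objects `data.frame` with columns `class`, `xmin`, `ymin`, `xmax`,
#'   `ymax`; defaults to an empty frame.
#' @return A [FrameAnnotation-class] object.
#' @examples
#' FrameAnnotation(0, 1920, 1080,
#'   data.frame(class = "Pelagia_noctiluca",
#'              xmin = 10, ymin = 20, xmax = 200, ymax = 240))
#' @export
FrameAnnotation <- function(frameId, imageWidth, imageHeight,
                            objects = emptyObjectTable()) {
  new("FrameAnnotation",
    frameId = as.integer(frameId),
    imageWidth = as.numeric(imageWidth),
    imageHeight = as.numeric(imageHeight),
    objects = as.data.frame(objects)
  )
}

#' Empty ground-truth object table
#'
#' @return Zero-row `data.frame` with the object-table columns.
#' @export
emptyObjectTable <- function() {
  data.frame(
    class = character(), xmin = numeric(), ymin = numeric(),
    xmax = numeric(), ymax = numeric(), stringsAsFactors = FALSE
  )
}

#' Empty detection table
#'
#' @return Zero-row `data.frame` with the detection-table columns
#'   (`frame`, `class`, `confidence`, `xmin`, `ymin`, `xmax`, `ymax`).
#' @export
emptyDetectionTable <- function() {
  data.frame(
    frame = integer(), class = character(), confidence = numeric(),
    xmin = numeric(), ymin = numeric(), xmax = numeric(), ymax = numeric(),
    stringsAsFactors = FALSE
  )
}

#' DetectionStream: per-frame detector output for a video
#'
#' An ordered stream of detections produced by any object detector running
#' over a video at `fps` analyzed frames per second. The stream records the
#' full set of analyzed frames (`frameIds`), including frames with no
#' detections, so that per-frame counts of zero are representable.
#'
#' @slot fps Analysis rate in frames per second (positive).
#' @slot frameIds Strictly increasing integer vector of analyzed frames.
#' @slot detections `data.frame` with columns `frame`, `class`,
#'   `confidence`, `xmin`, `ymin`, `xmax`, `ymax`, sorted by `frame`.
#' @slot classes Configured class vocabulary; detection labels must be
#'   drawn from it.
#' @aliases DetectionStream-class
#' @exportClass DetectionStream
setClass("DetectionStream",
  representation(
    fps = "numeric",
    frameIds = "integer",
    detections = "data.frame",
    classes = "character"
  )
)

setValidity("DetectionStream", function(object) {
  msg <- character()
  if (length(object@fps) != 1L || is.na(object@fps) || object@fps <= 0) {
    msg <- c(msg, "fps must be a single positive number")
  }
  if (length(object@frameIds) && any(diff(object@frameIds) <= 0L)) {
    msg <- c(msg, "frameIds must be strictly increasing")
  }
  err <- .checkDetectionFrame(object@detections)
  if (!is.null(err)) msg <- c(msg, err)
  if (is.null(err) && nrow(object@detections) > 0L) {
    if (is.unsorted(object@detections$frame)) {
      msg <- c(msg, "detections must be sorted by frame")
    }
    if (!all(object@detections$frame %in% object@frameIds)) {
      msg <- c(msg, "every detection frame must appear in frameIds")
    }
    unknown <- setdiff(unique(object@detections$class), object@classes)
    if (length(unknown)) {
      msg <- c(msg, paste0("unknown class label(s): ", paste(unknown, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DetectionStream
#'
#' @param detections Detection `data.frame` (see [emptyDetectionTable()]).
#' @param fps Analysis rate in frames per second.
#' @param frameIds Integer vector of all analyzed frames. Defaults to
#'   `0:max(frame)` over the detections (a contiguous video), or empty when
#'   there are no detections.
#' @param classes Class vocabulary; defaults to [jellyfishClasses()].
#' @return A [DetectionStream-class] object.
#' @export
DetectionStream <- function(detections = emptyDetectionTable(), fps = 1,
                            frameIds = NULL, classes = jellyfishClasses()) {
  detections <- as.data.frame(detections)
  if (nrow(detections)) {
    detections <- detections[order(detections$frame), , drop = FALSE]
    rownames(detections) <- NULL
  }
  if (is.null(frameIds)) {
    frameIds <- if (nrow(detections)) 0:max(detections$frame) else integer()
  }
  new("DetectionStream",
    fps = as.numeric(fps), frameIds = as.integer(frameIds),
    detections = detections, classes = as.character(classes)
  )
}

#' CountTimeline: per-frame animal counts by species
#'
#' A ground-truth (or derived) timeline giving, for every frame, the number
#' of individuals of each configured species present.
#'
#' @slot frameIds Strictly increasing integer frame indices.
#' @slot counts Integer matrix, one row per frame, one named column per
#'   species; all configured species are present (zero allowed).
#' @aliases CountTimeline-class
#' @exportClass CountTimeline
setClass("CountTimeline",
  representation(frameIds = "integer", counts = "matrix")
)

setValidity("CountTimeline", function(object) {
  msg <- character()
  if (length(object@frameIds) && any(diff(object@frameIds) <= 0L)) {
    msg <- c(msg, "frameIds must be strictly increasing")
  }
  if (nrow(object@counts) != length(object@frameIds)) {
    msg <- c(msg, "counts must have one row per frame")
  }
  if (is.null(colnames(object@counts)) && ncol(object@counts) > 0L) {
    msg <- c(msg, "counts columns must be named by species")
  }
  if (length(object@counts) && any(object@counts < 0)) {
    msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CountTimeline
#'
#' @param frameIds Integer frame indices (strictly increasing).
#' @param counts Matrix (frames x species) of non-negative integer counts
#'   with species column names.
#' @return A [CountTimeline-class] object.
#' @export
CountTimeline <- function(frameIds, counts) {
  storage.mode(counts) <- "integer"
  new("CountTimeline", frameIds = as.integer(frameIds), counts = counts)
}

#' InformationPoints: timestamped per-frame count vectors
#'
#' The unit of the quantification time series: one information point per
#' analyzed frame carrying a species-count vector and its timestamp
#' (`frameId / fps`). Extends [CountTimeline-class] with times; both the
#' raw per-frame points and the windowed-mode resulting information points
#' are represented this way.
#'
#' @slot times Timestamps in seconds, parallel to `frameIds`.
#' @aliases InformationPoints-class
#' @exportClass InformationPoints
setClass("InformationPoints",
  contains = "CountTimeline",
  representation(times = "numeric")
)

setValidity("InformationPoints", function(object) {
  if (length(object@times) != length(object@frameIds)) {
    return("times must be parallel to frameIds")
  }
  TRUE
})

#' Construct InformationPoints
#'
#' @param frameIds Integer frame indices.
#' @param counts Count matrix (frames x species).
#' @param times Timestamps in seconds.
#' @return An [InformationPoints-class] object.
#' @export
InformationPoints <- function(frameIds, counts, times) {
  storage.mode(counts) <- "integer"
  new("InformationPoints",
    frameIds = as.integer(frameIds), counts = counts,
    times = as.numeric(times)
  )
}

#' MatchResult: TP/FP/FN classification of predictions against ground truth
#'
#' Result of IoU-based matching of predictions to annotated boxes: matched
#' predictions (true positives) with the index of their ground-truth
#' partner, unmatched predictions (false positives), and per-class counts
#' of undetected ground-truth objects (false negatives).
#'
#' @slot tp Detection `data.frame` of true positives with extra columns
#'   `gtFrame` and `gtIndex` identifying the matched annotation.
#' @slot fp Detection `data.frame` of false positives.
#' @slot fnCounts Named integer vector: false negatives per class.
#' @slot gtCounts Named integer vector: ground-truth objects per class.
#' @aliases MatchResult-class
#' @exportClass MatchResult
setClass("MatchResult",
  representation(
    tp = "data.frame", fp = "data.frame",
    fnCounts = "integer", gtCounts = "integer"
  )
)

setValidity("MatchResult", function(object) {
  msg <- character()
  if (any(object@fnCounts < 0L)) msg <- c(msg, "fnCounts must be non-negative")
  if (!identical(names(object@fnCounts), names(object@gtCounts))) {
    msg <- c(msg, "fnCounts and gtCounts must cover the same classes")
  }
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: AP/mAP and the optimal-confidence-threshold sweep
#'
#' Complete detector evaluation on a labelled set: per-class average
#' precision, their mean (mAP), the precision/recall/F1 curves over the
#' 0--100\% confidence sweep, and the optimal threshold `Cthr1` (the lowest
#' threshold attaining the maximal F1).
#'
#' @slot perClassAP Named numeric vector of per-class AP (fractions).
#' @slot mAP Mean of the per-class APs.
#' @slot sweep `data.frame` with columns `threshold` (percent),
#'   `precision`, `recall`, `f1`.
#' @slot optimalCthr1 Optimal confidence threshold in percent.
#' @slot bestF1 F1 score attained at `optimalCthr1`.
#' @aliases EvaluationReport-class
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(
    perClassAP = "numeric", mAP = "numeric", sweep = "data.frame",
    optimalCthr1 = "numeric", bestF1 = "numeric"
  )
)

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (length(object@perClassAP) &&
      !isTRUE(all.equal(object@mAP, mean(object@perClassAP)))) {
    msg <- c(msg, "mAP must equal the mean of perClassAP")
  }
  if (nrow(object@sweep) &&
      !isTRUE(all.equal(object@bestF1, max(object@sweep$f1)))) {
    msg <- c(msg, "bestF1 must be the maximum of the sweep F1 curve")
  }
  if (length(msg)) msg else TRUE
})

#' WindowConfig: windowing parameters of the quantification algorithm
#'
#' @slot wSize Window length in information points (positive integer).
#' @slot wOverlap Fractional overlap between consecutive windows in
#'   `[0, 1)`; the stride `wSize * (1 - wOverlap)` must be a whole number
#'   of points, at least 1.
#' @slot cthr2 Confidence threshold (percent) applied on the
#'   quantification branch.
#' @aliases WindowConfig-class
#' @exportClass WindowConfig
setClass("WindowConfig",
  representation(wSize = "integer", wOverlap = "numeric", cthr2 = "numeric")
)

setValidity("WindowConfig", function(object) {
  msg <- character()
  if (object@wSize < 1L) msg <- c(msg, "wSize must be a positive integer")
  if (object@wOverlap < 0 || object@wOverlap >= 1) {
    msg <- c(msg, "wOverlap must lie in [0, 1)")
  }
  stride <- object@wSize * (1 - object@wOverlap)
  if (abs(stride - round(stride)) > 1e-9 || round(stride) < 1) {
    msg <- c(msg, sprintf(
      "wSize * (1 - wOverlap) = %.6f is not a whole stride >= 1", stride))
  }
  if (object@cthr2 < 0 || object@cthr2 > 100) {
    msg <- c(msg, "cthr2 must be a percentage in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a WindowConfig
#'
#' @param wSize Window length in information points.
#' @param wOverlap Fractional window overlap in `[0, 1)`.
#' @param cthr2 Quantification confidence threshold in percent.
#' @return A [WindowConfig-class] object.
#' @examples
#' WindowConfig(12, 0.25, 20)
#' @export
WindowConfig <- function(wSize, wOverlap = 0.25, cthr2 = 0) {
  new("WindowConfig",
    wSize = as.integer(wSize), wOverlap = as.numeric(wOverlap),
    cthr2 = as.numeric(cthr2)
  )
}

#' QuantificationResult: output of the windowed quantification algorithm
#'
#' @slot points Resulting information points after windowed-mode reduction.
#' @slot tRIPointSeconds Time between consecutive resulting points in
#'   seconds, `wSize * (1 - wOverlap) / fps`.
#' @slot similarityPct Percentage of resulting points whose full count
#'   vector matches the ground truth; `NA` when no truth was supplied.
#' @slot config The [WindowConfig-class] used.
#' @aliases QuantificationResult-class
#' @exportClass QuantificationResult
setClass("QuantificationResult",
  representation(
    points = "InformationPoints",
    tRIPointSeconds = "numeric",
    similarityPct = "numeric",
    config = "WindowConfig"
  )
)

#' SceneParams: parameters of the synthetic underwater scene
#'
#' Describes a simulated fixed-camera underwater scene: individuals of each
#' species enter the field of view as a Poisson process, remain for an
#' exponentially distributed dwell time, and drift as a reflected random
#' walk. Defaults emulate a few minutes of footage with about one slow
#' individual in view at a time whose count changes only every few minutes.
#'
#' @slot duration Scene duration in seconds.
#' @slot fps Analyzed frames per second.
#' @slot imageWidth,imageHeight Frame size in pixels.
#' @slot species Species labels simulated.
#' @slot arrivalRate Per-species arrival rate, individuals per second
#'   (recycled over species).
#' @slot dwellMean Per-species mean dwell time in seconds (recycled).
#' @slot boxSizeRange Min/max box side length in pixels.
#' @slot motionStep Random-walk step standard deviation, pixels per frame.
#' @aliases SceneParams-class
#' @exportClass SceneParams
setClass("SceneParams",
  representation(
    duration = "numeric", fps = "numeric",
    imageWidth = "numeric", imageHeight = "numeric",
    species = "character",
    arrivalRate = "numeric", dwellMean = "numeric",
    boxSizeRange = "numeric", motionStep = "numeric"
  )
)

setValidity("SceneParams", function(object) {
  msg <- character()
  if (object@duration <= 0 || object@fps <= 0) {
    msg <- c(msg, "duration and fps must be positive")
  }
  if (object@imageWidth <= 0 || object@imageHeight <= 0) {
    msg <- c(msg, "image dimensions must be positive")
  }
  if (!length(object@species)) msg <- c(msg, "at least one species required")
  if (any(object@arrivalRate < 0) || any(object@dwellMean <= 0)) {
    msg <- c(msg, "arrival rates must be >= 0 and dwell means > 0")
  }
  if (length(object@boxSizeRange) != 2L ||
      object@boxSizeRange[1] <= 0 ||
      object@boxSizeRange[2] < object@boxSizeRange[1]) {
    msg <- c(msg, "boxSizeRange must be an increasing positive pair")
  }
  if (object@boxSizeRange[2] > min(object@imageWidth, object@imageHeight)) {
    msg <- c(msg, "boxes must fit inside the image")
  }
  if (object@motionStep < 0) msg <- c(msg, "motionStep must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct SceneParams
#'
#' @param duration Scene duration in seconds.
#' @param fps Analyzed frames per second.
#' @param imageWidth,imageHeight Frame size in pixels.
#' @param species Species labels to simulate.
#' @param arrivalRate Arrivals per second per species (recycled).
#' @param dwellMean Mean dwell time in seconds per species (recycled).
#' @param boxSizeRange Min/max box side length in pixels.
#' @param motionStep Random-walk step SD in pixels per frame.
#' @return A [SceneParams-class] object.
#' @examples
#' sceneParams(duration = 60, species = "Pelagia_noctiluca")
#' @export
sceneParams <- function(duration = 300, fps = 1.6,
                        imageWidth = 1920, imageHeight = 1080,
                        species = "Pelagia_noctiluca",
                        arrivalRate = 1 / 180, dwellMean = 180,
                        boxSizeRange = c(80, 320), motionStep = 6) {
  ns <- length(species)
  new("SceneParams",
    duration = duration, fps = fps,
    imageWidth = imageWidth, imageHeight = imageHeight,
    species = species,
    arrivalRate = rep_len(arrivalRate, ns),
    dwellMean = rep_len(dwellMean, ns),
    boxSizeRange = as.numeric(boxSizeRange), motionStep = motionStep
  )
}

#' DetectorModel: stochastic model of an imperfect detector
#'
#' Encodes the failure modes of a real detector on underwater footage:
#' sporadic missed detections (changes in luminosity, unusual animal
#' poses, surface reflexes), sporadic spurious detections, bounding-box
#' jitter and occasional species confusion. True-positive confidences are
#' Beta-distributed near 1, false-positive confidences near 0, reflecting
#' that genuine detections typically carry high confidence.
#'
#' @slot pMiss Per-instance per-frame miss probability.
#' @slot fpRate Expected spurious detections per frame (Poisson mean).
#' @slot tpShape,fpShape Beta shape pairs for TP and FP confidences.
#' @slot boxJitter Box corner jitter SD in pixels.
#' @slot pConfuse Class-swap probability for true detections.
#' @slot fpBoxSizeRange Min/max side length of spurious boxes in pixels.
#' @aliases DetectorModel-class
#' @exportClass DetectorModel
setClass("DetectorModel",
  representation(
    pMiss = "numeric", fpRate = "numeric",
    tpShape = "numeric", fpShape = "numeric",
    boxJitter = "numeric", pConfuse = "numeric",
    fpBoxSizeRange = "numeric"
  )
)

setValidity("DetectorModel", function(object) {
  msg <- character()
  if (object@pMiss < 0 || object@pMiss > 1) msg <- c(msg, "pMiss must be in [0, 1]")
  if (object@fpRate < 0) msg <- c(msg, "fpRate must be >= 0")
  if (object@pConfuse < 0 || object@pConfuse > 1) {
    msg <- c(msg, "pConfuse must be in [0, 1]")
  }
  if (length(object@tpShape) != 2L || any(object@tpShape <= 0) ||
      length(object@fpShape) != 2L || any(object@fpShape <= 0)) {
    msg <- c(msg, "Beta shape parameters must be positive pairs")
  }
  if (object@boxJitter < 0) msg <- c(msg, "boxJitter must be >= 0")
  if (length(object@fpBoxSizeRange) != 2L || object@fpBoxSizeRange[1] <= 0 ||
      object@fpBoxSizeRange[2] < object@fpBoxSizeRange[1]) {
    msg <- c(msg, "fpBoxSizeRange must be an increasing positive pair")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DetectorModel
#'
#' @param pMiss Per-instance per-frame miss probability.
#' @param fpRate Expected spurious detections per frame.
#' @param tpShape Beta shape pair for true-positive confidences
#'   (default concentrated near 1).
#' @param fpShape Beta shape pair for false-positive confidences
#'   (default concentrated near 0).
#' @param boxJitter Box corner jitter SD in pixels.
#' @param pConfuse Class-swap probability.
#' @param fpBoxSizeRange Min/max side length of spurious boxes in pixels.
#' @return A [DetectorModel-class] object.
#' @examples
#' detectorModel(pMiss = 0.1, fpRate = 0.05)
#' @export
detectorModel <- function(pMiss = 0.1, fpRate = 0.05,
                          tpShape = c(8, 1.5), fpShape = c(1.5, 8),
                          boxJitter = 2, pConfuse = 0.02,
                          fpBoxSizeRange = c(80, 320)) {
  new("DetectorModel",
    pMiss = pMiss, fpRate = fpRate,
    tpShape = as.numeric(tpShape), fpShape = as.numeric(fpShape),
    boxJitter = boxJitter, pConfuse = pConfuse,
    fpBoxSizeRange = as.numeric(fpBoxSizeRange)
  )
}
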