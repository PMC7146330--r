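#' @include AllClasses.R
NULL

#' Accessors for jellyquant objects
#'
#' Small family of accessor generics exposing the slots of the package's
#' S4 classes without touching `@`.
#'
#' @param x A jellyquant S4 object.
#' @return The corresponding component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname accessors
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))

#' @rdname accessors
#' @export
setGeneric("frameIds", function(x) standardGeneric("frameIds"))

#' @rdname accessors
#' @export
setGeneric("countMatrix", function(x) standardGeneric("countMatrix"))

#' @rdname accessors
#' @export
setGeneric("pointTimes", function(x) standardGeneric("pointTimes"))

#' @rdname accessors
#' @export
setGeneric("annotationObjects", function(x) standardGeneric("annotationObjects"))

#' @rdname accessors
#' @export
setGeneric("truePositives", function(x) standardGeneric("truePositives"))

#' @rdname accessors
#' @export
setGeneric("falsePositives", function(x) standardGeneric("falsePositives"))

#' @rdname accessors
#' @export
setGeneric("falseNegativeCounts", function(x) standardGeneric("falseNegativeCounts"))

#' @rdname accessors
#' @export
setGeneric("groundTruthCounts", function(x) standardGeneric("groundTruthCounts"))

#' @rdname accessors
#' @export
setGeneric("perClassAP", function(x) standardGeneric("perClassAP"))

#' @rdname accessors
#' @export
setGeneric("meanAP", function(x) standardGeneric("meanAP"))

#' @rdname accessors
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' @rdname accessors
#' @export
setGeneric("optimalCthr1", function(x) standardGeneric("optimalCthr1"))

#' @rdname accessors
#' @export
setGeneric("bestF1", function(x) standardGeneric("bestF1"))

#' @rdname accessors
#' @export
setGeneric("resultingPoints", function(x) standardGeneric("resultingPoints"))

#' @rdname accessors
#' @export
setGeneric("strideSeconds", function(x) standardGeneric("strideSeconds"))

#' @rdname accessors
#' @export
setGeneric("similarityScore", function(x) standardGeneric("similarityScore"))

#' @rdname accessors
#' @export
setGeneric("windowConfig", function(x) standardGeneric("windowConfig"))

#' Similarity between predicted and manual quantification
#'
#' Generic for the Similarity metric; see the method for
#' [InformationPoints-class] against [CountTimeline-class].
#'
#' @param predicted Predicted resulting information points.
#' @param truth Manual ground-truth counts.
#' @param ... Passed to methods.
#' @export
setGeneric("similarity", function(predicted, truth, ...) {
  standardGeneric("similarity")
})

## ---- accessor methods ----

#' @rdname accessors
#' @export
setMethod("fps", "DetectionStream", function(x) x@fps)

#' @rdname accessors
#' @export
setMethod("detections", "DetectionStream", function(x) x@detections)

#' @rdname accessors
#' @export
setMethod("frameIds", "DetectionStream", function(x) x@frameIds)

#' @rdname accessors
#' @export
setMethod("frameIds", "CountTimeline", function(x) x@frameIds)

#' @rdname accessors
#' @export
setMethod("frameIds", "FrameAnnotation", function(x) x@frameId)

#' @rdname accessors
#' @export
setMethod("countMatrix", "CountTimeline", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("pointTimes", "InformationPoints", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("annotationObjects", "FrameAnnotation", function(x) x@objects)

#' @rdname accessors
#' @export
setMethod("truePositives", "MatchResult", function(x) x@tp)

#' @rdname accessors
#' @export
setMethod("falsePositives", "MatchResult", function(x) x@fp)

#' @rdname accessors
#' @export
setMethod("falseNegativeCounts", "MatchResult", function(x) x@fnCounts)

#' @rdname accessors
#' @export
setMethod("groundTruthCounts", "MatchResult", function(x) x@gtCounts)

#' @rdname accessors
#' @export
setMethod("perClassAP", "EvaluationReport", function(x) x@perClassAP)

#' @rdname accessors
#' @export
setMethod("meanAP", "EvaluationReport", function(x) x@mAP)

#' @rdname accessors
#' @export
setMethod("sweepTable", "EvaluationReport", function(x) x@sweep)

#' @rdname accessors
#' @export
setMethod("optimalCthr1", "EvaluationReport", function(x) x@optimalCthr1)

#' @rdname accessors
#' @export
setMethod("bestF1", "EvaluationReport", function(x) x@bestF1)

#' @rdname accessors
#' @export
setMethod("resultingPoints", "QuantificationResult", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("strideSeconds", "QuantificationResult", function(x) x@tRIPointSeconds)

#' @rdname accessors
#' @export
setMethod("similarityScore", "QuantificationResult", function(x) x@similarityPct)

#' @rdname accessors
#' @export
setMethod("windowConfig", "QuantificationResult", function(x) x@config)

## ---- show methods ----

setMethod("show", "FrameAnnotation", function(object) {
  cat(sprintf(
    "FrameAnnotation: frame %d (%gx%g px), %d object(s)\n",
    object@frameId, object@imageWidth, object@imageHeight,
    nrow(object@objects)
  ))
  if (nrow(object@objects)) {
    tab <- table(object@objects$class)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "DetectionStream", function(object) {
  cat(sprintf(
    "DetectionStream: %d detection(s) over %d frame(s) at %.3g fps\n",
    nrow(object@detections), length(object@frameIds), object@fps
  ))
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
})

setMethod("show", "CountTimeline", function(object) {
  cat(sprintf(
    "CountTimeline: %d frame(s), %d species\n",
    length(object@frameIds), ncol(object@counts)
  ))
  if (ncol(object@counts)) {
    m <- colMeans(object@counts)
    cat("  mean counts:",
        paste(sprintf("%s %.2f", colnames(object@counts), m), collapse = ", "),
        "\n")
  }
})

setMethod("show", "InformationPoints", function(object) {
  cat(sprintf(
    "InformationPoints: %d point(s) spanning %.1f s, %d species\n",
    length(object@frameIds),
    if (length(object@times)) diff(range(object@times)) else 0,
    ncol(object@counts)
  ))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf(
    "MatchResult: TP %d, FP %d, FN %d (over %d ground-truth object(s))\n",
    nrow(object@tp), nrow(object@fp), sum(object@fnCounts),
    sum(object@gtCounts)
  ))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  for (cl in names(object@perClassAP)) {
    cat(sprintf("  AP[%s] = %.1f%%\n", cl, 100 * object@perClassAP[[cl]]))
  }
  cat(sprintf("  mAP = %.1f%%\n", 100 * object@mAP))
  cat(sprintf("  optimal Cthr1 = %g%% (F1 = %.1f%%)\n",
              object@optimalCthr1, 100 * object@bestF1))
})

setMethod("show", "WindowConfig", function(object) {
  cat(sprintf(
    "WindowConfig: wSize %d, wOverlap %g%%, Cthr2 %g%%\n",
    object@wSize, 100 * object@wOverlap, object@cthr2
  ))
})

setMethod("show", "QuantificationResult", function(object) {
  cat(sprintf(
    "QuantificationResult: %d resulting point(s), one every %.2f s\n",
    length(object@points@frameIds), object@tRIPointSeconds
  ))
  show(object@config)
  if (!is.na(object@similarityPct)) {
    cat(sprintf("  Similarity = %.1f%%\n", object@similarityPct))
  }
})

setMethod("show", "SceneParams", function(object) {
  cat(sprintf(
    "SceneParams: %.0f s at %g fps, %gx%g px, species: %s\n",
    object@duration, object@fps, object@imageWidth, object@imageHeight,
    paste(object@species, collapse = ", ")
  ))
})

setMethod("show", "DetectorModel", function(object) {
  cat(sprintf(
    "DetectorModel: pMiss %.3g, fpRate %.3g/frame, jitter %.3g px, pConfuse %.3g\n",
    object@pMiss, object@fpRate, object@boxJitter, object@pConfuse
  ))
})
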