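#' Intersection over union of axis-aligned bounding boxes
#'
#' Computes IoU, the area of the intersection of two boxes divided by the
#' area of their union, the standard similarity between a predicted and an
#' annotated box. Boxes use continuous pixel coordinates
#' `(xmin, ymin, xmax, ymax)` with a half-open `[min, max)` convention, so
#' the area is `(xmax - xmin) * (ymax - ymin)`.
#'
#' @param a,b Numeric length-4 vectors `(xmin, ymin, xmax, ymax)` or
#'   matrices with those four columns. When one argument has a single box
#'   it is recycled against the other, giving vectorized one-vs-many IoU.
#' @return Numeric vector of IoU values in `[0, 1]`; 0 for disjoint boxes,
#'   1 only for identical boxes.
#' @examples
#' boxIoU(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
boxIoU <- function(a, b) {
  .boxOverlap(a, b, measure = "iou")
}

.asBoxMatrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 4L)
    return(x)
  }
  if (is.data.frame(x)) {
    return(as.matrix(x[, .BOX_COLS, drop = FALSE]))
  }
  stopifnot(length(x) == 4L)
  matrix(as.numeric(x), nrow = 1L)
}

## shared kernel for iou and intersection-over-min-area
.boxOverlap <- function(a, b, measure = c("iou", "iomin")) {
  measure <- match.arg(measure)
  a <- .asBoxMatrix(a)
  b <- .asBoxMatrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  areaA <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  areaB <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  if (any(areaA <= 0) || any(areaB <= 0)) {
    stop("degenerate bounding box: zero or negative area")
  }
  iw <- pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1])
  ih <- pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  denom <- switch(measure,
    iou = areaA + areaB - inter,
    iomin = pmin(areaA, areaB)
  )
  inter / denom
}
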