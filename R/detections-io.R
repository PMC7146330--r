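#' Read a JSON-lines detection stream
#'
#' The interchange format for detector output is JSON lines: a header
#' object on the first line carrying the analysis rate
#' (`{"fps": ..., "frame_start": ..., "frame_count": ...}`), then one
#' object per detection:
#' `{"frame": 12, "class": "Pelagia_noctiluca", "confidence": 0.93,
#' "bbox": [xmin, ymin, xmax, ymax]}`. The format is streaming-friendly
#' and appendable, suiting the real-time use case.
#'
#' Records are sorted by frame on read (with a warning if the file was out
#' of order). When the header omits the frame span, analyzed frames are
#' taken as `0:max(frame)`. An empty file yields an empty stream.
#'
#' @param path Path to the `.jsonl` file.
#' @param classes Class vocabulary; labels outside it are an error.
#' @return A [DetectionStream-class] object.
#' @seealso [writeDetections()]
#' @export
readDetections <- function(path, classes = jellyfishClasses()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(DetectionStream(emptyDetectionTable(), fps = 1,
                           frameIds = integer(), classes = classes))
  }
  header <- tryCatch(jsonlite::fromJSON(lines[[1]]),
                     error = function(e) stop("line 1: malformed JSON header"))
  if (is.null(header$fps)) stop("line 1: header must carry \"fps\"")
  fps <- as.numeric(header$fps)

  recs <- lapply(seq_along(lines)[-1], function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop("line ", i, ": malformed JSON record"))
    for (f in c("frame", "class", "confidence", "bbox")) {
      if (is.null(rec[[f]])) stop("line ", i, ": missing field \"", f, "\"")
    }
    if (length(rec$bbox) != 4L || any(is.na(as.numeric(rec$bbox)))) {
      stop("line ", i, ": malformed bbox (need 4 numbers)")
    }
    conf <- as.numeric(rec$confidence)
    if (is.na(conf) || conf < 0 || conf > 1) {
      stop("line ", i, ": confidence outside [0, 1]")
    }
    bb <- as.numeric(rec$bbox)
    if (bb[3] <= bb[1] || bb[4] <= bb[2]) {
      stop("line ", i, ": degenerate bbox")
    }
    data.frame(
      frame = as.integer(rec$frame), class = as.character(rec$class),
      confidence = conf,
      xmin = bb[1], ymin = bb[2], xmax = bb[3], ymax = bb[4],
      stringsAsFactors = FALSE
    )
  })
  dets <- if (length(recs)) do.call(rbind, recs) else emptyDetectionTable()
  if (nrow(dets) && is.unsorted(dets$frame)) {
    warning("detection records out of frame order in ", path, "; sorting")
  }
  unknown <- setdiff(unique(dets$class), classes)
  if (length(unknown)) {
    stop("unknown class label(s) in ", path, ": ", paste(unknown, collapse = ", "))
  }
  frameIds <- if (!is.null(header$frames)) {
    as.integer(header$frames)
  } else if (!is.null(header$frame_count)) {
    seq(from = as.integer(header$frame_start %||% 0L),
        length.out = as.integer(header$frame_count))
  } else NULL
  DetectionStream(dets, fps = fps, frameIds = frameIds, classes = classes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a DetectionStream as JSON lines
#'
#' Inverse of [readDetections()]; confidences are written at full double
#' precision so the round trip is lossless.
#'
#' @param stream A [DetectionStream-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeDetections <- function(stream, path) {
  stopifnot(is(stream, "DetectionStream"))
  fids <- stream@frameIds
  header <- list(fps = stream@fps)
  if (length(fids)) {
    if (identical(as.integer(fids), seq(fids[1], length.out = length(fids)))) {
      header$frame_start <- fids[1]
      header$frame_count <- length(fids)
    } else {
      header$frames <- fids
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  d <- stream@detections
  for (i in seq_len(nrow(d))) {
    rec <- list(
      frame = d$frame[i], class = d$class[i], confidence = d$confidence[i],
      bbox = c(d$xmin[i], d$ymin[i], d$xmax[i], d$ymax[i])
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
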