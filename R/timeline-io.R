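#' Read a count-timeline CSV
#'
#' A count timeline serializes the manual per-frame labels used as ground
#' truth for quantification: a CSV with a `frame_id` column plus one
#' column of non-negative integer counts per species.
#'
#' @param path Path to the CSV file.
#' @param classes Class vocabulary. All listed classes must be present as
#'   columns; extra columns are ignored with a warning. `NULL` takes every
#'   non-`frame_id` column as a class.
#' @return A [CountTimeline-class] object.
#' @seealso [writeCountTimeline()]
#' @export
readCountTimeline <- function(path, classes = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"frame_id" %in% names(df)) {
    stop("count timeline must have a frame_id column")
  }
  if (is.null(classes)) {
    classes <- setdiff(names(df), "frame_id")
  } else {
    missing <- setdiff(classes, names(df))
    if (length(missing)) {
      stop("count timeline lacks class column(s): ",
           paste(missing, collapse = ", "))
    }
    extra <- setdiff(names(df), c("frame_id", classes))
    if (length(extra)) {
      warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
    }
  }
  counts <- as.matrix(df[, classes, drop = FALSE])
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  ord <- order(df$frame_id)
  CountTimeline(df$frame_id[ord], counts[ord, , drop = FALSE])
}

#' Write a CountTimeline as CSV
#'
#' @param timeline A [CountTimeline-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeCountTimeline <- function(timeline, path) {
  stopifnot(is(timeline, "CountTimeline"))
  df <- data.frame(frame_id = timeline@frameIds, check.names = FALSE)
  for (cl in colnames(timeline@counts)) {
    df[[cl]] <- timeline@counts[, cl]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
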