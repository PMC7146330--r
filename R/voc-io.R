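#' Read a LabelImg PASCAL VOC XML annotation
#'
#' Parses one annotation file in the LabelImg dialect of PASCAL VOC XML
#' (root `<annotation>` with `<size>` and one `<object>` per animal, each
#' carrying `<name>` and a `<bndbox>`). VOC stores 1-based inclusive
#' integer pixel coordinates; these are converted to the internal
#' half-open convention as `xmin - 1, ymin - 1, xmax, ymax`, which makes
#' box areas exact pixel counts.
#'
#' @param path Path to the `.xml` file.
#' @param classes Optional class vocabulary; object names outside it are
#'   an error. `NULL` (default) accepts any name.
#' @param frameId Frame index to assign; by default parsed from the
#'   trailing integer of the `<filename>` element (e.g.
#'   `frame_000042.jpg` gives 42), falling back to 0.
#' @return A [FrameAnnotation-class] object, objects in file order.
#' @seealso [writeVocAnnotation()]
#' @export
readVocAnnotation <- function(path, classes = NULL, frameId = NULL) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "annotation") {
    stop("unknown XML root <", xml2::xml_name(doc), ">: expected <annotation>")
  }
  sz <- xml2::xml_find_first(doc, "./size")
  if (inherits(sz, "xml_missing")) stop("missing <size> element")
  width <- as.numeric(xml2::xml_text(xml2::xml_find_first(sz, "./width")))
  height <- as.numeric(xml2::xml_text(xml2::xml_find_first(sz, "./height")))
  if (is.na(width) || is.na(height)) stop("missing <width>/<height> in <size>")

  if (is.null(frameId)) {
    fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
    m <- regmatches(fname, regexpr("[0-9]+(?=\\.[A-Za-z]+$)", fname, perl = TRUE))
    frameId <- if (length(m) && nzchar(m)) as.integer(m) else 0L
  }

  objs <- xml2::xml_find_all(doc, "./object")
  rows <- lapply(objs, function(o) {
    name <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    if (is.na(name) || !nzchar(name)) stop("object without <name> element")
    bb <- xml2::xml_find_first(o, "./bndbox")
    if (inherits(bb, "xml_missing")) {
      stop("object '", name, "' without <bndbox> element")
    }
    coord <- vapply(c("xmin", "ymin", "xmax", "ymax"), function(f) {
      v <- xml2::xml_text(xml2::xml_find_first(bb, paste0("./", f)))
      if (is.na(v) || !nzchar(v)) {
        stop("missing <", f, "> in <bndbox> of object '", name, "'")
      }
      as.numeric(v)
    }, numeric(1))
    ## VOC 1-based inclusive -> internal half-open
    data.frame(
      class = name,
      xmin = coord[["xmin"]] - 1, ymin = coord[["ymin"]] - 1,
      xmax = coord[["xmax"]], ymax = coord[["ymax"]],
      stringsAsFactors = FALSE
    )
  })
  objects <- if (length(rows)) do.call(rbind, rows) else emptyObjectTable()
  if (nrow(objects) && any(objects$xmax <= objects$xmin | objects$ymax <= objects$ymin)) {
    stop("degenerate bounding box after VOC conversion (xmax <= xmin or ymax <= ymin)")
  }
  if (!is.null(classes) && nrow(objects)) {
    unknown <- setdiff(unique(objects$class), classes)
    if (length(unknown)) {
      stop("unknown class label(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
  }
  FrameAnnotation(frameId, width, height, objects)
}

#' Write a FrameAnnotation as LabelImg PASCAL VOC XML
#'
#' Inverse of [readVocAnnotation()]: internal half-open coordinates are
#' converted back to 1-based inclusive VOC integers
#' (`xmin + 1, ymin + 1, xmax, ymax`) and rounded to the nearest integer,
#' as LabelImg writes integer pixel coordinates.
#'
#' @param annotation A [FrameAnnotation-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeVocAnnotation <- function(annotation, path) {
  stopifnot(is(annotation, "FrameAnnotation"))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "annotations")
  xml2::xml_add_child(doc, "filename",
                      sprintf("frame_%06d.jpg", annotation@frameId))
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", format(round(annotation@imageWidth)))
  xml2::xml_add_child(sz, "height", format(round(annotation@imageHeight)))
  xml2::xml_add_child(sz, "depth", "3")
  xml2::xml_add_child(doc, "segmented", "0")
  ob <- annotation@objects
  for (i in seq_len(nrow(ob))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", ob$class[i])
    xml2::xml_add_child(o, "pose", "Unspecified")
    xml2::xml_add_child(o, "truncated", "0")
    xml2::xml_add_child(o, "difficult", "0")
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(round(ob$xmin[i] + 1)))
    xml2::xml_add_child(bb, "ymin", format(round(ob$ymin[i] + 1)))
    xml2::xml_add_child(bb, "xmax", format(round(ob$xmax[i])))
    xml2::xml_add_child(bb, "ymax", format(round(ob$ymax[i])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a directory of VOC annotations
#'
#' @param dir Directory containing `.xml` annotation files.
#' @param classes Optional class vocabulary passed to
#'   [readVocAnnotation()].
#' @return List of [FrameAnnotation-class] objects sorted by frame id.
#' @export
readVocDirectory <- function(dir, classes = NULL) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  anns <- lapply(files, readVocAnnotation, classes = classes)
  anns[order(vapply(anns, function(a) a@frameId, integer(1)))]
}
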