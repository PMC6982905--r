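#' PASCAL VOC annotation for one image
#'
#' @param folder,filename Strings recorded in the annotation; `filename` must
#'   be non-empty.
#' @param width,height,depth Image size in pixels and channel count.
#' @param objects List of `bbox` objects; every box must lie inside the
#'   image.
#' @return An object of class `voc_annotation`.
#' @export
voc_annotation <- function(folder, filename, width, height, depth = 3L,
                           objects = list()) {
  if (!nzchar(filename)) stop("filename must be non-empty")
  if (width <= 0 || height <= 0) stop("width and height must be positive")
  objects <- lapply(objects, as_bbox)
  for (b in objects) {
    if (b$xmin < 0 || b$ymin < 0 || b$xmax > width || b$ymax > height)
      stop("object box lies outside the image")
  }
  structure(
    list(folder = folder, filename = filename,
         width = as.integer(width), height = as.integer(height),
         depth = as.integer(depth), objects = objects),
    class = "voc_annotation"
  )
}

#' @method print voc_annotation
#' @export
print.voc_annotation <- function(x, ...) {
  cat(sprintf("<voc_annotation %s: %d x %d x %d, %d object(s)>\n",
              x$filename, x$width, x$height, x$depth, length(x$objects)))
  invisible(x)
}

#' Write a PASCAL VOC XML annotation
#'
#' Produces a LabelImg-compatible XML file with folder / filename / size /
#' object / bndbox elements. The package's 0-based half-open box coordinates
#' are converted to VOC's 1-based inclusive pixel convention on write
#' (`xmin + 1 .. xmax`), and back on read, so write/read is a lossless
#' roundtrip.
#'
#' @param ann A [voc_annotation()] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_voc <- function(ann, path) {
  if (!inherits(ann, "voc_annotation")) stop("expected a voc_annotation")
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", ann$folder)
  xml2::xml_add_child(doc, "filename", ann$filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(ann$width))
  xml2::xml_add_child(size, "height", format(ann$height))
  xml2::xml_add_child(size, "depth", format(ann$depth))
  for (b in ann$objects) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", b$label)
    bnd <- xml2::xml_add_child(obj, "bndbox")
    # VOC stores 1-based inclusive integer pixel coordinates
    xml2::xml_add_child(bnd, "xmin", format(as.integer(b$xmin) + 1L))
    xml2::xml_add_child(bnd, "ymin", format(as.integer(b$ymin) + 1L))
    xml2::xml_add_child(bnd, "xmax", format(as.integer(b$xmax)))
    xml2::xml_add_child(bnd, "ymax", format(as.integer(b$ymax)))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

voc_text <- function(node, name) {
  child <- xml2::xml_find_first(node, name)
  if (inherits(child, "xml_missing"))
    stop(sprintf("VOC annotation is missing element <%s>", name))
  xml2::xml_text(child)
}

#' Read a PASCAL VOC XML annotation
#'
#' Inverse of [write_voc()] on files it wrote; also accepts annotations with
#' the extra elements LabelImg emits (pose, truncated, difficult, source,
#' segmented), which are ignored.
#'
#' @param path Path to a VOC XML file.
#' @return A [voc_annotation()] object.
#' @export
read_voc <- function(path) {
  doc <- xml2::read_xml(path)
  size <- xml2::xml_find_first(doc, "size")
  if (inherits(size, "xml_missing")) stop("VOC annotation is missing <size>")
  width <- as.integer(voc_text(size, "width"))
  height <- as.integer(voc_text(size, "height"))
  depth <- as.integer(voc_text(size, "depth"))
  objects <- lapply(xml2::xml_find_all(doc, "object"), function(obj) {
    bnd <- xml2::xml_find_first(obj, "bndbox")
    if (inherits(bnd, "xml_missing"))
      stop("VOC <object> is missing element <bndbox>")
    xmin <- as.integer(voc_text(bnd, "xmin")) - 1L
    ymin <- as.integer(voc_text(bnd, "ymin")) - 1L
    xmax <- as.integer(voc_text(bnd, "xmax"))
    ymax <- as.integer(voc_text(bnd, "ymax"))
    if (any(is.na(c(xmin, ymin, xmax, ymax))))
      stop("non-integer coordinate in <bndbox>")
    if (xmin >= xmax || ymin >= ymax)
      stop("invalid <bndbox>: xmin >= xmax or ymin >= ymax")
    bbox(xmin, ymin, xmax, ymax, score = 1,
         label = xml2::xml_text(xml2::xml_find_first(obj, "name")))
  })
  voc_annotation(folder = voc_text(doc, "folder"),
                 filename = voc_text(doc, "filename"),
                 width = width, height = height, depth = depth,
                 objects = objects)
}

#' Write tracking records as CSV
#'
#' Machine-readable twin of the annotated video: one row per (frame, track),
#' with the position, whether it came from a detection or was filled from the
#' Kalman prediction, whether the nine-point correction moved it, and whether
#' the track had been coasting without detections for long ("stale").
#'
#' @param records Data frame from [track_video()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tracks_csv <- function(records, path) {
  need <- c("frame", "track_id", "x", "y", "source", "corrected", "stale")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0)
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  utils::write.csv(records[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
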