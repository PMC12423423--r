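# Annotation file formats. roLabelImg stores each rotated box as
# center/sides/angle (angle in radians) inside a PASCAL-VOC-like XML file;
# DOTA-style text stores the four corner coordinates per line plus the class
# name and either a difficulty flag (ground truth) or a score (detections).
# Internal representation is always the normalized long-side box table.

.xml_field <- function(node, name, path) {
  child <- xml2::xml_find_first(node, name)
  if (inherits(child, "xml_missing")) {
    abort(sprintf("missing field <%s> in %s", name, path),
      class = "spikeobb_schema_error"
    )
  }
  child
}

.xml_num <- function(node, name, path) {
  val <- suppressWarnings(as.numeric(xml2::xml_text(.xml_field(node, name, path))))
  if (is.na(val)) {
    abort(sprintf("field <%s> in %s is not numeric", name, path),
      class = "spikeobb_schema_error"
    )
  }
  val
}

#' Read a roLabelImg XML annotation
#'
#' Parses the `robndbox` entries (center, sides, angle in radians) of a
#' roLabelImg file, converts angles to degrees and normalizes every box to
#' the long-side convention.
#'
#' @param path Path to the XML file.
#' @return An [annotated_image()] without pixels: boxes plus the image size
#'   and id (file name stem).
#' @export
read_rolabelimg <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "spikeobb_missing_file")
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("malformed XML in ", path, ": ", conditionMessage(e)),
      class = "spikeobb_parse_error"
    )
  })
  size <- .xml_field(doc, "size", path)
  width <- .xml_num(size, "width", path)
  height <- .xml_num(size, "height", path)
  objects <- xml2::xml_find_all(doc, "object")
  rows <- lapply(objects, function(obj) {
    cls <- xml2::xml_text(.xml_field(obj, "name", path))
    rb <- .xml_field(obj, "robndbox", path)
    diff_node <- xml2::xml_find_first(obj, "difficult")
    tibble::tibble(
      cx = .xml_num(rb, "cx", path),
      cy = .xml_num(rb, "cy", path),
      w = .xml_num(rb, "w", path),
      h = .xml_num(rb, "h", path),
      theta = .xml_num(rb, "angle", path) * 180 / pi,
      cls = cls,
      score = NA_real_,
      difficult = if (inherits(diff_node, "xml_missing")) {
        0L
      } else {
        as.integer(xml2::xml_text(diff_node))
      }
    )
  })
  boxes <- dplyr::bind_rows(rows)
  if (nrow(boxes) == 0) {
    boxes <- oriented_box(
      numeric(0), numeric(0), numeric(0), numeric(0),
      numeric(0)
    )
    boxes$difficult <- integer(0)
  } else {
    boxes <- normalize_boxes(boxes)
  }
  fn_node <- xml2::xml_find_first(doc, "filename")
  id <- if (inherits(fn_node, "xml_missing")) {
    sub("\\.xml$", "", basename(path))
  } else {
    sub("\\.[^.]+$", "", xml2::xml_text(fn_node))
  }
  annotated_image(NULL, boxes, image_id = id, width = width, height = height)
}

#' Write a roLabelImg XML annotation
#'
#' @param img An [annotated_image()] (pixels not required).
#' @param path Output XML path.
#' @return `path`, invisibly.
#' @export
write_rolabelimg <- function(img, path) {
  stopifnot(inherits(img, "annotated_image"))
  boxes <- normalize_boxes(img$boxes)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", paste0(img$image_id, ".png"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(img$width))
  xml2::xml_add_child(size, "height", format(img$height))
  xml2::xml_add_child(size, "depth", "3")
  num <- function(x) trimws(formatC(x, format = "g", digits = 12))
  cls <- if ("cls" %in% names(boxes)) boxes$cls else rep("spike", nrow(boxes))
  diffc <- if ("difficult" %in% names(boxes)) {
    boxes$difficult
  } else {
    rep(0L, nrow(boxes))
  }
  for (i in seq_len(nrow(boxes))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "type", "robndbox")
    xml2::xml_add_child(obj, "name", cls[i])
    xml2::xml_add_child(obj, "difficult", as.character(diffc[i]))
    rb <- xml2::xml_add_child(obj, "robndbox")
    xml2::xml_add_child(rb, "cx", num(boxes$cx[i]))
    xml2::xml_add_child(rb, "cy", num(boxes$cy[i]))
    xml2::xml_add_child(rb, "w", num(boxes$w[i]))
    xml2::xml_add_child(rb, "h", num(boxes$h[i]))
    xml2::xml_add_child(rb, "angle", num(boxes$theta[i] * pi / 180))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read DOTA-style text annotations
#'
#' Each line holds the four corner coordinates
#' `x1 y1 x2 y2 x3 y3 x4 y4`, the class name, and a final column that is the
#' difficulty flag for ground truth or the detection score for detections.
#' Corners are converted back to an oriented box as the minimum-area
#' enclosing rotated rectangle.
#'
#' @param path Path to the text file.
#' @param type `"ground-truth"` (final column is difficulty) or
#'   `"detections"` (final column is a score in `[0, 1]`).
#' @return A normalized box tibble (with `difficult` or `score` filled in).
#' @export
read_dota <- function(path, type = c("ground-truth", "detections")) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "spikeobb_missing_file")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 10) {
      abort(sprintf(
        "line %d of %s: expected 10 columns, found %d",
        i, path, length(parts)
      ), class = "spikeobb_parse_error")
    }
    coords <- suppressWarnings(as.numeric(parts[1:8]))
    last <- suppressWarnings(as.numeric(parts[10]))
    if (anyNA(coords) || is.na(last)) {
      abort(sprintf("line %d of %s: non-numeric field", i, path),
        class = "spikeobb_parse_error"
      )
    }
    box <- min_rotated_rect(matrix(coords, ncol = 2, byrow = TRUE))
    box$cls <- parts[9]
    if (type == "detections") {
      box$score <- last
    } else {
      box$score <- NA_real_
      box$difficult <- as.integer(last)
    }
    box
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- oriented_box(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0))
    if (type == "ground-truth") out$difficult <- integer(0)
  }
  out
}

#' Write DOTA-style text annotations
#'
#' @param boxes A normalized box table; needs a complete `score` column when
#'   `type = "detections"`.
#' @param path Output text path.
#' @inheritParams read_dota
#' @return `path`, invisibly.
#' @export
write_dota <- function(boxes, path, type = c("ground-truth", "detections")) {
  type <- match.arg(type)
  validate_boxes(boxes)
  if (type == "detections" && (is.null(boxes$score) || anyNA(boxes$score))) {
    abort("detections need a complete score column", class = "spikeobb_invalid_input")
  }
  num <- function(x) trimws(formatC(x, format = "g", digits = 12))
  cls <- if ("cls" %in% names(boxes)) boxes$cls else rep("spike", nrow(boxes))
  diffc <- if ("difficult" %in% names(boxes)) {
    boxes$difficult
  } else {
    rep(0L, nrow(boxes))
  }
  lines <- vapply(seq_len(nrow(boxes)), function(i) {
    p <- .corners1(
      boxes$cx[i], boxes$cy[i], boxes$w[i], boxes$h[i],
      boxes$theta[i]
    )
    last <- if (type == "detections") num(boxes$score[i]) else as.character(diffc[i])
    paste(paste(num(as.vector(t(p))), collapse = " "), cls[i], last)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read an annotated image's pixels as PNG
#'
#' Thin wrappers over the png package; pixel values are stored as 8-bit and
#' round-trip exactly for integer-valued arrays.
#'
#' @param img An [annotated_image()] with pixels.
#' @param path PNG file path.
#' @return `write_image_png()`: `path`, invisibly. `read_image_png()`: an
#'   `H x W x 3` array in `[0, 255]`.
#' @export
write_image_png <- function(img, path) {
  stopifnot(inherits(img, "annotated_image"))
  if (is.null(img$pixels)) {
    abort("no pixels to write", class = "spikeobb_invalid_input")
  }
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "spikeobb_missing_file")
  }
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  round(a[, , 1:3, drop = FALSE] * 255)
}
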