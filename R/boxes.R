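#' Build a table of oriented bounding boxes
#'
#' An oriented box is parameterized by its center `(cx, cy)` in continuous
#' pixel coordinates (origin at the top-left corner of the image, x to the
#' right, y downward), its side lengths `w` and `h` in pixels, and `theta`,
#' the angle in degrees between the box's *long* side and the x-axis. Under
#' the long-side convention a box is unchanged by adding 180 degrees to
#' `theta`, so normalized boxes carry `theta` in `[0, 180)` with `w >= h`.
#'
#' @param cx,cy Box center coordinates (px).
#' @param w,h Side lengths (px); must be strictly positive.
#' @param theta Angle of the long side against the x-axis (degrees).
#' @param cls Category label; detection work here is single-class ("spike").
#' @param score Detection confidence in `[0, 1]`, or `NA` for ground truth.
#' @return A tibble with columns `cx`, `cy`, `w`, `h`, `theta`, `cls`,
#'   `score`, one row per box. Angles are stored as given; use
#'   [normalize_boxes()] to enforce the long-side convention.
#' @seealso [normalize_boxes()], [box_corners()], [rotated_iou()]
#' @examples
#' oriented_box(100, 50, 80, 20, 30)
#' @export
oriented_box <- function(cx, cy, w, h, theta, cls = "spike", score = NA_real_) {
  b <- tibble::tibble(
    cx = as.double(cx), cy = as.double(cy),
    w = as.double(w), h = as.double(h),
    theta = as.double(theta),
    cls = as.character(cls), score = as.double(score)
  )
  validate_boxes(b)
  b
}

#' Validate a box table
#'
#' Checks that the required columns are present, all geometric fields are
#' finite and both side lengths are strictly positive. Degenerate
#' (zero-area) boxes are rejected rather than treated as segments.
#'
#' @param boxes A data frame with columns `cx`, `cy`, `w`, `h`, `theta`.
#' @return The input, invisibly; errors with class
#'   `"spikeobb_invalid_box"` on violation.
#' @export
validate_boxes <- function(boxes) {
  needed <- c("cx", "cy", "w", "h", "theta")
  miss <- setdiff(needed, names(boxes))
  if (length(miss) > 0) {
    abort(
      paste0("box table is missing column(s): ", paste(miss, collapse = ", ")),
      class = "spikeobb_invalid_box"
    )
  }
  geom <- as.matrix(boxes[needed])
  mode(geom) <- "double"
  if (nrow(boxes) > 0 && !all(is.finite(geom))) {
    abort("box geometry must be finite", class = "spikeobb_invalid_box")
  }
  if (any(boxes$w <= 0 | boxes$h <= 0)) {
    abort("box side lengths must be strictly positive",
      class = "spikeobb_invalid_box"
    )
  }
  invisible(boxes)
}

#' Normalize boxes to the long-side convention
#'
#' Swaps `w` and `h` (adding 90 degrees) wherever `w < h`, then wraps
#' `theta` into `[0, 180)`. The returned boxes describe exactly the same
#' rectangles as the input.
#'
#' @param boxes A box table (see [oriented_box()]).
#' @return The box table with `w >= h` and `theta` in `[0, 180)` everywhere.
#' @examples
#' normalize_boxes(oriented_box(0, 0, 2, 6, 10)) # -> w 6, h 2, theta 100
#' @export
normalize_boxes <- function(boxes) {
  validate_boxes(boxes)
  swap <- boxes$w < boxes$h
  if (any(swap)) {
    tmp <- boxes$w[swap]
    boxes$w[swap] <- boxes$h[swap]
    boxes$h[swap] <- tmp
    boxes$theta[swap] <- boxes$theta[swap] + 90
  }
  boxes$theta <- boxes$theta %% 180
  boxes
}

#' Corner coordinates of oriented boxes
#'
#' @param boxes A box table.
#' @return A tibble with columns `box` (input row index), `corner` (1..4,
#'   in cyclic order) and the corner coordinates `x`, `y`.
#' @export
box_corners <- function(boxes) {
  validate_boxes(boxes)
  n <- nrow(boxes)
  out <- purrr::map(seq_len(n), function(i) {
    p <- .corners1(boxes$cx[i], boxes$cy[i], boxes$w[i], boxes$h[i], boxes$theta[i])
    tibble::tibble(box = i, corner = 1:4, x = p[, 1], y = p[, 2])
  })
  dplyr::bind_rows(out)
}

# 4x2 corner matrix of one box, cyclic order; orientation is consistent so
# the polygon has positive signed (shoelace) area.
.corners1 <- function(cx, cy, w, h, theta) {
  t <- theta * pi / 180
  ct <- cos(t)
  st <- sin(t)
  u <- c(-1, 1, 1, -1) * (w / 2)
  v <- c(-1, -1, 1, 1) * (h / 2)
  cbind(cx + u * ct - v * st, cy + u * st + v * ct)
}

# coerce polygon input (matrix or data frame with x/y) to an n x 2 matrix
.as_poly <- function(poly) {
  if (is.data.frame(poly)) {
    if (!all(c("x", "y") %in% names(poly))) {
      abort("polygon data frame needs columns x and y", class = "spikeobb_invalid_input")
    }
    poly <- cbind(poly$x, poly$y)
  }
  poly <- as.matrix(poly)
  if (length(poly) == 0) {
    return(matrix(numeric(0), 0, 2))
  }
  if (ncol(poly) != 2) {
    abort("polygon must have two coordinate columns", class = "spikeobb_invalid_input")
  }
  storage.mode(poly) <- "double"
  unname(poly)
}
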