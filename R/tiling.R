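# Tiling of large UAV frames into fixed-size sub-images with annotation
# clipping. The grid strides by the tile size; the final row/column is
# anchored to the image edge (so it may overlap its neighbour). A box
# belongs to the tile containing at least half its area, ties to the lower
# tile index; the assigned box is clipped to the tile and re-fit as the
# minimum-area rotated rectangle in tile coordinates.

# Smallest enclosing rotated rectangle that stays inside the tile. The
# unconstrained minimum-area rectangle of a clipped polygon can overshoot the
# cut line, so candidates (hull-edge orientations) are kept only when their
# corners lie within the tile; the axis-aligned candidate always does, since
# the polygon itself is inside the tile.
.min_rect_in_bounds <- function(points, xlim, ylim, tol = 1e-6) {
  p <- .dedupe_vertices(.as_poly(points))
  hull <- p[rev(grDevices::chull(p[, 1], p[, 2])), , drop = FALSE]
  n <- nrow(hull)
  angs <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    angs <- c(angs, atan2(hull[j, 2] - hull[i, 2], hull[j, 1] - hull[i, 1]))
  }
  best <- NULL
  best_area <- Inf
  for (ang in angs) {
    ct <- cos(-ang)
    st <- sin(-ang)
    rx <- p[, 1] * ct - p[, 2] * st
    ry <- p[, 1] * st + p[, 2] * ct
    wx <- max(rx) - min(rx)
    wy <- max(ry) - min(ry)
    if (wx <= 0 || wy <= 0) next
    mx <- (max(rx) + min(rx)) / 2
    my <- (max(ry) + min(ry)) / 2
    cx <- mx * cos(ang) - my * sin(ang)
    cy <- mx * sin(ang) + my * cos(ang)
    crn <- .corners1(cx, cy, wx, wy, ang * 180 / pi)
    if (any(crn[, 1] < xlim[1] - tol | crn[, 1] > xlim[2] + tol |
      crn[, 2] < ylim[1] - tol | crn[, 2] > ylim[2] + tol)) {
      next
    }
    if (wx * wy < best_area - .VERTEX_TOL) {
      best_area <- wx * wy
      best <- c(cx, cy, wx, wy, ang * 180 / pi)
    }
  }
  normalize_boxes(oriented_box(best[1], best[2], best[3], best[4], best[5]))
}

.tile_origins <- function(extent, tile) {
  xs <- seq(0, extent - tile, by = tile)
  if (xs[length(xs)] != extent - tile) xs <- c(xs, extent - tile)
  xs
}

#' Tile an annotated image
#'
#' Cuts the image into `tile_w x tile_h` sub-images on a stride-equal grid
#' with edge-anchored final tiles, so a 4032 x 2268 frame yields
#' `ceiling(4032/600) * ceiling(2268/600) = 28` tiles of 600 px. Each
#' ground-truth box is assigned to the first tile (row-major order)
#' containing at least 50% of its area, then clipped to that tile,
#' re-fit as the smallest enclosing rotated rectangle that stays within the
#' tile, and re-expressed in tile coordinates.
#'
#' @param img An [annotated_image()].
#' @param tile_w,tile_h Tile extent in px (default 600); must not exceed the
#'   image extent.
#' @return A list of [annotated_image()] tiles, ids suffixed
#'   `_tile_<col>_<row>` with zero-based grid indices.
#' @export
tile_image <- function(img, tile_w = 600, tile_h = tile_w) {
  stopifnot(inherits(img, "annotated_image"))
  if (tile_w > img$width || tile_h > img$height) {
    abort("tile is larger than the image", class = "spikeobb_invalid_config")
  }
  xs <- .tile_origins(img$width, tile_w)
  ys <- .tile_origins(img$height, tile_h)
  boxes <- normalize_boxes(img$boxes)
  nb <- nrow(boxes)
  m <- .box_rows(boxes)
  areas <- boxes$w * boxes$h
  assigned <- rep(FALSE, nb)
  tiles <- list()
  for (yi in seq_along(ys)) {
    for (xi in seq_along(xs)) {
      x0 <- xs[xi]
      y0 <- ys[yi]
      rect <- cbind(
        c(x0, x0 + tile_w, x0 + tile_w, x0),
        c(y0, y0, y0 + tile_h, y0 + tile_h)
      )
      rows <- list()
      for (b in seq_len(nb)) {
        if (assigned[b]) next
        clipped <- .clip_convex(
          .corners1(m[b, 1], m[b, 2], m[b, 3], m[b, 4], m[b, 5]),
          rect
        )
        frac <- polygon_area(clipped) / areas[b]
        if (frac >= 0.5 - .VERTEX_TOL) {
          assigned[b] <- TRUE
          local <- .min_rect_in_bounds(
            clipped,
            c(x0, x0 + tile_w), c(y0, y0 + tile_h)
          )
          local$cx <- local$cx - x0
          local$cy <- local$cy - y0
          if ("cls" %in% names(boxes)) local$cls <- boxes$cls[b]
          if ("score" %in% names(boxes)) local$score <- boxes$score[b]
          rows[[length(rows) + 1]] <- local
        }
      }
      tile_boxes <- if (length(rows)) {
        dplyr::bind_rows(rows)
      } else {
        oriented_box(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0))
      }
      px <- if (is.null(img$pixels)) {
        NULL
      } else {
        img$pixels[(y0 + 1):(y0 + tile_h), (x0 + 1):(x0 + tile_w), , drop = FALSE]
      }
      tiles[[length(tiles) + 1]] <- annotated_image(
        px, tile_boxes,
        image_id = sprintf("%s_tile_%d_%d", img$image_id, xi - 1, yi - 1),
        width = tile_w, height = tile_h
      )
    }
  }
  tiles
}
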