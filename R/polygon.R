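# Convex polygon machinery: triangulated areas, Sutherland-Hodgman clipping,
# minimum-area enclosing rotated rectangles. All coordinates are continuous
# pixels in the image frame (x right, y down); "counter-clockwise" below means
# positive signed shoelace area in that stored frame.

.VERTEX_TOL <- 1e-9

.signed_area <- function(p) {
  n <- nrow(p)
  if (n < 3) {
    return(0)
  }
  x <- p[, 1]
  y <- p[, 2]
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

.ensure_ccw <- function(p) {
  if (nrow(p) >= 3 && .signed_area(p) < 0) p[nrow(p):1, , drop = FALSE] else p
}

# drop consecutive duplicate vertices (closer than tol), including the wrap
.dedupe_vertices <- function(p, tol = .VERTEX_TOL) {
  n <- nrow(p)
  if (n == 0) {
    return(p)
  }
  keep <- rep(TRUE, n)
  prev <- p[n, ]
  for (i in seq_len(n)) {
    if (max(abs(p[i, ] - prev)) < tol) {
      keep[i] <- FALSE
    } else {
      prev <- p[i, ]
    }
  }
  p[keep, , drop = FALSE]
}

#' Area of a convex polygon by fan triangulation
#'
#' Splits the polygon into triangles sharing vertex 1 (the fan apex) and sums
#' their areas, the triangle-sum construction used when measuring the overlap
#' region of two oriented boxes. The `"shoelace"` method evaluates the
#' classical surveyor's formula instead; for a convex polygon the two agree
#' to floating-point precision.
#'
#' @param poly Polygon vertices in cyclic order: a two-column matrix or a
#'   data frame with columns `x`, `y`.
#' @param method `"fan"` (default) or `"shoelace"`.
#' @return The enclosed area (px^2), `0` for fewer than 3 vertices.
#' @examples
#' polygon_area(cbind(c(0, 1, 0), c(0, 0, 1))) # 0.5
#' @export
polygon_area <- function(poly, method = c("fan", "shoelace")) {
  method <- match.arg(method)
  p <- .as_poly(poly)
  n <- nrow(p)
  if (n < 3) {
    return(0)
  }
  if (method == "shoelace") {
    return(abs(.signed_area(p)))
  }
  a <- 0
  x0 <- p[1, 1]
  y0 <- p[1, 2]
  for (i in 2:(n - 1)) {
    a <- a + abs((p[i, 1] - x0) * (p[i + 1, 2] - y0) -
      (p[i + 1, 1] - x0) * (p[i, 2] - y0)) / 2
  }
  a
}

#' Intersection of two convex polygons
#'
#' Sutherland-Hodgman clipping of `a` against each edge of `b`. For two
#' rectangles the result has 0 or 3 to 8 vertices (triangle through octagon).
#' Touching contact (a shared edge or point) yields a degenerate polygon of
#' zero area, which is returned empty.
#'
#' @param a,b Convex polygons (two-column matrix or data frame with `x`, `y`).
#' @return A tibble with columns `x`, `y`: the intersection's vertices in
#'   counter-clockwise order, zero rows when the interiors are disjoint.
#' @export
convex_intersection <- function(a, b) {
  p <- .clip_convex(.as_poly(a), .as_poly(b))
  tibble::tibble(x = p[, 1], y = p[, 2])
}

.clip_convex <- function(subject, clip, tol = .VERTEX_TOL) {
  subject <- .ensure_ccw(.dedupe_vertices(subject))
  clip <- .ensure_ccw(.dedupe_vertices(clip))
  if (nrow(subject) < 3 || nrow(clip) < 3) {
    return(matrix(numeric(0), 0, 2))
  }
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    n <- nrow(out)
    if (n == 0) break
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1] - a[1]
    ey <- b[2] - a[2]
    # signed side of each vertex: >= 0 is inside (left of the CCW edge)
    d <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    res <- vector("list", 2L * n)
    m <- 0L
    for (j in seq_len(n)) {
      k <- if (j == n) 1L else j + 1L
      if (d[j] >= -tol) {
        m <- m + 1L
        res[[m]] <- out[j, ]
      }
      if ((d[j] > tol && d[k] < -tol) || (d[j] < -tol && d[k] > tol)) {
        t <- d[j] / (d[j] - d[k])
        m <- m + 1L
        res[[m]] <- out[j, ] + t * (out[k, ] - out[j, ])
      }
    }
    out <- if (m == 0L) matrix(numeric(0), 0, 2) else do.call(rbind, res[seq_len(m)])
  }
  out <- .dedupe_vertices(out)
  if (nrow(out) < 3 || abs(.signed_area(out)) < tol) {
    return(matrix(numeric(0), 0, 2))
  }
  out
}

#' Minimum-area enclosing rotated rectangle
#'
#' Rotating-calipers search over the convex hull: the minimum-area enclosing
#' rectangle of a point set has one side collinear with a hull edge, so each
#' hull edge direction is tried and the tightest kept. Used when converting
#' DOTA corner polygons, or tile-clipped polygons, back to an oriented box.
#'
#' @param points Two-column matrix or data frame with `x`, `y` (>= 3 distinct
#'   points not all collinear).
#' @return A one-row normalized box table ([oriented_box()]).
#' @export
min_rotated_rect <- function(points) {
  p <- .dedupe_vertices(.as_poly(points))
  if (nrow(p) < 3) {
    abort("need at least 3 distinct points", class = "spikeobb_invalid_input")
  }
  hull <- p[rev(grDevices::chull(p[, 1], p[, 2])), , drop = FALSE] # CCW
  n <- nrow(hull)
  if (n < 3) {
    abort("points are collinear; no enclosing rectangle", class = "spikeobb_invalid_input")
  }
  best <- NULL
  best_area <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ang <- atan2(hull[j, 2] - hull[i, 2], hull[j, 1] - hull[i, 1])
    ct <- cos(-ang)
    st <- sin(-ang)
    rx <- hull[, 1] * ct - hull[, 2] * st
    ry <- hull[, 1] * st + hull[, 2] * ct
    wx <- max(rx) - min(rx)
    wy <- max(ry) - min(ry)
    area <- wx * wy
    if (area < best_area - .VERTEX_TOL) {
      best_area <- area
      mx <- (max(rx) + min(rx)) / 2
      my <- (max(ry) + min(ry)) / 2
      best <- list(
        cx = mx * cos(ang) - my * sin(ang),
        cy = mx * sin(ang) + my * cos(ang),
        w = wx, h = wy, theta = ang * 180 / pi
      )
    }
  }
  normalize_boxes(oriented_box(best$cx, best$cy, best$w, best$h, best$theta))
}
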