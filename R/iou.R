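# Rotated-box overlap measures. The exported verbs are vectorized row-wise
# over two box tables (recycling a single row); internal single-pair kernels
# carry a cheap center-distance prescreen so dense all-pairs sweeps (NMS,
# matching) stay fast.

.iou_pair <- function(b1, b2) {
  # b* = c(cx, cy, w, h, theta)
  inter <- .inter_area_pair(b1, b2)
  a1 <- b1[3] * b1[4]
  a2 <- b2[3] * b2[4]
  inter / (a1 + a2 - inter)
}

.inter_area_pair <- function(b1, b2) {
  dx <- b1[1] - b2[1]
  dy <- b1[2] - b2[2]
  reach <- (sqrt(b1[3]^2 + b1[4]^2) + sqrt(b2[3]^2 + b2[4]^2)) / 2
  if (dx * dx + dy * dy > reach * reach) {
    return(0)
  }
  p1 <- .corners1(b1[1], b1[2], b1[3], b1[4], b1[5])
  p2 <- .corners1(b2[1], b2[2], b2[3], b2[4], b2[5])
  polygon_area(.clip_convex(p1, p2))
}

.box_rows <- function(boxes) {
  validate_boxes(boxes)
  unname(as.matrix(boxes[c("cx", "cy", "w", "h", "theta")]))
}

.recycle2 <- function(a, b) {
  if (nrow(a) == nrow(b)) {
    return(list(a = a, b = b))
  }
  if (nrow(a) == 1L) {
    return(list(a = a[rep(1L, nrow(b)), , drop = FALSE], b = b))
  }
  if (nrow(b) == 1L) {
    return(list(a = a, b = b[rep(1L, nrow(a)), , drop = FALSE]))
  }
  abort("box tables must have equal row counts (or one row)",
    class = "spikeobb_invalid_input"
  )
}

#' Rotated intersection-over-union
#'
#' Exact IoU of oriented boxes: the intersection polygon is obtained by
#' convex clipping and its area by fan triangulation, so any of the
#' triangle-to-octagon overlap shapes two rectangles can form is handled
#' exactly. Symmetric; 1 for identical point sets, 0 for disjoint interiors.
#'
#' @param a,b Box tables, matched row-wise (one may have a single row).
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' rotated_iou(oriented_box(0, 0, 2, 2, 0), oriented_box(1, 0, 2, 2, 0)) # 1/3
#' @export
rotated_iou <- function(a, b) {
  m <- .recycle2(.box_rows(a), .box_rows(b))
  vapply(
    seq_len(nrow(m$a)),
    function(i) .iou_pair(m$a[i, ], m$b[i, ]),
    numeric(1)
  )
}

#' Overlap area over the sum of box areas
#'
#' The duplicate-detection criterion: intersection area divided by the *sum*
#' of the two box areas, `area(a ∩ b) / (area(a) + area(b))`. It ranges
#' over `[0, 0.5]`, reaching 0.5 exactly when the boxes coincide, which makes
#' it a bounded alternative to IoU for deciding that two detections cover the
#' same spike.
#'
#' @inheritParams rotated_iou
#' @return Numeric vector of ratios in `[0, 0.5]`.
#' @seealso [oriented_nms()]
#' @export
overlap_ratio_sum <- function(a, b) {
  m <- .recycle2(.box_rows(a), .box_rows(b))
  vapply(seq_len(nrow(m$a)), function(i) {
    b1 <- m$a[i, ]
    b2 <- m$b[i, ]
    .inter_area_pair(b1, b2) / (b1[3] * b1[4] + b2[3] * b2[4])
  }, numeric(1))
}

# axis-aligned IoU of the decoupled horizontal representation (theta ignored)
.hiou_pair <- function(b1, b2) {
  ix <- min(b1[1] + b1[3] / 2, b2[1] + b2[3] / 2) - max(b1[1] - b1[3] / 2, b2[1] - b2[3] / 2)
  iy <- min(b1[2] + b1[4] / 2, b2[2] + b2[4] / 2) - max(b1[2] - b1[4] / 2, b2[2] - b2[4] / 2)
  if (ix <= 0 || iy <= 0) {
    return(0)
  }
  inter <- ix * iy
  inter / (b1[3] * b1[4] + b2[3] * b2[4] - inter)
}
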