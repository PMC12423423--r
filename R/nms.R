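# Oriented non-maximum suppression. Duplicate detections of the same spike
# are removed greedily: the highest-scoring box is kept, and any remaining
# box whose overlap with a kept box exceeds the threshold is discarded. The
# default overlap criterion is the overlap-to-area-sum ratio (see
# overlap_ratio_sum()); plain rotated IoU is available as an alternative.

#' Oriented non-maximum suppression
#'
#' Greedy score-descending suppression over oriented boxes. "Highest ratio
#' retained" is realized as standard NMS keyed by detection score: keeping
#' the most-overlapping box instead would discard isolated detections, which
#' contradicts the purpose of removing duplicates.
#'
#' Ties in score are broken by input row order (stable sort), so permuting
#' the input never changes the kept set.
#'
#' @param boxes A box table with a `score` column (all scores in `[0, 1]`).
#' @param overlap_threshold Suppression threshold: a kept/candidate pair
#'   whose criterion exceeds this discards the candidate. Must lie in
#'   `(0, 0.5]` for `"sum-ratio"` (its maximum is 0.5) and `(0, 1]` for
#'   `"iou"`. Default 0.25, the midpoint of the sum-ratio range.
#' @param criterion `"sum-ratio"` (default) or `"iou"`.
#' @return The kept boxes as a tibble in score-descending order (a subset of
#'   the input rows).
#' @examples
#' d <- oriented_box(c(0, 0.5, 50), c(0, 0.2, 50), 8, 3, c(10, 12, 90),
#'   score = c(0.9, 0.8, 0.7)
#' )
#' oriented_nms(d) # the 0.8 duplicate is suppressed
#' @export
oriented_nms <- function(boxes, overlap_threshold = 0.25,
                         criterion = c("sum-ratio", "iou")) {
  criterion <- match.arg(criterion)
  validate_boxes(boxes)
  if (!("score" %in% names(boxes)) || anyNA(boxes$score) && nrow(boxes) > 0) {
    abort("oriented_nms() needs a complete score column",
      class = "spikeobb_invalid_input"
    )
  }
  max_thr <- if (criterion == "sum-ratio") 0.5 else 1
  if (!is.finite(overlap_threshold) || overlap_threshold <= 0 ||
    overlap_threshold > max_thr) {
    abort(
      sprintf("overlap_threshold must lie in (0, %g] for the %s criterion", max_thr, criterion),
      class = "spikeobb_invalid_config"
    )
  }
  n <- nrow(boxes)
  if (n == 0) {
    return(dplyr::as_tibble(boxes))
  }
  if (any(boxes$score < 0 | boxes$score > 1)) {
    abort("scores must lie in [0, 1]", class = "spikeobb_invalid_input")
  }
  ord <- order(-boxes$score) # stable: ties keep input order
  m <- .box_rows(boxes)
  kept <- integer(0)
  for (i in ord) {
    suppressed <- FALSE
    for (j in kept) {
      ov <- if (criterion == "sum-ratio") {
        .inter_area_pair(m[i, ], m[j, ]) /
          (m[i, 3] * m[i, 4] + m[j, 3] * m[j, 4])
      } else {
        .iou_pair(m[i, ], m[j, ])
      }
      if (ov > overlap_threshold) {
        suppressed <- TRUE
        break
      }
    }
    if (!suppressed) kept <- c(kept, i)
  }
  dplyr::as_tibble(boxes[kept, , drop = FALSE])
}
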