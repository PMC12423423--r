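# Wise-IoU localization loss, forward evaluation only. A pair list is one
# prediction per ground-truth box (the assignment is taken as given); the
# loss is sum over pairs of alpha * (1 - IoU), where alpha is an exponential
# focusing factor driven by the center distance normalized by the
# ground-truth size.

.check_pairs <- function(pred, gt) {
  validate_boxes(pred)
  validate_boxes(gt)
  if (nrow(pred) != nrow(gt)) {
    abort("pred and gt must be row-aligned (one prediction per ground truth)",
      class = "spikeobb_invalid_input"
    )
  }
}

#' Wise-IoU focusing factor
#'
#' `alpha = exp(((GTx - Bx)^2 + (GTy - By)^2) / (GTw + GTh)^2)`: 1 when the
#' predicted center coincides with the ground-truth center, and growing
#' exponentially as the prediction drifts away, in units of the ground-truth
#' size. The normalizer uses the ground-truth sides only.
#'
#' @param pred,gt Row-aligned box tables (predictions and their assigned
#'   ground truths).
#' @return Numeric vector of factors, each `>= 1`.
#' @examples
#' wiou_alpha(oriented_box(2, 0, 2, 2, 0), oriented_box(0, 0, 2, 2, 0)) # exp(0.25)
#' @export
wiou_alpha <- function(pred, gt) {
  .check_pairs(pred, gt)
  exp(((gt$cx - pred$cx)^2 + (gt$cy - pred$cy)^2) / (gt$w + gt$h)^2)
}

#' Per-pair IoU loss term
#'
#' `1 - IoU(pred, gt)`. The default IoU is the *horizontal* (axis-aligned)
#' one of the decoupled representation, in which the angle is handled by the
#' CSL classification branch and the regression target is `(x, y, w, h)`
#' alone; set `iou_mode = "rotated"` to score the oriented rectangles
#' instead.
#'
#' @inheritParams wiou_alpha
#' @param iou_mode `"horizontal"` (default) or `"rotated"`.
#' @return Numeric vector of losses in `[0, 1]`.
#' @export
iou_loss <- function(pred, gt, iou_mode = c("horizontal", "rotated")) {
  iou_mode <- match.arg(iou_mode)
  .check_pairs(pred, gt)
  if (iou_mode == "rotated") {
    return(1 - rotated_iou(pred, gt))
  }
  mp <- .box_rows(pred)
  mg <- .box_rows(gt)
  1 - vapply(
    seq_len(nrow(mp)),
    function(i) .hiou_pair(mp[i, ], mg[i, ]),
    numeric(1)
  )
}

#' Wise-IoU localization loss
#'
#' Total loss `sum_i alpha_i * (1 - IoU_i)` over assigned pairs, with the
#' per-pair breakdown. Since every `alpha_i >= 1`, the total is never below
#' the plain IoU loss sum, with equality exactly when all centers coincide.
#'
#' @inheritParams iou_loss
#' @return A list with `total` (a single number) and `pairs`, a tibble with
#'   columns `alpha`, `iou`, `iou_loss` and `loss` (= `alpha * iou_loss`),
#'   one row per pair. An empty pair list gives total 0 with a warning.
#' @examples
#' wise_iou_loss(oriented_box(1, 0, 2, 2, 0), oriented_box(0, 0, 2, 2, 0))
#' @export
wise_iou_loss <- function(pred, gt, iou_mode = c("horizontal", "rotated")) {
  iou_mode <- match.arg(iou_mode)
  .check_pairs(pred, gt)
  if (nrow(pred) == 0) {
    warn("empty pair list; Wise-IoU loss defined as 0")
    return(list(
      total = 0,
      pairs = tibble::tibble(
        alpha = numeric(0), iou = numeric(0),
        iou_loss = numeric(0), loss = numeric(0)
      )
    ))
  }
  alpha <- wiou_alpha(pred, gt)
  l_iou <- iou_loss(pred, gt, iou_mode)
  pairs <- tibble::tibble(
    alpha = alpha,
    iou = 1 - l_iou,
    iou_loss = l_iou,
    loss = alpha * l_iou
  )
  list(total = sum(pairs$loss), pairs = pairs)
}
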