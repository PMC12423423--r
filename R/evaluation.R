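# Detection evaluation: greedy matching of scored predictions to ground
# truth by rotated IoU, precision-recall / average precision, pooled angle
# errors on matched pairs, and per-image count errors. Multi-image tables
# are keyed by an image_id column; a table without one is a single image.

.split_images <- function(boxes) {
  if (!("image_id" %in% names(boxes))) {
    return(list(image = boxes))
  }
  split(boxes, boxes$image_id)
}

#' Match detections to ground truth in one image
#'
#' Predictions are sorted by score (descending, stable) and each is greedily
#' matched to the not-yet-matched ground-truth box with the highest rotated
#' IoU, provided that IoU reaches `iou_threshold`. Matched pairs are the
#' true positives; leftover predictions are false positives and leftover
#' ground truths false negatives.
#'
#' @param preds Box table of scored predictions for one image.
#' @param gts Box table of ground-truth boxes for the same image.
#' @param iou_threshold Minimum rotated IoU for a match, in `(0, 1)`.
#' @return A list of class `"spike_matches"`: `pairs` (tibble with
#'   `pred_row`, `gt_row`, `iou`, `score`, `pred_theta`, `gt_theta`),
#'   `detections` (tibble with `score`, `is_tp` in score order), and counts
#'   `n_tp`, `n_fp`, `n_fn`, `n_gt`, `n_pred`.
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  validate_boxes(preds)
  validate_boxes(gts)
  if (!is.finite(iou_threshold) || iou_threshold <= 0 || iou_threshold >= 1) {
    abort("iou_threshold must lie in (0, 1)", class = "spikeobb_invalid_config")
  }
  if ("image_id" %in% names(preds) && "image_id" %in% names(gts)) {
    pid <- unique(preds$image_id)
    gid <- unique(gts$image_id)
    if (length(pid) > 1 || length(gid) > 1 ||
      (length(pid) == 1 && length(gid) == 1 && pid != gid)) {
      abort("match_detections() pairs one image: image ids must agree",
        class = "spikeobb_invalid_pairing"
      )
    }
  }
  if (nrow(preds) > 0 && (!("score" %in% names(preds)) || anyNA(preds$score))) {
    abort("predictions need a complete score column", class = "spikeobb_invalid_input")
  }
  np <- nrow(preds)
  ng <- nrow(gts)
  ord <- if (np > 0) order(-preds$score) else integer(0)
  mp <- .box_rows(preds)
  mg <- .box_rows(gts)
  gt_taken <- rep(FALSE, ng)
  pair_rows <- vector("list", np)
  is_tp <- logical(np)
  for (s in seq_along(ord)) {
    i <- ord[s]
    best_j <- 0L
    best_iou <- -1
    for (j in seq_len(ng)) {
      if (gt_taken[j]) next
      iou <- .iou_pair(mp[i, ], mg[j, ])
      if (iou > best_iou) {
        best_iou <- iou
        best_j <- j
      }
    }
    if (best_j > 0L && best_iou >= iou_threshold) {
      gt_taken[best_j] <- TRUE
      is_tp[s] <- TRUE
      pair_rows[[s]] <- tibble::tibble(
        pred_row = i, gt_row = best_j, iou = best_iou,
        score = preds$score[i],
        pred_theta = mp[i, 5] %% 180, gt_theta = mg[best_j, 5] %% 180
      )
    }
  }
  pairs <- dplyr::bind_rows(pair_rows)
  if (nrow(pairs) == 0) {
    pairs <- tibble::tibble(
      pred_row = integer(0), gt_row = integer(0), iou = numeric(0),
      score = numeric(0), pred_theta = numeric(0), gt_theta = numeric(0)
    )
  }
  structure(
    list(
      pairs = pairs,
      detections = tibble::tibble(
        score = if (np > 0) preds$score[ord] else numeric(0),
        is_tp = is_tp
      ),
      n_tp = sum(is_tp), n_fp = np - sum(is_tp),
      n_fn = ng - sum(is_tp), n_gt = ng, n_pred = np
    ),
    class = "spike_matches"
  )
}

.pool_detections <- function(matches) {
  if (inherits(matches, "spike_matches")) matches <- list(matches)
  det <- dplyr::bind_rows(lapply(matches, `[[`, "detections"))
  n_gt <- sum(vapply(matches, function(m) as.numeric(m$n_gt), numeric(1)))
  list(det = det, n_gt = n_gt)
}

#' Precision-recall curve
#'
#' Sorts pooled detections by descending score and computes cumulative
#' precision `TP / (TP + FP)` and recall `TP / (TP + FN)` after each
#' detection, one point per detection (distinct score cutoff).
#'
#' @param matches A `"spike_matches"` result or a list of them (one per
#'   image), or a data frame with columns `score` and `is_tp` (then `n_gt`
#'   is required).
#' @param n_gt Total number of ground-truth boxes (only when `matches` is a
#'   plain data frame).
#' @return A tibble with columns `score`, `recall`, `precision`.
#' @export
precision_recall_curve <- function(matches, n_gt = NULL) {
  if (is.data.frame(matches)) {
    det <- matches
    if (is.null(n_gt)) {
      abort("n_gt is required with a plain detection table",
        class = "spikeobb_invalid_input"
      )
    }
  } else {
    pooled <- .pool_detections(matches)
    det <- pooled$det
    n_gt <- pooled$n_gt
  }
  if (nrow(det) == 0) {
    return(tibble::tibble(
      score = numeric(0), recall = numeric(0),
      precision = numeric(0)
    ))
  }
  det <- det[order(-det$score), , drop = FALSE]
  tp <- cumsum(det$is_tp)
  fp <- cumsum(!det$is_tp)
  tibble::tibble(
    score = det$score,
    recall = if (n_gt > 0) tp / n_gt else rep(0, length(tp)),
    precision = tp / (tp + fp)
  )
}

#' Average precision
#'
#' Integrates precision over recall on `[0, 1]`. The default all-points
#' interpolation replaces precision at each recall by the maximum precision
#' at any recall at least as large (the monotone envelope) and integrates
#' exactly; `"11-point"` averages the interpolated precision at recalls
#' 0, 0.1, ..., 1 instead.
#'
#' @param curve A precision-recall curve from [precision_recall_curve()].
#' @param method `"all-points"` (default) or `"11-point"`.
#' @return Average precision in `[0, 1]`; with a single class this is the
#'   mAP.
#' @export
average_precision <- function(curve, method = c("all-points", "11-point")) {
  method <- match.arg(method)
  if (nrow(curve) == 0) {
    return(0)
  }
  r <- curve$recall
  p <- curve$precision
  # monotone non-increasing precision envelope, right to left
  env <- rev(cummax(rev(p)))
  if (method == "11-point") {
    pts <- vapply(seq(0, 1, by = 0.1), function(rr) {
      ok <- r >= rr - 1e-12
      if (any(ok)) max(p[ok]) else 0
    }, numeric(1))
    return(mean(pts))
  }
  rr <- c(0, r)
  sum((rr[-1] - rr[-length(rr)]) * env)
}

#' Pooled angle errors over matched pairs
#'
#' `RMSEa` and `MAEa` of predicted versus annotated long-side angles,
#' pooled over all matched (true-positive) pairs of all images. The default
#' angle difference is the periodic [circular_angle_distance()], so a
#' 179-degree prediction against a 1-degree truth counts 2 degrees; the raw
#' difference is available for comparability with conventions that ignore
#' the wrap.
#'
#' @param matches A `"spike_matches"` result or list of them.
#' @param method `"circular"` (default) or `"raw"`.
#' @return A tibble with `rmse_a`, `mae_a` (degrees) and `n_matched`. With
#'   no matched pairs the errors are `NA` (undefined, not zero) with a
#'   warning.
#' @export
angle_errors <- function(matches, method = c("circular", "raw")) {
  method <- match.arg(method)
  if (inherits(matches, "spike_matches")) matches <- list(matches)
  pairs <- dplyr::bind_rows(lapply(matches, `[[`, "pairs"))
  if (nrow(pairs) == 0) {
    warn("no matched pairs; angle errors are undefined")
    return(tibble::tibble(rmse_a = NA_real_, mae_a = NA_real_, n_matched = 0L))
  }
  d <- if (method == "circular") {
    circular_angle_distance(pairs$pred_theta, pairs$gt_theta)
  } else {
    pairs$pred_theta - pairs$gt_theta
  }
  tibble::tibble(
    rmse_a = sqrt(mean(d^2)),
    mae_a = mean(abs(d)),
    n_matched = nrow(pairs)
  )
}

#' Per-image count errors
#'
#' `RMSE = sqrt(mean((a_i - t_i)^2))` and `MAE = mean(|a_i - t_i|)` over
#' images, where `a_i` is the annotated spike count and `t_i` the predicted
#' count in image `i`.
#'
#' @param counts A data frame with columns `labeled` (`a_i`) and
#'   `predicted` (`t_i`), one row per image.
#' @return A tibble with `rmse`, `mae` (spikes) and `n_images`.
#' @export
count_errors <- function(counts) {
  if (!all(c("labeled", "predicted") %in% names(counts))) {
    abort("counts needs columns labeled and predicted",
      class = "spikeobb_invalid_input"
    )
  }
  if (nrow(counts) == 0) {
    abort("need at least one image", class = "spikeobb_invalid_input")
  }
  d <- counts$labeled - counts$predicted
  tibble::tibble(
    rmse = sqrt(mean(d^2)),
    mae = mean(abs(d)),
    n_images = nrow(counts)
  )
}

#' Evaluate oriented detections against ground truth
#'
#' Runs the full evaluation over one or many images: matching, the
#' precision-recall curve and mAP, pooled angle errors on matched pairs, and
#' per-image count errors. Angle metrics use matched pairs only; false
#' positives and negatives affect mAP and the counts.
#'
#' @param preds Scored prediction box table; an `image_id` column groups
#'   images (absent means a single image).
#' @param gts Ground-truth box table, same keying.
#' @param iou_threshold Rotated-IoU match threshold (default 0.5).
#' @param score_threshold Detections below this score are dropped before
#'   evaluation (counting requires an explicit operating point; default 0
#'   keeps everything).
#' @param angle_method Passed to [angle_errors()].
#' @param ap_method Passed to [average_precision()].
#' @return An object of class `"spike_eval"` with fields `map`, `curve`,
#'   `rmse_a`, `mae_a`, `rmse`, `mae`, `per_image` (tibble with `image_id`,
#'   `labeled`, `predicted`, `tp`, `fp`, `fn`) and `settings`. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' gt <- generate_annotations(n_spikes = 12, seed = 1)
#' pred <- dplyr::mutate(gt, score = 1)
#' glance(evaluate_detections(pred, gt))
#' @export
evaluate_detections <- function(preds, gts, iou_threshold = 0.5,
                                score_threshold = 0,
                                angle_method = c("circular", "raw"),
                                ap_method = c("all-points", "11-point")) {
  angle_method <- match.arg(angle_method)
  ap_method <- match.arg(ap_method)
  validate_boxes(preds)
  validate_boxes(gts)
  if (nrow(preds) > 0) {
    preds <- preds[preds$score >= score_threshold, , drop = FALSE]
  }
  gt_imgs <- .split_images(gts)
  pred_imgs <- .split_images(preds)
  ids <- union(names(gt_imgs), names(pred_imgs))
  empty <- function(tpl) tpl[0, , drop = FALSE]
  matches <- lapply(ids, function(id) {
    match_detections(
      pred_imgs[[id]] %||% empty(preds),
      gt_imgs[[id]] %||% empty(gts),
      iou_threshold
    )
  })
  names(matches) <- ids
  curve <- precision_recall_curve(matches)
  ang <- suppressWarnings(angle_errors(matches, angle_method))
  grab <- function(field) {
    unname(vapply(matches, function(m) as.numeric(m[[field]]), numeric(1)))
  }
  per_image <- tibble::tibble(
    image_id = ids,
    labeled = grab("n_gt"), predicted = grab("n_pred"),
    tp = grab("n_tp"), fp = grab("n_fp"), fn = grab("n_fn")
  )
  cnt <- count_errors(per_image)
  structure(
    list(
      map = average_precision(curve, ap_method),
      curve = curve,
      rmse_a = ang$rmse_a, mae_a = ang$mae_a, n_matched = ang$n_matched,
      rmse = cnt$rmse, mae = cnt$mae,
      per_image = per_image,
      matches = matches,
      settings = list(
        iou_threshold = iou_threshold,
        score_threshold = score_threshold,
        angle_method = angle_method, ap_method = ap_method
      )
    ),
    class = "spike_eval"
  )
}

#' @export
print.spike_eval <- function(x, ...) {
  cat("Oriented detection evaluation (", nrow(x$per_image), " image(s))\n", sep = "")
  cat(sprintf(
    "  mAP %.4f | RMSEa %.3f deg | MAEa %.3f deg | count RMSE %.3f | MAE %.3f\n",
    x$map, x$rmse_a, x$mae_a, x$rmse, x$mae
  ))
  cat(sprintf(
    "  matched %d | IoU threshold %.2f | score threshold %.2f\n",
    x$n_matched, x$settings$iou_threshold, x$settings$score_threshold
  ))
  invisible(x)
}

#' @rdname evaluate_detections
#' @param x A `"spike_eval"` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.spike_eval <- function(x, ...) {
  x$per_image
}

#' @rdname evaluate_detections
#' @exportS3Method generics::glance
glance.spike_eval <- function(x, ...) {
  tibble::tibble(
    map = x$map, rmse_a = x$rmse_a, mae_a = x$mae_a,
    rmse = x$rmse, mae = x$mae,
    n_images = nrow(x$per_image), n_matched = x$n_matched
  )
}

#' @rdname evaluate_detections
#' @param object A `"spike_eval"` object.
#' @exportS3Method ggplot2::autoplot
autoplot.spike_eval <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = sprintf("Precision-recall (AP = %.3f)", object$map)
    ) +
    ggplot2::theme_minimal()
}
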