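test_that("matching realizes the TP/FP/FN partition", {
  gt <- generate_annotations(n_spikes = 8, seed = 1)$boxes
  perfect <- dplyr::mutate(gt, score = 1)
  m <- match_detections(perfect, gt)
  expect_equal(m$n_tp, 8)
  expect_equal(m$n_fp, 0)
  expect_equal(m$n_fn, 0)
  expect_equal(m$pairs$iou, rep(1, 8), tolerance = 1e-9)
  # no predictions: everything is missed
  m0 <- match_detections(perfect[0, ], gt)
  expect_equal(m0$n_fn, 8)
  expect_equal(m0$n_tp, 0)
  # constructed TP(0.9), FP(0.8), TP(0.7) over 2 ground truths
  gt2 <- oriented_box(c(0, 100), c(0, 0), 10, 4, 0)
  preds <- oriented_box(c(0, 50, 100), c(0, 0, 0), 10, 4, 0,
    score = c(0.9, 0.8, 0.7)
  )
  m2 <- match_detections(preds, gt2, 0.5)
  expect_equal(m2$n_tp, 2)
  expect_equal(m2$n_fp, 1)
  expect_equal(m2$n_fn, 0)
  expect_equal(m2$detections$is_tp, c(TRUE, FALSE, TRUE))
  # each gt matched at most once: a duplicate prediction becomes an FP
  dup <- preds[c(1, 1), ]
  m3 <- match_detections(dup, gt2, 0.5)
  expect_equal(m3$n_tp, 1)
  expect_equal(m3$n_fp, 1)
  bad_gt <- dplyr::mutate(gt2, image_id = "a")
  bad_pred <- dplyr::mutate(preds, image_id = "b")
  expect_error(match_detections(bad_pred, bad_gt),
    class = "spikeobb_invalid_pairing"
  )
})

test_that("precision-recall points and average precision match hand computation", {
  gt2 <- oriented_box(c(0, 100), c(0, 0), 10, 4, 0)
  preds <- oriented_box(c(0, 50, 100), c(0, 0, 0), 10, 4, 0,
    score = c(0.9, 0.8, 0.7)
  )
  cv <- precision_recall_curve(match_detections(preds, gt2, 0.5))
  expect_equal(cv$recall, c(0.5, 0.5, 1))
  expect_equal(cv$precision, c(1, 0.5, 2 / 3))
  expect_equal(average_precision(cv), 5 / 6, tolerance = 1e-12)
  expect_equal(average_precision(cv, method = "11-point"),
    mean(c(rep(1, 6), rep(2 / 3, 5))),
    tolerance = 1e-12
  )
  # perfect single detection
  g1 <- oriented_box(0, 0, 10, 4, 0)
  cv1 <- precision_recall_curve(match_detections(
    dplyr::mutate(g1, score = 1),
    g1
  ))
  expect_equal(as.data.frame(cv1), data.frame(score = 1, recall = 1, precision = 1))
  expect_equal(average_precision(cv1), 1)
  # all false positives
  far <- oriented_box(500, 500, 10, 4, 0, score = 0.5)
  cv0 <- precision_recall_curve(match_detections(far, g1))
  expect_equal(cv0$precision, 0)
  expect_equal(average_precision(cv0), 0)
  # interpolated envelope is monotone non-increasing
  set.seed(2)
  det <- tibble::tibble(score = runif(50), is_tp = runif(50) < 0.6)
  cvr <- precision_recall_curve(det, n_gt = 40)
  env <- rev(cummax(rev(cvr$precision)))
  expect_true(all(diff(env) <= 1e-12))
  ap <- average_precision(cvr)
  expect_gte(ap, 0)
  expect_lte(ap, 1)
})

test_that("angle errors pool matched pairs and use the circular difference", {
  g <- oriented_box(c(0, 100), c(0, 0), 20, 8, c(10, 30))
  p <- dplyr::mutate(g, theta = theta + c(3, 4), score = 1)
  ae <- angle_errors(match_detections(p, g))
  expect_equal(ae$mae_a, 3.5)
  expect_equal(ae$rmse_a, sqrt(12.5))
  # wrap-around: 179 vs 1 counts as 2 degrees
  g2 <- oriented_box(0, 0, 20, 8, 1)
  p2 <- oriented_box(0, 0, 20, 8, 179, score = 1)
  ae2 <- angle_errors(match_detections(p2, g2, iou_threshold = 0.5))
  expect_equal(ae2$mae_a, 2)
  ae2r <- angle_errors(match_detections(p2, g2), method = "raw")
  expect_equal(ae2r$mae_a, 178)
  # exact predictions, and the undefined case
  ae0 <- angle_errors(match_detections(dplyr::mutate(g, score = 1), g))
  expect_equal(ae0$rmse_a, 0)
  expect_warning(
    nae <- angle_errors(match_detections(g[0, ], g)),
    "undefined"
  )
  expect_true(is.na(nae$rmse_a))
})

test_that("count errors follow the printed per-image formulas", {
  expect_equal(
    count_errors(tibble::tibble(labeled = c(30, 25), predicted = c(28, 25))),
    tibble::tibble(rmse = sqrt(2), mae = 1, n_images = 2L)
  )
  one <- count_errors(tibble::tibble(labeled = 30, predicted = 25))
  expect_equal(one$rmse, 5)
  expect_equal(one$mae, 5)
  perfect <- count_errors(tibble::tibble(labeled = c(3, 4), predicted = c(3, 4)))
  expect_equal(perfect$rmse, 0)
  expect_error(count_errors(tibble::tibble(labeled = numeric(0), predicted = numeric(0))),
    class = "spikeobb_invalid_input"
  )
})

test_that("self-evaluation is perfect and rmse >= mae always", {
  gts <- dplyr::bind_rows(lapply(1:4, function(i) {
    dplyr::mutate(generate_annotations(seed = i)$boxes, image_id = paste0("im", i))
  }))
  ev <- evaluate_detections(dplyr::mutate(gts, score = 1), gts)
  expect_equal(ev$map, 1)
  expect_equal(ev$rmse_a, 0)
  expect_equal(ev$mae_a, 0)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$mae, 0)
  g <- glance(ev)
  expect_equal(g$map, 1)
  expect_equal(nrow(tidy(ev)), 4)
  # degraded predictions keep the Cauchy-Schwarz ordering
  set.seed(9)
  noisy <- dplyr::bind_rows(lapply(1:4, function(i) {
    gt <- gts[gts$image_id == paste0("im", i), ]
    d <- perturb_annotations(gt,
      angle_sd = 8, center_sd = 2, p_miss = 0.2,
      fp_rate = 3, width = 600, height = 600
    )
    dplyr::mutate(d, image_id = paste0("im", i))
  }))
  ev2 <- evaluate_detections(noisy, gts, iou_threshold = 0.3)
  expect_gte(ev2$rmse_a, ev2$mae_a)
  expect_gte(ev2$rmse, ev2$mae)
  expect_lte(ev2$map, 1)
  pl <- autoplot(ev2)
  expect_s3_class(pl, "ggplot")
})

test_that("deleting boxes at rate p produces the expected count deficit", {
  set.seed(11)
  p <- 0.2
  n_img <- 60
  deficits <- vapply(seq_len(n_img), function(i) {
    gt <- generate_annotations(seed = 500 + i)$boxes
    d <- perturb_annotations(gt, p_miss = p)
    nrow(gt) - nrow(d)
  }, numeric(1))
  lambda <- 30
  expect_equal(mean(deficits), p * lambda,
    tolerance = 3 * sqrt(p * lambda / n_img) / (p * lambda)
  )
})

test_that("score threshold gates which detections are evaluated", {
  gt <- generate_annotations(n_spikes = 10, seed = 21)$boxes
  det <- dplyr::mutate(gt, score = seq(0.05, 0.95, length.out = 10))
  ev_all <- evaluate_detections(det, gt)
  ev_half <- evaluate_detections(det, gt, score_threshold = 0.5)
  expect_equal(ev_all$per_image$predicted, 10)
  expect_equal(ev_half$per_image$predicted, 5)
  expect_equal(ev_half$per_image$fn, 5)
})
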