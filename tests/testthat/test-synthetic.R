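test_that("scene generation is deterministic under a seed and honors the spec", {
  a <- generate_scene(
    width = 64, height = 64, n_spikes = 5, long_side = c(12, 20),
    seed = 7
  )
  b <- generate_scene(
    width = 64, height = 64, n_spikes = 5, long_side = c(12, 20),
    seed = 7
  )
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$boxes, b$boxes)
  expect_equal(nrow(a$boxes), 5)
  expect_true(all(a$pixels >= 0 & a$pixels <= 255))
  c <- generate_scene(
    width = 64, height = 64, n_spikes = 5, long_side = c(12, 20),
    seed = 8
  )
  expect_false(identical(a$boxes, c$boxes))
  # boxes normalized and fully inside the image
  crn <- box_corners(a$boxes)
  expect_true(all(crn$x >= 0 & crn$x <= 64 & crn$y >= 0 & crn$y <= 64))
  expect_true(all(a$boxes$w >= a$boxes$h))
  # infeasible spec: spikes larger than the image
  expect_error(
    generate_annotations(width = 40, height = 40, n_spikes = 1, long_side = c(60, 70), seed = 1),
    class = "spikeobb_invalid_config"
  )
})

test_that("generated geometry matches the field statistics it emulates", {
  set.seed(1)
  anns <- lapply(1:60, function(i) generate_annotations(seed = 1000 + i)$boxes)
  sides <- unlist(lapply(anns, `[[`, "w"))
  expect_lt(mean(sides), 100)
  expect_lt(stats::quantile(sides, 0.99), 100)
  counts <- vapply(anns, nrow, numeric(1))
  expect_equal(mean(counts), 30, tolerance = 0.1) # Poisson(30) scenes
  # pairwise overlap policy: no two distinct spikes overlap beyond the cap
  b <- anns[[1]]
  for (i in seq_len(nrow(b) - 1)) {
    for (j in (i + 1):nrow(b)) {
      expect_lte(overlap_ratio_sum(b[i, ], b[j, ]), 0.05 + 1e-9)
    }
  }
})

test_that("the angle mixture reproduces its configured distribution", {
  ang <- sample_spike_angles(10000, seed = 42)
  expect_true(all(ang >= 0 & ang < 180))
  # expected bin probabilities for the wrapped-normal + uniform mixture
  wrapped_bin <- function(lo, hi, mu, sd) {
    p <- 0
    for (k in -3:3) p <- p + pnorm(hi + 180 * k, mu, sd) - pnorm(lo + 180 * k, mu, sd)
    p
  }
  breaks <- seq(0, 180, by = 15)
  probs <- vapply(seq_len(length(breaks) - 1), function(i) {
    lo <- breaks[i]
    hi <- breaks[i + 1]
    0.45 * wrapped_bin(lo, hi, 0, 10) +
      0.15 * wrapped_bin(lo, hi, 90, 10) +
      0.40 * (hi - lo) / 180
  }, numeric(1))
  obs <- table(cut(ang, breaks, include.lowest = TRUE))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = probs / sum(probs)))
  expect_gt(gof$p.value, 0.01)
  # the mode at 0 dominates
  expect_gt(sum(ang < 15 | ang > 165), sum(ang > 75 & ang < 105))
})

test_that("perturbation respects its noise specification", {
  gt <- generate_annotations(seed = 3)
  # zero noise reproduces the ground truth with unit-free scores attached
  clean <- perturb_annotations(gt, seed = 1)
  expect_equal(clean[c("cx", "cy", "w", "h", "theta")], gt$boxes[c("cx", "cy", "w", "h", "theta")])
  expect_true(all(clean$score >= 0 & clean$score <= 1))
  # p_miss = 1 drops everything
  expect_equal(nrow(perturb_annotations(gt, p_miss = 1, seed = 1)), 0)
  # determinism
  d1 <- perturb_annotations(gt, angle_sd = 5, center_sd = 2, fp_rate = 4, seed = 9)
  d2 <- perturb_annotations(gt, angle_sd = 5, center_sd = 2, fp_rate = 4, seed = 9)
  expect_identical(d1, d2)
  expect_true(all(d1$theta >= 0 & d1$theta < 180))
  expect_error(perturb_annotations(gt, p_miss = 2), class = "spikeobb_invalid_config")
})

test_that("angle-noise recovery: pooled RMSEa tracks the injected sigma", {
  set.seed(4)
  for (sigma in c(5, 20)) {
    d <- rnorm(4000, 0, sigma)
    wrapped <- circular_angle_distance(d %% 180, 0)
    expect_equal(sqrt(mean(wrapped^2)), sigma, tolerance = 0.05)
  }
  # end-to-end at sigma = 5 over a modest sample (the sigma = 10 study runs
  # in the acceptance suite at full size)
  gts <- lapply(1:20, function(i) generate_annotations(seed = 600 + i))
  ms <- lapply(seq_along(gts), function(i) {
    det <- perturb_annotations(gts[[i]], angle_sd = 5, seed = 700 + i)
    match_detections(det, gts[[i]]$boxes, iou_threshold = 0.1)
  })
  ae <- angle_errors(ms)
  expect_gt(ae$n_matched, 500)
  expect_equal(ae$rmse_a, 5, tolerance = 0.1)
})

test_that("the rasterized oracle converges toward the exact IoU", {
  a <- oriented_box(0, 0, 2, 2, 0)
  b <- oriented_box(0, 0, 2, 2, 45)
  expect_equal(rasterized_iou_oracle(a, a, 500), 1)
  expect_equal(rasterized_iou_oracle(a, oriented_box(50, 50, 2, 2, 0), 200), 0)
  exact <- 1 / sqrt(2)
  errs <- vapply(
    c(250, 500, 1000, 2000),
    function(res) abs(rasterized_iou_oracle(a, b, res) - exact),
    numeric(1)
  )
  expect_lt(errs[4], 1e-3)
  expect_lt(errs[4], errs[1])
  expect_error(rasterized_iou_oracle(a, b, 50), class = "spikeobb_invalid_config")
})
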