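# Synthetic spike scenes. The generator emulates the geometric statistics of
# sorghum spikes seen from a UAV at ~10 m: roughly 30 elongated targets per
# 600 px frame, long sides generally under 100 px, and an angle distribution
# concentrated at 0 degrees with a secondary mode at 90 and a uniform
# background. Rendering is deliberately simple (textured ellipses on a noisy
# canopy-like background): the point is exact geometric ground truth, not
# photorealism.

#' Sample long-side angles from the field mixture
#'
#' Draws angles from a mixture of wrapped normals plus a uniform component
#' on `[0, 180)`. The default mixture -- 45% wrapped-normal at 0 degrees
#' (sd 10), 15% at 90 (sd 10), 40% uniform -- is a stylized match to the
#' annotated-field distribution, whose histogram peaks at 0 with a
#' secondary concentration near 90.
#'
#' @param n Number of draws.
#' @param weights Mixture weights (last entry is the uniform component);
#'   normalized internally.
#' @param means,sds Wrapped-normal component locations and sds (degrees).
#' @param seed Optional integer seed (local to the call).
#' @return `n` angles in `[0, 180)`.
#' @export
sample_spike_angles <- function(n, weights = c(0.45, 0.15, 0.40),
                                means = c(0, 90), sds = c(10, 10),
                                seed = NULL) {
  if (length(weights) != length(means) + 1) {
    abort("weights must have one entry per mean plus the uniform component",
      class = "spikeobb_invalid_config"
    )
  }
  draw <- function() {
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    ang <- runif(n, 0, 180)
    for (i in seq_along(means)) {
      sel <- comp == i
      ang[sel] <- rnorm(sum(sel), means[i], sds[i]) %% 180
    }
    ang
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

.place_boxes <- function(n, width, height, long_side, aspect, angles,
                         max_overlap, max_tries = 200) {
  placed <- matrix(numeric(0), 0, 5)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      w <- runif(1, long_side[1], long_side[2])
      h <- w * runif(1, aspect[1], aspect[2])
      margin <- sqrt(w^2 + h^2) / 2
      if (2 * margin >= min(width, height)) {
        abort("spikes are larger than the image", class = "spikeobb_invalid_config")
      }
      cand <- c(
        runif(1, margin, width - margin),
        runif(1, margin, height - margin),
        w, h, angles[i]
      )
      clash <- FALSE
      if (nrow(placed) > 0) {
        for (j in seq_len(nrow(placed))) {
          ov <- .inter_area_pair(cand, placed[j, ]) /
            (cand[3] * cand[4] + placed[j, 3] * placed[j, 4])
          if (ov > max_overlap) {
            clash <- TRUE
            break
          }
        }
      }
      if (!clash) {
        placed <- rbind(placed, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort("could not place all spikes; scene too dense for max_overlap",
        class = "spikeobb_invalid_config"
      )
    }
  }
  placed
}

#' Generate ground-truth spike annotations (no pixels)
#'
#' Draws a spike count (Poisson, or fixed via `n_spikes`), samples sizes,
#' aspects and angles, and places boxes by rejection so that no pair
#' overlaps more than `max_overlap` under the sum-of-areas ratio. All boxes
#' are normalized and lie fully inside the image.
#'
#' @param width,height Image extent (px); default 600, the working tile
#'   size for 4032 x 2268 UAV frames.
#' @param n_spikes Fixed spike count, or `NULL` to draw Poisson(`mean_spikes`).
#' @param mean_spikes Poisson mean when `n_spikes` is `NULL`; default 30,
#'   the typical per-image spike count in the field data.
#' @param long_side Range of long-side lengths (px); default `c(40, 95)`,
#'   keeping spikes in the under-100 px small-object regime.
#' @param aspect Range of short/long side ratios; default `c(0.2, 0.45)`
#'   (slender targets).
#' @param angle_weights,angle_means,angle_sds Passed to
#'   [sample_spike_angles()].
#' @param max_overlap Maximum allowed pairwise sum-of-areas overlap ratio
#'   between distinct spikes; default 0.05.
#' @param seed Optional integer seed (local to the call).
#' @param image_id Identifier for the annotation.
#' @return An [annotated_image()] without pixels.
#' @export
generate_annotations <- function(width = 600, height = 600,
                                 n_spikes = NULL, mean_spikes = 30,
                                 long_side = c(40, 95),
                                 aspect = c(0.2, 0.45),
                                 angle_weights = c(0.45, 0.15, 0.40),
                                 angle_means = c(0, 90),
                                 angle_sds = c(10, 10),
                                 max_overlap = 0.05,
                                 seed = NULL, image_id = "scene") {
  gen <- function() {
    n <- if (is.null(n_spikes)) rpois(1, mean_spikes) else n_spikes
    angles <- sample_spike_angles(n, angle_weights, angle_means, angle_sds)
    placed <- .place_boxes(
      n, width, height, long_side, aspect, angles,
      max_overlap
    )
    boxes <- if (n == 0) {
      oriented_box(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0))
    } else {
      normalize_boxes(oriented_box(
        placed[, 1], placed[, 2], placed[, 3], placed[, 4], placed[, 5]
      ))
    }
    annotated_image(NULL, boxes,
      image_id = image_id,
      width = width, height = height
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

.render_scene <- function(ann) {
  h <- ann$height
  w <- ann$width
  base <- c(62, 105, 48) # canopy green
  px <- array(0, c(h, w, 3))
  noise <- matrix(rnorm(h * w, 0, 10), h, w)
  for (c in 1:3) px[, , c] <- base[c] + noise
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  b <- ann$boxes
  for (i in seq_len(nrow(b))) {
    t <- b$theta[i] * pi / 180
    ct <- cos(t)
    st <- sin(t)
    du <- (xs - b$cx[i]) * ct + (ys - b$cy[i]) * st
    dv <- -(xs - b$cx[i]) * st + (ys - b$cy[i]) * ct
    inside <- (du / (b$w[i] / 2))^2 + (dv / (b$h[i] / 2))^2 <= 1
    n_in <- sum(inside)
    if (n_in == 0) next
    col <- c(150, 105, 55) + rnorm(3, 0, 12) # spike brown, per-spike tint
    grain <- rnorm(n_in, 0, 8)
    for (c in 1:3) {
      ch <- px[, , c]
      ch[inside] <- col[c] + grain
      px[, , c] <- ch
    }
  }
  pmin(pmax(px, 0), 255)
}

#' Generate a rendered synthetic spike scene
#'
#' [generate_annotations()] plus a simple renderer: each spike is drawn as a
#' textured filled ellipse inscribed in its ground-truth box, on a noisy
#' canopy-like background. The annotation boxes are the renderer's exact
#' placement rectangles. Same arguments and seed give a byte-identical
#' scene.
#'
#' @inheritParams generate_annotations
#' @return An [annotated_image()] with pixels in `[0, 255]`.
#' @export
generate_scene <- function(width = 600, height = 600,
                           n_spikes = NULL, mean_spikes = 30,
                           long_side = c(40, 95), aspect = c(0.2, 0.45),
                           angle_weights = c(0.45, 0.15, 0.40),
                           angle_means = c(0, 90), angle_sds = c(10, 10),
                           max_overlap = 0.05, seed = NULL,
                           image_id = "scene") {
  gen <- function() {
    ann <- generate_annotations(
      width, height, n_spikes, mean_spikes, long_side, aspect,
      angle_weights, angle_means, angle_sds, max_overlap,
      seed = NULL, image_id = image_id
    )
    annotated_image(.render_scene(ann), ann$boxes, image_id = image_id)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Perturb ground truth into synthetic detections
#'
#' Test harness for the evaluation metrics: each ground-truth box survives
#' with probability `1 - p_miss` and gets an independently noised copy
#' (wrapped-Gaussian angle noise, Gaussian center jitter, relative size
#' jitter) with a score drawn from `Beta(8, 2)`; spurious false positives
#' are added at `fp_rate` per image with `Beta(2, 5)` scores, placed like
#' scene spikes. Angles remain in `[0, 180)`.
#'
#' @param gt An [annotated_image()] or a plain box table (then `width` and
#'   `height` are required for false-positive placement).
#' @param angle_sd Wrapped-Gaussian angle noise sd (degrees).
#' @param center_sd Center jitter sd (px).
#' @param size_jitter Relative side-length jitter sd (e.g. 0.05 for 5%).
#' @param p_miss Per-box miss probability in `[0, 1]`.
#' @param fp_rate Expected false positives per image (Poisson).
#' @param seed Optional integer seed (local to the call).
#' @param width,height Image extent when `gt` is a plain table.
#' @return A scored box tibble (the synthetic detection set).
#' @export
perturb_annotations <- function(gt, angle_sd = 0, center_sd = 0,
                                size_jitter = 0, p_miss = 0, fp_rate = 0,
                                seed = NULL, width = NULL, height = NULL) {
  if (inherits(gt, "annotated_image")) {
    width <- gt$width
    height <- gt$height
    boxes <- gt$boxes
  } else {
    boxes <- gt
  }
  validate_boxes(boxes)
  if (p_miss < 0 || p_miss > 1 || fp_rate < 0) {
    abort("rates must lie in [0, 1] (p_miss) and be non-negative (fp_rate)",
      class = "spikeobb_invalid_config"
    )
  }
  gen <- function() {
    keep <- runif(nrow(boxes)) >= p_miss
    b <- boxes[keep, , drop = FALSE]
    n <- nrow(b)
    if (n > 0) {
      b$cx <- b$cx + rnorm(n, 0, center_sd)
      b$cy <- b$cy + rnorm(n, 0, center_sd)
      b$w <- b$w * pmax(1 + rnorm(n, 0, size_jitter), 0.05)
      b$h <- b$h * pmax(1 + rnorm(n, 0, size_jitter), 0.05)
      b$theta <- (b$theta + rnorm(n, 0, angle_sd)) %% 180
      b$score <- rbeta(n, 8, 2)
    }
    n_fp <- if (fp_rate > 0) rpois(1, fp_rate) else 0L
    if (n_fp > 0) {
      if (is.null(width) || is.null(height)) {
        abort("width and height are required to place false positives",
          class = "spikeobb_invalid_config"
        )
      }
      fw <- runif(n_fp, 40, 95)
      fp <- oriented_box(
        cx = runif(n_fp, 50, width - 50),
        cy = runif(n_fp, 50, height - 50),
        w = fw, h = fw * runif(n_fp, 0.2, 0.45),
        theta = runif(n_fp, 0, 180),
        score = rbeta(n_fp, 2, 5)
      )
      b <- dplyr::bind_rows(b, fp)
    }
    normalize_boxes(b)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Rasterized IoU oracle
#'
#' Independent brute-force check of [rotated_iou()]: a uniform
#' `resolution x resolution` grid of cell centers is laid over the joint
#' bounding region of the two boxes and membership of each point in each
#' rectangle is counted directly (coordinates rotated into each box frame;
#' no polygon clipping involved). Converges to the exact IoU as resolution
#' grows.
#'
#' @param a,b One-row box tables.
#' @param resolution Grid points per side (>= 100).
#' @return Approximate IoU in `[0, 1]`.
#' @export
rasterized_iou_oracle <- function(a, b, resolution = 2000) {
  if (resolution < 100) {
    abort("resolution must be at least 100", class = "spikeobb_invalid_config")
  }
  ma <- .box_rows(a)[1, ]
  mb <- .box_rows(b)[1, ]
  corners <- rbind(
    .corners1(ma[1], ma[2], ma[3], ma[4], ma[5]),
    .corners1(mb[1], mb[2], mb[3], mb[4], mb[5])
  )
  xr <- range(corners[, 1])
  yr <- range(corners[, 2])
  gx <- seq(xr[1], xr[2], length.out = resolution + 1)
  gy <- seq(yr[1], yr[2], length.out = resolution + 1)
  cx <- (gx[-1] + gx[-length(gx)]) / 2
  cy <- (gy[-1] + gy[-length(gy)]) / 2
  px <- rep(cx, times = resolution)
  py <- rep(cy, each = resolution)
  in_box <- function(m) {
    t <- m[5] * pi / 180
    du <- (px - m[1]) * cos(t) + (py - m[2]) * sin(t)
    dv <- -(px - m[1]) * sin(t) + (py - m[2]) * cos(t)
    abs(du) <= m[3] / 2 & abs(dv) <= m[4] / 2
  }
  ia <- in_box(ma)
  ib <- in_box(mb)
  inter <- sum(ia & ib)
  union <- sum(ia | ib)
  if (union == 0) 0 else inter / union
}
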