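# Annotated images and the augmentation suite: quarter-turn rotations,
# horizontal/vertical flips and global brightness scaling, each applied
# consistently to pixels and to the oriented-box annotations.

#' Annotated image
#'
#' Bundles an RGB pixel array with its oriented-box annotation. Pixels are
#' stored as an `H x W x 3` numeric array with values in `[0, 255]`;
#' `pixels = NULL` is allowed for annotation-only work (evaluation,
#' perturbation studies), in which case `width`/`height` must be given.
#'
#' @param pixels `H x W x 3` array in `[0, 255]`, or `NULL`.
#' @param boxes Box table (see [oriented_box()]).
#' @param image_id Identifier used in file names and evaluation keys.
#' @param width,height Image extent in px; inferred from `pixels` when
#'   present.
#' @return An object of class `"annotated_image"` with fields `pixels`,
#'   `boxes`, `image_id`, `width`, `height`.
#' @export
annotated_image <- function(pixels, boxes, image_id = "image",
                            width = NULL, height = NULL) {
  if (!is.null(pixels)) {
    if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
      abort("pixels must be an H x W x 3 array or NULL",
        class = "spikeobb_invalid_input"
      )
    }
    if (min(pixels) < 0 || max(pixels) > 255) {
      abort("pixel values must lie in [0, 255]", class = "spikeobb_invalid_input")
    }
    height <- dim(pixels)[1]
    width <- dim(pixels)[2]
  }
  if (is.null(width) || is.null(height)) {
    abort("width and height are required when pixels are absent",
      class = "spikeobb_invalid_input"
    )
  }
  validate_boxes(boxes)
  structure(
    list(
      pixels = pixels, boxes = dplyr::as_tibble(boxes),
      image_id = as.character(image_id),
      width = as.numeric(width), height = as.numeric(height)
    ),
    class = "annotated_image"
  )
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf(
    "<annotated_image '%s'> %g x %g px, %d box(es)%s\n",
    x$image_id, x$width, x$height, nrow(x$boxes),
    if (is.null(x$pixels)) ", no pixels" else ""
  ))
  invisible(x)
}

# one clockwise quarter-turn of an H x W x C array
.rot90_pixels <- function(a) {
  h <- dim(a)[1]
  aperm(a[h:1, , , drop = FALSE], c(2, 1, 3))
}

#' Rotate an annotated image by quarter turns
#'
#' Rotates pixels clockwise by `k * 90` degrees and maps every box with it:
#' one quarter-turn sends a center `(cx, cy)` to `(H - cy, cx)`, swaps the
#' image dimensions, and adds 90 degrees to the long-side angle (mod 180).
#'
#' @param img An [annotated_image()].
#' @param k Number of quarter turns, 1, 2 or 3.
#' @return The rotated annotated image.
#' @export
rotate90 <- function(img, k = 1) {
  stopifnot(inherits(img, "annotated_image"))
  if (!(length(k) == 1 && k %in% 1:3)) {
    abort("k must be 1, 2 or 3 quarter turns", class = "spikeobb_invalid_config")
  }
  out <- img
  for (i in seq_len(k)) {
    b <- out$boxes
    new_cx <- out$height - b$cy
    new_cy <- b$cx
    b$cx <- new_cx
    b$cy <- new_cy
    b$theta <- b$theta + 90
    out$boxes <- normalize_boxes(b)
    if (!is.null(out$pixels)) out$pixels <- .rot90_pixels(out$pixels)
    wh <- c(out$width, out$height)
    out$width <- wh[2]
    out$height <- wh[1]
  }
  out$image_id <- paste0(img$image_id, "_rot", 90 * k)
  out
}

#' Flip an annotated image
#'
#' Mirrors pixels and boxes about the vertical (`axis = "horizontal"`,
#' `cx' = W - cx`) or horizontal (`axis = "vertical"`, `cy' = H - cy`)
#' midline; either flip maps the long-side angle to `(180 - theta) mod 180`
#' and leaves side lengths unchanged. Coordinates are continuous, so the
#' mirror is about the image extent `W` (not `W - 1`).
#'
#' @param img An [annotated_image()].
#' @param axis `"horizontal"` or `"vertical"`.
#' @return The flipped annotated image.
#' @export
flip_image <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  stopifnot(inherits(img, "annotated_image"))
  out <- img
  b <- out$boxes
  if (axis == "horizontal") {
    b$cx <- out$width - b$cx
    if (!is.null(out$pixels)) {
      out$pixels <- out$pixels[, dim(out$pixels)[2]:1, , drop = FALSE]
    }
  } else {
    b$cy <- out$height - b$cy
    if (!is.null(out$pixels)) {
      out$pixels <- out$pixels[dim(out$pixels)[1]:1, , , drop = FALSE]
    }
  }
  b$theta <- 180 - b$theta
  out$boxes <- normalize_boxes(b)
  out$image_id <- paste0(
    img$image_id,
    if (axis == "horizontal") "_fliph" else "_flipv"
  )
  out
}

#' Adjust image brightness
#'
#' Scales all pixel values by `factor` and clips to `[0, 255]`; annotations
#' and image dimensions are untouched.
#'
#' @param img An [annotated_image()] with pixels.
#' @param factor Positive multiplier (e.g. 1.1 for +10%).
#' @return The brightness-adjusted annotated image.
#' @export
adjust_brightness <- function(img, factor) {
  stopifnot(inherits(img, "annotated_image"))
  if (!is.finite(factor) || factor <= 0) {
    abort("brightness factor must be positive", class = "spikeobb_invalid_config")
  }
  if (is.null(img$pixels)) {
    abort("adjust_brightness() needs pixels", class = "spikeobb_invalid_input")
  }
  out <- img
  out$pixels <- pmin(pmax(img$pixels * factor, 0), 255)
  out$image_id <- paste0(img$image_id, sprintf("_b%03d", round(100 * factor)))
  out
}

#' Apply the full augmentation suite to a dataset
#'
#' Per input image emits the three quarter-turn rotations (90, 180, 270
#' degrees), the horizontal and vertical flips, and four brightness variants
#' (factors 0.8, 0.9, 1.1, 1.2), i.e. brightness changed by plus and minus
#' 10% and 20% -- plus, when `retain_originals`, the original itself: ten
#' outputs per input. Augmentations are applied to the originals only (no
#' stacking). Output ids are the input id plus a deterministic suffix.
#'
#' @param images List of [annotated_image()] objects.
#' @param retain_originals Keep each original in the output (default TRUE).
#' @return A flat list of annotated images, `10 * length(images)` long with
#'   originals retained, `9 *` otherwise.
#' @examples
#' imgs <- lapply(1:2, function(i) {
#'   generate_scene(
#'     width = 32, height = 32, n_spikes = 2,
#'     long_side = c(8, 12), seed = i, image_id = paste0("img", i)
#'   )
#' })
#' length(augment_dataset(imgs)) # 20
#' @export
augment_dataset <- function(images, retain_originals = TRUE) {
  if (length(images) == 0) {
    abort("augment_dataset() needs at least one image", class = "spikeobb_invalid_input")
  }
  out <- lapply(images, function(img) {
    stopifnot(inherits(img, "annotated_image"))
    c(
      if (retain_originals) list(img),
      lapply(1:3, function(k) rotate90(img, k)),
      list(flip_image(img, "horizontal"), flip_image(img, "vertical")),
      lapply(c(0.8, 0.9, 1.1, 1.2), function(f) adjust_brightness(img, f))
    )
  })
  unlist(out, recursive = FALSE)
}

#' Random train/validation/test split
#'
#' Partitions a dataset at the given ratios (default 6:1:3) using a seeded
#' shuffle. Sizes are the rounded ratio shares (largest-remainder rounding),
#' so the parts are disjoint and exhaustive.
#'
#' Note the split is applied to the (possibly augmented) image list as
#' given; if augmented variants of one original should never straddle
#' splits, split the originals first and augment each part.
#'
#' @param images List (or vector) of items to split.
#' @param ratios Positive weights, one per part; default `c(6, 1, 3)` named
#'   train/val/test.
#' @param seed Integer seed for the shuffle.
#' @return A named list of parts in ratio order.
#' @export
split_dataset <- function(images, ratios = c(train = 6, val = 1, test = 3),
                          seed = 1) {
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    abort("ratios must be positive", class = "spikeobb_invalid_config")
  }
  n <- length(images)
  if (n < length(ratios)) {
    abort("fewer images than partitions", class = "spikeobb_invalid_input")
  }
  shares <- n * ratios / sum(ratios)
  sizes <- floor(shares)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(shares - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  idx <- withr::with_seed(seed, sample.int(n))
  grp <- rep(seq_along(sizes), times = sizes)
  parts <- lapply(seq_along(sizes), function(i) images[idx[grp == i]])
  names(parts) <- names(ratios) %||% paste0("part", seq_along(ratios))
  parts
}
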