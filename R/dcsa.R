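# Reference forward passes for the two DCSA building blocks: deformable
# convolution sampling and scaled dot-product attention. These document and
# verify the operator semantics numerically; offsets are plain inputs (the
# learned offset-prediction branch, backbone and training are out of scope).

.as_feature_map <- function(fm) {
  if (is.matrix(fm)) fm <- array(fm, c(dim(fm), 1L))
  if (!is.array(fm) || length(dim(fm)) != 3L) {
    abort("feature map must be an H x W x C array (or a matrix)",
      class = "spikeobb_invalid_input"
    )
  }
  if (!all(is.finite(fm))) {
    abort("feature map must be finite", class = "spikeobb_invalid_input")
  }
  fm
}

#' Bilinear sampling from a feature map
#'
#' Interpolates the four neighbouring grid points at a continuous location.
#' Coordinates are zero-based: `(x, y) = (0, 0)` is the first pixel, `x`
#' indexes columns and `y` rows. Samples falling outside the grid contribute
#' zero (zero padding).
#'
#' @param fm An `H x W x C` array (a matrix is treated as `C = 1`).
#' @param x,y Continuous sample location (px, zero-based).
#' @return Numeric vector of length `C`.
#' @examples
#' bilinear_sample(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE), 0.5, 0.5) # 2.5
#' @export
bilinear_sample <- function(fm, x, y) {
  fm <- .as_feature_map(fm)
  h <- dim(fm)[1]
  w <- dim(fm)[2]
  acc <- numeric(dim(fm)[3])
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  for (dy in 0:1) {
    for (dx in 0:1) {
      wt <- (if (dx == 1) fx else 1 - fx) * (if (dy == 1) fy else 1 - fy)
      xi <- x0 + dx
      yi <- y0 + dy
      if (wt != 0 && xi >= 0 && xi < w && yi >= 0 && yi < h) {
        acc <- acc + wt * fm[yi + 1, xi + 1, ]
      }
    }
  }
  acc
}

#' Deformable 2-D convolution (reference forward pass)
#'
#' Convolution whose sampling grid is displaced per output position and per
#' kernel tap by a continuous `(dx, dy)` offset, evaluated with
#' [bilinear_sample()]. Stride 1, zero padding, spatial extent preserved.
#' With all offsets zero this reduces exactly to a direct convolution
#' (cross-correlation orientation, as in deep-learning frameworks).
#'
#' @param fm Input `H x W x C_in` array.
#' @param kernel `k x k x C_in x C_out` weight array, `k` odd.
#' @param offsets `NULL` (all zero) or an `H x W x k^2 x 2` array; taps are
#'   ordered row-major over the kernel window and the last dimension is
#'   `(dx, dy)`.
#' @return An `H x W x C_out` array.
#' @export
deformable_conv2d <- function(fm, kernel, offsets = NULL) {
  fm <- .as_feature_map(fm)
  if (!is.array(kernel) || length(dim(kernel)) != 4L) {
    abort("kernel must be a k x k x C_in x C_out array", class = "spikeobb_invalid_input")
  }
  kd <- dim(kernel)
  h <- dim(fm)[1]
  w <- dim(fm)[2]
  c_in <- dim(fm)[3]
  k <- kd[1]
  if (kd[2] != k || k %% 2 != 1) {
    abort("kernel must be square with odd size", class = "spikeobb_invalid_input")
  }
  if (kd[3] != c_in) {
    abort("kernel C_in does not match the feature map", class = "spikeobb_invalid_input")
  }
  n_tap <- k * k
  if (is.null(offsets)) {
    offsets <- array(0, c(h, w, n_tap, 2L))
  }
  if (!is.array(offsets) || !identical(dim(offsets), c(h, w, n_tap, 2L))) {
    abort(sprintf("offsets must be an %d x %d x %d x 2 array", h, w, n_tap),
      class = "spikeobb_invalid_input"
    )
  }
  c_out <- kd[4]
  half <- (k - 1) / 2
  # kernel as (tap, c_in)-flattened rows x c_out, c_in fastest then taps in
  # row-major window order, so one vector-matrix product per output position
  kmat <- matrix(aperm(kernel, c(3, 2, 1, 4)), nrow = n_tap * c_in, ncol = c_out)
  out <- array(0, c(h, w, c_out))
  samp <- matrix(0, n_tap, c_in)
  for (oy in seq_len(h)) {
    for (ox in seq_len(w)) {
      t <- 0L
      for (ty in -half:half) {
        for (tx in -half:half) {
          t <- t + 1L
          sx <- (ox - 1) + tx + offsets[oy, ox, t, 1]
          sy <- (oy - 1) + ty + offsets[oy, ox, t, 2]
          samp[t, ] <- bilinear_sample(fm, sx, sy)
        }
      }
      out[oy, ox, ] <- as.vector(as.vector(t(samp)) %*% kmat)
    }
  }
  out
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d)) V` with a numerically stable (row-max
#' subtracted) softmax. In the DCSA block this re-weights features along the
#' color/channel dimension; here it is exposed as the bare operator.
#'
#' @param q `n_q x d` query matrix.
#' @param k `n_k x d` key matrix.
#' @param v `n_k x d_v` value matrix.
#' @return A list with `output` (`n_q x d_v`) and `weights` (`n_q x n_k`,
#'   rows summing to 1).
#' @export
scaled_dot_product_attention <- function(q, k, v) {
  q <- as.matrix(q)
  k <- as.matrix(k)
  v <- as.matrix(v)
  d <- ncol(q)
  if (d == 0L || ncol(k) != d) {
    abort("queries and keys must share a positive inner dimension",
      class = "spikeobb_invalid_input"
    )
  }
  if (nrow(k) != nrow(v) || nrow(k) == 0L) {
    abort("keys and values must have the same (positive) number of rows",
      class = "spikeobb_invalid_input"
    )
  }
  logits <- q %*% t(k) / sqrt(d)
  logits <- logits - apply(logits, 1, max)
  wts <- exp(logits)
  wts <- wts / rowSums(wts)
  list(output = wts %*% v, weights = wts)
}
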