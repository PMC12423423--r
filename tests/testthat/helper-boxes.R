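# Shared fixtures: random normalized boxes, tiny rendered scenes, and an
# independent direct-convolution oracle used against the deformable path.

random_boxes <- function(n, sides = c(5, 100), center_spread = 40) {
  w <- runif(n, sides[1], sides[2])
  h <- runif(n, sides[1], pmin(w, sides[2]))
  normalize_boxes(oriented_box(
    cx = runif(n, -center_spread, center_spread),
    cy = runif(n, -center_spread, center_spread),
    w = w, h = h, theta = runif(n, 0, 180)
  ))
}

tiny_scene <- function(seed, id = paste0("img", seed)) {
  generate_scene(
    width = 48, height = 48, n_spikes = 3,
    long_side = c(10, 16), aspect = c(0.25, 0.45),
    seed = seed, image_id = id
  )
}

# brute-force direct convolution (stride 1, zero padding), written
# independently of the bilinear-sampling code path
direct_conv2d <- function(fm, kernel) {
  kd <- dim(kernel)
  k <- kd[1]
  half <- (k - 1) / 2
  h <- dim(fm)[1]
  w <- dim(fm)[2]
  out <- array(0, c(h, w, kd[4]))
  for (oy in 1:h) {
    for (ox in 1:w) {
      for (co in 1:kd[4]) {
        acc <- 0
        for (ky in 1:k) {
          for (kx in 1:k) {
            sy <- oy + (ky - 1) - half
            sx <- ox + (kx - 1) - half
            if (sy >= 1 && sy <= h && sx >= 1 && sx <= w) {
              acc <- acc + sum(kernel[ky, kx, , co] * fm[sy, sx, ])
            }
          }
        }
        out[oy, ox, co] <- acc
      }
    }
  }
  out
}

# corner set comparison up to cyclic order / reversal
expect_same_rect <- function(a, b, tol = 1e-6) {
  a <- a[order(round(a[, 1] / tol), round(a[, 2] / tol)), , drop = FALSE]
  b <- b[order(round(b[, 1] / tol), round(b[, 2] / tol)), , drop = FALSE]
  expect_lt(max(abs(a - b)), tol)
}
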