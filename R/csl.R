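# Circular smooth labels: the long-side angle is treated as a classification
# target over 180 one-degree categories, with a Gaussian window around the
# true angle so that near-miss categories are penalized less than far ones,
# and with circular wrap-around so 179 and 0 degrees are neighbours.

.CSL_BINS <- 180L

#' Periodic distance between long-side angles
#'
#' Distance on the 180-degree circle of long-side angles:
#' `min(|a - b| mod 180, 180 - |a - b| mod 180)`, always in `[0, 90]`.
#' This is the natural error measure for box orientation -- a prediction of
#' 179 degrees against a truth of 1 degree is off by 2 degrees, not 178.
#'
#' @param a,b Angles in degrees (vectorized, any finite values).
#' @return Non-negative distances in degrees, at most 90.
#' @examples
#' circular_angle_distance(179, 1) # 2
#' @export
circular_angle_distance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Encode an angle as a circular smooth label vector
#'
#' Produces the 180-bin label vector `CSL(x) = g(x)` for
#' `theta - r < x < theta + r` and 0 otherwise, where `g` is a Gaussian
#' window `exp(-d(x, theta)^2 / (2 sigma^2))` on the circular angle distance
#' `d`, peak-normalized to 1 at the true angle. The window wraps across the
#' 0/180 boundary.
#'
#' Defaults: `r = 6` degrees with `sigma = r / 3`, placing the window edge at
#' three standard deviations. Bins are integer degrees; non-integer angles
#' are encoded about their real value and decode to the nearest integer
#' degree (quantization error at most 0.5 degrees).
#'
#' @param theta Angle in degrees; wrapped into `[0, 180)`.
#' @param r Window radius in degrees, in `(0, 90)`.
#' @param sigma Gaussian width in degrees, positive.
#' @return Numeric vector of length 180, bin `k + 1` holding the label value
#'   for the integer angle `k`.
#' @examples
#' v <- csl_encode(45)
#' which.max(v) - 1 # 45
#' @export
csl_encode <- function(theta, r = 6, sigma = r / 3) {
  if (length(theta) != 1L || !is.finite(theta)) {
    abort("theta must be a single finite angle", class = "spikeobb_invalid_angle")
  }
  if (!is.finite(r) || r <= 0 || r >= 90) {
    abort("window radius r must lie in (0, 90)", class = "spikeobb_invalid_input")
  }
  if (!is.finite(sigma) || sigma <= 0) {
    abort("sigma must be positive", class = "spikeobb_invalid_input")
  }
  theta <- theta %% 180
  d <- circular_angle_distance(seq_len(.CSL_BINS) - 1, theta)
  ifelse(d < r, exp(-d^2 / (2 * sigma^2)), 0)
}

#' Decode a circular smooth label vector to an angle
#'
#' Argmax decoding: the index (0-based degree) of the largest bin, ties
#' broken toward the smallest index.
#'
#' @param vec Numeric vector of length 180 with no missing values.
#' @return Integer angle in degrees, in `[0, 180)`.
#' @examples
#' csl_decode(csl_encode(117)) # 117
#' @export
csl_decode <- function(vec) {
  if (length(vec) != .CSL_BINS || anyNA(vec) || !is.numeric(vec)) {
    abort("expected a numeric length-180 label vector without NAs",
      class = "spikeobb_invalid_input"
    )
  }
  which.max(vec) - 1L
}
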