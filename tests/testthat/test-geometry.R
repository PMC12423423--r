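test_that("normalization enforces the long-side convention without changing the rectangle", {
  cases <- list(
    list(in_ = c(0, 0, 2, 6, 10), out = c(0, 0, 6, 2, 100)),
    list(in_ = c(0, 0, 6, 2, 190), out = c(0, 0, 6, 2, 10)),
    list(in_ = c(0, 0, 6, 2, 45), out = c(0, 0, 6, 2, 45))
  )
  for (cs in cases) {
    b <- normalize_boxes(oriented_box(
      cs$in_[1], cs$in_[2], cs$in_[3], cs$in_[4],
      cs$in_[5]
    ))
    expect_equal(unlist(b[1, 1:5], use.names = FALSE), cs$out)
  }
  # same point set before and after
  set.seed(1)
  for (i in 1:20) {
    raw <- oriented_box(runif(1, -5, 5), runif(1, -5, 5),
      runif(1, 1, 10), runif(1, 1, 10),
      theta = runif(1, -360, 360)
    )
    norm <- normalize_boxes(raw)
    expect_true(norm$w >= norm$h)
    expect_true(norm$theta >= 0 && norm$theta < 180)
    expect_equal(rotated_iou(raw, norm), 1, tolerance = 1e-9)
  }
  expect_error(oriented_box(0, 0, 0, 2, 0), class = "spikeobb_invalid_box")
  expect_error(oriented_box(0, 0, 3, -1, 0), class = "spikeobb_invalid_box")
})

test_that("box corners have the right centroid, edge lengths and placement", {
  p <- box_corners(oriented_box(0, 0, 4, 2, 0))
  expect_same_rect(
    cbind(p$x, p$y),
    matrix(c(-2, -1, 2, -1, 2, 1, -2, 1), ncol = 2, byrow = TRUE)
  )
  p90 <- box_corners(oriented_box(0, 0, 4, 2, 90))
  expect_same_rect(
    cbind(p90$x, p90$y),
    matrix(c(-1, -2, 1, -2, 1, 2, -1, 2), ncol = 2, byrow = TRUE)
  )
  # 45-degree square: corners on the diagonals at distance sqrt(2)
  p45 <- box_corners(oriented_box(5, 5, 2, 2, 45))
  d <- sqrt((p45$x - 5)^2 + (p45$y - 5)^2)
  expect_equal(d, rep(sqrt(2), 4))
  expect_true(any(abs(p45$x - 5) < 1e-12), TRUE) # corners sit on the axes
  # generic: centroid and edge lengths
  set.seed(2)
  b <- random_boxes(10)
  crn <- box_corners(b)
  for (i in 1:10) {
    p <- crn[crn$box == i, ]
    expect_equal(mean(p$x), b$cx[i], tolerance = 1e-9)
    expect_equal(mean(p$y), b$cy[i], tolerance = 1e-9)
    e <- sqrt(diff(c(p$x, p$x[1]))^2 + diff(c(p$y, p$y[1]))^2)
    expect_equal(sort(e), sort(c(b$h[i], b$h[i], b$w[i], b$w[i])), tolerance = 1e-9)
  }
})

test_that("fan-triangulated area equals shoelace and known closed forms", {
  expect_equal(polygon_area(cbind(c(0, 1, 0), c(0, 0, 1))), 0.5)
  expect_equal(polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))), 1)
  hexagon <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))
  expect_equal(polygon_area(hexagon), 3 * sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(polygon_area(cbind(0, 0)), 0) # degenerate
  # fan == shoelace == pracma oracle on random intersections
  set.seed(3)
  for (i in 1:50) {
    ab <- random_boxes(2, center_spread = 30)
    ca <- box_corners(ab[1, ])
    cb <- box_corners(ab[2, ])
    inter <- convex_intersection(cbind(ca$x, ca$y), cbind(cb$x, cb$y))
    a_fan <- polygon_area(inter)
    expect_equal(a_fan, polygon_area(inter, method = "shoelace"),
      tolerance = 1e-9
    )
    if (nrow(inter) >= 3) {
      expect_equal(a_fan, abs(pracma::polyarea(inter$x, inter$y)),
        tolerance = 1e-9
      )
    }
  }
})

test_that("convex intersection handles the classic cases and the vertex-count bound", {
  sq <- function(x0, s) cbind(c(x0, x0 + s, x0 + s, x0), c(x0, x0, x0 + s, x0 + s))
  inter <- convex_intersection(sq(0, 2), sq(1, 2))
  expect_equal(polygon_area(inter), 1)
  expect_equal(nrow(inter), 4)
  expect_equal(nrow(convex_intersection(sq(0, 1), sq(5, 1))), 0)
  # square vs itself rotated 45 degrees: regular octagon, area 8(sqrt2 - 1)
  a <- oriented_box(0, 0, 2, 2, 0)
  b <- oriented_box(0, 0, 2, 2, 45)
  ca <- box_corners(a)
  cb <- box_corners(b)
  oct <- convex_intersection(cbind(ca$x, ca$y), cbind(cb$x, cb$y))
  expect_equal(nrow(oct), 8)
  expect_equal(polygon_area(oct), 8 * (sqrt(2) - 1), tolerance = 1e-12)
  # two rectangles never intersect in more than 8 vertices
  set.seed(4)
  for (i in 1:100) {
    ab <- random_boxes(2, center_spread = 25)
    ca <- box_corners(ab[1, ])
    cb <- box_corners(ab[2, ])
    expect_lte(nrow(convex_intersection(cbind(ca$x, ca$y), cbind(cb$x, cb$y))), 8)
  }
})

test_that("rotated IoU matches analytic values and the rasterized oracle", {
  a <- oriented_box(0, 0, 2, 2, 0)
  expect_equal(rotated_iou(a, a), 1)
  expect_equal(rotated_iou(a, oriented_box(1, 0, 2, 2, 0)), 1 / 3, tolerance = 1e-12)
  expect_equal(rotated_iou(a, oriented_box(0, 0, 2, 2, 45)), 1 / sqrt(2),
    tolerance = 1e-12
  )
  expect_equal(rotated_iou(a, oriented_box(10, 10, 2, 2, 30)), 0)
  # moderate-resolution oracle sweep (the full-scale one runs in the
  # acceptance suite)
  set.seed(5)
  for (i in 1:40) {
    ab <- random_boxes(2)
    err <- abs(rotated_iou(ab[1, ], ab[2, ]) -
      rasterized_iou_oracle(ab[1, ], ab[2, ], resolution = 600))
    expect_lt(err, 0.02)
  }
})

test_that("IoU and sum-ratio are symmetric and rigid-motion invariant", {
  set.seed(6)
  for (i in 1:30) {
    ab <- random_boxes(2)
    a <- ab[1, ]
    b <- ab[2, ]
    expect_equal(rotated_iou(a, b), rotated_iou(b, a), tolerance = 1e-12)
    expect_equal(overlap_ratio_sum(a, b), overlap_ratio_sum(b, a),
      tolerance = 1e-12
    )
    # common rigid transform: rotate both about a point, then translate
    phi <- runif(1, 0, 360)
    t <- phi * pi / 180
    dx <- runif(1, -50, 50)
    dy <- runif(1, -50, 50)
    move <- function(bx) {
      cx <- bx$cx * cos(t) - bx$cy * sin(t) + dx
      cy <- bx$cx * sin(t) + bx$cy * cos(t) + dy
      oriented_box(cx, cy, bx$w, bx$h, bx$theta + phi)
    }
    expect_equal(rotated_iou(move(a), move(b)), rotated_iou(a, b),
      tolerance = 1e-9
    )
  }
})

test_that("overlap-to-sum ratio reaches 0.5 only at identity", {
  a <- oriented_box(3, 7, 10, 4, 25)
  expect_equal(overlap_ratio_sum(a, a), 0.5)
  expect_equal(
    overlap_ratio_sum(
      oriented_box(0, 0, 2, 2, 0),
      oriented_box(1, 0, 2, 2, 0)
    ), 0.25
  )
  expect_equal(
    overlap_ratio_sum(
      oriented_box(0, 0, 2, 2, 0),
      oriented_box(9, 0, 2, 2, 0)
    ), 0
  )
  set.seed(7)
  for (i in 1:20) {
    ab <- random_boxes(2)
    r <- overlap_ratio_sum(ab[1, ], ab[2, ])
    expect_gte(r, 0)
    expect_lte(r, 0.5)
  }
})

test_that("minimum-area rotated rectangle recovers boxes from their corners", {
  set.seed(8)
  for (i in 1:25) {
    b <- random_boxes(1)
    crn <- box_corners(b)
    rec <- min_rotated_rect(cbind(crn$x, crn$y))
    expect_equal(rec$cx, b$cx, tolerance = 1e-6)
    expect_equal(rec$cy, b$cy, tolerance = 1e-6)
    expect_equal(rec$w, b$w, tolerance = 1e-6)
    expect_equal(rec$h, b$h, tolerance = 1e-6)
    expect_lt(circular_angle_distance(rec$theta, b$theta) * max(b$w, 1), 1e-4)
  }
  expect_error(min_rotated_rect(cbind(c(0, 1, 2), c(0, 1, 2))),
    class = "spikeobb_invalid_input"
  )
})
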