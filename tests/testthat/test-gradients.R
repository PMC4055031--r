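test_that("constant images have zero gradient everywhere", {
  img <- matrix(3.7, 16, 16)
  g <- gaussian_derivative_filter(img, sigma = 1.5)
  expect_true(all(abs(g$gx) < 1e-12))
  expect_true(all(abs(g$gy) < 1e-12))
})

test_that("a linear ramp reproduces its slope exactly", {
  img <- matrix(rep(1:32, each = 32), 32, 32) # f(row, col) = col
  g <- gaussian_derivative_filter(img, sigma = 2)
  interior <- 10:23
  expect_true(all(abs(g$gx[interior, interior] - 1) < 1e-6))
  expect_true(all(abs(g$gy[interior, interior]) < 1e-9))
  mo <- gradient_orientation(g$gx, g$gy)
  expect_true(all(ang_diff(mo$orientation_deg[interior, interior], 0) < 1e-6))
})

test_that("separable filtering equals brute-force 2D convolution", {
  set.seed(42)
  img <- matrix(runif(49), 7, 7)
  sigma <- 1
  r <- ceiling(4 * sigma)
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  dg <- -(x / sigma^2) * exp(-x^2 / (2 * sigma^2))
  dg <- dg / sum(-x * dg)
  ref_gx <- brute_conv2(img, g, dg)
  ref_gy <- brute_conv2(img, dg, g)
  got <- gaussian_derivative_filter(img, sigma)
  expect_lt(max(abs(got$gx - ref_gx)), 1e-10)
  expect_lt(max(abs(got$gy - ref_gy)), 1e-10)
})

test_that("gradient orientation follows atan2(gy, gx) in [0, 360)", {
  mo <- gradient_orientation(matrix(1, 1, 1), matrix(0, 1, 1))
  expect_equal(mo$orientation_deg[1, 1], 0)
  expect_equal(mo$magnitude[1, 1], 1)
  mo <- gradient_orientation(matrix(0, 1, 1), matrix(-1, 1, 1))
  expect_equal(mo$orientation_deg[1, 1], 270)
  mo <- gradient_orientation(matrix(3, 1, 1), matrix(4, 1, 1))
  expect_equal(mo$magnitude[1, 1], 5)
  expect_equal(mo$orientation_deg[1, 1], atan2(4, 3) * 180 / pi,
               tolerance = 1e-12)
  expect_error(gradient_orientation(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shape")
})

test_that("magnitude is invariant to an additive intensity constant", {
  ph <- cached_phantom(size = 128, seed = 3)
  g1 <- gradient_field(ph$fixed, sigma = 2)
  g2 <- gradient_field(ph$fixed + 5, sigma = 2)
  expect_equal(g1$magnitude, g2$magnitude, tolerance = 1e-9)
})

test_that("non-maximal suppression thins a vertical step edge to a line", {
  img <- matrix(0, 32, 32)
  img[, 17:32] <- 1
  f <- gradient_field(img, sigma = 1.5, nms = TRUE)
  kept_cols <- which(apply(f$keep_mask, 2, any))
  # ridge of a vertical step: one or two columns at the transition
  expect_true(all(kept_cols %in% 16:17))
  # brute-force check: every kept pixel beats both horizontal neighbours
  for (idx in which(f$keep_mask)) {
    rc <- arrayInd(idx, dim(img))
    expect_gte(f$magnitude[rc[1], rc[2]], f$magnitude[rc[1], rc[2] - 1])
    expect_gte(f$magnitude[rc[1], rc[2]], f$magnitude[rc[1], rc[2] + 1])
  }
})

test_that("NMS keep mask is a subset of positive-magnitude pixels and excludes the border", {
  ph <- cached_phantom(size = 128, seed = 5)
  f <- gradient_field(ph$fixed, sigma = 2, nms = TRUE)
  expect_true(all(f$magnitude[f$keep_mask] > 0))
  expect_false(any(f$keep_mask[c(1, nrow(f$keep_mask)), ]))
  expect_false(any(f$keep_mask[, c(1, ncol(f$keep_mask))]))
  f0 <- gradient_field(matrix(1, 16, 16), sigma = 1, nms = TRUE)
  expect_false(any(f0$keep_mask))
})

test_that("Gaussian-derivative orientations are locally smoother than Sobel's", {
  ph <- cached_phantom(size = 128, seed = 1)
  circ_var5 <- function(field) {
    th <- field$orientation_deg * pi / 180
    # mean resultant length within 5x5 windows, via separable box sums
    box <- function(m) {
      for (ax in 1:2) {
        acc <- m * 0
        for (dd in -2:2) {
          idx <- pmin.int(pmax.int(seq_len(dim(m)[ax]) + dd, 1L), dim(m)[ax])
          acc <- acc + (if (ax == 1) m[idx, ] else m[, idx])
        }
        m <- acc / 5
      }
      m
    }
    w <- field$magnitude
    c2 <- box(w * cos(2 * th))
    s2 <- box(w * sin(2 * th))
    wm <- box(w)
    r <- sqrt(c2^2 + s2^2) / pmax(wm, 1e-12)
    mean(1 - r[wm > stats::quantile(wm, 0.5)])
  }
  vg <- circ_var5(gradient_field(ph$fixed, sigma = 2, derivative = "gaussian"))
  vs <- circ_var5(gradient_field(ph$fixed, derivative = "sobel"))
  expect_lt(vg, vs)
})

test_that("sigma must be positive", {
  expect_error(gaussian_derivative_filter(matrix(0, 5, 5), 0), "positive")
  expect_error(gaussian_derivative_filter(matrix(0, 5, 5), -1), "positive")
})
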