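mk_field <- function(m, th) {
  keep <- m > 0
  structure(list(gx = m * cos(th * pi / 180), gy = m * sin(th * pi / 180),
                 magnitude = m, orientation_deg = th, keep_mask = keep,
                 sigma = 1),
            class = "gradient_field")
}

test_that("a uniform rightward-gradient field puts all mass in bin 0", {
  f <- mk_field(matrix(1, 64, 64), matrix(0, 64, 64))
  h <- orientation_histogram(f, K = 360, use_nms = FALSE)
  expect_gt(h$bins[1], 0)
  expect_true(all(h$bins[-1] == 0))
})

test_that("hand-accumulated two-pixel field lands in the right bin", {
  m <- matrix(0, 64, 64)
  th <- matrix(0, 64, 64)
  m[32, 32] <- 2; th[32, 32] <- 10.4
  m[32, 33] <- 3; th[32, 33] <- 10.9
  h <- orientation_histogram(mk_field(m, th), K = 360)
  expect_equal(h$bins[11], 5) # bin 10 covers [10, 11)
  expect_equal(sum(h$bins), 5)
})

test_that("total mass is conserved across bin counts", {
  ph <- cached_phantom(size = 128, seed = 1)
  f <- gradient_field(ph$fixed, sigma = 2)
  masses <- vapply(c(90, 180, 360, 720),
                   function(K) sum(orientation_histogram(f, K = K)$bins),
                   numeric(1))
  expect_true(all(abs(masses - masses[1]) < 1e-9 * masses[1]))
})

test_that("pixels outside the inscribed circle never contribute", {
  m <- matrix(0, 64, 64)
  th <- matrix(0, 64, 64)
  m[2, 2] <- 1e6; th[2, 2] <- 45 # poisoned corner, outside the circle
  m[32, 32] <- 1; th[32, 32] <- 100
  h <- orientation_histogram(mk_field(m, th), K = 360)
  expect_equal(sum(h$bins), 1)
  expect_equal(h$bins[101], 1)
})

test_that("normalization produces unit mass and is scale invariant", {
  h <- rotalign:::new_orientation_histogram(c(2, 2, 0, 0))
  n <- normalize_histogram(h)
  expect_equal(n$bins, c(0.5, 0.5, 0, 0))
  h2 <- rotalign:::new_orientation_histogram(c(2, 2, 0, 0) * 17)
  expect_equal(normalize_histogram(h2)$bins, n$bins)
  ph <- cached_phantom(size = 128, seed = 2)
  hA <- orientation_histogram(gradient_field(ph$fixed, sigma = 2))
  hB <- orientation_histogram(gradient_field(3 * ph$fixed, sigma = 2))
  expect_equal(normalize_histogram(hA)$bins, normalize_histogram(hB)$bins,
               tolerance = 1e-9)
})

test_that("an all-zero histogram is flagged degenerate, not rescaled", {
  h <- rotalign:::new_orientation_histogram(numeric(8))
  expect_warning(n <- normalize_histogram(h), "degenerate")
  expect_true(n$degenerate)
  expect_equal(n$bins, numeric(8))
})

test_that("circular smoothing matches brute-force wrap-around convolution", {
  set.seed(7)
  bins <- runif(36)
  h <- rotalign:::new_orientation_histogram(bins)
  sd_bins <- 1.5
  r <- ceiling(4 * sd_bins)
  k <- exp(-((-r):r)^2 / (2 * sd_bins^2))
  k <- k / sum(k)
  ref <- vapply(0:35, function(i) {
    sum(vapply(seq_along(k), function(a) {
      k[a] * bins[((i - (a - r - 1)) %% 36) + 1]
    }, numeric(1)))
  }, numeric(1))
  got <- smooth_circular(h, sd_bins)$bins
  expect_equal(got, ref, tolerance = 1e-12)
  expect_equal(sum(got), sum(bins), tolerance = 1e-9)
})

test_that("delta histogram smooths to a symmetric wrap-around bell", {
  h <- rotalign:::new_orientation_histogram(c(1, rep(0, 15)))
  s <- smooth_circular(h, 1)$bins
  expect_equal(s[2], s[16])  # symmetric around bin 0, wrapping
  expect_equal(s[3], s[15])
  expect_equal(sum(s), 1, tolerance = 1e-9)
  expect_identical(smooth_circular(h, 0)$bins, h$bins)
})

test_that("parameter validation", {
  ph <- cached_phantom(size = 128, seed = 1)
  f <- gradient_field(ph$fixed, sigma = 2)
  expect_error(orientation_histogram(f, K = 3), "K")
  h <- orientation_histogram(f)
  expect_error(smooth_circular(h, -1), ">= 0")
})
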