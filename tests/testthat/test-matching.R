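hist_of <- function(bins) rotalign:::new_orientation_histogram(bins)

test_that("identical histograms match at shift zero with zero cost", {
  set.seed(1)
  h <- hist_of(runif(360))
  cc <- cyclic_cost(h, h, metric = "l1")
  expect_equal(cc[1], 0)
  expect_equal(which.min(cc), 1L)
})

test_that("an exact cyclic shift is recovered with zero cost", {
  set.seed(2)
  b <- runif(360)
  hA <- hist_of(b)
  hB <- hist_of(b[((0:359 - 11) %% 360) + 1]) # hB(i) = hA(i - 11)
  for (metric in c("l1", "l2")) {
    cc <- cyclic_cost(hA, hB, metric = metric)
    J <- which.min(cc) - 1L
    expect_equal(cc[J + 1], 0, tolerance = 1e-12)
    # shifting hB by J must re-align it with hA: hA(i) = hB(i + J)
    expect_equal(J, 11L)
  }
})

test_that("cost curves equal the brute-force double loop for both metrics", {
  set.seed(3)
  A <- runif(16)
  B <- runif(16)
  hA <- hist_of(A)
  hB <- hist_of(B)
  ref <- function(p) vapply(0:15, function(j)
    sum(abs(A - B[((0:15 + j) %% 16) + 1])^p), numeric(1))
  expect_lt(max(abs(cyclic_cost(hA, hB, "l1") - ref(1))), 1e-12)
  expect_lt(max(abs(cyclic_cost(hA, hB, "l2") - ref(2))), 1e-12)
})

test_that("FFT-accelerated L2 equals direct L2 on random histograms", {
  set.seed(4)
  for (i in 1:200) {
    K <- sample(c(16, 90, 360), 1)
    hA <- hist_of(runif(K))
    hB <- hist_of(runif(K))
    direct <- cyclic_cost(hA, hB, "l2", method = "direct")
    fftc <- cyclic_cost(hA, hB, "l2", method = "fft")
    expect_lt(max(abs(direct - fftc)) / max(direct), 1e-9)
  }
})

test_that("cyclic_cost validates bin-count agreement", {
  expect_error(cyclic_cost(hist_of(runif(8)), hist_of(runif(16))), "bins")
})

test_that("sub-bin refinement returns the parabola vertex with fallbacks", {
  # costs (4, 1, 2) around J: vertex offset (4 - 2) / (2 * (4 - 2 + 2)) = 0.25
  cc <- c(9, 4, 1, 2, 9, 9)
  expect_equal(refine_subbin(cc, 2), 2.25)
  # symmetric neighbours: vertex at J
  expect_equal(refine_subbin(c(9, 3, 1, 3, 9), 2), 2)
  # flat (collinear) costs: fallback to J
  expect_equal(refine_subbin(rep(1, 8), 3), 3)
})

test_that("self-estimation returns zero rotation", {
  ph <- cached_phantom(size = 128, seed = 4)
  est <- estimate_rotation(ph$fixed, ph$fixed, sigma = 2)
  expect_equal(est$angle_deg, 0)
  expect_equal(est$J, 0L)
  expect_s3_class(est, "rotation_estimate")
})

test_that("rotation estimates are equivariant over a ladder of angles", {
  ph <- cached_phantom(size = 256, seed = 3)
  # ladder spans the validated envelope (small through 90 degrees); past
  # ~90 the cost curve can develop near-tied minima for some scenes, a
  # documented limitation of the method
  for (a in c(4, 8, 40, 70, 90)) {
    est <- estimate_rotation(ph$fixed, rotate_image(ph$fixed, a), sigma = 5)
    expect_lte(abs(est$angle_deg - a), 1)
  }
  est <- estimate_rotation(ph$fixed, rotate_image(ph$fixed, -25), sigma = 5)
  expect_lte(abs(est$angle_deg + 25), 1)
})

test_that("degenerate (flat) images raise an estimation error", {
  flat <- matrix(0.5, 64, 64)
  expect_error(estimate_rotation(flat, flat), "degenerate")
})

test_that("straight-only scenes are flagged 180-degree ambiguous", {
  # a single soft bar: gradients occur in opposed pairs, so the histogram
  # is near-symmetric and both J and J + 180 are candidate rotations
  n <- 128
  xs <- rep(seq_len(n), each = n) - (n + 1) / 2
  ys <- rep(seq_len(n), times = n) - (n + 1) / 2
  ang <- 25 * pi / 180
  u <- cos(ang) * xs + sin(ang) * ys
  v <- -sin(ang) * xs + cos(ang) * ys
  img <- matrix(exp(-(u / 40)^8) * exp(-(v / 4)^2), n, n)
  est <- estimate_rotation(img, rotate_image(img, 10), sigma = 2)
  expect_true(est$ambiguous_180)
  expect_equal(ang_diff(est$runner_up$angle_deg, est$angle_deg + 180), 0)
})

test_that("phase correlation recovers exact translations", {
  ph <- cached_phantom(size = 128, seed = 6)
  img <- ph$fixed
  expect_equal(estimate_translation(img, img), c(dy = 0, dx = 0))
  shifted <- translate_image(img, dy = 5, dx = -3)
  expect_equal(estimate_translation(img, shifted), c(dy = 5, dx = -3))
  set.seed(11)
  noisy <- shifted + matrix(rnorm(128^2, 0, sd(img) / sqrt(10)), 128, 128)
  expect_equal(estimate_translation(img, noisy), c(dy = 5, dx = -3))
  expect_error(estimate_translation(img * 0, img), "all-zero")
})

test_that("tidy and glance expose the estimate as tibbles", {
  ph <- cached_phantom(size = 128, seed = 4)
  est <- estimate_rotation(ph$fixed, rotate_image(ph$fixed, 30), sigma = 5)
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), est$K)
  expect_equal(td$cost[est$J + 1], min(td$cost))
  gl <- glance(est)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$angle_deg, est$angle_deg)
  p <- ggplot2::autoplot(est)
  expect_s3_class(p, "ggplot")
})
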