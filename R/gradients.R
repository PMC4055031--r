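# Gradient fields: Gaussian-derivative (default) or Sobel filtering,
# magnitude/orientation, and Canny-style non-maximal suppression.
#
# Orientation is theta = atan2(dy, dx) in degrees wrapped to [0, 360),
# measured in the display frame (x = columns rightward, y = rows
# downward). The two-argument arctangent order is fixed package-wide; any
# consistent choice permutes the orientation histograms of both images
# identically and cancels in cyclic matching.

# reflect an out-of-range 1-based index into 1..n (mirror about the edge
# pixel, no duplication); handles arbitrarily large overshoot
reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  i <- (i - 1L) %% p
  ifelse(i >= n, p - i, i) + 1L
}

# 1D convolution along rows (vertical) with reflect padding;
# out(i) = sum_k w[k] f(i - k), k = -r..r
conv1d_rows <- function(img, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  h <- nrow(img)
  pad <- img[reflect_idx((1L - r):(h + r), h), , drop = FALSE]
  out <- matrix(0, h, ncol(img))
  for (k in -r:r)
    out <- out + kernel[k + r + 1L] * pad[(1L:h) - k + r, , drop = FALSE]
  out
}

conv1d_cols <- function(img, kernel) t(conv1d_rows(t(img), kernel))

# sampled Gaussian and Gaussian-derivative kernels, truncated at 4 sigma.
# The smoothing kernel is normalized to unit sum; the derivative kernel is
# scaled so the response to a unit-slope ramp is exactly 1.
gaussian_kernels <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  dg <- -(x / sigma^2) * exp(-x^2 / (2 * sigma^2))
  dg <- dg / sum(-x * dg)
  list(g = g, dg = dg)
}

#' Gaussian-derivative gradient filtering
#'
#' Computes the partial derivatives of an image by separable convolution
#' with a sampled 1D Gaussian along one axis and its derivative along the
#' other (kernels truncated at 4 sigma; reflect padding). `gx` is the
#' derivative along columns (x, rightward), `gy` along rows (y, downward).
#'
#' A relatively large sigma (e.g. 5.0) is recommended when one of the
#' images was produced by interpolation (e.g. synthetic bicubic rotation),
#' to suppress resampling artifacts in the orientation statistics.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels, > 0. Default 2.
#' @return list with `gx`, `gy`, `sigma`.
#' @export
gaussian_derivative_filter <- function(img, sigma = 2) {
  img <- as_image(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single positive number")
  k <- gaussian_kernels(sigma)
  gx <- conv1d_cols(conv1d_rows(img, k$g), k$dg)
  gy <- conv1d_rows(conv1d_cols(img, k$g), k$dg)
  list(gx = gx, gy = gy, sigma = sigma)
}

# Sobel 3x3 finite-difference path (comparison only; produces axis-aligned
# histogram peaks at 0/90/180/270 degrees on natural images). Scaled so a
# unit-slope ramp gives gradient 1.
sobel_filter <- function(img) {
  img <- as_image(img)
  gx <- conv1d_cols(conv1d_rows(img, c(1, 2, 1) / 4), c(1, 0, -1) / 2)
  gy <- conv1d_rows(conv1d_cols(img, c(1, 2, 1) / 4), c(1, 0, -1) / 2)
  list(gx = gx, gy = gy, sigma = NA_real_)
}

#' Gradient magnitude and orientation
#'
#' Magnitude is `sqrt(gx^2 + gy^2)`; orientation is the two-argument
#' arctangent `atan2(gy, gx)` in degrees wrapped to `[0, 360)`, defined as
#' 0 where the magnitude is 0.
#'
#' @param gx,gy partial-derivative matrices of identical shape.
#' @return list with `magnitude` and `orientation_deg`.
#' @export
gradient_orientation <- function(gx, gy) {
  if (!all(dim(gx) == dim(gy))) stop("`gx` and `gy` must have the same shape")
  m <- sqrt(gx^2 + gy^2)
  th <- wrap360(atan2(gy, gx) * 180 / pi)
  th[m == 0] <- 0
  list(magnitude = m, orientation_deg = th)
}

#' Compute the full gradient field of an image
#'
#' Convenience wrapper: derivative filtering ([gaussian_derivative_filter()]
#' or Sobel), magnitude/orientation, and optional non-maximal suppression.
#'
#' @inheritParams gaussian_derivative_filter
#' @param derivative `"gaussian"` (default) or `"sobel"`.
#' @param nms apply non-maximal suppression (default TRUE). When FALSE the
#'   keep mask marks pixels whose magnitude exceeds a numerical-noise floor
#'   (a small multiple of machine epsilon times the image scale, so constant
#'   images have an empty mask despite floating-point residue).
#' @return object of class `"gradient_field"`: list with `gx`, `gy`,
#'   `magnitude`, `orientation_deg`, `keep_mask`, `sigma`.
#' @export
gradient_field <- function(img, sigma = 2, derivative = c("gaussian", "sobel"),
                           nms = TRUE) {
  derivative <- match.arg(derivative)
  d <- if (derivative == "gaussian") gaussian_derivative_filter(img, sigma)
       else sobel_filter(img)
  mo <- gradient_orientation(d$gx, d$gy)
  # filtering a constant region leaves O(eps) floating-point residue in the
  # derivatives; anything below this image-scaled floor is treated as zero
  mag_tol <- 64 * .Machine$double.eps * max(abs(img), 0)
  field <- structure(
    list(gx = d$gx, gy = d$gy, magnitude = mo$magnitude,
         orientation_deg = mo$orientation_deg,
         keep_mask = mo$magnitude > mag_tol, mag_tol = mag_tol,
         sigma = d$sigma),
    class = "gradient_field")
  if (nms) field <- nonmax_suppress(field)
  field
}

#' Non-maximal suppression of a gradient field
#'
#' Canny-style edge thinning: each pixel's orientation is quantized to one
#' of four directions (0, 45, 90, 135 degrees mod 180) and the pixel is
#' kept iff its magnitude is >= both neighbours along that direction.
#' The 1-pixel border frame is always suppressed. Suppressed pixels
#' contribute zero weight to orientation histograms downstream.
#'
#' @param field a `"gradient_field"`.
#' @return the field with `keep_mask` replaced by the suppression result.
#' @export
nonmax_suppress <- function(field) {
  if (!inherits(field, "gradient_field")) stop("`field` must be a gradient_field")
  m <- field$magnitude
  th <- field$orientation_deg
  h <- nrow(m)
  w <- ncol(m)
  q <- floor(((th + 22.5) %% 180) / 45) # 0:0deg 1:45 2:90 3:135
  shift2 <- function(mat, dr, dc) {
    out <- matrix(-Inf, h, w)
    rs <- seq_len(h) - dr
    cs <- seq_len(w) - dc
    okr <- rs >= 1L & rs <= h
    okc <- cs >= 1L & cs <= w
    out[okr, okc] <- mat[rs[okr], cs[okc]]
    out
  }
  # neighbour offsets along the gradient direction, (dr, dc) in the
  # y-down frame: 0deg -> left/right; 45deg -> down-right/up-left;
  # 90deg -> down/up; 135deg -> down-left/up-right
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, h, w)
  for (d in 0:3) {
    o <- offs[[d + 1L]]
    sel <- q == d
    ok <- m >= shift2(m, o[1], o[2]) & m >= shift2(m, -o[1], -o[2])
    keep[sel & ok] <- TRUE
  }
  tol <- if (is.null(field$mag_tol)) 0 else field$mag_tol
  keep[m <= tol] <- FALSE
  keep[c(1L, h), ] <- FALSE
  keep[, c(1L, w)] <- FALSE
  field$keep_mask <- keep
  field
}
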