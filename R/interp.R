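# Bicubic resampling and geometric transforms.
#
# All transforms use backward mapping: for each output pixel the source
# location is computed and sampled with Keys' cubic convolution (a = -0.5).
# Coordinates are 1-based (row, col); the image center is at
# ((H + 1) / 2, (W + 1) / 2), i.e. (H - 1) / 2 in 0-based pixels.
#
# Angle convention (fixed package-wide): a positive angle rotates image
# content counterclockwise in the display frame (row index increasing
# downwards, column index increasing rightwards). All estimators report
# angles in this same convention.

# Keys cubic convolution weights for fractional offset t in [0, 1):
# returns a length(t) x 4 matrix of weights for samples at offsets
# -1, 0, +1, +2 relative to floor(x).
cubic_weights <- function(t, a = -0.5) {
  w <- matrix(0, length(t), 4L)
  s <- 1 + t # distance to sample at -1, in [1, 2)
  w[, 1L] <- a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a
  s <- t # distance to sample at 0, in [0, 1)
  w[, 2L] <- (a + 2) * s^3 - (a + 3) * s^2 + 1
  s <- 1 - t # sample at +1
  w[, 3L] <- (a + 2) * s^3 - (a + 3) * s^2 + 1
  s <- 2 - t # sample at +2, in (1, 2]
  w[, 4L] <- a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a
  w
}

# Sample img at fractional (row, col) locations with bicubic interpolation.
# Points whose center falls outside [1, H] x [1, W] get `fill`; in-bounds
# points use edge-clamped neighbours. Returns list(values, valid).
interp_bicubic <- function(img, row, col, fill = 0) {
  h <- nrow(img)
  w <- ncol(img)
  valid <- row >= 1 & row <= h & col >= 1 & col <= w
  r0 <- floor(row)
  c0 <- floor(col)
  wr <- cubic_weights(row - r0)
  wc <- cubic_weights(col - c0)
  vals <- numeric(length(row))
  for (m in -1:2) {
    rr <- pmin.int(pmax.int(r0 + m, 1L), h)
    wm <- wr[, m + 2L]
    for (n in -1:2) {
      cc <- pmin.int(pmax.int(c0 + n, 1L), w)
      vals <- vals + wm * wc[, n + 2L] * img[cbind(rr, cc)]
    }
  }
  vals[!valid] <- fill
  list(values = vals, valid = valid)
}

#' Rotate an image about its center with bicubic interpolation
#'
#' Rotates image content by `angle_deg` about the image center using Keys'
#' bicubic convolution kernel. Positive angles rotate content
#' counterclockwise in the display frame (rows down, columns right); this
#' convention is shared by every estimator in the package. Regions rotated
#' in from outside the original support are filled with the background
#' value 0.
#'
#' @param img numeric matrix (rows x cols) of intensities.
#' @param angle_deg rotation in signed degrees, `|angle_deg| < 360`.
#' @param method interpolation method; only `"bicubic"` is provided.
#' @return a numeric matrix of the same dimensions as `img`.
#' @examples
#' ph <- make_phantom(phantom_spec(size = 64, seed = 1))
#' rot <- rotate_image(ph$fixed, 17)
#' @export
rotate_image <- function(img, angle_deg, method = "bicubic") {
  img <- as_image(img)
  if (!is.numeric(angle_deg) || length(angle_deg) != 1L || !is.finite(angle_deg))
    stop("`angle_deg` must be a single finite number")
  if (abs(angle_deg) >= 360) stop("`angle_deg` must satisfy |angle| < 360")
  method <- match.arg(method, "bicubic")
  if (angle_deg == 0) return(img)
  h <- nrow(img)
  w <- ncol(img)
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  a <- angle_deg * pi / 180
  yo <- rep(seq_len(h), times = w) - cy
  xo <- rep(seq_len(w), each = h) - cx
  # inverse of the visual-CCW rotation in (x right, y down) coordinates
  xs <- cos(a) * xo - sin(a) * yo + cx
  ys <- sin(a) * xo + cos(a) * yo + cy
  out <- interp_bicubic(img, ys, xs)$values
  matrix(out, h, w)
}

#' Translate image content with background fill
#'
#' Shifts content by an integer number of pixels; pixels shifted in from
#' outside are set to 0. Used to synthesize partial occlusion.
#'
#' @param img numeric matrix.
#' @param dy,dx integer shifts along rows (down positive) and columns
#'   (right positive).
#' @return shifted matrix, same size.
#' @export
translate_image <- function(img, dy = 0, dx = 0) {
  img <- as_image(img)
  dy <- as.integer(round(dy))
  dx <- as.integer(round(dx))
  h <- nrow(img)
  w <- ncol(img)
  out <- matrix(0, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1L & src_r <= h
  ok_c <- src_c >= 1L & src_c <= w
  if (any(ok_r) && any(ok_c))
    out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

# Backward-map warp by an arbitrary displacement field: output pixel (r, c)
# samples the input at (r + dy[r,c], c + dx[r,c]). Used by the phantom
# generator's smooth nonrigid deformation.
warp_displacement <- function(img, dy, dx) {
  h <- nrow(img)
  w <- ncol(img)
  stopifnot(all(dim(dy) == dim(img)), all(dim(dx) == dim(img)))
  rows <- rep(seq_len(h), times = w) + as.vector(dy)
  cols <- rep(seq_len(w), each = h) + as.vector(dx)
  matrix(interp_bicubic(img, rows, cols)$values, h, w)
}
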