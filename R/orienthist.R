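# Gradient-magnitude-weighted orientation histograms.
#
# Each pixel inside the largest inscribed circle (and surviving NMS)
# contributes its gradient magnitude to the bin containing its
# orientation. The inscribed-circle accumulation region makes the two
# images contribute comparable content to their histograms regardless of
# rotation; normalization removes slight scale differences and partial
# occlusion; circular Gaussian smoothing suppresses bin-level noise before
# matching.

new_orientation_histogram <- function(bins, normalized = FALSE,
                                      smoothing_sd = 0, degenerate = FALSE) {
  structure(list(bins = as.numeric(bins), K = length(bins),
                 normalized = normalized, smoothing_sd = smoothing_sd,
                 degenerate = degenerate),
            class = "orientation_histogram")
}

#' Accumulate a magnitude-weighted orientation histogram
#'
#' Bins the gradient orientations of all pixels that (a) lie inside the
#' largest inscribed circle centered at the image center (radius
#' `min(H, W) / 2`, pixel included iff its center is strictly inside) and
#' (b) survived non-maximal suppression (disable with `use_nms = FALSE`).
#' Each contributing pixel adds its gradient magnitude to the bin
#' containing its orientation (hard assignment, bin width 360 / K degrees).
#'
#' @param field a `"gradient_field"`.
#' @param K number of bins, >= 4. Default 360 (1 degree resolution, which
#'   balances accuracy against robustness).
#' @param use_nms honour the field's suppression mask (default TRUE).
#' @return an unnormalized `"orientation_histogram"`.
#' @export
orientation_histogram <- function(field, K = 360, use_nms = TRUE) {
  if (!inherits(field, "gradient_field")) stop("`field` must be a gradient_field")
  K <- as.integer(K)
  if (is.na(K) || K < 4L) stop("`K` must be an integer >= 4")
  m <- field$magnitude
  h <- nrow(m)
  w <- ncol(m)
  cy <- (h - 1) / 2
  cx <- (w - 1) / 2
  rad <- min(h, w) / 2
  yy <- rep(seq_len(h) - 1, times = w) - cy
  xx <- rep(seq_len(w) - 1, each = h) - cx
  inside <- (xx^2 + yy^2) < rad^2
  tol <- if (is.null(field$mag_tol)) 0 else field$mag_tol
  sel <- inside & as.vector(if (use_nms) field$keep_mask else m > tol)
  delta <- 360 / K
  bins <- numeric(K)
  if (any(sel)) {
    b <- floor(as.vector(field$orientation_deg)[sel] / delta) %% K
    agg <- rowsum(as.vector(m)[sel], b)
    bins[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  }
  new_orientation_histogram(bins)
}

#' Normalize an orientation histogram to unit mass
#'
#' Divides the bins by their sum so histograms from images with slight
#' scale differences or partial occlusion become comparable. An all-zero
#' histogram is returned unchanged with its `degenerate` flag set (with a
#' warning).
#'
#' @param h an `"orientation_histogram"`.
#' @return the normalized histogram.
#' @export
normalize_histogram <- function(h) {
  stopifnot(inherits(h, "orientation_histogram"))
  s <- sum(h$bins)
  if (s <= 0) {
    warning("histogram has zero total mass; returning degenerate histogram")
    h$degenerate <- TRUE
    return(h)
  }
  h$bins <- h$bins / s
  h$normalized <- TRUE
  h
}

#' Circular Gaussian smoothing of a histogram
#'
#' Wrap-around convolution with a unit-sum 1D Gaussian kernel of standard
#' deviation `sd_bins` bins (truncated at 4 sd). Total mass is conserved;
#' `sd_bins = 0` is the identity.
#'
#' @param h an `"orientation_histogram"`.
#' @param sd_bins smoothing standard deviation in bins, >= 0. Default 1.
#' @return the smoothed histogram.
#' @export
smooth_circular <- function(h, sd_bins = 1) {
  stopifnot(inherits(h, "orientation_histogram"))
  if (!is.numeric(sd_bins) || length(sd_bins) != 1L || !is.finite(sd_bins) ||
      sd_bins < 0)
    stop("`sd_bins` must be a single number >= 0")
  if (sd_bins == 0) return(h)
  r <- max(1L, ceiling(4 * sd_bins))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sd_bins^2))
  g <- g / sum(g)
  K <- h$K
  out <- numeric(K)
  for (k in x)
    out <- out + g[k + r + 1L] * h$bins[((seq_len(K) - 1L - k) %% K) + 1L]
  h$bins <- out
  h$smoothing_sd <- sd_bins
  h
}
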