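# Synthetic phantom pairs with known ground truth.
#
# A phantom is a mixture of curved structures (elliptical blobs and annuli
# with smooth intensity ramps) and straight structures (soft-edged bars at
# irregular, non-axis-aligned angles) on a dark background. Curved content
# keeps the orientation histogram asymmetric, so rotation estimates are not
# 180-degree ambiguous; bars exercise the opposed-gradient geometry that
# makes straight-only scenes ambiguous. The "moving" image emulates a
# second acquisition of the same scene: spatial scale change, smooth
# nonrigid deformation, an intensity remap standing in for a modality
# change, a content translation producing partial occlusion, and additive
# noise — applied in that order. Rotation is deliberately NOT applied here;
# compose with rotate_image() so the ground-truth angle is explicit.

#' Specify a synthetic phantom pair
#'
#' @param size image side in pixels (square), at least 64.
#' @param seed integer RNG seed; identical specs give bit-identical pairs.
#' @param n_blobs number of curved structures (ellipses / annuli).
#' @param n_bars number of straight bar structures at irregular angles.
#' @param noise_sd additive Gaussian noise standard deviation, in intensity
#'   units (images are on a 0..1 scale).
#' @param contrast_mode intensity remap applied to the moving image:
#'   `"identity"` (none), `"monotone"` (smooth increasing gamma-like remap,
#'   preserving gradient directions), `"inverting"` (smooth non-monotone
#'   band-inverting remap, emulating T1/T2-like contrast reversal), or
#'   `"piecewise"` (continuous piecewise-linear non-monotone remap).
#' @param deform_amp peak displacement of the smooth nonrigid field, pixels.
#' @param occlusion_shift translation (pixels, along columns) applied to the
#'   moving image content; shifted-out content is lost (partial occlusion).
#' @param scale_factor global spatial scale of the moving image.
#' @return an object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(size = 256, seed = 1, n_blobs = 6, n_bars = 4,
                         noise_sd = 0, contrast_mode = "identity",
                         deform_amp = 0, occlusion_shift = 0,
                         scale_factor = 1) {
  contrast_mode <- match.arg(contrast_mode,
                             c("identity", "monotone", "inverting", "piecewise"))
  size <- as.integer(size)
  if (is.na(size) || size < 64L) stop("`size` must be an integer >= 64")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.finite(deform_amp) || deform_amp < 0) stop("`deform_amp` must be >= 0")
  if (!is.finite(scale_factor) || scale_factor <= 0)
    stop("`scale_factor` must be > 0")
  if (!is.finite(occlusion_shift)) stop("`occlusion_shift` must be finite")
  structure(
    list(size = size, seed = as.integer(seed), n_blobs = as.integer(n_blobs),
         n_bars = as.integer(n_bars), noise_sd = noise_sd,
         contrast_mode = contrast_mode, deform_amp = deform_amp,
         occlusion_shift = occlusion_shift, scale_factor = scale_factor),
    class = "phantom_spec")
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# intensity remaps for the simulated second modality; all smooth (or
# continuous) and deterministic, mapping [0,1] into [0,1]
contrast_remap <- function(img, mode) {
  switch(mode,
    identity = img,
    monotone = { x <- pmin(pmax(img, 0), 1); 1.5 * x - 0.5 * x^2 },
    inverting = 0.9 * sin(pi * pmin(pmax(img, 0), 1)^1.35),
    piecewise = {
      xb <- c(0, 0.3, 0.6, 1)
      yb <- c(0.05, 0.9, 0.2, 0.7)
      matrix(stats::approx(xb, yb, xout = pmin(pmax(img, 0), 1))$y,
             nrow(img), ncol(img))
    })
}

# draw the fixed scene: a large elliptical outline (the "anatomy boundary",
# which spreads gradient mass smoothly over all orientations, as a skull or
# organ wall does in clinical images) plus blobs and bars, scaled to [0, 1]
draw_scene <- function(size, n_blobs, n_bars) {
  xs <- rep(seq_len(size), each = size) - (size + 1) / 2
  ys <- rep(seq_len(size), times = size) - (size + 1) / 2
  img <- numeric(size * size)
  # outer boundary: soft elliptical ring with mild random elongation/tilt
  th0 <- stats::runif(1, 0, pi)
  ax0 <- stats::runif(1, 0.36, 0.42) * size
  ay0 <- stats::runif(1, 0.30, 0.36) * size
  u0 <- (cos(th0) * xs + sin(th0) * ys) / ax0
  v0 <- (-sin(th0) * xs + cos(th0) * ys) / ay0
  # egg-shaped: low-order angular modulation of the radius breaks the
  # mirror/180-degree symmetry of a pure ellipse, giving the orientation
  # histogram a stable asymmetric signature (as a real head outline does)
  phi <- atan2(ys, xs)
  phi0 <- stats::runif(1, 0, 2 * pi)
  q0 <- sqrt(u0^2 + v0^2) /
    (1 + 0.10 * cos(phi - phi0) + 0.05 * cos(2 * phi - 2.4 * phi0))
  img <- img + 0.6 * exp(-((q0 - 1) / 0.08)^2) + 0.45 * exp(-(q0 / 0.9)^4) +
    0.35 * exp(-((q0 - 0.55) / 0.06)^2)
  for (i in seq_len(n_blobs)) {
    cx <- stats::runif(1, -0.28, 0.28) * size
    cy <- stats::runif(1, -0.28, 0.28) * size
    ax <- stats::runif(1, 0.06, 0.16) * size
    ay <- stats::runif(1, 0.06, 0.16) * size
    th <- stats::runif(1, 0, pi)
    amp <- stats::runif(1, 0.5, 0.7)
    u <- (cos(th) * (xs - cx) + sin(th) * (ys - cy)) / ax
    v <- (-sin(th) * (xs - cx) + cos(th) * (ys - cy)) / ay
    q2 <- u^2 + v^2
    if (i %% 2L == 0L) {
      img <- img + amp * exp(-((sqrt(q2) - 1) / 0.3)^2) # annulus
    } else {
      img <- img + amp * exp(-q2)                       # filled blob
    }
  }
  base_angles <- c(13, 47, 112, 158, 75, 29, 96, 140, 61, 124)
  for (i in seq_len(n_bars)) {
    ang <- (base_angles[(i - 1L) %% length(base_angles) + 1L] +
              stats::runif(1, -5, 5)) * pi / 180
    cx <- stats::runif(1, -0.2, 0.2) * size
    cy <- stats::runif(1, -0.2, 0.2) * size
    len <- stats::runif(1, 0.25, 0.4) * size
    wid <- stats::runif(1, 0.015, 0.03) * size
    amp <- stats::runif(1, 0.5, 0.7)
    u <- cos(ang) * (xs - cx) + sin(ang) * (ys - cy)
    v <- -sin(ang) * (xs - cx) + cos(ang) * (ys - cy)
    img <- img + amp * exp(-(u / len)^8) * exp(-(v / wid)^2)
  }
  # fine-scale tissue texture inside the boundary: band-limited Gaussian
  # field, so the orientation histogram is densely populated (as in real
  # tissue) rather than carried by a handful of structure spikes
  mask <- exp(-(q0 / 0.95)^6)
  k <- gaussian_kernels(2.5)$g
  tex <- conv1d_cols(conv1d_rows(matrix(stats::rnorm(size^2), size, size),
                                 k), k)
  img <- img + tex / stats::sd(tex) * 0.25 * mask
  # a fine-scale layer (short correlation length) on top of the coarse one:
  # real tissue has detail at several scales, and intensity-based
  # registration metrics on such images have narrow, rugged basins
  kf <- gaussian_kernels(0.8)$g
  fine <- conv1d_cols(conv1d_rows(matrix(stats::rnorm(size^2), size, size),
                                  kf), kf)
  img <- img + fine / stats::sd(fine) * 0.18 * mask
  normalize01(matrix(pmax(img, 0), size, size))
}

# smooth low-frequency displacement fields with peak amplitude `amp` pixels
deform_fields <- function(size, amp) {
  xs <- rep(seq_len(size), each = size) / size
  ys <- rep(seq_len(size), times = size) / size
  comp <- function() {
    f <- 0
    for (k in 1:3) {
      fx <- stats::runif(1, 0.5, 2)
      fy <- stats::runif(1, 0.5, 2)
      ph <- stats::runif(2, 0, 2 * pi)
      f <- f + sin(2 * pi * fx * xs + ph[1]) * cos(2 * pi * fy * ys + ph[2])
    }
    f
  }
  dx <- comp()
  dy <- comp()
  peak <- max(sqrt(dx^2 + dy^2))
  if (peak > 0) {
    dx <- dx / peak * amp
    dy <- dy / peak * amp
  }
  list(dy = matrix(dy, size, size), dx = matrix(dx, size, size))
}

#' Generate a synthetic phantom pair with known ground truth
#'
#' Draws a fixed scene of curved and straight structures, then derives the
#' moving image by applying, in order: global spatial scale, smooth
#' nonrigid warp, intensity remap, content translation, and additive
#' Gaussian noise — per the supplied [phantom_spec()]. Rotation is not
#' applied here; compose with [rotate_image()] downstream so the true
#' rotation is 0 unless you add it explicitly.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `fixed`, `moving` (numeric matrices) and
#'   `truth` (list with `rotation_deg`, `shift_px`, `scale`).
#' @examples
#' ph <- make_phantom(phantom_spec(size = 128, seed = 7,
#'                                 contrast_mode = "inverting"))
#' mov <- rotate_image(ph$moving, 11.46)
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  with_seed(spec$seed, {
    fixed <- draw_scene(spec$size, spec$n_blobs, spec$n_bars)
    moving <- fixed
    if (spec$scale_factor != 1) {
      p <- affine_params(scale_x = spec$scale_factor,
                         scale_y = spec$scale_factor)
      moving <- warp_affine(moving, p)$pixels
    }
    if (spec$deform_amp > 0) {
      d <- deform_fields(spec$size, spec$deform_amp)
      moving <- warp_displacement(moving, d$dy, d$dx)
    }
    moving <- contrast_remap(moving, spec$contrast_mode)
    if (spec$occlusion_shift != 0)
      moving <- translate_image(moving, dx = spec$occlusion_shift)
    if (spec$noise_sd > 0)
      moving <- moving + matrix(stats::rnorm(spec$size^2, 0, spec$noise_sd),
                                spec$size, spec$size)
    list(fixed = fixed, moving = moving,
         truth = list(rotation_deg = 0, shift_px = spec$occlusion_shift,
                      scale = spec$scale_factor))
  })
}
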