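# Iterative affine registration under SSD, with optional rotation
# prealignment. The point of prealignment: an intensity-driven local
# optimizer started at the identity stalls in a local minimum when the
# true rotation is large; starting it at the histogram-matching rotation
# estimate (plus a phase-correlation translation) puts it inside the
# basin of the global minimum.

#' 2D affine transform parameters
#'
#' Composition order is fixed: scale, then shear, then rotation, then
#' translation, all about the image center. Rotation follows the package
#' angle convention (positive = content counterclockwise on screen).
#'
#' @param rotation_deg signed rotation in degrees.
#' @param scale_x,scale_y unitless scale factors, > 0.
#' @param shear unitless shear coefficient (x' gains `shear * y`).
#' @param tx,ty translation in pixels (columns, rows).
#' @return object of class `"affine_params"`.
#' @export
affine_params <- function(rotation_deg = 0, scale_x = 1, scale_y = 1,
                          shear = 0, tx = 0, ty = 0) {
  vals <- c(rotation_deg, scale_x, scale_y, shear, tx, ty)
  if (!all(is.finite(vals))) stop("affine parameters must all be finite")
  if (scale_x <= 0 || scale_y <= 0) stop("scale factors must be positive")
  structure(list(rotation_deg = rotation_deg, scale_x = scale_x,
                 scale_y = scale_y, shear = shear, tx = tx, ty = ty),
            class = "affine_params")
}

# 2x2 linear part of the transform (rotate %*% shear %*% scale), oriented
# so warp_affine(img, affine_params(rotation_deg = b)) rotates content by
# +b, identically to rotate_image(img, b)
affine_matrix <- function(p) {
  a <- p$rotation_deg * pi / 180
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
  Sh <- matrix(c(1, 0, p$shear, 1), 2, 2)
  S <- diag(c(p$scale_x, p$scale_y))
  R %*% Sh %*% S
}

#' Warp an image by an affine transform (bicubic)
#'
#' Applies the transform about the image center by backward mapping with
#' bicubic interpolation. Output pixels whose source location falls
#' outside the input support are 0 and marked invalid.
#'
#' @param img numeric matrix.
#' @param params an [affine_params()].
#' @return list with `pixels` (matrix) and `valid` (logical matrix).
#' @export
warp_affine <- function(img, params) {
  img <- as_image(img)
  stopifnot(inherits(params, "affine_params"))
  h <- nrow(img)
  w <- ncol(img)
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  M <- affine_matrix(params)
  Minv <- solve(M)
  yo <- rep(seq_len(h), times = w) - cy
  xo <- rep(seq_len(w), each = h) - cx
  xq <- xo - params$tx
  yq <- yo - params$ty
  xs <- Minv[1, 1] * xq + Minv[1, 2] * yq + cx
  ys <- Minv[2, 1] * xq + Minv[2, 2] * yq + cy
  s <- interp_bicubic(img, ys, xs)
  list(pixels = matrix(s$values, h, w), valid = matrix(s$valid, h, w))
}

#' Mean squared intensity difference over the valid overlap
#'
#' The registration similarity metric: mean of squared differences between
#' the fixed image and a warped moving image, over the pixels where the
#' warped image has in-bounds data. Intensities are expected to be
#' pre-normalized to \[0, 1\] so values are comparable across inputs.
#'
#' @param fixed,warped numeric matrices of identical size.
#' @param valid optional logical matrix marking in-bounds warped pixels;
#'   default all pixels.
#' @return a single nonnegative number.
#' @export
ssd <- function(fixed, warped, valid = NULL) {
  fixed <- as_image(fixed)
  warped <- as_image(warped)
  if (!all(dim(fixed) == dim(warped))) stop("images must have the same size")
  if (is.null(valid)) valid <- matrix(TRUE, nrow(fixed), ncol(fixed))
  if (!any(valid)) stop("empty overlap: no valid pixels")
  mean((fixed[valid] - warped[valid])^2)
}

#' Rotation (and translation) prealignment for registration
#'
#' Estimates the rotation by orientation-histogram matching, derotates the
#' moving image, and estimates the residual translation by phase
#' correlation. The result is an [affine_params()] suitable as `init` for
#' [register_affine()].
#'
#' @param fixed,moving numeric matrices.
#' @param sigma Gaussian-derivative sd passed to [estimate_rotation()].
#' @param translation also estimate translation (default TRUE).
#' @param ... further arguments passed to [estimate_rotation()].
#' @return an [affine_params()] with `rotation_deg` (and `tx`, `ty`) set.
#' @export
prealign <- function(fixed, moving, sigma = 5, translation = TRUE, ...) {
  est <- estimate_rotation(fixed, moving, sigma = sigma, ...)
  ang <- est$angle_deg
  # the aligning transform applies the inverse of the moving image's
  # estimated rotation, then cancels the residual translation measured by
  # phase correlation on the derotated image
  p <- affine_params(rotation_deg = -ang)
  if (translation) {
    derot <- rotate_image(moving, -ang)
    tr <- estimate_translation(fixed, derot)
    p <- affine_params(rotation_deg = -ang, tx = -tr[["dx"]], ty = -tr[["dy"]])
  }
  p
}

#' Affine SSD registration with optional initialization
#'
#' Minimizes [ssd()] between the fixed image and the bicubic-warped moving
#' image over the affine parameters, using derivative-free Nelder-Mead
#' local optimization. Both images are min-max normalized to \[0, 1\]
#' first. With `init = NULL` the search starts at the identity; passing
#' the [prealign()] result starts it near the global basin instead.
#'
#' Scale is softly constrained to \[0.5, 2\], shear to \[-0.5, 0.5\] and
#' translation to a quarter of the image size; outside these the objective
#' returns a large penalty (an unconstrained intensity optimizer can
#' otherwise drive the overlap to degenerate configurations).
#'
#' @param fixed,moving numeric matrices of identical size.
#' @param init an [affine_params()] starting point, or NULL for identity.
#' @param include_shear search over shear too (default TRUE).
#' @param max_iter maximum optimizer iterations (default 500).
#' @param tol relative convergence tolerance (default 1e-6).
#' @return object of class `"registration_result"`: `params`,
#'   `ssd_initial` (at the identity, before registration), `ssd_final`,
#'   `iterations`, `converged`, `initialized_rotation`.
#' @export
register_affine <- function(fixed, moving, init = NULL, include_shear = TRUE,
                            max_iter = 500, tol = 1e-6) {
  fixed <- normalize01(as_image(fixed))
  moving <- normalize01(as_image(moving))
  if (!all(dim(fixed) == dim(moving))) stop("images must have the same size")
  if (is.null(init)) init <- affine_params()
  stopifnot(inherits(init, "affine_params"))
  lim_t <- max(dim(fixed)) / 4
  par0 <- c(init$rotation_deg, init$scale_x, init$scale_y, init$shear,
            init$tx, init$ty)
  idx <- if (include_shear) 1:6 else c(1:3, 5:6)
  to_params <- function(par) {
    full <- c(par0[1:4], par0[5:6])
    full[idx] <- par
    affine_params(rotation_deg = full[1], scale_x = full[2],
                  scale_y = full[3], shear = full[4],
                  tx = full[5], ty = full[6])
  }
  objective <- function(par) {
    full <- par0
    full[idx] <- par
    if (abs(full[1]) > 180 || full[2] < 0.5 || full[2] > 2 ||
        full[3] < 0.5 || full[3] > 2 || abs(full[4]) > 0.5 ||
        abs(full[5]) > lim_t || abs(full[6]) > lim_t)
      return(1e6)
    w <- warp_affine(moving, to_params(par))
    if (!any(w$valid)) return(1e6)
    ssd(fixed, w$pixels, w$valid)
  }
  ssd_initial <- ssd(fixed, moving)
  opt <- tryCatch(
    stats::optim(par0[idx], objective, method = "Nelder-Mead",
                 control = list(maxit = max_iter, reltol = tol,
                                parscale = c(10, 0.1, 0.1, 0.1, 5, 5)[idx])),
    error = function(e) NULL)
  if (is.null(opt)) {
    return(structure(
      list(params = init, ssd_initial = ssd_initial,
           ssd_final = ssd_initial, iterations = 0L, converged = FALSE,
           initialized_rotation = init$rotation_deg),
      class = "registration_result"))
  }
  structure(
    list(params = to_params(opt$par), ssd_initial = ssd_initial,
         ssd_final = opt$value, iterations = unname(opt$counts[1]),
         converged = opt$convergence == 0,
         initialized_rotation = init$rotation_deg),
    class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("Affine SSD registration\n")
  cat(sprintf("  SSD: %.4g -> %.4g (%s, %d iterations)\n",
              x$ssd_initial, x$ssd_final,
              if (x$converged) "converged" else "not converged",
              x$iterations))
  p <- x$params
  cat(sprintf("  rotation %.2f deg, scale (%.3f, %.3f), shear %.3f, t (%.1f, %.1f)\n",
              p$rotation_deg, p$scale_x, p$scale_y, p$shear, p$tx, p$ty))
  invisible(x)
}
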