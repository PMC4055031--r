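# Image container: a plain numeric matrix, row 1 at the top, pixel
# spacing assumed isotropic. Validation lives here so every entry point
# shares it.

#' Validate and coerce a 2D image
#'
#' Images in this package are plain numeric matrices (rows x cols) of
#' finite intensities with at least 3 rows and 3 columns (the gradient
#' operators need a neighborhood). Row 1 is the top of the image.
#'
#' @param img a numeric matrix.
#' @return the validated matrix.
#' @export
as_image <- function(img) {
  if (is.data.frame(img)) img <- as.matrix(img)
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix")
  if (nrow(img) < 3L || ncol(img) < 3L)
    stop("image must be at least 3 x 3 pixels")
  if (!all(is.finite(img)))
    stop("image intensities must all be finite")
  storage.mode(img) <- "double"
  img
}

#' Min-max normalize an image to \[0, 1\]
#'
#' Constant images map to all zeros.
#'
#' @param img numeric matrix.
#' @return numeric matrix on the \[0, 1\] scale.
#' @export
normalize01 <- function(img) {
  rng <- range(img)
  if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
}

# wrap angles (degrees) to [-180, 180)
wrap180 <- function(x) ((x + 180) %% 360) - 180

# wrap angles (degrees) to [0, 360)
wrap360 <- function(x) x %% 360
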