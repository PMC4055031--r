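# Tidy accessors and plots for the result objects: the tabular views
# (cost curves, histograms, sweeps) come back as tibbles so they drop
# straight into dplyr/ggplot2 workflows.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.rotation_estimate <- function(x, ...) {
  K <- x$K
  j <- 0:(K - 1)
  tibble::tibble(shift_bins = j,
                 angle_deg = wrap180(-j * 360 / K),
                 cost = x$cost_curve)
}

#' @export
glance.rotation_estimate <- function(x, ...) {
  tibble::tibble(angle_deg = x$angle_deg,
                 refined_angle_deg = x$refined_angle_deg,
                 J = x$J, K = x$K, metric = x$metric,
                 ambiguous_180 = x$ambiguous_180,
                 runner_up_angle_deg = x$runner_up$angle_deg)
}

#' @export
tidy.orientation_histogram <- function(x, ...) {
  delta <- 360 / x$K
  tibble::tibble(bin = 0:(x$K - 1),
                 angle_mid_deg = (0:(x$K - 1) + 0.5) * delta,
                 weight = x$bins)
}

#' @export
tidy.registration_result <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("rotation_deg", "scale_x", "scale_y", "shear", "tx", "ty"),
    estimate = c(p$rotation_deg, p$scale_x, p$scale_y, p$shear, p$tx, p$ty))
}

#' @export
glance.registration_result <- function(x, ...) {
  tibble::tibble(ssd_initial = x$ssd_initial, ssd_final = x$ssd_final,
                 iterations = x$iterations, converged = x$converged,
                 initialized_rotation = x$initialized_rotation)
}

#' @export
autoplot.rotation_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shift_bins, y = .data$cost)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$J, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "cyclic shift j (bins)",
                  y = paste0("T_D (", toupper(object$metric), ")"),
                  title = sprintf("Cyclic histogram matching: J = %d (%g deg)",
                                  object$J, object$angle_deg)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.orientation_histogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle_mid_deg, y = .data$weight)) +
    ggplot2::geom_col(width = 360 / object$K) +
    ggplot2::labs(x = "gradient orientation (deg)",
                  y = if (object$normalized) "relative weight" else "weight") +
    ggplot2::theme_minimal()
}

#' Rotation-recovery sweep over a ladder of true angles
#'
#' Applies each rotation to the phantom's moving image by bicubic
#' interpolation, runs the requested estimator(s), and tabulates estimates
#' and errors. The histogram method reports its signed discrete estimate;
#' the edge-map baseline reports an angle in `[0, 180)`, so its error is
#' computed modulo 180.
#'
#' @param fixed,moving numeric matrices (e.g. from [make_phantom()]).
#' @param angles numeric vector of true rotations in degrees.
#' @param method `"histogram"`, `"edgemap"`, or both.
#' @param sigma Gaussian-derivative sd for the histogram method (default 5,
#'   appropriate for interpolated inputs).
#' @param metric L1/L2 for the histogram method.
#' @param ... further arguments passed to [estimate_rotation()] or
#'   [edgemap_estimate()].
#' @return tibble with columns `method`, `true_angle_deg`,
#'   `estimate_deg`, `error_deg` (mod-180 circular for the edge-map
#'   method), `ambiguous_180`.
#' @export
rotation_sweep <- function(fixed, moving = fixed, angles = c(1:8, 40, 70),
                           method = "histogram", sigma = 5,
                           metric = "l1", ...) {
  method <- match.arg(method, c("histogram", "edgemap"), several.ok = TRUE)
  rows <- list()
  for (a in angles) {
    rot <- rotate_image(moving, a)
    if ("histogram" %in% method) {
      e <- estimate_rotation(fixed, rot, sigma = sigma, metric = metric, ...)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = "histogram", true_angle_deg = a,
        estimate_deg = e$angle_deg,
        error_deg = abs(wrap180(e$angle_deg - a)),
        ambiguous_180 = e$ambiguous_180)
    }
    if ("edgemap" %in% method) {
      e <- edgemap_estimate(fixed, rot, ...)
      d <- abs(e$angle_deg - (a %% 180))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = "edgemap", true_angle_deg = a,
        estimate_deg = e$angle_deg,
        error_deg = min(d, 180 - d),
        ambiguous_180 = NA)
    }
  }
  do.call(rbind, rows)
}

#' @importFrom rlang .data
NULL
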