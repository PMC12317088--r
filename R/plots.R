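# ggplot2 visualisations. Rasters are drawn with the v (row) axis
# reversed so plots match image orientation.

image_df <- function(image, value = "intensity") {
  h <- nrow(image)
  w <- ncol(image)
  tibble::tibble(
    u = rep(0:(w - 1L), each = h),
    v = rep(0:(h - 1L), times = w),
    !!value := as.vector(image)
  )
}

#' Plot a feature-magnitude map
#'
#' @param object A [magnitude_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.magnitude_map <- function(object, ...) {
  df <- image_df(object$values, "magnitude")
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v, fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Feature magnitude map", x = "u", y = "v")
}

#' Plot keypoints over their image
#'
#' @param keypoints A `keypoints` tibble.
#' @param image The image they were detected in.
#' @return A ggplot.
#' @export
plot_keypoints <- function(keypoints, image) {
  df <- image_df(as_image(image))
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(.data$u, .data$v, fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_point(data = keypoints,
                        ggplot2::aes(.data$u, .data$v, size = .data$magnitude),
                        colour = "dodgerblue", shape = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "u", y = "v")
}

#' Side-by-side matched-keypoint plot
#'
#' Draws the fixed and moving images side by side with lines joining
#' matched keypoints.
#'
#' @param reg A `registration` object.
#' @param which `"geometry"` (inliers, default) or `"ratio"`.
#' @param gap Horizontal gap between the two panels, pixels.
#' @return A ggplot.
#' @export
plot_matches <- function(reg, which = c("geometry", "ratio"), gap = 16) {
  which <- match.arg(which)
  m <- if (which == "geometry") reg$matches_geometry else reg$matches_ratio
  off <- ncol(reg$warped) + gap  # moving panel drawn to the right
  seg <- tibble::tibble(
    x = reg$keypoints_fixed$u[m$fixed],
    y = reg$keypoints_fixed$v[m$fixed],
    xend = reg$keypoints_moving$u[m$moving] + off,
    yend = reg$keypoints_moving$v[m$moving]
  )
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "dodgerblue", alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(.data$x, .data$y), colour = "red", size = 0.8) +
    ggplot2::geom_point(ggplot2::aes(.data$xend, .data$yend),
                        colour = "red", size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%d matched pairs (%s)", nrow(seg), which),
                  x = NULL, y = NULL)
}

#' Overlay plot of a registration result
#'
#' Shows the absolute difference between the fixed image and the warped
#' moving image (both min-max normalized); dark = good alignment.
#'
#' @param object A `registration` object.
#' @param fixed The fixed image used in the registration.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.registration <- function(object, fixed = NULL, ...) {
  if (is.null(fixed)) {
    return(plot_matches(object))
  }
  diff_img <- abs(normalize_intensity(fixed) - normalize_intensity(object$warped))
  df <- image_df(diff_img, "difference")
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v, fill = .data$difference)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Registration residual (|fixed - warped|)",
                  x = "u", y = "v")
}

#' @importFrom rlang .data :=
NULL
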