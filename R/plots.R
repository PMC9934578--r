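# ggplot2 visualizations for the main result types.

#' @export
autoplot.bandwidth_scan <- function(object, sigma_star = NULL, ...) {
  sc <- object$scaling
  grid <- seq(min(object$scan$sigma), max(object$scan$sigma), length.out = 400)
  fit <- tibble(
    sigma = grid,
    n_peaks = poly_eval(object$poly, (grid - sc$mid) / sc$half)
  )
  p <- ggplot2::ggplot(object$scan, ggplot2::aes(x = .data$sigma, y = .data$n_peaks)) +
    ggplot2::geom_line(data = fit, color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(sigma ~ "(px)"),
      y = "detected fibrils N",
      title = "Bandwidth scan and 5th-degree count polynomial"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(sigma_star)) {
    p <- p + ggplot2::geom_vline(xintercept = sigma_star,
                                 linetype = "dashed", color = "firebrick")
  }
  p
}

#' @export
autoplot.population_summary <- function(object, ...) {
  dat <- tidy(object)
  if (nrow(dat) == 0L) stop("empty population summary: nothing to plot")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value, y = .data$density)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "density",
                  title = "Fibril population distributions") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fibril_run <- function(object, show_ellipses = TRUE, ...) {
  img <- object$image$intensity
  h <- nrow(img); w <- ncol(img)
  raster <- tibble(
    u = rep(0:(w - 1), each = h),
    v = rep(0:(h - 1), times = w),
    intensity = c(img)
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(
      data = raster,
      ggplot2::aes(x = .data$u, y = .data$v, fill = .data$intensity)
    ) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::geom_point(
      data = tibble(u = object$centroids$u, v = object$centroids$v),
      ggplot2::aes(x = .data$u, y = .data$v),
      color = "red", shape = 3, size = 1.2
    ) +
    ggplot2::theme_void()
  if (show_ellipses) {
    ok <- !object$records$degenerate
    ell <- purrr::map_dfr(which(ok), function(i) {
      rec <- object$records[i, ]
      tt <- seq(0, 2 * pi, length.out = 90)
      a <- rec$r_major_nm / object$image$pixel_size
      b <- rec$r_minor_nm / object$image$pixel_size
      th <- rec$orientation_rad
      tibble(
        id = rec$id,
        u = rec$u + a * cos(tt) * cos(th) - b * sin(tt) * sin(th),
        v = rec$v + a * cos(tt) * sin(th) + b * sin(tt) * cos(th)
      )
    })
    p <- p + ggplot2::geom_path(
      data = ell,
      ggplot2::aes(x = .data$u, y = .data$v, group = .data$id),
      color = "dodgerblue", linewidth = 0.3
    )
  }
  p
}
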