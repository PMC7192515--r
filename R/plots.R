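#' Plot a distance distribution
#'
#' Histogram of per-focus minimal distances to the nearest axis, with
#' reference lines at the chromatin radius (0.35 um) and the 0.6 um
#' envelope and the median marked.
#'
#' @param x a `dist_distribution` from [distance_distribution()].
#' @param chromatin_radius,envelope reference radii in um.
#' @return A ggplot object.
#' @export
plot_distance_distribution <- function(x, chromatin_radius = 0.35,
                                       envelope = 0.6) {
  ggplot2::ggplot(x$bins, ggplot2::aes(x = .data$bin_lo + diff(c(0, 0.1)) / 2,
                                       y = .data$count)) +
    ggplot2::geom_col(width = x$bins$bin_hi[1] - x$bins$bin_lo[1],
                      fill = "grey35") +
    ggplot2::geom_vline(xintercept = envelope, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = chromatin_radius, linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::geom_vline(xintercept = x$median_um, colour = "red") +
    ggplot2::labs(x = "minimal distance to nearest axis (µm)",
                  y = "foci",
                  title = sprintf("n = %d foci, median %.2f µm",
                                  x$n_objects, x$median_um)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dist_distribution <- function(object, ...)
  plot_distance_distribution(object, ...)

#' Plot curvature distributions
#'
#' Box-style summary of pooled per-point kappa values, optionally for
#' several groups.
#'
#' @param ... named `kappa_distribution` objects.
#' @return A ggplot object.
#' @export
plot_curvature_distribution <- function(...) {
  groups <- list(...)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  df <- dplyr::bind_rows(lapply(names(groups), function(g)
    tibble::tibble(group = g, kappa = groups[[g]]$pooled)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$kappa)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = NULL, y = "kappa (µm⁻¹)") +
    ggplot2::theme_minimal()
}

#' Show one z-plane of a volume
#'
#' @param image a [vol_img()], [label_vol()] or `dist_map`.
#' @param z plane index.
#' @return A ggplot object (raster).
#' @export
plot_slice <- function(image, z = NULL) {
  arr <- if (inherits(image, "vol_img")) image$data
         else if (inherits(image, "label_vol")) image$labels
         else if (inherits(image, "dist_map")) image$data
         else image
  if (is.null(z)) z <- ceiling(dim(arr)[1] / 2)
  sl <- arr[z, , ]
  df <- tidyr::expand_grid(y = seq_len(nrow(sl)), x = seq_len(ncol(sl)))
  df$value <- as.numeric(sl[cbind(df$y, df$x)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("z = %d", z)) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
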