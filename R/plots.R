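#' Plot one z slice of a volume or labelled mask
#'
#' @param vol A 3D array.
#' @param z Slice index (default: middle slice).
#' @param labels Render integer values as discrete instance colours.
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, z = NULL, labels = is.integer(vol)) {
  vol <- as_volume(vol)
  z <- z %||% ((dim(vol)[1] + 1L) %/% 2L)
  sl <- vol[z, , ]
  df <- expand.grid(y = seq_len(nrow(sl)), x = seq_len(ncol(sl)),
                    KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("z = %d", z)) +
    ggplot2::theme_minimal()
  if (labels) {
    df$value <- factor(df$value)
    p + ggplot2::geom_raster(data = df[df$value != "0", , drop = FALSE],
                             ggplot2::aes(fill = .data$value),
                             show.legend = FALSE)
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   name = "intensity")
  }
}

#' @export
autoplot.cell_atlas <- function(object, ...) {
  df <- tidy(object)
  df$sigma <- sqrt(df$sx^2 + df$sy^2 + df$sz^2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   size = .data$sigma,
                                   colour = .data$gamma)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_fixed() +
    ggplot2::scale_colour_viridis_c(name = "topological\nvariability") +
    ggplot2::scale_size_continuous(name = "positional\nsigma") +
    ggplot2::labs(x = "x (voxels)", y = "y (voxels)",
                  title = "Statistical atlas: average positions and variability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dvf_net <- function(object, ...) {
  if (is.null(object$history)) abort("the network has no training history")
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.8) +
    ggplot2::labs(x = "optimisation step", y = "total loss",
                  title = "DVF regression training") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.recognition_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$confidence)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "assignment confidence", y = "cells",
                  title = "Recognition confidence") +
    ggplot2::theme_minimal()
}

#' @export
tidy.dvf_net <- function(x, ...) {
  if (is.null(x$history)) abort("the network has no training history")
  x$history
}

#' @export
glance.dvf_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  h <- x$history
  tibble(
    levels = x$cfg$levels,
    n_parameters = np,
    steps = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)]
  )
}
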