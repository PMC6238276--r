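#' Plot a synthetic scene, an image array or a mask
#'
#' Renders the raster with ggplot2; scenes can overlay the ground-truth
#' frame corners and plant centres.
#'
#' @param x A `wheat_scene`, an `H x W x 3` array or a logical matrix.
#' @param truth Overlay ground truth (scenes only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_raster <- function(x, truth = FALSE, ...) {
  scene <- NULL
  if (inherits(x, "wheat_scene")) {
    scene <- x
    x <- x$image
  }
  if (is.logical(x)) {
    df <- tibble::tibble(
      row = as.vector(row(x)), col = as.vector(col(x)),
      fill = ifelse(as.vector(x), "#1a7a1a", "#202020")
    )
  } else {
    df <- tibble::tibble(
      row = as.vector(slice.index(x, 1)[, , 1]),
      col = as.vector(slice.index(x, 2)[, , 1]),
      fill = grDevices::rgb(as.vector(x[, , 1]), as.vector(x[, , 2]),
                            as.vector(x[, , 3]))
    )
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
  if (truth && !is.null(scene)) {
    corners <- tibble::as_tibble(unclass(scene$frame_corners)[c(1:4, 1), ])
    centers <- tibble::as_tibble(scene$centers)
    p <- p +
      ggplot2::geom_path(data = corners, colour = "red", linewidth = 0.4) +
      ggplot2::geom_point(data = centers, colour = "yellow", size = 0.3)
  }
  p
}

#' @rdname plot_raster
#' @export
autoplot.wheat_scene <- function(x, truth = TRUE, ...) {
  plot_raster(x, truth = truth, ...)
}

#' Observed-versus-predicted plot for a fitted counting model
#'
#' @param x A `stage_fit` or `unified_fit`.
#' @param ... Unused.
#' @return A ggplot object: predictions against true counts with the 1:1
#'   line and the fit metrics in the subtitle.
#' @export
autoplot.stage_fit <- function(x, ...) {
  pred <- suppressWarnings(predict_stagewise(x$data, x$model))
  plot_pred_obs(pred, x$data$SN_true, x$metrics)
}

#' @rdname autoplot.stage_fit
#' @export
autoplot.unified_fit <- function(x, ...) {
  pred <- suppressWarnings(predict_unified(x$data, x$model))
  plot_pred_obs(pred, x$data$SN_true, x$metrics)
}

plot_pred_obs <- function(pred, obs, metrics) {
  df <- tibble::tibble(observed = obs, predicted = pred)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "observed seedlings per m²",
      y = "predicted seedlings per m²",
      subtitle = sprintf("R² = %.3f, RMSE = %.1f, REP = %.1f%%",
                         metrics$r2, metrics$rmse, metrics$rep)
    ) +
    ggplot2::theme_minimal()
}
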