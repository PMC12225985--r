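#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plots of predicted versus true lesion metrics
#'
#' Two-panel agreement plot: reconstructed versus true maximum absorption
#' contrast and 50 percent-contour diameter, with the identity line.
#'
#' @param object an `aegan_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot aegan_eval
#' @export
autoplot.aegan_eval <- function(object, ...) {
  pc <- object$per_case
  df <- rbind(
    data.frame(metric = sprintf("max contrast (R^2 = %.3f)",
                                object$r2_max_mua),
               truth = pc$true_max_mua, pred = pc$pred_max_mua),
    data.frame(metric = sprintf("50%%-contour diameter (R^2 = %.3f)",
                                object$r2_diameter),
               truth = pc$true_diameter, pred = pc$pred_diameter))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "ground truth", y = "reconstruction") +
    ggplot2::theme_minimal()
}

#' Depth-slice maps of an absorption volume
#'
#' One raster panel per depth slice, the standard layout for inspecting a
#' reconstruction.
#'
#' @param object a `dot_volume`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dot_volume
#' @export
autoplot.dot_volume <- function(object, ...) {
  ax <- grid_axes(object$grid)
  d <- dim(object$values)
  df <- expand.grid(x = ax$x, y = ax$y, z = ax$z)
  df$value <- as.vector(object$values)
  df$slice <- factor(sprintf("depth %.1f cm", df$z),
                     levels = sprintf("depth %.1f cm", ax$z))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice, nrow = 1) +
    ggplot2::scale_fill_viridis_c(name = "mu_a (1/cm)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Training loss curves
#'
#' @param fit an `aegan_fit` from [train()].
#' @return a ggplot object with the supervised and reconstruction losses
#'   per step.
#' @export
plot_loss_history <- function(fit) {
  h <- fit$history
  df <- rbind(data.frame(step = h$step, loss = h$l_p2p,
                         sequence = "P2P (supervised)"),
              data.frame(step = h$step, loss = h$l_r,
                         sequence = "R2R (reconstruction)"))
  df <- df[is.finite(df$loss), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loss,
                                   colour = .data$sequence)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "training step", y = "loss") +
    ggplot2::theme_minimal()
}
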