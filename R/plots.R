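#' Plot the loss-family comparison curves
#'
#' Draws the Dice, Tversky and sigmoid-adaptive Tversky losses from
#' [loss_curve_table()] against the predicted likelihood of the single
#' foreground voxel. The sigmoid-adaptive curve's steep fall around
#' `p = 0.5` is the visual signature of its voxel-wise gradient adaptation.
#'
#' @param table a data.frame from [loss_curve_table()].
#' @return A ggplot object.
#' @export
plot_loss_curves <- function(table = loss_curve_table()) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_loss_curves requires the ggplot2 package")
  long <- data.frame(
    p = rep(table$p, 3),
    loss = c(table$dice, table$tversky, table$stl),
    family = rep(c("Dice", "Tversky", "Sigmoid-adaptive Tversky"),
                 each = nrow(table))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = p, y = loss, colour = family)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "predicted likelihood of the foreground voxel",
                  y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a training log
#'
#' @param ckpt an `sg_checkpoint` (or its `log` data.frame).
#' @return A ggplot object with the total, segmentation and skeleton loss
#'   per epoch.
#' @export
plot_training_log <- function(ckpt) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_training_log requires the ggplot2 package")
  log <- if (inherits(ckpt, "sg_checkpoint")) ckpt$log else ckpt
  long <- data.frame(
    epoch = rep(log$epoch, 3),
    loss = c(log$loss_total, log$loss_seg, log$loss_skel),
    term = rep(c("total", "segmentation", "skeleton"), each = nrow(log))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = loss, colour = term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean loss", colour = NULL) +
    ggplot2::theme_minimal()
}
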