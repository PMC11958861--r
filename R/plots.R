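#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot training and validation loss curves
#'
#' @param object A `dvr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dvr_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss") |>
    dplyr::filter(!is.na(loss)) |>
    dplyr::mutate(set = dplyr::recode(set, train_loss = "training",
                                      val_loss = "validation"))
  ggplot2::ggplot(h, ggplot2::aes(epoch, loss, colour = set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "mean L2 loss", colour = NULL)
}

#' Plot a joint histogram with its least-squares line
#'
#' @param object A `joint_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.joint_fit <- function(object, ...) {
  h <- dplyr::filter(object$histogram, count > 0)
  ggplot2::ggplot(h, ggplot2::aes(x_mid, y_mid, fill = count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "ground-truth DVR", y = "predicted DVR",
                  subtitle = sprintf("y = %.3f x + %.3f,  rho = %.3f",
                                     object$slope, object$intercept, object$rho))
}

#' Plot per-group metric distributions of an experiment report
#'
#' @param object An `experiment_report`.
#' @param metric Metric column to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.experiment_report <- function(object, metric = "ssim", ...) {
  d <- object$per_participant |>
    dplyr::mutate(stratum = ifelse(low_dose, "low-dose", "normal-dose"))
  ggplot2::ggplot(d, ggplot2::aes(diagnosis, .data[[metric]], fill = stratum)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::labs(x = NULL, y = metric, fill = NULL)
}

#' Plot an axial slice of a volume
#'
#' @param v A volume.
#' @param z Slice index along the third axis (default: middle).
#' @param title Optional title.
#' @return A ggplot.
#' @export
plot_volume_slice <- function(v, z = NULL, title = NULL) {
  d <- dim(v)
  if (is.null(z)) z <- (d[3] + 1) %/% 2
  sl <- vol_values(v)[, , z]
  df <- tidyr::expand_grid(i = seq_len(d[1]), j = seq_len(d[2])) |>
    dplyr::mutate(value = as.vector(sl))
  ggplot2::ggplot(df, ggplot2::aes(i, j, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL)
}
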