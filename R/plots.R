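#' Plot helpers (ggplot2)
#'
#' `plot_field()` shows a simulated field's phase with tumor cells circled;
#' `plot_phase_map()` a reconstructed phase map; `plot_metrics()` the
#' cell-level metrics of a report; `plot_history()` the training curves.
#' All return ggplot objects.
#'
#' @param field a `ground_truth_field`.
#' @name holostain-plots
NULL

raster_df <- function(m) {
  data.frame(
    x = rep(seq_len(ncol(m)), each = nrow(m)),
    y = rep(seq_len(nrow(m)), ncol(m)),
    value = as.vector(m)
  )
}

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
}

#' @rdname holostain-plots
#' @export
plot_field <- function(field) {
  need_ggplot()
  df <- raster_df(field$phase)
  tum <- field$cells[field$cells$kind == "TUMOR", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = tum, ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 1, color = "red", size = 4,
                        inherit.aes = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "phase (rad)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = field$field_id, x = NULL, y = NULL)
}

#' @rdname holostain-plots
#' @param pm a `phase_map` or matrix.
#' @export
plot_phase_map <- function(pm) {
  need_ggplot()
  m <- if (inherits(pm, "phase_map")) pm$phase else pm
  ggplot2::ggplot(raster_df(m), ggplot2::aes(x = .data$x, y = .data$y,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "phase (rad)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @rdname holostain-plots
#' @param report a `metrics_report`.
#' @export
plot_metrics <- function(report) {
  need_ggplot()
  g <- glance_metrics(report)
  df <- data.frame(
    metric = factor(c("precision", "recall", "f1", "accuracy"),
                    levels = c("precision", "recall", "f1", "accuracy")),
    value = c(g$precision, g$recall, g$f1, g$accuracy)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(y = NULL, x = NULL,
                  title = sprintf("split '%s' (%d images), SSIM %.4f",
                                  report$split, report$n_images,
                                  report$ssim_mean))
}

#' @rdname holostain-plots
#' @param history training-history tibble from [train_unet()].
#' @export
plot_history <- function(history) {
  need_ggplot()
  df <- rbind(
    data.frame(epoch = history$epoch, mae = history$train_mae, set = "train"),
    data.frame(epoch = history$epoch, mae = history$val_mae, set = "validation")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mae,
                                   color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "MAE", color = NULL)
}
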