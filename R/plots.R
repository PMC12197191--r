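#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot training curves of a fitted mixer
#'
#' Training and validation loss components per epoch, with the best
#' (restored) epoch marked.
#'
#' @param object A `mixer_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mixer_fit
#' @export
autoplot.mixer_fit <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, value = h$train_loss, series = "train loss"),
    tibble::tibble(epoch = h$epoch, value = h$val_loss, series = "val loss"),
    tibble::tibble(epoch = h$epoch, value = h$val_accuracy, series = "val accuracy")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$series), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Mixer training history",
                  subtitle = paste0("best epoch ", object$best_epoch,
                                    " (dashed)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a channel-mask importance scan
#'
#' Per-mask masked accuracy with the unmasked accuracy, the mean masked
#' accuracy, and the 95% interval bounds; critical masks highlighted.
#'
#' @param object A `mask_scan` (see [channel_mask_scan()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mask_scan
#' @export
autoplot.mask_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mask_id, y = .data$accuracy,
                                   fill = .data$critical)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_hline(yintercept = attr(object, "unmasked_accuracy"),
                        colour = "red", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = attr(object, "mask_mean"),
                        colour = "black", linetype = "dotted") +
    ggplot2::geom_hline(yintercept = attr(object, "ci_lower"),
                        colour = "darkgreen", linetype = "dotdash") +
    ggplot2::geom_hline(yintercept = attr(object, "ci_upper"),
                        colour = "blue", linetype = "dotdash") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mask", y = "masked accuracy",
                  title = "Channel-mask importance scan",
                  subtitle = "dashed: unmasked; dotted: mask mean; dot-dash: 95% bounds") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a discrepancy-weight sweep
#'
#' Mean validation accuracy against the discrepancy weight alpha, from a
#' [grid_search()] summary run over an alpha grid.
#'
#' @param summary Tibble with columns `alpha` and `mean_val_accuracy` (the
#'   `summary` element of [grid_search()]).
#' @return A ggplot object.
#' @export
plot_alpha_sweep <- function(summary) {
  df <- summary |>
    dplyr::group_by(.data$alpha) |>
    dplyr::summarise(mean_val_accuracy = max(.data$mean_val_accuracy),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$mean_val_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(alpha), y = "mean validation accuracy",
                  title = "Discrepancy-weight sweep") +
    ggplot2::theme_minimal()
}

#' Plot the split-scenario benchmark
#'
#' Accuracy and Wasserstein shift diagnostic per split scenario.
#'
#' @param benchmark Result of [run_split_benchmark()].
#' @return A ggplot object.
#' @export
plot_split_benchmark <- function(benchmark) {
  long <- benchmark$results |>
    tidyr_longer()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scenario, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "split scenario", y = NULL,
                  title = "Split-scenario benchmark") +
    ggplot2::theme_minimal()
}

# small local reshape (avoids importing tidyr for one call)
tidyr_longer <- function(results) {
  dplyr::bind_rows(
    tibble::tibble(scenario = results$scenario, metric = "accuracy",
                   value = results$accuracy),
    tibble::tibble(scenario = results$scenario, metric = "wasserstein",
                   value = results$wasserstein)
  )
}
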