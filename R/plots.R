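#' ROC curve plot
#'
#' @param x A [roc_auc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(x, ...) {
  ggplot2::ggplot(x$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", x$auc)
    )
}

#' Training-history plot for a fitted deep classifier
#'
#' @param x A fitted model (`dnn_fit`, `capsnet_fit`, `bilstm_fit`, `gpt_fit`).
#' @param ... Unused.
#' @return A ggplot object of loss (and validation loss, if tracked) by epoch.
#' @method autoplot drugseqr_fit
#' @export
autoplot.drugseqr_fit <- function(x, ...) {
  df <- x$log |>
    dplyr::select(dplyr::any_of(c("epoch", "loss", "val_loss"))) |>
    tidyr::pivot_longer(-"epoch", names_to = "series", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Binary cross-entropy", colour = NULL)
}

#' Bar plot of attribution-group importances
#'
#' @param importance Tibble from [aggregate_group_importance()].
#' @return A ggplot object.
#' @export
plot_group_importance <- function(importance) {
  ggplot2::ggplot(
    importance,
    ggplot2::aes(x = stats::reorder(.data$group, .data$importance), y = .data$importance)
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean |attribution| per feature")
}

#' Heat-map of a predicted contact map
#'
#' @param contacts L x L matrix from [predict_contacts()].
#' @return A ggplot object.
#' @export
plot_contact_map <- function(contacts) {
  df <- tidyr::expand_grid(
    i = seq_len(nrow(contacts)),
    j = seq_len(ncol(contacts))
  )
  df$p <- as.vector(t(contacts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Residue", y = "Residue", fill = "Contact")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
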