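# ggplot2 views of the result types.

#' Plot the training trace of a network
#'
#' @param object A trained `mito_cnn`.
#' @param ... Unused.
#' @return A ggplot: loss (and validation loss, when present) per epoch.
#' @export
autoplot.mito_cnn <- function(object, ...) {
  h <- tidy(object)
  if (nrow(h) == 0) stop("model has no training history", call. = FALSE)
  long <- tidyr::pivot_longer(
    h, dplyr::any_of(c("loss", "val_loss")),
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-class MCC from a cross-validation
#'
#' @param object A `submito_cv`.
#' @param ... Unused.
#' @return A ggplot bar chart of pooled per-class MCC.
#' @export
autoplot.submito_cv <- function(object, ...) {
  ggplot2::ggplot(object$mcc,
                  ggplot2::aes(as_compartment(.data$class), .data$mcc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = NULL, y = "Matthews correlation coefficient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a confusion matrix
#'
#' @param cm 4 x 4 confusion matrix from [confusion()].
#' @return A ggplot tile heat map (true rows x predicted columns).
#' @export
plot_confusion <- function(cm) {
  df <- as_tibble(as.data.frame(as.table(cm)))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(compartment_levels())) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Plot cluster enrichment results
#'
#' @param enrichment Enrichment tibble from [enrich_clusters()].
#' @return A ggplot of -log10 p per term, faceted by cluster, coloured by
#'   Bonferroni significance.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(.data$go_term, -log10(.data$p_value),
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~cluster_id, scales = "free_x") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
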