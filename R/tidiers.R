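# broom-style tidiers for the fitted objects.

#' Tidy a trained network
#'
#' Returns the per-epoch training trace.
#'
#' @param x A `mito_cnn`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `accuracy` (and `val_loss` when a
#'   validation split was used); empty for an untrained model.
#' @export
tidy.mito_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble(epoch = integer(), loss = numeric(), accuracy = numeric()))
  }
  as_tibble(x$history)
}

#' Glance at a network
#'
#' @param x A `mito_cnn`.
#' @param ... Unused.
#' @return One-row tibble summarising architecture and training state.
#' @export
glance.mito_cnn <- function(x, ...) {
  tibble(
    n_filters = x$config$n_filters,
    kernel_width = x$config$kernel_width,
    n_hidden = x$config$n_hidden,
    n_classes = x$config$n_classes,
    n_parameters = n_parameters(x),
    trained = x$trained,
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)]
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `submito_cv`.
#' @param ... Unused.
#' @return Per-class MCC tibble computed from the pooled confusion matrix.
#' @export
tidy.submito_cv <- function(x, ...) x$mcc

#' Glance at a cross-validation result
#'
#' @param x A `submito_cv`.
#' @param ... Unused.
#' @return One-row tibble: folds, n, pooled accuracy and macro-averaged MCC.
#' @export
glance.submito_cv <- function(x, ...) {
  tibble(
    k_folds = x$k_folds,
    n = nrow(x$folds),
    accuracy = sum(diag(x$pooled)) / sum(x$pooled),
    macro_mcc = mean(x$mcc$mcc)
  )
}

#' Tidy a mitochondrial screen
#'
#' @param x A `mito_screen`.
#' @param ... Unused.
#' @return The decisions tibble.
#' @export
tidy.mito_screen <- function(x, ...) x$decisions

#' Glance at a mitochondrial screen
#'
#' @param x A `mito_screen`.
#' @param ... Unused.
#' @return One-row tibble of decision/reject counts.
#' @export
glance.mito_screen <- function(x, ...) {
  tibble(
    n_decided = nrow(x$decisions),
    n_mitochondrial = sum(x$decisions$is_mitochondrial),
    n_rejected = nrow(x$rejects)
  )
}
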