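# Per-class Matthews correlation coefficients over a 4-way confusion matrix,
# and stratified k-fold cross-validation.

#' Four-way confusion matrix
#'
#' Rows are true compartments, columns predicted, in the fixed class order.
#' Predictions and truth are aligned by protein id.
#'
#' @param predictions Tibble with `protein_id` and `predicted_compartment`.
#' @param truth Tibble with `protein_id` and `label`.
#' @return 4 x 4 integer matrix whose total equals the number of proteins.
#' @export
confusion <- function(predictions, truth) {
  if (!setequal(predictions$protein_id, truth$protein_id) ||
      nrow(predictions) != nrow(truth)) {
    stop("protein ids in predictions and truth do not match", call. = FALSE)
  }
  tr <- as_compartment(truth$label[match(predictions$protein_id, truth$protein_id)])
  pr <- as_compartment(predictions$predicted_compartment)
  tab <- table(true = tr, predicted = pr)
  matrix(as.integer(tab), 4, 4, dimnames = dimnames(tab))
}

mcc_from_counts <- function(TP, TN, FP, FN) {
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  if (den == 0) return(0)  # degenerate margins: report 0 by convention
  (TP * TN - FP * FN) / den
}

#' Per-class Matthews correlation coefficient
#'
#' One-vs-rest binarization of class `class`, then
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A zero denominator (an empty margin) returns 0.
#'
#' @param cm 4 x 4 confusion matrix (true rows x predicted columns).
#' @param class Compartment label or index 1-4.
#' @return MCC in \[-1, 1\].
#' @export
per_class_mcc <- function(cm, class) {
  i <- if (is.numeric(class)) as.integer(class) else
    match(class, compartment_levels())
  if (is.na(i) || i < 1 || i > 4) stop("unknown class: ", class, call. = FALSE)
  TP <- cm[i, i]
  FN <- sum(cm[i, -i])
  FP <- sum(cm[-i, i])
  TN <- sum(cm[-i, -i])
  mcc_from_counts(TP, TN, FP, FN)
}

#' Per-class MCC for all four compartments
#' @param cm 4 x 4 confusion matrix.
#' @return Tibble with columns `class`, `mcc`.
#' @export
mcc_by_class <- function(cm) {
  tibble(
    class = compartment_levels(),
    mcc = vapply(1:4, per_class_mcc, numeric(1), cm = cm)
  )
}

#' Stratified fold assignment
#'
#' Splits each class as evenly as possible across folds, shuffled under the
#' seed; the folds partition the data.
#'
#' @param labels Compartment labels.
#' @param k_folds Number of folds (>= 2).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in 1..k_folds.
#' @export
make_folds <- function(labels, k_folds, seed = 1) {
  labels <- as_compartment(labels)
  if (k_folds < 2) stop("k_folds must be at least 2", call. = FALSE)
  counts <- table(droplevels(labels))
  small <- counts[counts < k_folds]
  if (length(small) > 0) {
    stop("class ", names(small)[1], " has only ", small[1],
         " member(s), fewer than ", k_folds, " folds; use fewer folds",
         call. = FALSE)
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(droplevels(labels))) {
      ix <- sample(which(labels == cl))
      fold[ix] <- rep(seq_len(k_folds), length.out = length(ix))
    }
  })
  fold
}

#' Cross-validate the compartment predictor
#'
#' Stratified k-fold cross-validation: for each fold a fresh model is built
#' and trained on the remaining folds, then scored on the held-out fold. The
#' pooled confusion matrix is the sum of the fold matrices and the per-class
#' MCCs are computed from it.
#'
#' @param x List of `encoded_protein` matrices.
#' @param labels Compartment labels aligned with `x`.
#' @param k_folds Number of folds.
#' @param model_config,train_config Architecture and training settings.
#' @param seed Seed for the fold assignment.
#' @return A `submito_cv` object: fold assignment, per-fold confusion
#'   matrices, pooled matrix and per-class MCC tibble.
#' @export
cross_validate <- function(x, labels, k_folds = 5,
                           model_config = submito::model_config(),
                           train_config = submito::train_config(),
                           seed = 1) {
  labels <- as_compartment(labels)
  fold <- make_folds(labels, k_folds, seed)
  ids <- unname(vapply(x, function(e) attr(e, "protein_id"), character(1)))
  confusions <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    model <- build_model(model_config)
    model <- train(model, x[tr], labels[tr], train_config)
    preds <- predict(model, x[!tr])
    confusions[[f]] <- confusion(
      preds, tibble(protein_id = ids[!tr], label = labels[!tr])
    )
  }
  pooled <- Reduce(`+`, confusions)
  structure(
    list(folds = tibble(protein_id = ids, label = labels, fold = fold),
         confusions = confusions, pooled = pooled,
         mcc = mcc_by_class(pooled), k_folds = k_folds, seed = seed),
    class = "submito_cv"
  )
}

#' @export
print.submito_cv <- function(x, ...) {
  cat("<submito_cv> ", x$k_folds, "-fold stratified cross-validation, n = ",
      nrow(x$folds), "\n", sep = "")
  print(x$mcc)
  invisible(x)
}
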