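# Fixed class order used everywhere: index 1..4.

#' Sub-mitochondrial compartment labels
#'
#' The four compartments of a mitochondrion in the fixed index order used by
#' the predictor, the confusion matrix and every table in the package: outer
#' membrane, inner membrane, intermembrane space, matrix.
#'
#' @return Character vector of length four.
#' @export
#' @examples
#' compartment_levels()
compartment_levels <- function() {
  c("outer_membrane", "inner_membrane", "intermembrane_space", "matrix")
}

#' Coerce labels to the compartment factor
#'
#' @param x Character vector or factor of compartment labels.
#' @return Factor with the four canonical levels in fixed order.
#' @export
as_compartment <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), compartment_levels())
  if (length(bad) > 0) {
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = compartment_levels())
}
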