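# The mitochondrial discovery screen: three external localization tools
# each cast a boolean "mitochondrion" vote; a protein is called
# mitochondrial when at least two of the three agree.

#' Two-out-of-three majority vote
#'
#' @param votes Logical vector of exactly three tool votes (no NA).
#' @return TRUE iff at least two votes are TRUE.
#' @export
#' @examples
#' majority_vote(c(TRUE, TRUE, FALSE))   # TRUE
#' majority_vote(c(FALSE, FALSE, TRUE))  # FALSE
majority_vote <- function(votes) {
  if (!is.logical(votes) || length(votes) != 3 || anyNA(votes)) {
    stop("exactly three TRUE/FALSE votes are required", call. = FALSE)
  }
  sum(votes) >= 2
}

#' Screen a proteome for mitochondrial proteins
#'
#' Applies the 2-of-3 majority rule to a tool-vote table. Proteins lacking a
#' vote from every tool are excluded from the decisions and listed in a
#' rejects report (missing votes are never imputed). Decisions are
#' deterministic and independent of input row order.
#'
#' @param votes Vote tibble (`protein_id`, `tool`, `is_mitochondrial`).
#' @param tools The required tool set (exactly three tools).
#' @return A `mito_screen` list with `decisions` (tibble: `protein_id`,
#'   `n_positive`, `is_mitochondrial`) and `rejects` (tibble: `protein_id`,
#'   `n_votes`), both sorted by protein id.
#' @export
screen_proteome <- function(votes, tools = mito_tools()) {
  if (length(tools) != 3) stop("exactly three tools are required", call. = FALSE)
  votes <- validate_votes(votes, tools)
  per_protein <- votes |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(n_votes = dplyr::n(),
                     n_positive = sum(.data$is_mitochondrial),
                     .groups = "drop") |>
    dplyr::arrange(.data$protein_id)
  complete <- per_protein$n_votes == 3L
  decisions <- per_protein |>
    dplyr::filter(complete) |>
    dplyr::mutate(is_mitochondrial = .data$n_positive >= 2L) |>
    dplyr::select("protein_id", "n_positive", "is_mitochondrial")
  rejects <- per_protein |>
    dplyr::filter(!complete) |>
    dplyr::select("protein_id", "n_votes")
  structure(list(decisions = decisions, rejects = rejects),
            class = "mito_screen")
}

#' @export
print.mito_screen <- function(x, ...) {
  cat("<mito_screen> ", nrow(x$decisions), " decision(s), ",
      sum(x$decisions$is_mitochondrial), " mitochondrial, ",
      nrow(x$rejects), " reject(s)\n", sep = "")
  invisible(x)
}
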