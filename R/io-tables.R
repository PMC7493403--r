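# Tabular interchange formats. All tables are TSV with a mandatory header;
# no delimiter sniffing.

#' Names of the three external localization tools
#' @return Character vector: BUSCA, TargetP2, MitoFates.
#' @export
mito_tools <- function() c("BUSCA", "TargetP2", "MitoFates")

GO_SOURCES <- c("GOA_manual", "GOA_IEA", "BAR")
GO_ASPECTS <- c("BP", "MF")

#' Read a tool-vote table
#'
#' One row per (protein, tool) pair with a boolean mitochondrial call.
#'
#' @param path TSV file with columns `protein_id`, `tool`, `is_mitochondrial`.
#' @param tools Allowed tool names.
#' @return Tibble with the three columns, `is_mitochondrial` logical.
#' @export
read_votes <- function(path, tools = mito_tools()) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = "c", tool = "c", is_mitochondrial = "l"
  ), progress = FALSE)
  validate_votes(tbl, tools)
}

validate_votes <- function(tbl, tools = mito_tools()) {
  need <- c("protein_id", "tool", "is_mitochondrial")
  if (!all(need %in% names(tbl))) {
    stop("vote table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(tbl$tool), tools)
  if (length(bad) > 0) {
    stop("unknown tool name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- tbl[duplicated(tbl[c("protein_id", "tool")]), ]
  if (nrow(dup) > 0) {
    stop("duplicate (protein, tool) vote(s): ",
         paste(unique(paste(dup$protein_id, dup$tool, sep = "/")), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(tbl$is_mitochondrial)) {
    stop("missing is_mitochondrial value(s) in vote table", call. = FALSE)
  }
  as_tibble(tbl)
}

#' Write a tool-vote table
#' @param votes Tibble as returned by [read_votes()].
#' @param path Output TSV path.
#' @export
write_votes <- function(votes, path) {
  readr::write_tsv(validate_votes(votes), path)
  invisible(path)
}

#' Read a GO annotation table
#'
#' Five-column GAF-like TSV restricted to the two aspects used for
#' mitochondrial functional characterization (BP, MF).
#'
#' @param path TSV file with columns `protein_id`, `go_term`, `aspect`,
#'   `evidence`, `source`.
#' @return Tibble of annotations.
#' @export
read_go_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  validate_go_table(tbl)
}

validate_go_table <- function(tbl) {
  need <- c("protein_id", "go_term", "aspect", "evidence", "source")
  if (!all(need %in% names(tbl))) {
    stop("GO table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad_aspect <- setdiff(unique(tbl$aspect), GO_ASPECTS)
  if (length(bad_aspect) > 0) {
    stop("unknown GO aspect(s): ", paste(bad_aspect, collapse = ", "),
         " (only BP and MF are supported)", call. = FALSE)
  }
  bad_term <- !grepl("^GO:[0-9]{7}$", tbl$go_term)
  if (any(bad_term)) {
    stop("malformed GO id(s): ",
         paste(unique(tbl$go_term[bad_term]), collapse = ", "), call. = FALSE)
  }
  bad_source <- setdiff(unique(tbl$source), GO_SOURCES)
  if (length(bad_source) > 0) {
    stop("unknown annotation source(s): ", paste(bad_source, collapse = ", "),
         call. = FALSE)
  }
  as_tibble(tbl)
}

#' Write a GO annotation table
#' @param annotations Tibble of annotations.
#' @param path Output TSV path.
#' @export
write_go_table <- function(annotations, path) {
  readr::write_tsv(validate_go_table(annotations), path)
  invisible(path)
}

#' Write predictor output
#'
#' @param results Tibble with columns `protein_id`, `predicted_compartment`,
#'   `p_outer`, `p_inner`, `p_ims`, `p_matrix`.
#' @param path Output TSV path.
#' @export
write_predictions <- function(results, path) {
  need <- c("protein_id", "predicted_compartment",
            "p_outer", "p_inner", "p_ims", "p_matrix")
  if (!all(need %in% names(results))) {
    stop("prediction table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  readr::write_tsv(results[need], path)
  invisible(path)
}

#' Read predictor output
#' @param path TSV written by [write_predictions()].
#' @return Tibble of predictions.
#' @export
read_predictions <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = "c", predicted_compartment = "c",
    p_outer = "d", p_inner = "d", p_ims = "d", p_matrix = "d"
  ), progress = FALSE)
  as_compartment(tbl$predicted_compartment)  # validates labels
  as_tibble(tbl)
}
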