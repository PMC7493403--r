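#' Read a FASTA proteome
#'
#' Parses a FASTA file of amino-acid sequences into a tibble of protein
#' records. Sequences are uppercased on ingest; multi-line sequences are
#' concatenated; record order is preserved. Ids are the first whitespace
#' token of the header. Letters outside the 20 standard residues but in the
#' tolerated set (X, B, Z, U, O) are accepted with a warning naming the
#' records; any other character is an error.
#'
#' @param path Path to a FASTA file.
#' @param species Optional species tag added as a column to every record.
#' @return A tibble with columns `id`, `sequence` (and `species` if given).
#' @export
read_fasta <- function(path, species = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    out <- tibble(id = character(), sequence = character())
    if (!is.null(species)) out$species <- character()
    return(out)
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    stop("malformed FASTA: expected a '>' header at line ", nonblank[1],
         " of ", path, call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  sequence <- toupper(unname(as.character(seqs)))
  if (any(nchar(sequence) == 0)) {
    stop("zero-length sequence for id(s): ",
         paste(ids[nchar(sequence) == 0], collapse = ", "), call. = FALSE)
  }
  check_residue_letters(ids, sequence)
  out <- tibble(id = ids, sequence = sequence)
  if (!is.null(species)) out$species <- species
  out
}

# Error on letters outside the tolerated alphabet; warn (flag) on tolerated
# non-standard letters.
check_residue_letters <- function(ids, sequence) {
  std <- paste(PSSM_RESIDUES, collapse = "")
  amb <- paste(AMBIGUOUS_RESIDUES, collapse = "")
  illegal <- grepl(sprintf("[^%s%s]", std, amb), sequence)
  if (any(illegal)) {
    stop("sequence(s) contain letters outside the tolerated amino-acid ",
         "alphabet: ", paste(ids[illegal], collapse = ", "), call. = FALSE)
  }
  flagged <- grepl(sprintf("[%s]", amb), sequence)
  if (any(flagged)) {
    warning("non-standard residue letters (", paste(AMBIGUOUS_RESIDUES, collapse = ""),
            ") in: ", paste(ids[flagged], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write protein records to FASTA
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
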