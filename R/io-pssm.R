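# PSI-BLAST ASCII PSSM support (`-out_ascii_pssm` dialect): three header
# lines (blank, title, residue columns) followed by one row per residue with
# position, letter, 20 log-odds integers, 20 weighted-percentage integers and
# two trailing floats. Only the log-odds block is retained; the percentage
# columns and trailing floats are ignored.

new_pssm <- function(protein_id, matrix, residues) {
  stopifnot(is.matrix(matrix), ncol(matrix) == 20,
            nrow(matrix) == length(residues))
  storage.mode(matrix) <- "integer"
  colnames(matrix) <- PSSM_RESIDUES
  rownames(matrix) <- NULL
  structure(
    list(protein_id = protein_id, matrix = matrix, residues = residues),
    class = "pssm_profile"
  )
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("<pssm_profile> ", x$protein_id, ": ", nrow(x$matrix),
      " residues x 20 log-odds columns\n", sep = "")
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the log-odds block of a PSI-BLAST `-out_ascii_pssm` file. When the
#' protein's sequence is supplied, each row's residue letter is verified
#' against the corresponding sequence position.
#'
#' @param path Path to the `.pssm` file.
#' @param sequence Optional amino-acid sequence of the profiled protein.
#' @param protein_id Protein identifier; defaults to the file name without
#'   its `.pssm` extension.
#' @return A `pssm_profile`: protein id, L x 20 integer log-odds matrix
#'   (columns in the fixed PSI-BLAST residue order) and the per-row residue
#'   letters.
#' @export
read_pssm <- function(path, sequence = NULL, protein_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path, call. = FALSE)
  protein_id <- protein_id %||% sub("\\.pssm$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) {
    stop("not a PSI-BLAST ASCII PSSM (fewer than 4 lines): ", path, call. = FALSE)
  }
  body <- lines[-(1:3)]
  is_row <- grepl("^\\s*[0-9]+\\s+[A-Z](\\s|$)", body)
  if (!any(is_row)) stop("no PSSM data rows found in ", path, call. = FALSE)
  first <- which(is_row)[1]
  run_end <- first
  while (run_end < length(body) && is_row[run_end + 1]) run_end <- run_end + 1
  fields <- strsplit(trimws(body[first:run_end]), "\\s+")
  short <- which(lengths(fields) < 22)
  if (length(short) > 0) {
    stop("PSSM row at position ", short[1], " has fewer than 22 fields in ",
         path, call. = FALSE)
  }
  positions <- vapply(fields, function(f) as.integer(f[1]), integer(1))
  residues <- vapply(fields, `[`, character(1), 2)
  scores <- t(vapply(fields, function(f) {
    v <- suppressWarnings(as.integer(f[3:22]))
    if (anyNA(v)) stop("non-integer log-odds value in ", path, call. = FALSE)
    v
  }, integer(20)))
  if (!identical(positions, seq_along(positions))) {
    stop("PSSM positions are not consecutive from 1 in ", path, call. = FALSE)
  }
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != length(residues)) {
      stop("PSSM has ", length(residues), " rows but the sequence has length ",
           nchar(sequence), call. = FALSE)
    }
    seq_letters <- strsplit(sequence, "")[[1]]
    mism <- which(seq_letters != residues)
    if (length(mism) > 0) {
      stop("PSSM residue letter mismatch at position ", mism[1], ": profile has ",
           sQuote(residues[mism[1]]), ", sequence has ",
           sQuote(seq_letters[mism[1]]), call. = FALSE)
    }
  }
  new_pssm(protein_id, scores, residues)
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Emits the three-line header, the log-odds block, zeroed percentage columns
#' and zeroed trailing per-row statistics, so that files round-trip bit-exactly
#' through [read_pssm()] on the log-odds block.
#'
#' @param profile A `pssm_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  m <- profile$matrix
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0(strrep(" ", 9),
           paste(sprintf("%3s", c(PSSM_RESIDUES, PSSM_RESIDUES)), collapse = " "))
  )
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste0(sprintf("%5d %s ", i, profile$residues[i]),
           paste(sprintf("%3d", m[i, ]), collapse = " "), " ",
           paste(sprintf("%3d", rep(0L, 20)), collapse = " "),
           "  0.00 0.00")
  }, character(1))
  writeLines(c(header, rows, ""), path)
  invisible(path)
}

#' Read a directory of per-protein PSSM files
#'
#' Expects one `<id>.pssm` file per record and validates each profile against
#' its sequence.
#'
#' @param dir Directory containing `<id>.pssm` files.
#' @param records Tibble of protein records (`id`, `sequence`).
#' @return Named list of `pssm_profile` objects, in record order.
#' @export
read_pssm_dir <- function(dir, records) {
  paths <- file.path(dir, paste0(records$id, ".pssm"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing PSSM file(s) for: ",
         paste(records$id[missing], collapse = ", "), call. = FALSE)
  }
  profiles <- purrr::map2(paths, seq_len(nrow(records)), function(p, i) {
    read_pssm(p, sequence = records$sequence[i], protein_id = records$id[i])
  })
  setNames(profiles, records$id)
}
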