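# The Lx30 network input: 20 logistic-squashed profile channels followed by
# 10 Kidera channels.

encoding_channels <- function() {
  c(paste0("pssm_", PSSM_RESIDUES), paste0("KF", 1:10))
}

#' Squash a PSSM into (0, 1)
#'
#' Elementwise logistic transform `1 / (1 + exp(-x))` of the integer log-odds
#' scores, the standard squashing for profile-fed networks. Strictly monotone,
#' so the score ordering within and across positions is preserved.
#'
#' @param x A `pssm_profile` or an L x 20 numeric matrix of log-odds scores.
#' @return L x 20 numeric matrix with entries strictly inside (0, 1).
#' @export
scale_pssm <- function(x) {
  m <- if (inherits(x, "pssm_profile")) x$matrix else x
  if (!is.matrix(m) || ncol(m) != 20) {
    stop("'x' must be a pssm_profile or an L x 20 matrix", call. = FALSE)
  }
  s <- plogis(m)
  colnames(s) <- PSSM_RESIDUES
  s
}

#' Encode a protein for the network
#'
#' Builds the L x 30 input matrix: columns 1-20 are the logistic-squashed
#' profile (PSI-BLAST residue order), columns 21-30 the Kidera factors of each
#' residue. Kidera channels depend only on the residue letter; non-standard
#' letters contribute all-zero Kidera rows.
#'
#' @param record A one-row data frame or list with fields `id` and `sequence`.
#' @param profile The protein's `pssm_profile`; must have one row per residue.
#' @return An `encoded_protein`: L x 30 numeric matrix with the protein id
#'   and channel layout stored as attributes.
#' @export
encode_protein <- function(record, profile) {
  id <- record$id %||% record$protein_id
  sequence <- toupper(record$sequence)
  if (is.null(id) || is.null(sequence)) {
    stop("'record' must carry 'id' and 'sequence' fields", call. = FALSE)
  }
  letters <- strsplit(sequence, "")[[1]]
  if (nrow(profile$matrix) != length(letters)) {
    stop("profile has ", nrow(profile$matrix), " rows but sequence ", id,
         " has length ", length(letters), call. = FALSE)
  }
  kid <- t(vapply(letters, kidera_vector, numeric(10)))
  m <- cbind(scale_pssm(profile), kid)
  dimnames(m) <- list(NULL, encoding_channels())
  structure(m, protein_id = id, class = c("encoded_protein", class(m)))
}

#' Encode a whole proteome
#'
#' @param records Tibble of protein records (`id`, `sequence`).
#' @param profiles Named list of `pssm_profile` objects or a directory of
#'   `<id>.pssm` files.
#' @return Named list of `encoded_protein` matrices, in record order.
#' @export
encode_proteome <- function(records, profiles) {
  if (is.character(profiles) && length(profiles) == 1) {
    profiles <- read_pssm_dir(profiles, records)
  }
  missing <- setdiff(records$id, names(profiles))
  if (length(missing) > 0) {
    stop("no profile for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- purrr::map(seq_len(nrow(records)), function(i) {
    encode_protein(records[i, ], profiles[[records$id[i]]])
  })
  setNames(out, records$id)
}
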