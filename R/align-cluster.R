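# Sequence identity clustering for annotation transfer. Pairs are aligned
# locally (Smith-Waterman, BLOSUM62, gap open 11 / extend 1); an edge joins
# two sequences when identity exceeds 40% over at least 90% coverage, and
# clusters are the connected components (single linkage). Identity is
# identities / alignment length; coverage is alignment length / length of
# the shorter sequence (the strictest symmetric reading).

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

hit_from_alignment <- function(aln, len_a, len_b) {
  alen <- Biostrings::nchar(aln)  # alignment columns, gaps included
  identity <- Biostrings::nmatch(aln) / alen * 100
  coverage <- alen / pmin(len_a, len_b) * 100
  list(identity = identity, coverage = coverage, alignment_length = alen)
}

#' Align one pair of proteins
#'
#' Local alignment under BLOSUM62 with affine gaps (open 11, extend 1).
#'
#' @param a,b One-row records (fields `id`, `sequence`).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return One-row tibble: `id_a`, `id_b`, `identity`, `coverage`,
#'   `alignment_length`.
#' @export
align_pair <- function(a, b, gap_opening = 11, gap_extension = 1) {
  aln <- Biostrings::pairwiseAlignment(
    a$sequence, b$sequence, type = "local",
    substitutionMatrix = blosum62(),
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  h <- hit_from_alignment(aln, nchar(a$sequence), nchar(b$sequence))
  tibble(id_a = a$id, id_b = b$id, identity = h$identity,
         coverage = h$coverage, alignment_length = h$alignment_length)
}

#' All-against-all pairwise hits
#'
#' @param records Tibble of protein records (`id`, `sequence`).
#' @inheritParams align_pair
#' @return Tibble of unordered pairs with identity/coverage statistics.
#' @export
pairwise_hits <- function(records, gap_opening = 11, gap_extension = 1) {
  n <- nrow(records)
  if (n < 2) {
    return(tibble(id_a = character(), id_b = character(), identity = numeric(),
                  coverage = numeric(), alignment_length = integer()))
  }
  seqs <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  lens <- nchar(records$sequence)
  out <- vector("list", n - 1)
  for (j in 2:n) {
    alns <- Biostrings::pairwiseAlignment(
      seqs[seq_len(j - 1)], seqs[[j]], type = "local",
      substitutionMatrix = blosum62(),
      gapOpening = gap_opening, gapExtension = gap_extension
    )
    h <- hit_from_alignment(alns, lens[seq_len(j - 1)], lens[j])
    out[[j - 1]] <- tibble(
      id_a = records$id[seq_len(j - 1)], id_b = records$id[j],
      identity = h$identity, coverage = h$coverage,
      alignment_length = h$alignment_length
    )
  }
  dplyr::bind_rows(out)
}

#' Single-linkage identity clusters
#'
#' Two sequences join the same cluster when linked (directly or
#' transitively) by hits with identity strictly above `min_identity` and
#' coverage at least `min_coverage`. Everything else is a singleton.
#'
#' @param records Tibble of protein records (`id`, `sequence`).
#' @param min_identity Percent identity threshold (exclusive; default 40).
#' @param min_coverage Percent coverage threshold (inclusive; default 90).
#' @param hits Optional precomputed [pairwise_hits()] table.
#' @return Tibble with `protein_id`, `cluster_id`, `singleton`; the clusters
#'   partition the input.
#' @export
build_clusters <- function(records, min_identity = 40, min_coverage = 90,
                           hits = NULL) {
  if (nrow(records) < 1) stop("at least one record is required", call. = FALSE)
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup) > 0) {
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(hits)) hits <- pairwise_hits(records)
  edges <- dplyr::filter(hits, .data$identity > min_identity,
                         .data$coverage >= min_coverage)
  g <- igraph::graph_from_data_frame(
    edges[c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = records$id)
  )
  membership <- igraph::components(g)$membership[records$id]
  # relabel components in order of first appearance for determinism
  cluster_id <- paste0("C", match(membership, unique(membership)))
  sizes <- table(cluster_id)
  tibble(
    protein_id = records$id,
    cluster_id = cluster_id,
    singleton = as.vector(sizes[cluster_id]) == 1L
  )
}
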