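# Synthetic data generators. Every stage of the toolkit can be exercised
# without external services: motif-planted labelled proteomes, profiles
# consistent with their sequences, tool-vote tables and GO worlds with
# planted over-represented terms. All generators are pure functions of
# (spec, seed); passing seed = NULL draws from the current RNG stream
# instead (used when a caller fans one seed out over several generators).

with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

default_motifs <- function() {
  c(outer_membrane      = "WDYKRHPENFC",
    inner_membrane      = "LMIVAGTLSIV",
    intermembrane_space = "CQHGEDNKRTY",
    matrix              = "FPWSYAMVQGI")
}

#' Synthetic proteome specification
#'
#' Describes a four-compartment proteome in which class identity is carried
#' by one planted consensus motif per compartment: each protein is a uniform
#' random background sequence with its class motif embedded at a random
#' position, mutated at the given per-position substitution rate. An 11-mer
#' motif sits well inside the network's width-19 filters, so the planted
#' signal directly probes the convolutional layer.
#'
#' @param n_per_class Proteins per compartment (default 60).
#' @param length_range Min/max sequence length in residues (default 60-120).
#' @param motifs Named character vector: one 8-15-mer consensus per
#'   compartment; must be pairwise distinct.
#' @param substitution_rate Per-position probability of mutating a motif
#'   residue (default 0.1).
#' @param pssm_noise Standard deviation of the Gaussian perturbation on
#'   non-observed profile scores (default 1).
#' @param seed RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = 60, length_range = c(60, 120),
                           motifs = default_motifs(),
                           substitution_rate = 0.1, pssm_noise = 1,
                           seed = 1) {
  stopifnot(n_per_class >= 1, length(length_range) == 2,
            substitution_rate >= 0, substitution_rate <= 1, pssm_noise >= 0)
  if (!setequal(names(motifs), compartment_levels())) {
    stop("motifs must be named by the four compartments", call. = FALSE)
  }
  motifs <- motifs[compartment_levels()]
  if (anyDuplicated(motifs)) stop("motifs must be pairwise distinct", call. = FALSE)
  if (any(nchar(motifs) < 8 | nchar(motifs) > 15)) {
    stop("each motif must be 8-15 residues long", call. = FALSE)
  }
  if (length_range[1] < max(nchar(motifs))) {
    stop("length range is shorter than the longest motif", call. = FALSE)
  }
  structure(
    list(n_per_class = as.integer(n_per_class),
         length_range = as.integer(length_range),
         motifs = motifs, substitution_rate = substitution_rate,
         pssm_noise = pssm_noise, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

random_sequence <- function(L) {
  paste(sample(PSSM_RESIDUES, L, replace = TRUE), collapse = "")
}

mutate_sequence <- function(sequence, rate) {
  if (rate == 0) return(sequence)
  letters <- strsplit(sequence, "")[[1]]
  hit <- runif(length(letters)) < rate
  letters[hit] <- vapply(letters[hit], function(a) {
    sample(setdiff(PSSM_RESIDUES, a), 1)
  }, character(1))
  paste(letters, collapse = "")
}

#' Generate a motif-planted labelled proteome
#'
#' @param spec A [synthetic_spec()].
#' @param seed Overrides the spec seed when given; `NULL` uses the current
#'   RNG stream.
#' @return Tibble with `id`, `sequence`, `label`; exactly `n_per_class`
#'   records per compartment.
#' @export
generate_proteome <- function(spec = synthetic_spec(), seed = spec$seed) {
  with_seed_opt(seed, {
    rows <- purrr::imap(spec$motifs, function(motif, cls) {
      purrr::map(seq_len(spec$n_per_class), function(i) {
        L <- sample(seq(spec$length_range[1], spec$length_range[2]), 1)
        bg <- strsplit(random_sequence(L), "")[[1]]
        planted <- strsplit(mutate_sequence(motif, spec$substitution_rate),
                            "")[[1]]
        pos <- sample(L - length(planted) + 1L, 1)
        bg[pos:(pos + length(planted) - 1L)] <- planted
        list(sequence = paste(bg, collapse = ""), label = cls)
      })
    })
    rows <- purrr::flatten(rows)
    tibble(
      id = sprintf("SYN%04d", seq_along(rows)),
      sequence = purrr::map_chr(rows, "sequence"),
      label = purrr::map_chr(rows, "label")
    )
  })
}

#' Generate a sequence-consistent synthetic profile
#'
#' Emulates the shape of a PSI-BLAST profile: the observed residue scores a
#' high log-odds of +7 at every position, all other residues score -3
#' perturbed by Gaussian noise and rounded to integers. With `noise = 0` the
#' row argmax is always the observed residue.
#'
#' @param record One-row record (fields `id`, `sequence`) or a sequence string.
#' @param noise Standard deviation of the perturbation (default 1).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return A `pssm_profile`.
#' @export
generate_pssm <- function(record, noise = 1, seed = 1) {
  if (is.character(record)) record <- list(id = "synthetic", sequence = record)
  letters <- strsplit(toupper(record$sequence), "")[[1]]
  L <- length(letters)
  with_seed_opt(seed, {
    m <- matrix(as.integer(round(-3 + rnorm(L * 20, 0, noise))), L, 20)
    obs <- match(letters, PSSM_RESIDUES)
    known <- !is.na(obs)
    m[cbind(which(known), obs[known])] <- 7L
    new_pssm(record$id, m, letters)
  })
}

#' Generate a synthetic tool-vote table
#'
#' Draws a latent mitochondrial status per protein, then lets each of the
#' three tools report it correctly with probability `accuracy`.
#'
#' @param protein_ids Character vector of protein ids.
#' @param p_mito Prevalence of true mitochondrial proteins (default 0.5).
#' @param accuracy Per-tool probability of reporting the true status.
#' @param tools Tool names (exactly three).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return List with `votes` (long tibble) and `truth` (per-protein status).
#' @export
generate_votes <- function(protein_ids, p_mito = 0.5, accuracy = 0.9,
                           tools = mito_tools(), seed = 1) {
  stopifnot(length(tools) == 3, accuracy >= 0, accuracy <= 1)
  with_seed_opt(seed, {
    truth <- runif(length(protein_ids)) < p_mito
    votes <- tidyr::crossing(protein_id = protein_ids, tool = tools) |>
      dplyr::mutate(
        is_true = truth[match(.data$protein_id, protein_ids)],
        is_mitochondrial = ifelse(runif(dplyr::n()) < accuracy,
                                  .data$is_true, !.data$is_true)
      ) |>
      dplyr::select("protein_id", "tool", "is_mitochondrial")
    list(votes = votes,
         truth = tibble(protein_id = protein_ids, is_mitochondrial = truth))
  })
}

#' Generate a GO world with planted over-represented terms
#'
#' Builds `n_clusters` sequence families (each a founder plus point-mutated
#' copies, so identity clustering recovers them) on top of a background of
#' unrelated random sequences. One planted GO term per family is annotated
#' at `inside_freq` within the family and `outside_freq` elsewhere; decoy
#' terms are annotated uniformly everywhere. The returned truth table maps
#' each family to its planted term for recovery scoring.
#'
#' @param n_clusters Number of planted families (default 3).
#' @param cluster_size Members per family (default 8).
#' @param background_size Number of unrelated background proteins (default 200).
#' @param inside_freq,outside_freq Planted-term annotation frequencies inside
#'   vs outside the family; `inside_freq` must exceed `outside_freq`.
#' @param n_decoy_terms Number of decoy terms (default 5).
#' @param decoy_freq Uniform decoy annotation frequency (default 0.1).
#' @param founder_length Family founder length in residues (default 100).
#' @param member_substitution_rate Point-mutation rate applied to each family
#'   member (default 0.1).
#' @param background_length_range Length range of background sequences.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return List with `records` (tibble: `id`, `sequence`, `family`),
#'   `annotations` (standard five-column tibble) and `truth`
#'   (tibble: `family`, `go_term`).
#' @export
generate_go_world <- function(n_clusters = 3, cluster_size = 8,
                              background_size = 200, inside_freq = 0.9,
                              outside_freq = 0.05, n_decoy_terms = 5,
                              decoy_freq = 0.1, founder_length = 100,
                              member_substitution_rate = 0.1,
                              background_length_range = c(80, 120),
                              seed = 1) {
  freqs <- c(inside_freq, outside_freq, decoy_freq)
  if (any(freqs < 0 | freqs > 1)) {
    stop("annotation frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (inside_freq <= outside_freq) {
    stop("inside_freq must exceed outside_freq", call. = FALSE)
  }
  with_seed_opt(seed, {
    fam_records <- purrr::map(seq_len(n_clusters), function(j) {
      founder <- random_sequence(founder_length)
      tibble(
        id = sprintf("FAM%d_%02d", j, seq_len(cluster_size)),
        sequence = vapply(seq_len(cluster_size), function(i) {
          mutate_sequence(founder, member_substitution_rate)
        }, character(1)),
        family = j
      )
    })
    bg_records <- tibble(
      id = sprintf("BG%04d", seq_len(background_size)),
      sequence = vapply(
        sample(seq(background_length_range[1], background_length_range[2]),
               background_size, replace = TRUE),
        random_sequence, character(1)),
      family = NA_integer_
    )
    records <- dplyr::bind_rows(c(fam_records, list(bg_records)))

    planted_terms <- sprintf("GO:%07d", seq_len(n_clusters))
    decoy_terms <- sprintf("GO:%07d", 1000L + seq_len(n_decoy_terms))
    ann <- list()
    for (j in seq_len(n_clusters)) {
      inside <- records$family %in% j
      p <- ifelse(inside, inside_freq, outside_freq)
      hit <- runif(nrow(records)) < p
      ann[[length(ann) + 1]] <- tibble(protein_id = records$id[hit],
                                       go_term = planted_terms[j])
    }
    for (t in decoy_terms) {
      hit <- runif(nrow(records)) < decoy_freq
      ann[[length(ann) + 1]] <- tibble(protein_id = records$id[hit],
                                       go_term = t)
    }
    annotations <- dplyr::bind_rows(ann) |>
      dplyr::mutate(aspect = "BP", evidence = "IEA", source = "GOA_IEA") |>
      dplyr::arrange(.data$protein_id, .data$go_term)

    list(records = records, annotations = annotations,
         truth = tibble(family = seq_len(n_clusters), go_term = planted_terms))
  })
}
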