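# Per-cluster GO-term over-representation and annotation transfer. For each
# term observed inside a cluster, a one-sided Fisher exact test (the
# hypergeometric upper tail) compares the term's frequency among cluster
# members with the background; the Bonferroni divisor is the number of terms
# tested in that cluster and the significance level is 1%.

#' Term over-representation within one cluster
#'
#' For every GO term carried by at least one cluster member, tests whether
#' the term is over-represented among the `n` cluster members relative to
#' the `N` background proteins: with `k` members and `K` background proteins
#' carrying the term, the one-sided p-value is the hypergeometric tail
#' `P(X >= k)` for `X ~ Hypergeom(N, K, n)`. A term is significant when
#' `p <= alpha / m`, `m` being the number of terms tested in this cluster.
#'
#' @param members Character vector of cluster member ids.
#' @param annotations Annotation tibble for the background (must cover the
#'   cluster's own annotations).
#' @param background_ids Protein ids forming the background universe;
#'   defaults to all ids appearing in `annotations`. Must include the
#'   cluster members.
#' @param alpha Significance level before Bonferroni correction (default 0.01).
#' @return Tibble: `go_term`, `aspect`, `k`, `n`, `K`, `N`, `p_value`,
#'   `n_terms_tested`, `significant`.
#' @export
enrich_cluster <- function(members, annotations, background_ids = NULL,
                           alpha = 0.01) {
  ann <- dplyr::distinct(annotations, .data$protein_id, .data$go_term,
                         .data$aspect)
  background_ids <- background_ids %||% unique(ann$protein_id)
  if (length(background_ids) == 0) stop("empty background", call. = FALSE)
  if (!all(members %in% background_ids)) {
    stop("background must include every cluster member", call. = FALSE)
  }
  ann <- dplyr::filter(ann, .data$protein_id %in% background_ids)
  N <- length(unique(background_ids))
  n <- length(unique(members))
  member_ann <- dplyr::filter(ann, .data$protein_id %in% members)
  terms <- dplyr::distinct(member_ann, .data$go_term, .data$aspect)
  m <- nrow(terms)
  if (m == 0) {
    return(tibble(go_term = character(), aspect = character(),
                  k = integer(), n = integer(), K = integer(), N = integer(),
                  p_value = numeric(), n_terms_tested = integer(),
                  significant = logical()))
  }
  k <- vapply(terms$go_term, function(t) {
    sum(member_ann$go_term == t)
  }, integer(1), USE.NAMES = FALSE)
  K <- vapply(terms$go_term, function(t) {
    length(unique(ann$protein_id[ann$go_term == t]))
  }, integer(1), USE.NAMES = FALSE)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(
    go_term = terms$go_term, aspect = terms$aspect,
    k = k, n = n, K = K, N = N, p_value = p,
    n_terms_tested = m, significant = p <= alpha / m
  )
}

#' Term over-representation for every cluster
#'
#' Runs [enrich_cluster()] for each non-singleton cluster.
#'
#' @param clusters Cluster table from [build_clusters()].
#' @param annotations Background annotation tibble.
#' @param background_ids Background universe; defaults to all clustered ids.
#' @param alpha Significance level (default 0.01).
#' @return Tibble of enrichment results with a leading `cluster_id` column.
#' @export
enrich_clusters <- function(clusters, annotations, background_ids = NULL,
                            alpha = 0.01) {
  background_ids <- background_ids %||% clusters$protein_id
  real <- dplyr::filter(clusters, !.data$singleton)
  out <- real |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::group_map(function(g, key) {
      res <- enrich_cluster(g$protein_id, annotations, background_ids, alpha)
      if (nrow(res) > 0) dplyr::mutate(res, cluster_id = key$cluster_id,
                                       .before = 1) else NULL
    }) |>
    dplyr::bind_rows()
  out
}

#' Transfer significant terms to unannotated cluster members
#'
#' Each significant term is assigned, with source `BAR` and evidence `ISS`
#' (inferred from sequence similarity), to every cluster member that does not
#' already carry it; existing (protein, term) pairs are never duplicated and
#' never removed.
#'
#' @param members Character vector of cluster member ids.
#' @param enriched Enrichment table for this cluster ([enrich_cluster()]).
#' @param annotations Existing annotations (used to skip already-annotated
#'   members).
#' @param evidence Evidence code recorded on transferred annotations.
#' @return Tibble of new annotations in the standard five-column layout.
#' @export
transfer_annotations <- function(members, enriched, annotations,
                                 evidence = "ISS") {
  sig <- dplyr::filter(enriched, .data$significant)
  if (nrow(sig) == 0) {
    return(tibble(protein_id = character(), go_term = character(),
                  aspect = character(), evidence = character(),
                  source = character()))
  }
  existing <- dplyr::distinct(annotations, .data$protein_id, .data$go_term)
  new <- tidyr::crossing(protein_id = members,
                         sig[c("go_term", "aspect")]) |>
    dplyr::anti_join(existing, by = c("protein_id", "go_term")) |>
    dplyr::mutate(evidence = evidence, source = "BAR")
  dplyr::arrange(new, .data$protein_id, .data$go_term)
}

#' Merge annotation pools by evidence quality
#'
#' Collapses duplicate (protein, term, aspect) annotations across pools,
#' keeping the entry with the highest-quality provenance under the strict
#' ordering manually curated GOA > electronically inferred GOA > transferred
#' (`GOA_manual` > `GOA_IEA` > `BAR`).
#'
#' @param ... Annotation tibbles (or a single list of them).
#' @return Deduplicated annotation tibble.
#' @export
merge_annotations <- function(...) {
  pools <- list(...)
  if (length(pools) == 1 && is.list(pools[[1]]) &&
      !is.data.frame(pools[[1]])) {
    pools <- pools[[1]]
  }
  all <- dplyr::bind_rows(pools)
  if (nrow(all) == 0) return(as_tibble(all))
  rank <- setNames(seq_along(GO_SOURCES), GO_SOURCES)  # manual < IEA < BAR
  unknown <- setdiff(unique(all$source), names(rank))
  if (length(unknown) > 0) {
    stop("unknown annotation source(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  all |>
    dplyr::mutate(.rank = rank[.data$source]) |>
    dplyr::arrange(.data$.rank) |>
    dplyr::distinct(.data$protein_id, .data$go_term, .data$aspect,
                    .keep_all = TRUE) |>
    dplyr::select(-".rank") |>
    dplyr::arrange(.data$protein_id, .data$go_term)
}
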