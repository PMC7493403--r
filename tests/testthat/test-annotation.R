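test_that("self-alignment gives identity 100 and coverage 100", {
  seqc <- paste(rep(c("M", "K", "T", "A", "Y", "I", "W", "Q", "R", "L"), 5),
                collapse = "")
  a <- list(id = "A", sequence = seqc)
  hit <- align_pair(a, list(id = "B", sequence = seqc))
  expect_equal(hit$identity, 100)
  expect_equal(hit$coverage, 100)
  expect_equal(hit$alignment_length, 50)
})

test_that("identity matches a hand-counted forced-ungapped alignment", {
  # random 60-mer vs a copy with 30 interior substitutions; matched ends and
  # the alternating matches keep the local alignment ungapped and
  # full-length, so identity is exactly the substitution count.
  withr::with_seed(5, {
    base <- strsplit(submito:::random_sequence(60), "")[[1]]
    mutated <- base
    subs <- c(seq(2, 58, by = 2), 31)   # 30 positions, ends untouched
    mutated[subs] <- vapply(base[subs], function(a) {
      sample(setdiff(submito:::PSSM_RESIDUES, a), 1)
    }, character(1))
    a <- list(id = "A", sequence = paste(base, collapse = ""))
    b <- list(id = "B", sequence = paste(mutated, collapse = ""))
    hit <- align_pair(a, b)
    expect_equal(hit$alignment_length, 60)
    expect_equal(hit$identity, 30 / 60 * 100)
    expect_equal(hit$coverage, 100)
  })
})

test_that("unrelated random sequences fall below both thresholds", {
  withr::with_seed(11, {
    a <- list(id = "A", sequence = submito:::random_sequence(100))
    b <- list(id = "B", sequence = submito:::random_sequence(100))
    hit <- align_pair(a, b)
    expect_true(hit$identity <= 40 || hit$coverage < 90)
  })
})

test_that("single linkage takes the transitive closure of qualifying hits", {
  records <- tibble::tibble(id = c("A", "B", "C", "D"),
                            sequence = rep("MKT", 4))
  hits <- tibble::tibble(
    id_a = c("A", "B", "A", "A", "B", "C"),
    id_b = c("B", "C", "C", "D", "D", "D"),
    identity = c(80, 75, 10, 10, 10, 10),
    coverage = c(95, 95, 95, 95, 95, 95),
    alignment_length = 3L
  )
  cl <- build_clusters(records, hits = hits)
  expect_equal(cl$cluster_id[1:3], rep(cl$cluster_id[1], 3))  # {A,B,C}
  expect_true(cl$singleton[cl$protein_id == "D"])
  # partition: every id exactly once
  expect_setequal(cl$protein_id, records$id)

  # boundary semantics: identity exactly 40 is NOT enough; coverage 90 is
  hits$identity <- c(40, 40, 10, 10, 10, 10)
  cl40 <- build_clusters(records, hits = hits)
  expect_true(all(cl40$singleton))
  hits$identity[1] <- 40.0001
  hits$coverage[1] <- 90
  cl_edge <- build_clusters(records, hits = hits)
  expect_false(cl_edge$singleton[1])

  expect_error(build_clusters(tibble::tibble(id = c("A", "A"),
                                             sequence = c("MK", "MK"))),
               "duplicate")
})

test_that("planted families are recovered and random sequences stay singletons", {
  world <- generate_go_world(n_clusters = 3, cluster_size = 4,
                             background_size = 5, seed = 13)
  cl <- build_clusters(world$records)
  merged <- dplyr::left_join(cl, world$records, by = c(protein_id = "id"))
  fam_clusters <- merged |>
    dplyr::filter(!is.na(family)) |>
    dplyr::distinct(family, cluster_id)
  expect_equal(nrow(fam_clusters), 3)                 # one cluster per family
  expect_equal(dplyr::n_distinct(fam_clusters$cluster_id), 3)
  expect_true(all(merged$singleton[is.na(merged$family)]))
})

test_that("enrichment p-values match the exhaustive hypergeometric oracle", {
  # the textbook case: term in all 5 members of a 5-cluster, absent in the
  # other 95 of a 100-protein background -> p = 1 / C(100, 5)
  members <- sprintf("M%d", 1:5)
  background <- c(members, sprintf("B%d", 1:95))
  ann <- tibble::tibble(
    protein_id = members, go_term = "GO:0000001", aspect = "BP",
    evidence = "IDA", source = "GOA_manual"
  )
  res <- enrich_cluster(members, ann, background_ids = background)
  expect_equal(res$p_value, 1 / choose(100, 5), tolerance = 1e-12)
  expect_equal(res$k, 5L); expect_equal(res$K, 5L)
  expect_equal(res$n, 5L); expect_equal(res$N, 100L)
  expect_true(res$significant)

  # exhaustive oracle over all 2x2 tables with N <= 30
  for (N in c(5, 12, 30)) {
    for (n in 1:(N - 1)) {
      for (K in 1:N) {
        for (k in 1:min(n, K)) {
          expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                       hyper_tail_oracle(k, K, N, n), tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("uniform terms are not significant and Bonferroni divides by terms tested", {
  members <- sprintf("M%d", 1:10)
  background <- c(members, sprintf("B%d", 1:90))
  # same 50% frequency inside and outside
  carriers <- c(members[1:5], sprintf("B%d", 1:45))
  ann <- tibble::tibble(protein_id = carriers, go_term = "GO:0000002",
                        aspect = "BP", evidence = "IEA", source = "GOA_IEA")
  res <- enrich_cluster(members, ann, background_ids = background)
  expect_gt(res$p_value, 0.5)
  expect_false(res$significant)

  # Bonferroni arithmetic: raw p 0.005 with 10 terms tested is not significant
  expect_false(0.005 <= 0.01 / 10)
  withr::with_seed(3, {
    many <- dplyr::bind_rows(lapply(1:10, function(i) {
      tibble::tibble(protein_id = sample(background, 40),
                     go_term = sprintf("GO:%07d", i), aspect = "BP",
                     evidence = "IEA", source = "GOA_IEA")
    }))
    res10 <- enrich_cluster(members, many, background_ids = background)
    expect_equal(unique(res10$n_terms_tested), 10L)
    expect_equal(res10$significant, res10$p_value <= 0.01 / 10)
  })

  expect_error(enrich_cluster(members, ann, background_ids = character(0)),
               "background")
})

test_that("transfer adds significant terms only to unannotated members", {
  members <- c("M1", "M2", "M3", "M4")
  ann <- tibble::tibble(protein_id = c("M1", "M2"), go_term = "GO:0000001",
                        aspect = "BP", evidence = "IDA", source = "GOA_manual")
  enriched <- tibble::tibble(go_term = "GO:0000001", aspect = "BP",
                             k = 2L, n = 4L, K = 2L, N = 50L,
                             p_value = 1e-5, n_terms_tested = 1L,
                             significant = TRUE)
  new <- transfer_annotations(members, enriched, ann)
  expect_equal(new$protein_id, c("M3", "M4"))
  expect_true(all(new$source == "BAR"))
  # no duplicates against existing annotations
  expect_equal(nrow(dplyr::inner_join(new, ann,
                                      by = c("protein_id", "go_term"))), 0)

  none <- transfer_annotations(members, dplyr::mutate(enriched,
                                                      significant = FALSE),
                               ann)
  expect_equal(nrow(none), 0)
})

test_that("evidence-quality merge keeps the best-ranked duplicate", {
  manual <- tibble::tibble(protein_id = "P1", go_term = "GO:0000001",
                           aspect = "BP", evidence = "IDA",
                           source = "GOA_manual")
  iea <- dplyr::mutate(manual, evidence = "IEA", source = "GOA_IEA")
  bar <- dplyr::mutate(manual, evidence = "ISS", source = "BAR")

  m1 <- merge_annotations(manual, iea, bar)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$source, "GOA_manual")

  m2 <- merge_annotations(iea, bar)
  expect_equal(m2$source, "GOA_IEA")

  disjoint <- merge_annotations(
    manual, dplyr::mutate(bar, go_term = "GO:0000009"))
  expect_equal(nrow(disjoint), 2)

  expect_error(merge_annotations(dplyr::mutate(bar, source = "PDB")),
               "unknown annotation source")
})

test_that("merged output never exceeds the pooled size and keeps all proteins", {
  withr::with_seed(29, {
    pool1 <- tibble::tibble(
      protein_id = sample(sprintf("P%d", 1:10), 30, replace = TRUE),
      go_term = sample(sprintf("GO:%07d", 1:5), 30, replace = TRUE),
      aspect = "MF", evidence = "IEA", source = "GOA_IEA"
    )
    pool2 <- dplyr::mutate(pool1[1:10, ], source = "BAR", evidence = "ISS")
    merged <- merge_annotations(pool1, pool2)
    expect_lte(nrow(merged), nrow(pool1) + nrow(pool2))
    expect_setequal(unique(merged$protein_id), unique(pool1$protein_id))
    expect_equal(nrow(merged),
                 nrow(dplyr::distinct(merged, protein_id, go_term, aspect)))
  })
})
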