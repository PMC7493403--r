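# End-to-end pipeline over the stages simulate -> encode -> train ->
# predict -> evaluate -> screen -> annotate. One global seed fans out to
# per-stage seeds by fixed offsets so each stage is individually
# reproducible; every stage writes a manifest (input/output checksums,
# config hash, stage seed) next to its artifacts.

PIPELINE_STAGES <- c("simulate", "encode", "train", "predict", "evaluate",
                     "screen", "annotate")

#' Pipeline run configuration
#'
#' Aggregates the stage settings and the method thresholds (identity 40,
#' coverage 90, significance level 0.01) with a single global seed.
#'
#' @param output_dir Directory receiving all artifacts.
#' @param synthetic [synthetic_spec()] for the simulate stage.
#' @param model [model_config()] for the network.
#' @param train [train_config()] for training.
#' @param go_world Named list of [generate_go_world()] arguments.
#' @param identity,coverage Clustering thresholds in percent.
#' @param alpha Enrichment significance level.
#' @param seed Global seed; stages derive their own seeds from it.
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir = "submito-run",
                       synthetic = synthetic_spec(),
                       model = model_config(),
                       train = train_config(),
                       go_world = list(),
                       identity = 40, coverage = 90, alpha = 0.01,
                       seed = 1) {
  if (identity < 0 || identity > 100) {
    stop("identity threshold must be in [0, 100]", call. = FALSE)
  }
  if (coverage < 0 || coverage > 100) {
    stop("coverage threshold must be in [0, 100]", call. = FALSE)
  }
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  structure(
    list(output_dir = output_dir, synthetic = synthetic, model = model,
         train = train, go_world = go_world, identity = identity,
         coverage = coverage, alpha = alpha, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Serialize / restore a run configuration as JSON
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   the restored `run_config` (round-trips with the writer).
#' @export
write_run_config <- function(config, path) {
  out <- unclass_deep(config)
  out$synthetic$motifs <- as.list(out$synthetic$motifs)  # keep names in JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- raw$synthetic
  run_config(
    output_dir = raw$output_dir,
    synthetic = synthetic_spec(
      n_per_class = syn$n_per_class, length_range = syn$length_range,
      motifs = unlist(syn$motifs), substitution_rate = syn$substitution_rate,
      pssm_noise = syn$pssm_noise, seed = syn$seed
    ),
    model = do.call(model_config,
                    raw$model[setdiff(names(raw$model), "n_channels")]),
    train = do.call(train_config, raw$train),
    go_world = raw$go_world %||% list(),
    identity = raw$identity, coverage = raw$coverage, alpha = raw$alpha,
    seed = raw$seed
  )
}

pipeline_paths <- function(config) {
  d <- config$output_dir
  list(
    fasta = file.path(d, "proteins.fasta"),
    pssm_dir = file.path(d, "pssms"),
    labels = file.path(d, "labels.tsv"),
    votes = file.path(d, "votes.tsv"),
    go_fasta = file.path(d, "go_proteins.fasta"),
    go_annotations = file.path(d, "go_annotations.tsv"),
    go_truth = file.path(d, "go_truth.tsv"),
    encoded = file.path(d, "encoded.rds"),
    model = file.path(d, "model.rds"),
    history = file.path(d, "history.tsv"),
    predictions = file.path(d, "predictions.tsv"),
    confusion = file.path(d, "confusion.tsv"),
    mcc = file.path(d, "mcc_report.tsv"),
    decisions = file.path(d, "decisions.tsv"),
    rejects = file.path(d, "rejects.tsv"),
    clusters = file.path(d, "clusters.tsv"),
    enrichment = file.path(d, "enrichment.tsv"),
    transferred = file.path(d, "transferred.tsv"),
    merged = file.path(d, "merged.tsv")
  )
}

require_inputs <- function(paths, stage_needed) {
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing) > 0) {
    stop("missing input artifact ", unlist(missing)[1], "; run stage '",
         stage_needed, "' first", call. = FALSE)
  }
  invisible(TRUE)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, stage, seed, inputs, outputs) {
  md5_of <- function(paths) {
    paths <- unlist(paths)
    if (length(paths) == 0) return(setNames(list(), character()))
    as.list(tools::md5sum(paths))
  }
  manifest <- list(
    stage = stage, seed = seed, config_md5 = config_hash(config),
    inputs = md5_of(inputs), outputs = md5_of(outputs)
  )
  path <- file.path(config$output_dir, paste0(stage, ".manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

stage_seed <- function(config, stage) {
  config$seed + 10L * match(stage, PIPELINE_STAGES)
}

#' Run the pipeline
#'
#' Executes the requested stages in canonical order. Each stage reads only
#' declared artifacts of earlier stages, writes its outputs under the
#' configured output directory and records a manifest. Deterministic stages
#' are byte-identical on rerun with an unchanged configuration.
#'
#' @param config A [run_config()].
#' @param stages Subset of
#'   `c("simulate", "encode", "train", "predict", "evaluate", "screen",
#'   "annotate")`; defaults to all.
#' @return Invisibly, the list of stage manifests.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- pipeline_paths(config)
  manifests <- list()

  for (stage in stages) {
    seed <- stage_seed(config, stage)
    manifests[[stage]] <- switch(
      stage,
      simulate = stage_simulate(config, p, seed),
      encode = stage_encode(config, p, seed),
      train = stage_train(config, p, seed),
      predict = stage_predict(config, p, seed),
      evaluate = stage_evaluate(config, p, seed),
      screen = stage_screen(config, p, seed),
      annotate = stage_annotate(config, p, seed)
    )
  }
  invisible(manifests)
}

stage_simulate <- function(config, p, seed) {
  withr::with_seed(seed, {
    proteome <- generate_proteome(config$synthetic, seed = NULL)
    write_fasta(proteome, p$fasta)
    readr::write_tsv(proteome[c("id", "label")], p$labels)
    dir.create(p$pssm_dir, showWarnings = FALSE)
    purrr::walk(seq_len(nrow(proteome)), function(i) {
      prof <- generate_pssm(proteome[i, ], noise = config$synthetic$pssm_noise,
                            seed = NULL)
      write_pssm(prof, file.path(p$pssm_dir, paste0(proteome$id[i], ".pssm")))
    })
    votes <- generate_votes(proteome$id, seed = NULL)
    write_votes(votes$votes, p$votes)
    world <- do.call(generate_go_world, c(config$go_world, list(seed = NULL)))
    write_fasta(world$records, p$go_fasta)
    write_go_table(world$annotations, p$go_annotations)
    readr::write_tsv(world$truth, p$go_truth)
  })
  write_manifest(config, "simulate", seed, list(),
                 list(p$fasta, p$labels, p$votes, p$go_fasta,
                      p$go_annotations, p$go_truth))
}

stage_encode <- function(config, p, seed) {
  require_inputs(list(p$fasta), "simulate")
  records <- read_fasta(p$fasta)
  encoded <- encode_proteome(records, p$pssm_dir)
  saveRDS(encoded, p$encoded)
  write_manifest(config, "encode", seed, list(p$fasta), list(p$encoded))
}

stage_train <- function(config, p, seed) {
  require_inputs(list(p$encoded), "encode")
  require_inputs(list(p$labels), "simulate")
  encoded <- readRDS(p$encoded)
  labels_tbl <- readr::read_tsv(p$labels, col_types = "cc", progress = FALSE)
  labels <- labels_tbl$label[match(names(encoded), labels_tbl$id)]
  model <- build_model(config$model)
  model <- train(model, encoded, labels, config$train)
  save_model(model, p$model)
  readr::write_tsv(model$history, p$history)
  write_manifest(config, "train", seed, list(p$encoded, p$labels),
                 list(p$model, p$history))
}

stage_predict <- function(config, p, seed) {
  require_inputs(list(p$model), "train")
  require_inputs(list(p$encoded), "encode")
  model <- load_model(p$model)
  preds <- predict(model, readRDS(p$encoded))
  write_predictions(preds, p$predictions)
  write_manifest(config, "predict", seed, list(p$model, p$encoded),
                 list(p$predictions))
}

stage_evaluate <- function(config, p, seed) {
  require_inputs(list(p$predictions), "predict")
  require_inputs(list(p$labels), "simulate")
  preds <- read_predictions(p$predictions)
  labels_tbl <- readr::read_tsv(p$labels, col_types = "cc", progress = FALSE)
  cm <- confusion(preds, tibble(protein_id = labels_tbl$id,
                                label = labels_tbl$label))
  readr::write_tsv(as_tibble(as.data.frame(cm), rownames = "true"),
                   p$confusion)
  readr::write_tsv(mcc_by_class(cm), p$mcc)
  write_manifest(config, "evaluate", seed, list(p$predictions, p$labels),
                 list(p$confusion, p$mcc))
}

stage_screen <- function(config, p, seed) {
  require_inputs(list(p$votes), "simulate")
  screen <- screen_proteome(read_votes(p$votes))
  readr::write_tsv(screen$decisions, p$decisions)
  readr::write_tsv(screen$rejects, p$rejects)
  write_manifest(config, "screen", seed, list(p$votes),
                 list(p$decisions, p$rejects))
}

stage_annotate <- function(config, p, seed) {
  require_inputs(list(p$go_fasta, p$go_annotations), "simulate")
  records <- read_fasta(p$go_fasta)
  annotations <- read_go_table(p$go_annotations)
  clusters <- build_clusters(records, min_identity = config$identity,
                             min_coverage = config$coverage)
  enrichment <- enrich_clusters(clusters, annotations,
                                background_ids = records$id,
                                alpha = config$alpha)
  transferred <- enrichment |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::group_map(function(g, key) {
      members <- clusters$protein_id[clusters$cluster_id == key$cluster_id]
      transfer_annotations(members, g, annotations)
    }) |>
    dplyr::bind_rows()
  if (nrow(transferred) == 0) {
    transferred <- tibble(protein_id = character(), go_term = character(),
                          aspect = character(), evidence = character(),
                          source = character())
  }
  merged <- merge_annotations(annotations, transferred)
  readr::write_tsv(clusters, p$clusters)
  readr::write_tsv(enrichment, p$enrichment)
  readr::write_tsv(transferred, p$transferred)
  readr::write_tsv(merged, p$merged)
  write_manifest(config, "annotate", seed,
                 list(p$go_fasta, p$go_annotations),
                 list(p$clusters, p$enrichment, p$transferred, p$merged))
}
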