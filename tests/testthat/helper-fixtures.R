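# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except through the package's own writers.

write_toy_fasta <- function(path, records) {
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    c(paste0(">", records$id[i]), records$sequence[i])
  }))
  writeLines(lines, path)
  path
}

# A tiny labelled proteome with encodings, for model tests.
toy_training_set <- function(n_per_class = 10, seed = 42,
                             length_range = c(40, 60)) {
  spec <- synthetic_spec(n_per_class = n_per_class,
                         length_range = length_range, seed = seed)
  prot <- generate_proteome(spec)
  encoded <- withr::with_seed(seed + 1, {
    profs <- lapply(seq_len(nrow(prot)), function(i) {
      generate_pssm(prot[i, ], noise = spec$pssm_noise, seed = NULL)
    })
    names(profs) <- prot$id
    encode_proteome(prot, profs)
  })
  list(records = prot, encoded = encoded, labels = prot$label, spec = spec)
}

# Small architecture so model tests stay fast.
small_model_config <- function(seed = 1) {
  model_config(n_filters = 32, kernel_width = 19, n_hidden = 32, seed = seed)
}

# Random confusion matrix with total n.
random_cm <- function(n = 50) {
  matrix(as.integer(stats::rmultinom(1, n, rep(1 / 16, 16))), 4, 4,
         dimnames = list(compartment_levels(), compartment_levels()))
}

# Independent MCC oracle: Pearson correlation of one-vs-rest indicator
# vectors reconstructed from the confusion matrix.
mcc_pearson_oracle <- function(cm, class_index) {
  truth <- c()
  pred <- c()
  for (i in 1:4) for (j in 1:4) {
    cnt <- cm[i, j]
    if (cnt > 0) {
      truth <- c(truth, rep(i == class_index, cnt))
      pred <- c(pred, rep(j == class_index, cnt))
    }
  }
  if (length(unique(truth)) < 2 || length(unique(pred)) < 2) return(0)
  stats::cor(as.numeric(truth), as.numeric(pred))
}

# Independent hypergeometric upper-tail oracle by exhaustive enumeration.
hyper_tail_oracle <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
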