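# submito

Fine-grained annotation of mitochondrial proteomes in R. Mitochondria have
four internal compartments — outer membrane, inner membrane, intermembrane
space and matrix — and most proteins known to be mitochondrial carry no
annotation at this resolution. `submito` implements, end to end, the
computational stack used to close that gap:

* **Compartment predictor.** A 1D convolutional neural network over an
  L×30 sequence encoding (20 logistic-squashed PSSM channels from
  PSI-BLAST profiles + the 10 Kidera physico-chemical factors):
  256 filters of width 19 with length-preserving convolution, parallel
  global max/average pooling concatenated to 512 features, a 256-unit
  dense layer and a 4-way softmax. Forward pass, exact backpropagation and
  Adam training are implemented in base R matrix algebra.
* **Evaluation.** Per-compartment one-vs-rest Matthews correlation
  coefficient,
  MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
  with stratified k-fold cross-validation.
* **Mitochondrial discovery screen.** Combines boolean calls from three
  external localization tools (BUSCA, TargetP-2.0, MitoFates): a protein
  is called mitochondrial when at least two of three tools agree.
* **GO annotation transfer.** Single-linkage clustering of sequences
  sharing >40% identity over ≥90% coverage (exact Smith–Waterman,
  BLOSUM62, gap 11/1), per-cluster one-sided Fisher exact tests with
  Bonferroni correction at the 1% level, transfer of significant terms to
  unannotated members, and evidence-ranked merging
  (GOA manual > GOA IEA > transferred).
* **Synthetic data.** Generators for motif-planted labelled proteomes,
  sequence-consistent PSSMs, tool-vote tables and GO worlds with planted
  over-represented terms, so every stage runs and is tested without any
  external service.

All user-facing functions take and return tibbles, fitted objects have
`tidy()`/`glance()` methods and `autoplot()` views, and a pipeline driver
(`run_pipeline()`, CLI wrapper `inst/exec/submito-kit`) chains the stages
under a single seeded JSON configuration.

## Worked example

Train the network on a synthetic four-compartment proteome and score a
held-out set:

```r
library(submito)

spec  <- synthetic_spec(n_per_class = 10, length_range = c(60, 100))
prot  <- generate_proteome(spec, seed = 11)
profs <- lapply(seq_len(nrow(prot)), function(i)
  generate_pssm(prot[i, ], noise = 1, seed = 100 + i))
names(profs) <- prot$id
enc <- encode_proteome(prot, profs)

model <- train(build_model(model_config()), enc, prot$label,
               train_config(epochs = 20, seed = 3))
preds <- predict(model, enc)
cm    <- confusion(preds, tibble::tibble(protein_id = prot$id,
                                         label = prot$label))
mcc_by_class(cm)
#> # A tibble: 4 × 2
#>   class                 mcc
#>   <chr>               <dbl>
#> 1 outer_membrane          1
#> 2 inner_membrane          1
#> 3 intermembrane_space     1
#> 4 matrix                  1
```

Each row is the one-vs-rest MCC of one compartment on the scored set
(1 = perfect recovery of the planted class signal; 0 = chance). The
training trace is available as `tidy(model)` and `autoplot(model)`.

Annotation transfer on a synthetic GO world:

```r
world    <- generate_go_world(seed = 1)   # 3 planted families + background
clusters <- build_clusters(world$records)
enrich   <- enrich_clusters(clusters, world$annotations,
                            background_ids = world$records$id)
enrich[enrich$significant, c("cluster_id", "go_term", "k", "n", "p_value")]
#> # A tibble: 3 × 5
#>   cluster_id go_term        k     n      p_value
#>   <chr>      <chr>      <int> <int>        <dbl>
#> 1 C1         GO:0000001     7     8 0.000000251
#> 2 C2         GO:0000002     6     8 0.00000417
#> 3 C3         GO:0000003     7     8 0.0000000476
```

Exactly the three planted terms come back significant: `k` of the `n`
members of each recovered family carry the term, and the Bonferroni-
corrected hypergeometric tail p-value is far below the 1% level.

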