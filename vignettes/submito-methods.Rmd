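---
title: "Methods: sub-mitochondrial localization prediction and annotation transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sub-mitochondrial localization prediction and annotation transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Mitochondria are compartmentalized organelles: an outer membrane and an
inner membrane enclose the intermembrane space, and the inner membrane
encapsulates the matrix. Where a mitochondrial protein resides among these
four compartments constrains its function, yet most proteins annotated as
"mitochondrial" carry no sub-mitochondrial localization. `submito`
implements a complete toolkit for closing that gap at desk scale:

1. a four-compartment sequence-based predictor (a 1D convolutional neural
   network over profile + physico-chemical encodings);
2. per-class Matthews correlation coefficient (MCC) scoring with stratified
   cross-validation;
3. a two-out-of-three majority-vote screen that turns three external
   subcellular-localization calls into a mitochondrial discovery decision;
4. similarity-based Gene Ontology annotation transfer: identity/coverage
   clustering, per-cluster Fisher over-representation tests with Bonferroni
   correction, and evidence-ranked merging of annotation pools.

Synthetic generators for proteomes, profiles, vote tables and GO worlds
make every stage testable without any external database or web service.

# Input encoding

A protein of length $L$ is encoded as an $L \times 30$ real matrix.

**Profile channels (columns 1–20).** Evolutionary information enters as a
position-specific scoring matrix (PSSM): per-position integer log-odds for
the 20 residues, as produced by iterated profile search (the PSI-BLAST
ASCII dialect is parsed directly; only the log-odds block is used, the
weighted-percentage columns and per-row statistics are ignored). Raw
log-odds are unbounded, so they are squashed elementwise by the logistic
function $s(x) = 1/(1+e^{-x})$ into $(0,1)$. The squashing function is a
design choice of this package: it is the standard convention for
profile-fed networks, strictly monotone (score order is preserved), and
configurable in principle by swapping `scale_pssm()`.

**Physico-chemical channels (columns 21–30).** Each residue contributes the
ten Kidera factors — orthogonalized summaries of 188 amino-acid properties,
approximately zero-mean and unit-variance across the 20 residues. The table
ships as the packaged constant `kidera_factors` (Kidera et al., *J Protein
Chem* 4:23–55, 1985). Non-standard letters (X, B, Z, U, O) receive the
all-zero vector: a deterministic, physico-chemically neutral treatment;
their profile rows are used as parsed. Channel order (profile first, Kidera
second) is recorded in every encoded matrix and model checkpoint so
encoder/model compatibility is checkable.

# The network

The predictor maps the $L \times 30$ encoding to four class probabilities:

* **Convolution.** 256 filters of width 19 scan the sequence with stride 1
  and symmetric zero padding of 9 rows, so the feature map has exactly $L$
  rows per filter ($L \times 256$ overall). ReLU activation.
* **Global pooling.** For each filter, the maximum and the mean over the
  $L$ positions are computed in parallel and concatenated into a vector of
  $2 \times 256 = 512$ values. Pooling removes $L$, making the architecture
  length-agnostic (any $L \ge 1$ is valid; no truncation or length cap is
  imposed).
* **Classifier.** A dense ReLU layer of 256 units feeds a 4-way softmax.
  The predicted compartment is the argmax; exact ties resolve to the lowest
  class index (outer membrane < inner membrane < intermembrane space <
  matrix), which makes inference deterministic.

The forward and backward passes are written directly in R as BLAS matrix
products over an im2col expansion of the input; gradients are exact (the
max-pool gradient routes to the argmax position, the average-pool gradient
spreads $1/L$ over the true length) and are verified against finite
differences in the test suite.

## Training

Hyper-parameters are deliberately the conventional choices for an
architecture of this size, exposed through `train_config()`:

| parameter | default | rationale |
|---|---|---|
| loss | categorical cross-entropy | standard for softmax classifiers |
| optimizer | Adam, learning rate $10^{-3}$ | robust default for small CNNs |
| epochs | 100 | ample for desk-scale sets |
| batch size | 16 | stable gradients at small $n$ |
| class weights | inverse frequency | curated localization sets are skewed toward the inner membrane; weighting protects the intermembrane space, the smallest class |

Within a mini-batch the proteins' im2col matrices are stacked so the
convolution runs as one matrix product; pooling statistics are always taken
at each protein's true length, so padding never enters any statistic. Early
stopping on a stratified validation slice is available
(`validation_split`, `patience`) but off by default: the package prefers a
fixed, fully deterministic epoch count for its reference experiments, and
the separable synthetic task converges long before 100 epochs. With a fixed
seed the loss trace is reproducible run-to-run on the same platform.

Multi-localized proteins are outside the label space: the predictor scores
proteins with a single-compartment annotation only.

# Evaluation

Performance is scored per compartment by one-vs-rest MCC from the 4-way
confusion matrix:

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}$$

MCC is used because it is robust to the strong class imbalance of
sub-mitochondrial data. A zero denominator (an empty margin) returns 0 by
the usual convention, which keeps whole-table reports total. The test suite
checks the implementation against an independent oracle — the Pearson
correlation of the binarized indicator vectors, to which MCC is
algebraically equal — on a thousand random confusion matrices.

`cross_validate()` performs stratified k-fold cross-validation (each class
split as evenly as possible, shuffled under a seed); the pooled confusion
matrix is the sum of the fold matrices and per-class MCCs are computed from
it. One-vs-rest per compartment is the standard reading of per-compartment
MCC reporting and is the interpretation adopted here.

# The mitochondrial discovery screen

Proteins lacking any localization annotation can be screened with three
external predictors (BUSCA, TargetP-2.0, MitoFates). Their outputs are
consumed as pre-tabulated booleans — "predicted compartment equals
mitochondrion" — because the tools themselves are web services or binaries
outside this package; for BUSCA's multi-compartment output the binary
adapter follows the literal rule that any compartment other than
mitochondrion counts as a negative vote. A protein is called mitochondrial
when **at least two of the three** tools agree. Proteins with fewer than
three votes are excluded and reported, never imputed: the rule is defined
on complete vote triples. The decision is monotone (flipping a vote to
positive can never withdraw a positive call) and order-independent.

# Annotation transfer

Functional annotation follows the cluster-and-transfer strategy:

1. **Clustering.** All-against-all local alignment (Smith–Waterman under
   BLOSUM62, gap open 11 / extend 1 — the classical BLAST defaults; exact
   alignment replaces the heuristic since inputs are desk-scale, and the
   thresholds, not the engine, define the method). An edge joins two
   sequences when identity is **strictly greater than 40%** over a coverage
   of **at least 90%** — the strict/inclusive split mirrors the defining
   phrases "more than 40%" and "at least 90%". Identity is identities
   divided by alignment columns; coverage is alignment columns divided by
   the length of the *shorter* sequence, the strictest symmetric reading of
   an ambiguous convention (configurable). Clusters are connected
   components (single linkage); everything else is a singleton.
2. **Enrichment.** For each term observed in a cluster of size $n$ within a
   background of $N$ proteins, with $k$ members and $K$ background proteins
   carrying the term, the one-sided Fisher exact p-value is the
   hypergeometric tail $P(X \ge k)$. The test is one-sided because only
   over-represented terms are transferred. The Bonferroni divisor is the
   number of terms tested *in that cluster* (the natural per-cluster
   reading; a global divisor is a one-line change) and the significance
   level is 1%. No minimum number of annotated members is imposed beyond
   $k \ge 1$.
3. **Transfer.** Each significant term is assigned to every cluster member
   not already carrying it, with source `BAR` and evidence `ISS`. Transfer
   never removes or duplicates an existing annotation.
4. **Merging.** Identical (protein, term, aspect) annotations from
   different pools collapse to the entry with the best evidence under the
   strict three-tier ranking `GOA_manual` > `GOA_IEA` > `BAR` (manually
   reviewed beats electronically inferred beats transferred). Finer
   evidence-code orderings are out of scope.

Only the BP and MF aspects are supported, matching the functional
characterization the toolkit targets; tables with other aspects are
rejected at parse time.

# Synthetic data: what it emulates, and what not

The generators define the package's reference study conditions:

* `generate_proteome()` — four compartments, default **60 proteins per
  class**, lengths uniform in **60–120** residues over a uniform background
  alphabet, one distinct 11-mer consensus motif per compartment embedded at
  a random position and mutated at a **10%** per-position substitution
  rate. The class signal is motif-based rather than composition-based on
  purpose: an 11-mer sits inside the width-19 filters, so learning the task
  directly probes the convolutional layer. Held-out evaluation uses an
  independently generated set of 30 proteins per class.
* `generate_pssm()` — profiles consistent with their sequences: +7 log-odds
  on the observed residue, $-3 + \mathcal{N}(0, \sigma)$ elsewhere
  (default $\sigma = 1$), rounded to integers and written through the ASCII
  writer so parser round-trips are exercised.
* `generate_votes()` — a latent mitochondrial status per protein
  (prevalence 0.5) reported correctly by each tool with probability 0.9.
* `generate_go_world()` — 3 sequence families of 8 members (a founder
  point-mutated at 10%) over 200 unrelated background sequences; one
  planted term per family annotated at frequency **0.9 inside / 0.05
  outside**, plus 5 decoy terms at a uniform 0.1. The wide frequency gap
  makes the planted terms decisively significant while decoys stay below
  the per-cluster Bonferroni threshold.

All generators are pure functions of their seed. What the synthetic world
does *not* emulate: real targeting peptides and sorting signals, natural
residue composition (a natural-frequency background is configurable),
homology structure between compartments, noisy or missing experimental
labels, and the evidence heterogeneity of real GO annotation sets. Passing
tests therefore demonstrate that the implementation is correct and that the
architecture can extract localized sequence signals — not that the default
weights would perform on real proteomes, which require real PSSMs and
curated training data.

# Numerical choices and degenerate inputs

* Logistic squashing keeps profile channels strictly inside (0,1); integer
  log-odds never saturate to exactly 0 or 1.
* Softmax is computed with max subtraction; probabilities sum to 1 within
  1e-6 (asserted at predict time).
* MCC returns 0 on zero denominators; enrichment requires a non-empty
  background containing the cluster.
* Argmax ties (prediction and max-pool routing) resolve to the first index.
* Training rejects empty or single-class data; cross-validation refuses a
  class with fewer members than folds and says to use fewer folds.
* Sequences of length 1 encode and predict correctly (padding handles
  kernels wider than the input).
* Reference problem sizes (240 training proteins, 100 epochs, 224-sequence
  GO world) were chosen so the full reference experiments run in minutes on
  a single CPU.

# The pipeline

`run_pipeline()` chains simulate → encode → train → predict → evaluate →
screen → annotate under one `run_config()` (thresholds default to identity
40, coverage 90, alpha 0.01). One global seed fans out to per-stage seeds
by fixed offsets, so any stage can be rerun individually and
deterministically; each stage writes a JSON manifest with input/output
checksums and the config hash. A thin command-line wrapper,
`inst/exec/submito-kit`, exposes the stages as subcommands over a JSON
configuration.

# Known limitations

* The trained weights of the original published predictor are not
  reproduced; the package trains from scratch on user or synthetic data.
* The predictor's training hyper-parameters are documented assumptions, not
  published values.
* Single-label classification only; multi-localized proteins must be
  handled upstream.
* The annotation-transfer stage scales quadratically in the number of
  sequences (exact all-against-all alignment) and is intended for
  desk-scale inputs, not 28-million-sequence databases.
* GO-graph ancestor propagation and domain-based transfer are out of scope.
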