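---
title: "Methods: embedding-based KO annotation"
author: "koannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: embedding-based KO annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koannot)
```

## The problem and the model

KEGG Orthology (KO) identifiers — K numbers such as `K02030` — label
functional ortholog groups of proteins. Assigning a K number to an
uncharacterized bacterial protein sequence is classically done by sequence
search (BLAST-family tools, profile HMMs). `koannot` implements an
alternative two-stage pipeline built on protein-sequence embeddings:

1. **Gate.** A binary classifier over a fixed-dimension embedding of the
   sequence decides KO vs non-KO. Only sequences called KO proceed.
2. **Transfer.** The gated sequence's embedding is compared to an annotated
   reference set under Euclidean distance
   $d(x,y)=\sqrt{\sum_i (x_i-y_i)^2}$; the K number(s) of the nearest
   reference are transferred. If several references are exactly tied at the
   minimum distance with different K numbers, all are reported.

The premise is that a good protein language model places functional
relatives close together in embedding space even at low sequence identity,
so nearest-neighbour transfer can recognize distant relatives that
alignment-based search misses.

The package treats the embedder as a pluggable contract
(`embedder_spec()`): a deterministic mock embedder runs everywhere at desk
scale, and a pre-trained protein language model can be plugged in behind
the same interface (`plm_fun`, returning per-residue hidden states) without
changing any downstream code.

## Dataset construction rules

`build_dataset()` composes the data-preparation rules used to train and
evaluate the gate:

* **Length filter** (`filter_by_length()`): keep sequences with
  $100 \le L \le 600$ residues (both defaults configurable). Boundary
  lengths are retained; only strictly shorter/longer sequences are removed.
* **Undefined residues** (`remove_undefined()`): drop sequences containing
  letters outside the 20 standard codes (X, B, Z, U, O, J, ...).
* **De-duplication** (`deduplicate()`): one record per distinct sequence.
  When copies disagree in annotation, the union of K numbers is kept, so an
  annotated copy always beats an unannotated one. Keeping the union (rather
  than picking one K number) is lossless and deterministic; downstream
  evaluation treats truth as a set and scores a match on any overlap, which
  reduces exactly to K-number identity for singleton sets.
* **Length-distribution balance** (`check_length_balance()`,
  `rebalance_by_downsampling()`): to avoid length bias in the gate, the KO
  and non-KO length distributions are compared on consecutive 50-residue
  bins; the deviation statistic is the maximum over bins of the absolute
  difference of the two classes' bin proportions, and the check passes
  below 0.05. These choices (per-bin max-absolute-difference, bin width 50)
  are this package's concrete definitions of "consistent length
  distributions"; the balancing mechanism is uniform seeded down-sampling
  of the over-represented class in the worst bin, with the removal count
  solved in closed form from the current totals, iterated to convergence.
  A bin populated in only one class cannot be balanced and raises an error
  naming the bin.
* **Split** (`split_train_test()`): seeded uniform shuffle, train fraction
  0.8 (floor), exact partition. The split is not stratified by label or
  species.
* **Held-out species** (`exclude_species()`): drops records by organism
  prefix and any record whose sequence is identical to a dropped one —
  the protocol for evaluating on whole held-out genomes.

All randomness is seeded; each operation derives its own named stream from
the configured seed via a string hash, so operations are individually
reproducible and order-independent.

## The classifier

The production gate (`architecture = "mlp"`) is a multilayer perceptron
over sequence embeddings: two fully connected layers with hidden size 100,
rectified-linear activation, and a logistic output scoring KO membership
in $[0,1]$. A sequence is called KO when its score is strictly greater
than the decision threshold (default 0.5; a score exactly at the threshold
is non-KO).

Training (`train_classifier()`) uses binary cross-entropy loss and the
Adam optimizer, with 20% of the training data held out as a validation
set. Early stopping halts training after `patience` (default 5) epochs
without validation-loss improvement and restores the best-on-validation
parameter snapshot. Batch size (32), learning rate (1e-3) and the epoch
budget (100) are conventional defaults exposed in
`classifier_config()`. The forward/backward passes and the optimizer are
implemented in plain R (`R/nn.R`): the models are small and desk-scale by
design, and an explicit implementation keeps training bit-reproducible
from the seed.

Two baseline architectures are included for comparison, operating on
integer-encoded sequences (amino acids mapped 1–20 in alphabetical
one-letter order, zero-padded to 600): a 128-dimensional token embedding,
a 1-D convolution with 64 filters (kernel 3, stride 1), global temporal
max pooling, then either an LSTM layer with 100 units or a single
attention layer, and a logistic output. Because the pooling is global, the
recurrent/attention stage receives a single pooled vector (one LSTM cell
step; attention over one token reduces to its value projection) — a
deliberate simplification: these baselines exist to be compared against,
and the MLP path is the supported production path.

Classifier quality is summarized by `classifier_metrics()`:
$\mathrm{precision}^* = TP/(TP+FP)$, $\mathrm{recall}^* = TP/(TP+FN)$ and
their harmonic mean $F_1^*$ (starred to distinguish them from the
pipeline-level metrics below). A metric with a zero denominator is
reported `NaN`; when precision\* and recall\* are both zero, $F_1^*$ is 0
by the limit convention.

## Nearest-neighbour annotation transfer

`build_index()` validates an annotated reference set (every reference must
carry at least one K number); `assign_ko()` performs exact, exhaustive
nearest-neighbour search — no approximate indexing in the default path —
and reports every reference within `tie_tol` of the minimum distance
(default 0, i.e. exact ties only; exact ties are vanishingly rare for
real-valued embeddings but the reporting contract is kept explicit).
`assign_with_threshold()` is the classifier-free variant: a query whose
minimum distance exceeds the threshold is returned as an explicit
no-assignment and treated as non-KO. No default threshold is provided —
it is an additional hyperparameter that the gated pipeline avoids — so the
caller must choose one deliberately.

## Evaluation framework

Each evaluated sequence falls into one of five categories
(`categorize()`): **match** (prediction overlaps the truth K-number set),
**unmatch** (disjoint), **missed** (annotated but unpredicted), **added**
(predicted but unannotated), and **true negative** (neither), the last
excluded from all metrics. Pipeline metrics (`pipeline_metrics()`) are

$$\mathrm{Precision} = \frac{match}{match+unmatch+added}, \qquad
  \mathrm{Recall} = \frac{match}{match+unmatch+missed}, \qquad
  F_1 = \frac{2}{\mathrm{Recall}^{-1}+\mathrm{Precision}^{-1}}.$$

Values are kept at full precision and displayed at 3 decimals. The sum
$match+unmatch+missed$ equals the number of annotated sequences evaluated,
so it is invariant across tools compared on one truth set — a useful
consistency check on published comparison tables.

## Structural and sequence validation

**TM-score.** For a target/template pair with a residue correspondence,
`tm_score()` computes
$$\mathrm{TM} = \frac{1}{L_{target}} \sum_{i=1}^{L_{common}}
  \frac{1}{1+(d_i/d_0)^2}, \qquad
  d_0(L_{target}) = 1.24\sqrt[3]{L_{target}-15} - 1.8\ \text{Å},$$
with $d_0$ floored at 0.5 Å (the printed formula is negative for targets
shorter than about 27 residues; flooring follows common practice). The
maximization over superpositions is approximated by a least-squares Kabsch
fit on the correspondence followed by up to 5 rounds of re-weighting
(pairs with $d_i > 2 d_0$ are dropped from the fit, all pairs are always
scored), so the returned score is a lower bound on the true maximum. The
full structural-alignment search that produces correspondences (e.g.
circular-permutation-aware aligners) is out of scope: correspondences are
inputs. With fewer than three pairs a rigid fit is underdetermined; the
raw coordinate distances are then scored directly, with a warning.
Reported scores carry the conventional reading: $\ge 0.5$ similar
structural domains, $\ge 0.8$ highly similar structures.

**Percent identity.** `smith_waterman()` implements local alignment with
affine gaps (Gotoh dynamic programming; a length-$L$ gap costs
$open + L \cdot extend$, defaults BLOSUM62/10/0.5) with a deterministic
traceback tie-break: diagonal over gap-in-reference over gap-in-query.
"Identity" has no universal denominator; the default is identical columns
over all alignment columns (gaps included), with `min_length` and
`aligned_columns` as configurable alternatives. `identity_distribution()`
bins identities into ten-point classes, half-open except the closed top
bin $[90, 100]$.

## The synthetic generators, and what passing tests show

The package is testable offline because three generators emulate the
statistical structure the pipeline assumes of real data:

* `make_sequences()`: KO families as point-mutant clouds (5% per-site
  substitutions, no indels) around random ancestors, plus i.i.d. random
  non-KO sequences; optional injection of undefined letters and exact
  duplicates at known rates, so filter behaviour is exactly predictable.
* `make_embedding_clusters()`: one centroid per family with isotropic
  within-family noise ($\sigma = 0.5$, centroid separation 10 — a
  separation-to-noise ratio of 20), and non-KO queries placed at least
  three separations from every centroid.
* `make_toy_structures()`: extended 3-D chains with exact 3.8 Å bonds;
  templates are rigid motions plus optional Gaussian jitter, with identity
  correspondence.

The mock embedder hashes each overlapping k-mer (default $k=3$) to a fixed
unit direction (a seeded string hash with an avalanche finalizer, so
directions behave as independent unit vectors), sums the directions
covering each residue, and pools per-residue vectors (mean by default —
the conventional per-protein reduction for language-model hidden states —
with max/first as options). It gives relatives nearby embeddings and
strangers independent ones, which is precisely the premise the pipeline
needs — and nothing more. Passing tests therefore demonstrate the
*machinery* (exact nearest-neighbour search, correct metrics, faithful
training protocol, correct geometry) under the assumed structure; they say
nothing about how well a real protein language model separates KO from
non-KO sequences, which is an empirical property of the model and data.

Sizes used by the test suite and surrogate checks (chosen to keep every
property sharp at desk scale): 200 queries against 100 references for the
search oracle; 20 families × 20 members for label recovery; 400 points in
64 dimensions for the two-Gaussian classifier check; 50 random 30-residue
pairs for the alignment oracle.

## Numerical and degenerate-input conventions

* Distances, scores and metrics are computed in double precision and never
  display-rounded internally; rounding to 3 decimals happens only in
  printing and reporting.
* `classifier_metrics()` / `pipeline_metrics()`: zero numerators with
  positive denominators give 0; zero denominators give `NaN`/`NA`.
* Kabsch superposition requires three point pairs; near-collinear sets
  produce a warning and a best-effort fit (the SVD sign correction keeps
  the rotation proper, determinant +1).
* Tie-breaks are deterministic everywhere: first-encountered best cell and
  diagonal-first traceback in alignment; exact distance equality for
  assignment ties; first occurrence kept in de-duplication.
* Empty inputs: an empty FASTA reads as an empty list; an empty local
  alignment (best score 0) reports identity 0 over 0 columns; degenerate
  one-class training data is rejected with an error.

## Known limitations

* The real protein-language-model adapter is a contract, not a bundled
  model: no weights ship with the package, and mock-embedder results do
  not transfer quantitatively to any particular model.
* The LSTM/attention baselines use global pooled input to the recurrent
  stage (see above) and are not tuned; they are comparison scaffolding.
* TM-score is a documented lower-bound approximation for a *given*
  correspondence; it does not search alignments.
* The Smith-Waterman implementation is plain R and intended for
  validation-scale pairs (hundreds of residues), not proteome-scale
  search.
* Sequences longer than the configured maximum are out of scope for the
  classifier's padded encodings; handling long sequences would require a
  long-context embedder.
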