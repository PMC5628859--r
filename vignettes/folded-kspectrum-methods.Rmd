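---
title: "The folded k-spectrum kernel: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The folded k-spectrum kernel: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldkspec)
```

## The problem

Cis-regulatory modules (CRMs, enhancers) are non-coding DNA regions that bind
transcription factors (TFs) and regulate gene expression. Discriminating CRMs
from background DNA is commonly cast as binary sequence classification: an SVM
is trained on known regulatory sequences (positives) against composition-
matched background sequences (negatives), with each sequence represented by
its *k-spectrum* — the vector of occurrence frequencies of all `4^k`
contiguous k-mers.

Many TF binding sites, however, carry *gapped* nucleotide dependencies:
positions that covary while intervening bases are free. The binding sites
AACA, ACGA and AGTA share no informative contiguous 4-mer (any contiguous
4-mer matches at most one of them), yet the single gapped pattern `ANNA`
matches all three. A purely contiguous k-spectrum dilutes such a site across
many coordinates; a feature map that includes gapped k-mers concentrates it
in one.

## The model

### Dependency models (gap masks)

A dependency model over a k-mer is a binary pattern marking dependent
positions (1) versus gaps (0), written with position 1 as the most
significant bit; decimal 5 at `k = 3` is the pattern `101`, the features
`ANA ... TNT`. Masks with a trailing gap duplicate a shorter mask at a
shifted window offset, so only odd decimals are enumerated: exactly
`2^(k-1)` models, from the monomer model `N...Nx` (decimal 1) to the
contiguous model (decimal `2^k - 1`). The union of all models' features has
dimension

\[ N \;=\; \sum_{\text{models}} 4^{\mathrm{popcount}} \;=\; 4 \cdot 5^{k-1}, \]

i.e. 100 features at `k = 3` and 12,500 at the default `k = 6`.

### Relative-frequency normalization

Raw counts depend on sequence length and background composition. Each
contiguous k-mer count is therefore mapped to

\[ \phi_\alpha(\chi) \;=\; \frac{\#\alpha \text{ in } \chi}{|\chi| - k + 1}
   \Big/ \frac{\#\alpha \text{ in genome} + c}{|\text{genome}| - k + 1 + 4^k c}, \]

the frequency of the word in the sequence relative to its background
frequency. Two numerical choices:

* **Background source.** No genome assembly is bundled. By default the
  background model is built from the union of all training sequences
  (positives plus scrambled negatives), which preserves the intent —
  cancelling composition — while keeping the tool self-contained. A genome
  FASTA can be supplied instead.
* **Pseudocount.** Small backgrounds can assign a k-mer zero frequency,
  making the ratio undefined. A Laplace pseudocount `c` (default 1) is added
  to every background count. Setting `c = 0` reproduces the raw formula on
  large backgrounds; an observed word with zero background frequency is then
  an error, by design.
* **Windows containing N** count toward no word (neither sequence nor
  background), but the printed denominator `|χ| − k + 1` is kept as stated;
  the discrepancy is limited to degenerate inputs.

### Folding

Only the contiguous spectrum is ever counted. The value of a gapped feature
is the *unweighted sum* of the normalized contiguous features compatible
with it at its dependent positions, e.g.

\[ \phi_{ANA} = \phi_{AAA} + \phi_{ACA} + \phi_{AGA} + \phi_{ATA}. \]

Folding is a fixed linear map, precomputed once per `k` as a sparse 0/1
matrix with `4^k` rows and `N` columns, so featurizing a sequence set is one
matrix product. Note the order of operations: features are normalized
*before* folding — a gapped feature is a sum of normalized contiguous
frequencies, matching the identity above — not the background-normalized
direct gapped frequency (the two differ, since the gapped background
frequency is not the sum of the contiguous ones' denominators).

Folding raw counts is exactly equivalent to scanning the sequence with the
gapped pattern as a wildcard matcher; the test suite verifies this
coordinate-wise against an independent string scanner for random sequences at
`k ∈ {3, 4, 6}`.

### Classification

A soft-margin linear SVM is trained on the explicit feature vectors; because
the map is explicit, the linear kernel equals the folded k-spectrum kernel.
The quadratic program is delegated to libsvm (via **e1071**); the primal
weights are recovered as \(w = \sum_i y_i \alpha_i x_i\) and the decision
value of a sequence is \(f(x) = w^\top x + b\).

* **Cost parameter.** `C = 1` by default (unstated in the field's common
  practice for this setting; exposed as an argument).
* **No feature standardization.** The φ normalization already removes length
  and composition effects; standardization is available behind a flag.
* **Ties.** A decision value of exactly 0 is labeled −1 (conservative for
  the positive class).
* **Factorized-Gram solving.** With hundreds of sequences and `N = 12500`
  features, the dual QP depends on the data only through the n×n Gram matrix
  `K = XXᵀ`. When `n < N` the implementation eigendecomposes `K` and runs
  libsvm on `Z = UΛ^{1/2}` (so `ZZᵀ = K` exactly), then recovers `w =
  Xᵀ(α∘y)`. This is an exact reformulation of the same optimization problem
  — decision values agree with the direct solve to ~1e−9 — and makes
  repeated cross-validation roughly 20× faster since `K` is computed once
  per dataset and subset per fold.

## Enrichment, motif fragments, and false-discovery elimination

The enrichment score of feature `n` in a sequence is `r(n) = w(n)·x(n)`, its
additive contribution to the decision value (`Σ r(n) + b = f(x)`). Features
with `r` strictly above the cutoff (default 0.005) are "top-enriched"; per
sequence and per dependency model they are assembled into motif fragments
rendered like `(A/T)NT` and exportable as MEME-format position probability
matrices for comparison against a motif database with an external tool.

Composition alone can enrich features that are not binding sites. The
elimination procedure replaces each positive with its scrambled copies,
trains the same folded-kernel SVM on this "false positive" set, and records
the features enriched above the cutoff in each copy. A positive sequence's
scores are then zeroed at every feature whose *dependency model* was
implicated by its own copies (`by_model`, the default; `by_feature` zeroes
only exact feature matches and is strictly less aggressive). The surviving
selections, pooled over positives, form the high-confidence index set on
which the final SVM is refit.

Two design choices were genuinely open:

* **Negatives for the false-positive training.** The composition of this
  negative set is not prescribed by the procedure itself. The package
  scrambles each scrambled copy once more (one fresh scramble per copy),
  giving a balanced training set with the same null composition; the
  multiplicity is exposed (`n_neg_per_copy`).
* **Elimination granularity.** `by_model` follows the procedure's wording;
  on desk-scale data with few models (small `k`) it can implicate every
  model, in which case the fit warns and falls back to the unconstrained
  map rather than training on an empty feature set.

A hit table from an external motif-comparison run can refine the filter:
only false features whose fragment has a database hit with `p < 0.001` are
retained as false (a background pattern resembling a known motif is exactly
the spurious enrichment worth removing); the comparison tool itself is out
of scope.

## Cross-validation and group assignment

Evaluation uses stratified 10-fold cross-validation repeated (by default)
100 times with fresh random partitions, accumulating per-positive
false-negative (FN) call counts, per-repeat ROC and precision–recall curves,
and their average areas. Choices:

* **Scramble grouping.** All scrambled copies of a positive are assigned to
  the same fold as their parent. This is the conservative reading of
  stratified splitting: per-sequence composition never leaks between train
  and test.
* **Leak-free elimination.** When feature elimination runs inside CV, the
  filter and the surviving index set are derived from the training folds
  only, then applied to both train and test featurization.
* **Detection boundary.** A positive is "detected" unless its FN call rate
  strictly exceeds the cutoff: at 10% over 100 repeats, FN = 10 still counts
  as detected.
* **Groups.** Group 1 = detected by the folded kernel only; Group 2 =
  neither; Group 3 = both; the remainder (contiguous only) is tracked as
  Group 0 and expected empty, since contiguous features are a subset of the
  folded map.
* **Curves.** Threshold sweep over unique scores (ties share a threshold),
  trapezoidal integration for both AUC and AUCPR.

## The synthetic-data generator

`make_dataset()` emulates the study design: i.i.d. background sequences
(uniform composition by default) carrying non-overlapping planted motif
instances, each positive matched by 10 composition-preserving scrambled
negatives. A plant specification gives a consensus over `{A,C,G,T,N}` — `N`
positions keep the background base, the synthetic analogue of a gapped
dependency — a per-sequence plant count, and a per-dependent-position
substitution rate emulating binding-site degeneracy. The plant log records
every realized instance and is verified against a rescan of the output.

What the generator does *not* emulate: positional clustering and homotypic
site arrangements, dinucleotide background structure, repeats, flanking
context, and strandedness (plants are forward-strand only, as is the feature
map). Passing tests on this generator therefore demonstrate correctness of
the machinery and the qualitative advantage of the folded map on gapped
signals — not performance on real genomic data.

## Desk-scale study conditions

The packaged evaluation study (also run by `scripts/acceptance.R`) uses 25
positives of 500 bp with 8 planted instances each (about one site per 60 bp,
a realistic density for developmental CRMs), mutation rate 0.1, 10 scrambled
negatives per positive, `k = 6`, `C = 1`, 10-fold CV with one pass per
generator seed, and 10 generator seeds per motif type. The gapped consensus
`GANNTC` (dependency model `110011`, decimal 51) tests recovery of a gapped
dependency; `GACGTC` is the contiguous control of identical composition.
Under these conditions the folded kernel's mean AUC exceeds the contiguous
kernel's on gapped plants (≈0.89 vs ≈0.78), the planted mask ranks among the
top models by maximum feature weight, and on contiguous plants the two
kernels agree to well within 0.02.

## Known limitations

* Forward strand only; no reverse-complement canonicalization.
* `k ≤ 8` for the materialized feature space (memory grows as `4·5^(k-1)`).
* The false-discovery filter is aggressive on small datasets in `by_model`
  mode (few models at small `k`; few sequences inflate per-parent unions).
* Decision-threshold classification (sign of `f`) is sensitive to the 1:10
  class imbalance; ranking metrics (AUC/AUCPR) are the primary readout.
* The motif-database comparison step consumes a precomputed hit table; no
  database or comparison tool is bundled.
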