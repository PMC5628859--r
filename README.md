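# foldkspec

SVM classification of regulatory DNA sequences with the **folded k-spectrum
kernel**: an explicit feature map over *all* gapped k-mer dependency models,
for detecting transcription-factor binding sites whose informative positions
are non-adjacent.

## The problem

Enhancers (cis-regulatory modules, CRMs) are non-coding regions bound by
transcription factors. Classical spectrum-kernel SVMs represent a sequence by
the frequencies of its contiguous k-mers, but many binding sites carry
*gapped* dependencies: the sites `AACA`, `ACGA`, `AGTA` share no informative
contiguous 4-mer, while the single gapped pattern `ANNA` matches all three.

`foldkspec` extends the k-spectrum with every dependency model over k
positions. A model is a binary mask (1 = dependent base, 0 = gap, written
MSB-first, so decimal 5 at k = 3 is `101` = patterns `ANA ... TNT`); masks
with trailing gaps duplicate shorter masks, leaving the `2^(k-1)` odd
decimals. The full map has

    N = 4 * 5^(k-1)

coordinates (12,500 at the default k = 6). Each contiguous k-mer count is
first normalized to a background-relative frequency

    phi_a(x) = [ #a in x / (|x|-k+1) ] / [ #a in genome / (|genome|-k+1) ]

and each gapped feature is then computed by **folding** — summing the
normalized contiguous features compatible with it at its dependent positions
(e.g. `phi_ANA = phi_AAA + phi_ACA + phi_AGA + phi_ATA`). A soft-margin
linear SVM on these explicit features is exactly the folded k-spectrum
kernel machine. On top of the classifier the package provides:

* composition-preserving scrambling to generate matched negative sets;
* per-sequence feature **enrichment scores** `r(n) = w(n) x(n)` with a 0.005
  cutoff, gapped **motif fragments** (`(A/T)NT`-style) and MEME-format export
  for external motif-database comparison;
* **false-discovery feature elimination**: retrain on scrambled positives,
  flag features enriched by composition alone, and constrain the map to the
  surviving high-confidence index set;
* repeated stratified **cross-validation** with per-positive false-negative
  call accounting, ROC/PR curves, AUC/AUCPR averages, and assignment of
  positives to detection groups (folded-only / neither / both);
* a **synthetic data generator** with planted (gapped) motifs and a full
  ground-truth plant log.

## Worked example

Plant a gapped motif (`GANNTC`: positions 3–4 free) into synthetic positives
and fit the model:

```r
library(foldkspec)

spec <- plant_spec("GANNTC", plants_per_sequence = 8, mutation_rate = 0.1,
                   seed = 5)
dat  <- make_dataset(n_pos = 25, length = 500, spec = spec,
                     n_scrambles = 10, seed = 205)
fit  <- foldkspec(dat[dat$label == 1, ], negatives = dat[dat$label == -1, ],
                  k = 6, seed = 1)
fit
#> foldkspec: folded k-spectrum kernel SVM, k = 6
#>   features: 12500 of 12500
#>   training set: 25 positives, 250 negatives; C = 1
#>   training accuracy: 1.000

head(sort(coef(fit), decreasing = TRUE), 5)
#>       NGANNT       GANNTC       GANNNC       NANNTC       GNNNTC
#> 0.0011946395 0.0009752919 0.0009407313 0.0008135322 0.0008054325
```

The top-weighted features are the planted pattern `GANNTC` itself and its
shifted/sub-gapped variants — the classifier has recovered both the motif and
its dependency structure (mask `110011`). Cross-validated performance:

```r
cv <- repeat_cv(dat, k = 6, kernel = "folded", folds = 10, repeats = 3,
                seed = 1, keep_curves = FALSE)
cv
#> kspec_cv: folded kernel, k=6, 10-fold x 3 repeats
#>   AUC_avg = 0.8558, AUCPR_avg = 0.5054
#>   positives with FN calls: 20 of 25 (max FN 3/3)
```

AUC_avg is the mean area under the ROC curve over the repeated CV runs; the
FN counts say how often each held-out positive was missed. Run the same data
through `kernel = "contiguous"` to quantify the advantage of the gapped
features, and `assign_groups()` to find the positives only the folded kernel
detects.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/foldkspec.R`
(`featurize | train | enrich | filter | crossval | report`).

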