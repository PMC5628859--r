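Package: foldkspec
Title: Folded k-Spectrum Kernel SVM for Regulatory DNA Sequence Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Support vector machine classification of regulatory DNA
    sequences with the folded k-spectrum kernel: an explicit feature map over
    all 2^(k-1) gapped k-mer dependency models, computed by counting the
    contiguous k-spectrum once and folding it onto every gapped feature set.
    Includes background-normalized relative k-mer frequencies,
    composition-preserving sequence scrambling for negative sets, per-sequence
    feature-enrichment scoring, false-discovery feature elimination against
    scrambled positives, gapped k-mer motif-fragment construction with MEME
    minimal-format export, and repeated stratified cross-validation with
    ROC/PR evaluation and false-negative call accounting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Matrix,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
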