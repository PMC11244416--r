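Package: DynMaskERP
Title: Dynamic Multi-Scale Masked Convolution for Cross-Subject ERP Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a dynamic multi-scale masked convolution network for
    cross-subject binary classification of event-related potentials (ERPs),
    in particular self-face (P300-bearing) versus stranger-face (N200-bearing)
    epochs recorded under the Complex Trial Protocol. A variable-length filter
    generator produces, per input epoch and per scale, a soft sigmoid mask that
    truncates Gaussian-initialised depthwise convolution kernels in a fully
    differentiable way. The package bundles a synthetic CTP-paradigm ERP
    simulator, imbalance-aware training (class-weighted cross-entropy on
    logits) with subject-disjoint splitting and cross-validation,
    imbalance-aware evaluation metrics (balanced accuracy, F1, TPR/TNR/FPR,
    rank-based AUC), pointwise t-test significance windows, and an ablation
    harness comparing masked against standard fixed-length models across
    scale counts, mask sharpness values, and mask-generator window placements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
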