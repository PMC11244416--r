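# DynMaskERP

Cross-subject classification of event-related potentials (ERPs) with a
**dynamic multi-scale masked convolution** network, plus a synthetic
Complex-Trial-Protocol (CTP) ERP simulator, imbalance-aware training and
evaluation, and an ablation harness.

## The problem

In a CTP face experiment a participant sees their own face (*probe*,
positive class) and stranger faces (*irrelevants*, negative class) at a
1:4 ratio. Self-face epochs elicit a P300-like positivity (~300–500 ms,
peak ≈ 400 ms, maximal at Pz); stranger-face epochs an N200-like
negativity (~180–250 ms, peak ≈ 211 ms). Classifying epochs across
subjects is hard because component latency and width vary between
people, so any fixed convolution kernel length is a compromise.

## The model

For an epoch *S* ∈ ℝ^(C×T), the network computes, per scale
*i* = 1..K:

1. width-3 feature convolution **e**ᵢ = Wᶠᵢ·S + bᵢ, pooled over
   channels (GAP) to E′ ∈ ℝ^(K×1×T);
2. a segment L = E′[P : P+l) feeding a variable-length filter
   generator: rᵢ = σ(W_m2(W_m1(Lᵢ ⊕ Wᵢ) + b_m1) + b_m2) ∈ (0,1);
3. a differentiable soft mask over kernel taps *j* = 1..l,
   m⁠ᵢⱼ = σ(λ(lᵢ − j)) with ideal length lᵢ = rᵢ·l and sharpness λ;
4. masked depthwise convolution of the end-padded epoch with
   Wᵛ = W ⊗ M, keeping one map per (scale, channel):
   D ∈ ℝ^(K×C×T);
5. batch norm → dropout → flatten → a single linear unit → logit.

The *standard* variant is the same network with M ≡ 1 (fixed
full-length kernels). Training minimises class-weighted cross-entropy
on logits (positive weight 4), lr 1e-5, weight decay 1e-4, dropout 0.5,
threshold 0.5, with subject-disjoint 9:1 splits and 3-fold CV.

## Worked example

```r
library(DynMaskERP)

es <- simulateEpochs(syntheticSpec(seed = 1))   # 10 subjects x 60 trials
es
#> EpochSet: 600 trials x 30 channels x 1000 samples @ 1000 Hz
#>   positives (self-face): 120, negatives (stranger-face): 480
#>   subjects: 10, epoch span 0..999 ms

fold <- splitBySubject(es, trainFraction = 0.9, seed = 1)[[1]]
model <- fitModel(fold$train,
                  modelConfig(K = 10, l = 200, P = 300),
                  trainConfig(epochs = 5))
head(model@history$trainLoss)
#> [1] 1.1916575 0.6099465 0.3503535 0.2274076 0.1458872

pred <- predictEpochs(model, fold$test)
evalReport(epochLabels(fold$test), pred$scores)
#> EvalReport: TP 12, FP 9, TN 39, FN 0 (n = 60)
#>   BA 0.9062, F1 0.7273, TPR 1.0000, TNR 0.8125, FPR 0.1875, AUC 0.9705
```

The training loss falls steeply within a few epochs; the held-out
subject (60 trials, 12 positives) is classified with balanced accuracy
0.91 after five epochs — all positives found (TPR 1.0) at the cost of
nine false alarms (FPR 0.19). Longer schedules (50 epochs, as in the
shipped acceptance checks) reach ceiling on this simulated task.

Mask diagnostics for a single epoch:

```r
fw <- dynForward(model, t(epochData(es)[, , 1]))
fw$maskDiagnostics$r        # per-scale mask ratios in (0,1)
fw$maskDiagnostics$M[1, ]   # soft mask of scale 1: decreasing sigmoid ramp
```

A command-line wrapper (`exec/dynmaskerp`) exposes
`simulate` / `train` / `evaluate` / `ablate`; see `dynmaskerp --help`.

## Package layout

- `R/` — S4 classes (`EpochSet`, `SyntheticSpec`, `ModelConfig`,
  `TrainConfig`, `DynMaskModel`, `EvalReport`, `AblationGrid`), the
  reference implementation of every network stage, training,
  metrics, and the ablation harness.
- `src/` — fused single-precision batch training/inference path
  (AVX-512 with runtime dispatch and scalar fallbacks).
- `vignettes/dynamic-masked-convolution.Rmd` — the model, the
  simulator's assumptions, numerical choices, and limitations.
- `tests/testthat/` — unit, property and acceptance tests (the
  compiled path is tested against the double-precision reference, and
  analytic gradients against central finite differences).
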