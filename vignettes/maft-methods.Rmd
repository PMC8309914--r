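---
title: "Estimating depression severity with per-feature transformer encoders and adaptive late fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating depression severity with per-feature transformer encoders and adaptive late fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maft)
```

## The problem and the model

Clinical screening interviews yield long multimodal recordings: acoustic
descriptors (MFCCs, eGeMAPS), facial action units and head pose, and deep
representations of both, each exported as a frame-per-row numeric stream.
The target is the subject's PHQ-8 total, an integer severity score in
[0, 24]. Two properties make this setting awkward for sequence models:
streams are very long (tens of thousands of frames for low-level features),
and the feature types differ wildly in dimension, length and usefulness.

`maft` addresses this with a two-stage design:

1. **Per-feature encoding.** One transformer encoder is trained
   independently per feature type. The input sequence receives sinusoidal
   positional encoding and passes through `num_layers` encoder layers, each
   a single-head (by default) scaled dot-product self-attention
   `softmax(QK'/sqrt(d_k))V` and a two-layer position-wise feed-forward
   block, both wrapped in residual addition followed by layer normalization
   (post-norm). The encoded frames are averaged over time, mapped by an
   embedding FC block (ReLU, dropout, linear) to a fixed-width subject
   embedding, and fed to two independent FC-block heads: a regression head
   emitting the predicted PHQ-8 score and a classification head emitting
   logits over the five severity classes (minimal 0–4, mild 5–9, moderate
   10–14, moderately severe 15–19, severe 20–24).
2. **Adaptive late fusion.** Each fitted feature model scores the
   development set; its concordance correlation coefficient (CCC) there
   becomes its fusion weight, `w_m = CCC_m / sum(CCC)`, optionally after
   restricting to the top-M features by CCC. The fused prediction is the
   weighted average of the per-feature scores. Averaged fusion (equal
   weights) is available as the baseline.

Training minimizes the joint loss `a * (1 - CCC) + b * CE`, where CCC is
computed over the minibatch with population moments and CE is the
cross-entropy of the severity classification. The conventional weights are
`a = 1, b = 0` (single-task) and `a = 0.9, b = 0.1` (multi-task); the
auxiliary classification task regularizes the shared embedding.

### Assumptions

* Severity is expressed in the *distributional statistics* of the frame
  stream, not in any specific short event, so temporal averaging after
  self-attention is an adequate pooling.
* Feature types are conditionally independent carriers of the same latent
  severity, which justifies independent per-feature models and late
  (decision-level) fusion.
* The development-set CCC is an unbiased enough ranking signal to act as a
  fusion weight; with very small development sets this weight is noisy,
  which is why top-M selection and weight clamping exist.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `sampling.N_low_mid` / `N_high` | 2048 / 720 frames | frame budget after segment sampling, per feature level |
| `sampling.segments` | 8 | number of contiguous segments the budget is spread over |
| `functional.window` / `hop` | 100 / 25 frames | sliding window for mean/sd functional features |
| `functional.target_len` | 1768 | fixed functional-sequence length |
| `encoder.num_layers` | 6 | encoder depth |
| `encoder.num_heads` | 1 | attention heads (must divide `d_model`) |
| `encoder.ff_hidden` | 2048 | feed-forward width |
| `encoder.embed_dim` | 256 | subject-embedding width |
| `encoder.dropout` | 0.1 | dropout rate, FC blocks and sublayer outputs |
| `training.learning_rate` | 1e-5 | Adam step size |
| `training.a` / `b` | 0.9 / 0.1 | loss weights (1 / 0 for single-task) |
| batch size / epochs | 48 / 500 (low–mid), 24 / 200 (high) | resolved by feature level |

Segment sampling keeps `s` runs of `N/s` consecutive frames, one per
equal segment of the recording, so the shortened sequence still covers the
whole session while preserving local temporal structure for the attention
layers to use. Resampling the draw every epoch doubles as augmentation; a
flag freezes it.

## What the synthetic cohort emulates — and what it does not

Because the clinical corpora this model family targets are
access-restricted, the package ships a generator whose defaults define the
package's study conditions: 40 training and 16 development subjects, PHQ-8
scores drawn from a skewed-low histogram (class weights 77/36/26/17/7,
matching the imbalance typical of screening cohorts), and three feature
streams per subject:

* `acoustic_lld` — low level, 8 dims, ~60–80 frames, signal strength 0.9,
  noise sd 0.6;
* `facial_au` — middle level, 6 dims, signal strength 0.5, noise sd 0.8;
* `deep_noise` — high level, 4 dims, signal strength 0, pure noise.

Each stream is a stationary AR(1) process (autocorrelation 0.5) around a
feature-specific baseline whose mean is shifted by
`signal_strength * (score/24) * direction`, with a fixed random direction
vector per feature. The choices were made once, on first principles: the
noise level leaves the subject-level signal clearly recoverable for the
strong feature (the temporal mean averages the AR(1) noise down by roughly
a factor of four at these lengths), marginal for the medium feature, and
absent for the noise feature, so the planted informativeness ordering is
testable. AR(1) smoothness gives segment sampling something to preserve.

What passing tests on this cohort demonstrate: the optimizer and gradients
are correct, the encoder can extract a mean-coded severity signal from
noisy sequences, CCC-weighted fusion downweights uninformative features,
and the whole pipeline is deterministic under a seed. What they do not
demonstrate: performance on real interview data, where the severity signal
is far subtler, non-stationary, and not linearly coded in feature means.

## Desk-scale study conditions

The test suite trains 2-layer encoders (feed-forward width 64, embedding
width 32) for 200 epochs on 32 sampled frames per subject, at learning
rate `1e-3`. The learning rate is deliberately larger than the production
default: `1e-5` is matched to 500-epoch runs over hundreds of long
sequences, while the toy problem has ~200 gradient steps in total and a
much smaller, better-conditioned parameter space. All other conventions
(Adam, loss weights 0.9/0.1, per-epoch resampling, best-development-CCC
checkpoint) are the production ones.

## Numerical choices

* **Attention scaling** is the standard `1/sqrt(d_k)`.
* **Layer norm** is post-norm (applied after the residual add), following
  the original encoder design, with variance epsilon `1e-5`.
* **Population moments** (divide by `n`) everywhere CCC appears — loss,
  metric, and the z-scoring statistics — matching Lin's definition.
* **CCC loss vs metric granularity**: the loss uses minibatch statistics
  (that is what the gradient can see); the reported metric is always
  computed once over the full evaluation set on raw, unrounded predictions.
* **Degenerate CCC**: for two identical constant vectors the metric is
  0/0; `ccc()` errors by default (`undefined = "one"` returns 1 with a
  warning). The loss instead adds `1e-12` to the denominator so a
  degenerate batch stays finite and differentiable.
* **Cross-entropy** accepts probabilities (floored at `1e-12`) or logits,
  which go through log-sum-exp.
* **Segment sampling edge cases**: when `N` is not divisible by `s`, the
  first `N - s*floor(N/s)` segments contribute one extra frame; a segment
  shorter than its quota is taken whole and right-padded by repeating its
  last frame; sequences shorter than `N` are repeat-padded cyclically
  (configurable off, then an error).
* **Functional resampling** to `target_len` uses nearest-index selection —
  the simplest length-exact rule; the window/hop defaults (100/25) are
  exposed because the canonical functional exports do not document theirs,
  and no fidelity to any specific export is claimed.
* **Initialization** is uniform fan-in (`U(-1/sqrt(n_in), 1/sqrt(n_in))`)
  for weights and biases; layer-norm gains 1, shifts 0. Odd `d_model`
  gives the unpaired last positional-encoding column the sine term.
* **Adaptive weights**: negative development CCCs are clamped to 0 before
  normalization; if *every* CCC is non-positive the fusion operator errors
  (weights are undefined), and the pipeline falls back to averaged fusion
  with a warning so a batch run still completes.
* **Ties in top-M selection** break toward the lexicographically smaller
  feature name, making selection deterministic.

## Design decisions that were genuinely open

* **Severity brackets** are treated as closed integer ranges
  ([0–4], [5–9], …), the standard reading of the PHQ-8 cut-points 0, 5,
  10, 15, 20.
* **Attention shapes**: the per-position formulation of attention is
  implemented with conventional `t x d_k` query/key/value matrices.
* **Checkpoint selection**: the parameters with the best development CCC
  are retained (evaluated every `eval_every` epochs) rather than the final
  epoch, since development-set results are what fusion consumes.
* **z-normalization** of inputs is on by default: the feature families
  differ by orders of magnitude in scale, which destabilizes training at
  small learning rates. Statistics come from training frames only.
* **Per-feature training seeds** in the pipeline are derived as
  `seed + 1000 * feature_index`, so single-feature reruns are reproducible
  independently of which other features are trained.
* **Fusion operates on regression scores only**; class probabilities are
  reported per feature but never fused — the classification task exists to
  shape the embedding, not to be ensembled.
* The per-level number of segments `s` is a hyperparameter with no
  canonical value; the default 8 keeps blocks long enough (256 frames at
  the low/middle budget) for attention to see local structure.

## Known limitations

* The encoder is quadratic in the sampled length `t`; budgets beyond a few
  thousand frames are the practical ceiling, which is exactly why segment
  sampling exists.
* Development-set CCC is both the checkpoint criterion and the fusion
  weight, so with small development sets the fused CCC on that same set is
  optimistically biased; an untouched test split is needed for honest
  error estimates.
* Class imbalance (severe cases are rare) biases predictions toward the
  low end of the scale; the auxiliary classification task mitigates but
  does not remove this.
* The synthetic generator codes severity in feature means. A model could
  in principle pass all tests here yet fail on signals carried in
  higher-order temporal statistics.
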