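# maft

Multimodal adaptive-fusion transformer models for depression severity
estimation in R.

## What problem this solves

Automatic depression screening works from long audiovisual interview
recordings, exported as frame-level feature streams: acoustic low-level
descriptors (MFCC, eGeMAPS), facial action units and head pose, and deep
representations of either. The target is the subject's PHQ-8 score, an
integer in [0, 24], with an associated five-class severity label
(minimal [0–4], mild [5–9], moderate [10–14], moderately severe [15–19],
severe [20–24]). The two hard parts are extracting long-range temporal
context from sequences with tens of thousands of frames, and combining
feature types whose usefulness varies enormously.

`maft` is for researchers in affective computing and digital mental health
who want a fully inspectable, dependency-light R implementation of this
model family, plus a synthetic cohort generator that makes every stage
testable without access-restricted clinical corpora.

## The model

One transformer encoder is trained **independently per feature type**:
sinusoidal positional encoding, `N` layers of single-head scaled
dot-product self-attention

    Z = softmax(Q K' / sqrt(d_k)) V

and a position-wise feed-forward block, each wrapped in residual addition
and layer normalization; temporal averaging; an embedding FC block
(ReLU → dropout → linear); and two task heads predicting the PHQ-8 score
and the severity class. Training minimizes the joint loss

    L = a * (1 - CCC(y, ŷ)) + b * CE(p, class)

with Lin's concordance correlation coefficient

    CCC = 2 S_ŷy / (S_ŷ² + S_y² + (ȳ̂ - ȳ)²)

in population-moment convention (`a = 0.9, b = 0.1` for multi-task,
`1, 0` for single-task). Long streams are shortened beforehand by segment
sampling: the sequence is split into `s` even segments and a run of `N/s`
consecutive frames is drawn from each.

Per-feature development-set predictions are then combined by **adaptive
late fusion**: feature `m` receives weight `CCC_m / Σ CCC` (negative CCCs
clamped to zero), optionally after keeping only the top-M features by CCC.
Averaged fusion (equal weights) is the baseline.

## Worked example

A complete run on the bundled synthetic cohort (40 training / 16
development subjects; one strong-signal, one medium-signal and one
pure-noise feature stream), at the desk-scale settings used throughout the
test suite (~30 s on one core):

```r
library(maft)
res <- run_pipeline(list(
  seed = 1L,
  sampling = list(N_low_mid = 32L, N_high = 32L, segments = 4L),
  encoder = list(num_layers = 2L, ff_hidden = 64L, embed_dim = 32L),
  training = list(learning_rate = 1e-3, epochs = 200L, batch_size = 48L),
  out = tempfile("maft_demo")))
#> Generating synthetic cohort (train 40 / dev 16)
#> Training feature 'acoustic_lld' (low-level, N = 32)
#>   dev CCC 0.652, RMSE 4.436
#> Training feature 'facial_au' (middle-level, N = 32)
#>   dev CCC 0.338, RMSE 7.002
#> Training feature 'deep_noise' (high-level, N = 32)
#>   dev CCC 0.021, RMSE 7.600
#> Fused (adaptive): dev CCC 0.560, RMSE 5.033

tidy(res$fusion)
#> # A tibble: 3 × 3
#>   feature_name    ccc weight
#>   <chr>         <dbl>  <dbl>
#> 1 acoustic_lld 0.652  0.645
#> 2 facial_au    0.338  0.334
#> 3 deep_noise   0.0208 0.0205
```

The per-feature development CCCs recover the planted informativeness
ordering (signal strengths 0.9 > 0.5 > 0), and the adaptive weights — each
feature's CCC normalized by the sum — push the pure-noise stream's
influence to 2% of the fused score. `glance()` on any fitted model and
`autoplot()` on models, prediction sets and fusion results give one-row
summaries, training-history plots and weight charts; artifacts
(checkpoints, prediction CSVs, `fused.csv`, `weights.csv`, `metrics.json`,
and the resolved `config.yaml`) land in `out`.

A thin command-line wrapper is installed at `inst/cli/maft.R`
(`synth`, `pipeline`, `fuse` subcommands).

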