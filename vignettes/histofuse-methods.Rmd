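---
title: "Dual-branch CNN-Transformer fusion for histopathology tiles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch CNN-Transformer fusion for histopathology tiles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Breast-cancer histopathology tiles carry diagnostic signal at two scales at
once: *local* cytological cues (nuclear density, nuclear size and atypia,
chromatin texture) and *global* architectural cues (how glands, ducts and
cell populations are arranged across the field). Convolutional networks
excel at the former but their effective receptive fields limit the latter;
Vision Transformers model long-range structure but are comparatively weak
texture extractors. histofuse implements a parallel hybrid that runs both
families side by side and fuses their embeddings with a token-level
attention module, together with everything needed to use it: patch
extraction, leakage-safe splitting, training, evaluation with
patch-to-image voting, run-comparison statistics and gradient-based
explanations.

## Model

**CNN branch.** A five-stage residual backbone with total stride 32 maps an
RGB tile $X \in \mathbb{R}^{H\times W\times 3}$ to a local feature map
$F \in \mathbb{R}^{C\times H/32\times W/32}$ ($C = 2048$ at full scale). A
squeeze-and-excitation (SE) block is applied once, after the final stage:
the map is globally average-pooled to a channel descriptor, passed through a
two-layer bottleneck (reduction ratio $r$, ReLU then sigmoid), and each
channel is rescaled by the resulting gate $s \in (0,1)^C$,

$$ s = \sigma\!\big(W_2\,\delta(W_1\,\mathrm{GAP}(F))\big), \qquad
   \tilde F = F \odot s . $$

In tissue tiles much of the field is diagnostically irrelevant (fat, empty
space, stroma); the gate learns to amplify channels that respond to
lesion-relevant structure. Pooling and a linear projection give the branch
embedding $z_{\mathrm{cnn}} \in \mathbb{R}^d$.

**ViT branch.** The tile is cut into $P\times P$ patches ($P = 16$ by
default), each flattened and linearly projected to a $D$-dimensional token;
a learned classification token is prepended and a learned position encoding
added. A stack of pre-norm Transformer blocks (LayerNorm, multi-head
self-attention, residual; LayerNorm, GELU MLP, residual) encodes the
sequence. Instead of reading only the final classification-token state, the
branch taps it after three depths spread over the stack (layers 6, 9 and 12
of a 12-layer encoder) and averages them,

$$ z_{\mathrm{vit}} = \tfrac13\,(z_6 + z_9 + z_{12}), $$

mixing mid-level and high-level global summaries. Taps are captured after
the full block (post-MLP, post-residual); raw block outputs are averaged
without an extra normalization.

**Token-aligned fusion.** The two embeddings are concatenated and linearly
reduced back to $d$ ($d = 768$ by default). The fusion sequence has $T = 3$
tokens: the CNN embedding, the ViT embedding, and the reduced joint vector.
This choice resolves a genuine tension in the written formulation: a single
reduced vector leaves self-attention and sequence pooling degenerate,
whereas the three-token sequence gives every stated operation a
non-degenerate home while containing exactly the written quantities. A
strict single-token mode is available behind
`model$fusion$sequence_mode = "single"` for comparison.

Two attention stages refine the sequence. The first is a plain multi-head
self-attention (separate Q/K/V projections, 8 heads, concatenated heads,
output projection; per-head scaling $1/\sqrt{d_k}$ with $d_k = d/h$). The
second, the token-alignment (TA) layer, applies LayerNorm, a *shared*
linear projection producing $Q = K = V$, multi-head attention, and an
output projection, wrapped in a residual connection. The residual and
pre-norm placement are not part of the written equations; they are adopted
because a stacked attention layer without them is hard to train, and they
can be disabled (`ta_residual = FALSE`). Mean pooling over the $T$ tokens
and a classifier head (ReLU, dropout, linear, softmax) produce class
probabilities. Training minimizes the batch-mean multi-class cross-entropy
$-x_y + \log\sum_j e^{x_j}$ computed in log-sum-exp form.

## Parameters that matter

| parameter | default | notes |
|---|---|---|
| shared dimension $d$ | 768 | also the ViT token width; reduced preset 64 |
| SE reduction ratio $r$ | 16 (reduced: 8) | standard SE practice |
| ViT patch size $P$ | 16 px | consistent with $d = 768$ |
| CLS tap layers | 6, 9, 12 | reduced preset keeps the "three evenly spaced taps ending at the final layer" pattern (2, 3, 4 of 4) |
| fusion heads | 8 | $d$ must be divisible by the head count |
| head dropout | 0.5 (reduced: 0.1) | 0.5 is the common default at full scale, lowered at toy scale where the model is small |
| learning rate | 2e-4 peak, AdamW, weight decay 0.01 | cosine annealing with 5 warmup epochs (warmup length is our choice) |
| epochs / batch | 50 / 32 | early stop after 15 epochs without validation-loss improvement; checkpoint by best validation accuracy |

## Initialization

Weights are He/Glorot-style Gaussian draws from a seeded RNG. The final
normalization gain of every residual block is initialized to $1/\sqrt{L}$
($L$ = number of residual blocks) rather than 1: with unit gains the
activation variance of a fresh stride-32 backbone grows geometrically with
depth, which saturates the SE sigmoid (gates of exactly 0/1 in double
precision) and produces meaningless logits at random initialization.
Depth-scaled gains bound the growth to a constant factor while leaving
early-training dynamics close to the unit-gain behaviour at shallow depth.
Pretrained initialization is not bundled: the package trains from
scratch.

## Data pipeline

Grid patching cuts a fixed `cols x rows` array of non-overlapping square
patches anchored at the image origin (a 2048x1536 field with a 4x3 grid of
512 px patches gives exactly 12). Sliding-window patching places origins at
stride multiples with full containment, `floor((dim - patch)/stride) + 1`
per axis (a 700x460 field with 224 px windows at stride 112 gives 5 x 3 =
15). Coordinates are 0-based (row, col) with half-open intervals;
reassembling grid patches reproduces the source region pixel-exactly.

The image-level split stratifies by class at the *source-image* level:
validation and test receive `floor(fraction * class size)` images, the
remainder goes to training (for 200 images per class at 70/10/20 this gives
exactly 140/20/40), and every patch follows its source image. The
patient-grouped k-fold planner allocates whole patients to folds with a
greedy largest-first heuristic that minimizes the deviation of per-fold
class proportions from the global ones; within each fold's complement a
second grouped, stratified pass carves a validation subset (20% of the
non-test portion, the customary BreakHis convention). No exact solver
is warranted: the plan is audited, not assumed — `audit_fold_plan()`
reports pairwise shared patients (invariant: zero) and the worst class-
proportion deviation.

Augmentation policies: the 4-class policy uses horizontal/vertical flips,
rotations by multiples of 90 degrees (chosen over arbitrary angles to
preserve tissue statistics and avoid border fill), brightness/contrast
jitter of +-20% and Gaussian blur with sigma in 0.1-1.0; the 8-class policy
uses flips and small-angle rotations within +-10 degrees (bilinear, with
reflection padding). Each transform fires with probability 0.5; jitter
ranges and the firing probability are this package's choices.

## Evaluation and statistics

All threshold metrics derive from a single confusion matrix: per-class
precision, recall, F1 and one-vs-rest accuracy, plus macro averages
(per-class "accuracy" columns in benchmark reports are ambiguous between
one-vs-rest accuracy and recall, so this report emits both, labelled). ROC
AUC is computed one-vs-rest per class and micro-averaged over the pooled
indicator/score pairs. Image-level decisions take the modal class over a
source image's patches; ties break by the highest mean softmax probability
among tied classes, then by the lowest class id — fully deterministic.
Repeated-run comparisons use the paired t-test on per-run differences with
Cohen's d for the paired design ($\bar{\Delta}/s_\Delta$; 0.2/0.5/0.8
labelled small/medium/large), Benjamini-Hochberg adjustment by default and
Bonferroni as an alternative; zero-variance differences are flagged
degenerate instead of yielding NaN.

## Explanations

Grad-CAM weights each channel of a registered CNN activation by the spatial
mean of the gradient of the *pre-softmax* class score, and rectifies the
weighted sum. Three maps are taken from late backbone blocks (at full scale:
the last block of stage 3, the second and the last block of stage 4 — the
registry is configurable by name), bilinearly resized to a common
resolution, averaged with equal weights and min-max normalized to [0, 1]; a
zero-range map normalizes to zeros with a warning. Interpolation uses
half-pixel centers, pinned so fused maps are bit-reproducible. Overlays are
the convex combination `image*(1-alpha) + heatmap*alpha` with a jet-like
piecewise-linear colormap. Localization quality is the IoU between the
top-q quantile region of the fused map (q = 0.2) and a binary lesion mask;
for an uninformative map this has closed-form expectation
$qa/(q + a - qa)$ at mask fraction $a$, which serves as the chance
baseline. Maps explain the predicted class by default (the true class can
be requested), computed on the CNN branch only.

## The synthetic fixture generator

The generator emulates just enough H&E structure for the pipeline to be
exercised without external data: eosin-pink low-frequency backgrounds,
hematoxylin-purple anti-aliased elliptical blobs standing in for nuclei, a
blob-enriched disc as the "lesion" with its binary mask, and optional
class-pure synthetic patients. Classes form a factorial design: two *local*
levels (blob density 14 vs 34 per 96 px tile, radius 2.6 vs 4.0 px) crossed
with *global* layouts (scattered/ring for 4 classes; plus clustered/banded
for 8). Because local parameters take only two values, a pure-texture
classifier caps at 50% on the 4-class task, and likewise a pure-layout one:
separating all classes requires both cue families. Every tile is a pure
function of (spec, seed, class, index). Default tile size is 96 px; 224 and
512 presets mirror common patch sizes.

What the fixtures do *not* emulate: stain variation, scanner noise,
tissue-boundary artifacts, correlated patches from shared slides, class
imbalance in pixel statistics. Passing the fixture study therefore shows
the implementation learns and explains as designed, not that it matches
benchmark accuracies on real cohorts — those require the external datasets
and GPU-scale training, and are out of scope here. The generative-
augmentation stage sometimes paired with these benchmarks (StyleGAN2-ADA
synthesis,
1536x1536 center crop, 1024x1024 resize, 3000 kimg, 100 images per class,
class-conditional) is likewise not re-trained; externally generated images
enter through the ordinary manifest, optionally confined to the training
split (`synthetic` items should stay out of evaluation subsets to avoid
optimistic bias).

## The desk-scale study

`run_toy_study()` is the packaged reference experiment: 4 classes x 100
tiles of 96 px (seed 0), split 70/10/20 at the tile level, the reduced
dual-branch model (about 0.7 M parameters: channels 12-128, ViT depth 4,
width 64, patch size 12 so that lesion foci span several tokens, taps
2/3/4, 4-head fusion) trained with a toy-scale recipe: AdamW at a peak rate
of 1e-3 with 2 warmup epochs (the full-scale default of 2e-4/5 is tuned for
a 100M-parameter model and under-trains a 0.7M one within the 30-epoch
budget), batch 32, and geometry-preserving augmentation only — flips and
right-angle rotations — because the photometric transforms of the full
policy (Gaussian blur up to sigma 1 px) erase the 1.4 px blob-radius cue
that defines the fixture's local levels. The CNN-only and ViT-only ablation arms
train under the identical recipe and epoch budget and are compared on the
held-out split test tiles plus an enlarged generated evaluation set (100
fresh tiles per class at generator indices beyond the training pool,
disjoint by construction) — the 80-tile split test is too small to resolve
close arms. Fused-CAM localization is scored on held-out test tiles
against the generator's lesion masks. Problem sizes were chosen so the
whole study runs in minutes on one CPU core; the vignette asserts no
numbers — the study prints its own.

At reduced scale the CAM registry targets stages 1-3 (cell sizes 4, 8 and
16 px): the late-stage maps are 3x3 or 6x6 grids of 16-32 px cells,
structurally too coarse to localize foci of ~14 px radius, whereas the
full-scale registry keeps the conventional late-layer choice at 224 px where
those maps are 14x14 and 7x7.

A caveat the reader should know: at 96 px the reduced backbone's
theoretical receptive field exceeds the tile, so the "CNN-only" arm is not
a strictly local model the way a 50-layer backbone on 512 px patches is.
The factorial cue structure still guarantees that *texture statistics
alone* cannot separate the classes, but a deep CNN ablation can recover
the arrangement cue through its receptive field; the dual-branch advantage
at this scale is therefore an empirical question about capacity
allocation, not a structural certainty — and in this study's measurements
the CNN-only arm is in fact competitive with (and on the enlarged
evaluation set slightly ahead of) the dual-branch model, while the
ViT-only arm trails far behind. The hybrid's documented advantage on real
high-resolution cohorts should not be inferred from, or refuted by, this
desk-scale fixture.

## Numerical choices and degenerate inputs

LayerNorm and BatchNorm use eps = 1e-5; a zero-variance token normalizes to
the learned shift. Softmax and cross-entropy subtract row maxima before
exponentiation. Dropout is inverted (scaling at train time). Attention over
a single token is the identity distribution (weight exactly 1). Majority-
vote ties and k-fold ties are broken deterministically (documented above).
Empty tap lists, empty CAM lists, empty lesion masks, non-finite logits,
out-of-range taps, and images indivisible by stride or patch size raise
informative errors rather than propagating NaN.

## Known limitations

* Training is single-threaded CPU R; the full-scale configuration is
  practical for forward passes and architecture checks, not for training.
* BatchNorm running statistics make eval-mode outputs depend on training
  history; two checkpoints with identical weights but different buffer
  histories differ slightly.
* The greedy fold planner approximates stratification; with few patients
  per class the per-fold proportions can deviate noticeably (the audit
  reports the deviation rather than guaranteeing a bound).
* The fixture task is far easier than real histopathology; accuracy numbers
  from the desk-scale study do not transfer.
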