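---
title: "Methods: lung slice localization and adipose tissue segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lung slice localization and adipose tissue segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungfat)
```

## The problem

Quantifying subcutaneous (SAT) and visceral (VAT) adipose tissue around the
lungs on chest CT requires two steps: deciding *which* axial slices belong
to the lung region, and segmenting the fat classes on those slices. The
package implements both stages: a convolutional bidirectional GRU that
classifies each slice (via a short window of its neighbours) as the first
lung slice, the last lung slice, or neither; and a UNet, optionally
extended with three skip-pathway blocks, that produces per-pixel
foreground probabilities for one tissue class at a time.

Everything runs on CPU in plain R: the convolutions are im2col + BLAS
matrix products, and both networks are trained by backpropagation written
alongside the forward passes. There is no external deep-learning runtime.

## Stage 1: slice localization

### Windows and classes

An ordered volume of slices is cut into sliding windows of odd length
$L \in \{3, 5, 7\}$ (stride 1). Each window carries the class of its
**center** slice: `0` = first lung slice, `1` = other, `2` = last lung
slice. Center labeling keeps the bidirectional context symmetric; slices
too close to the volume ends are never window centers. $L = 5$ is the
default working point.

### The recurrent cell

The cell is a GRU whose gate transformations are same-padded convolutions
acting on the channel concatenation of hidden state and input:

$$
\begin{aligned}
z_t &= \sigma(W_z \ast [h_{t-1}, x_t]) &\text{(update gate)}\\
r_t &= \sigma(W_r \ast [h_{t-1}, x_t]) &\text{(reset gate)}\\
\tilde h_t &= \tanh(W \ast [r_t \odot h_{t-1}, x_t]) &\text{(candidate)}\\
h_t &= (1 - z_t) \odot h_{t-1} + z_t \odot \tilde h_t
\end{aligned}
$$

Two recurrences run over the window in opposite directions from zero
initial states (zero is the symmetric, conventional choice); their final
hidden states are concatenated channel-wise, globally average-pooled, and
mapped by a single linear layer to 3-class softmax probabilities. The head
is deliberately minimal — nothing in the two-stage design depends on a
deeper classifier.

One printed variant of the candidate equation nests a sigmoid inside the
tanh, $\tilde h_t = \tanh(\sigma(\cdot))$, which would confine the
candidate to $(0, \tanh 1)$ and departs from the standard GRU. The package
treats the standard form as the default and exposes the nested composition
behind `literal_eq3 = TRUE` in `localizer_config()`, so both behaviours
are testable; the two variants share all other code.

### Normalizations

Two per-slice intensity normalizations are available:

* **MaxIntensity** — division by the fixed 12-bit ceiling 4095. Stored
  16-bit values above 4095 are clipped to 1 so the output range contract
  holds on real files.
* **MaxMinNorm** — per-slice min–max rescaling
  $(f - \min f) / (\max f - \min f)$, using only that slice's statistics.
  A constant slice has no admissible rescaling and is reported as a
  degenerate input, naming the slice index.

MaxMinNorm is the default: it adapts to per-acquisition intensity offsets,
which matters for archives that store raw shifted intensities.

### Input pooling

`localizer_config(input_pool = 2)` block-averages each normalized slice
before the recurrence. Slice classification depends on coarse anatomy
(how much lung area is present and how it changes across the window), not
on fine texture, and halving each spatial dimension cuts the recurrence
cost to a quarter. Setting `input_pool = 1` disables it.

### Class imbalance

Boundary slices are rare: a volume contributes exactly one first and one
last slice and many "other" slices. Two mechanisms address this:

1. **Balanced subsets** (`balance_subsets()`): the training windows are
   split into disjoint subsets holding a fixed number of boundary-positive
   windows each (optionally with a fixed total size), so the positive
   fraction seen by the optimizer is controlled rather than incidental.
2. **Logarithmic class-weight penalties** (`compute_class_weights()`):
   occurrence counts are normalized to fractions $w_i$ and mapped to
   $W_i = 1 / \log(\alpha + w_i)$ with natural log and $\alpha = 1.1$, so
   every $W_i$ lies strictly inside $(1/\log 2.1,\, 1/\log 1.1)$ and rarer
   classes receive larger penalties. The penalty of the true class is
   **added** to the sample's loss. An additive per-sample constant does
   not alter gradients — it shifts the reported training loss — so the
   *learning* effect of imbalance handling comes from the balanced
   subsets; the penalty keeps the printed loss comparable across class
   mixes. The base of the logarithm is not forced by the interval above
   (the interval's form is base-invariant); natural log is declared and
   used consistently.

### Evaluation: mean distance

Per volume, the predicted first (last) lung slice is the center index of
the window with the highest first-class (last-class) probability; ties
break toward the smaller index. The error is converted to physical
distance with the inter-slice spacing $sp_t$:

$$ MD = \frac{1}{N} \sum |No_{pred} - No_{true}| \cdot sp_t $$

The absolute value is taken (a signed version could cancel errors and go
negative, while the metric reports positive millimetres). `mean_distance()`
is zero exactly when every prediction is exact.

## Stage 2: segmentation

### Backbone

A depth-4 UNet (configurable): per encoder level two same-padded 3×3
convolutions with ReLU, then 2×2 max pooling; a two-convolution
bottleneck; per decoder level nearest-neighbour 2× upsampling followed by
a 1×1 projection, a skip concatenation, and two 3×3 convolutions. The
1-channel output head applies the logistic function
$S(p) = 1/(1 + e^{-p})$, which maps logits into $(0,1)$ as a probability
map. (A printed form of this output function, $1/\exp(-p) = e^p$, is not a
$(0,1)$ map; the stated codomain forces the logistic reading, which is
what the package implements.) Channel widths start at `base_channels`
(default 16 — enough for desk-scale phantom work) and double per level;
input dims must be divisible by $2^{depth}$, which is checked with an
explicit error.

### The three skip-pathway blocks

* **Multi-resolution (MR)** — the next-deeper encoder output is
  upsampled, projected by a 1×1 convolution to the skip's channel count,
  and added to the skip, enriching it with coarser context. At the
  deepest level the bottleneck output plays the deeper role. Fusion spans
  adjacent level pairs; wider fans are a possible extension.
* **Attention gate (ATTN)** — a per-pixel gate
  $\alpha = \sigma(\psi \ast \mathrm{relu}(W_s \ast skip + W_g \ast g))
  \in (0,1)$ driven by the projected decoder features $g$ at the peer
  level, multiplying the pathway. The gated output can never exceed the
  skip in magnitude.
* **Competitive Maxout (CP)** — the elementwise maximum of the pathway
  and $g$, keeping the stronger activation per position.

When several blocks are active they compose in the order **MR → ATTN →
CP** on the skip pathway. MR must precede CP because CP arbitrates between
the (possibly MR-enriched) pathway and the peer decoder features; the
attention gate's input is fixed to the upsampled peer-level decoder
features; and placing CP last lets the Maxout arbitrate the final
candidates whenever it is enabled. With no block enabled the pathway is
the identity — a plain UNet — and the result is always concatenated with
$g$ exactly as in the plain UNet, so all $2^3$ combinations share one
wiring and one ablation harness (`run_ablation()`). With CP enabled but MR
absent, the raw skip and $g$ are the only available candidate pair, and
that is what competes.

### Loss

Training minimizes the smoothed Dice loss

$$ DC = \frac{\kappa + 2\sum y_{true}\, y_{pred}}
             {\kappa + \sum y_{true}^2 + \sum y_{pred}^2},
   \qquad DCL = 1 - DC, \qquad \kappa = 1 $$

implemented with the squared-sum denominator exactly as written (for
binary masks it coincides with the count form). $\kappa = 1$ makes the
loss finite and well-behaved on empty masks — $DC(0,0) = 1$ — and the
$\kappa \to 0$ limit recovers the classical $2|A\cap B|/(|A|+|B|)$, which
the tests check against a set-based oracle at $\kappa = 10^{-8}$.

The class-weight penalty can be added here too (`DCLW = DCL + W`,
`loss_config(use_weight_penalty = )`, default on): as in the localizer it
is an additive per-sample constant with zero gradient. For the binary
segmentation task the foreground/background pixel counts of the training
set define the two classes and the foreground penalty is used. Whether
the penalty belongs to the segmentation loss at all is genuinely
ambiguous — the imbalance argument is made for the localization task while
the formula is attached to the Dice loss — hence the flag.

### Optimizer

Pure stochastic gradient descent, one update per sample, with the
momentum form $v \leftarrow \beta v + (1-\beta) g$,
$\theta \leftarrow \theta - \eta v$, $\beta = 0.9$. Learning rates are
not architecturally determined; defaults are 0.3 for the segmenter and
0.05 for the localizer, chosen once as the fastest stable settings on
phantom data at the default sizes, and both are plain arguments. Weights
use seeded He-style initialization (a standard choice for ReLU networks;
initialization is otherwise unspecified). Metrics binarize the
probability map at 0.5 — the natural threshold for a logistic output and
configurable in `train_segmenter()`.

## The phantom generator

`generate_volume()` produces what the two networks *assume* about chest
CT, and nothing more:

* an elliptical body of soft-tissue intensity on a dark background;
* a subcutaneous fat ring just inside the body contour whose thickness
  varies smoothly around the perimeter;
* two low-intensity lung fields that appear at `lung_first`, grow, and
  shrink to disappear after `lung_last` (unimodal area profile, the
  apex–base–apex progression), with exactly one slice labeled first and
  one labeled last;
* 2–6 irregular visceral fat blobs per slice around the mediastinum,
  disjoint from the ring by construction;
* additive Gaussian noise, then quantization to integers in $[0, 4095]$.

Intensity bands follow the CT ordering air < lung < fat < soft tissue
(background 0–100, lung 100–400, fat 1400–1800, soft tissue 2200–2800,
noise sd 50). The absolute values are arbitrary — both normalizations are
scale-free — but the ordering and separation make the classes learnable
by a small network, which is the point: the phantom exercises every code
path (16-bit I/O, polygon masks, windowing, training, evaluation) with
known ground truth.

What the phantom does **not** emulate: ribs, vessels, airways, pathology,
partial-volume effects, scanner noise structure, or the blurred
fat/soft-tissue boundaries that make clinical VAT segmentation hard.
Passing phantom tests therefore demonstrates that the implementation is
correct and trainable, not that clinical accuracy numbers transfer; the
ablation ranking of the three blocks on phantoms need not match their
ranking on clinical data, and the harness deliberately asserts nothing
about which configuration wins.

Determinism: each volume is a bit-exact function of its integer seed; the
generator uses a private RNG stream and restores the caller's stream, and
batches derive per-volume seeds from one master seed.

## File formats

* Slices: single-channel **16-bit** grayscale PNG, stored values exactly
  preserved (no rescaling, no intensity offset applied — archives that
  store offset raw values must handle the offset upstream). The package
  includes its own minimal 16-bit PNG *encoder* because the R `png`
  package writes only 8-bit files; decoding uses `png::readPNG`, and a
  write/read round trip is pixel-identical. An 8-bit rendering is a
  known annotation convenience in this domain but is never a training
  input, and the reader rejects it explicitly.
* Masks: JSON, `{"tissue": "SAT"|"VAT", "polygons": [[[x,y],...], ...]}`
  with 0-based (x = column, y = row) vertices, rasterized with the
  even-odd rule so nested contours cut holes (the inner boundary of the
  SAT ring). Mask export traces 0.5-level contours; tracing is sub-pixel
  but not exact at corners, and the tests require a round-trip Dice of at
  least 0.99 rather than identity.
* Localization labels: one CSV per volume, columns `index,label` with
  label ∈ {0, 1, 2}. (Binary renderings `00`/`01`/`10` of the same three
  classes appear in some figures of the source literature; the package
  emits the integer codes.)
* Coordinates are 0-based row-major throughout; slice index 0 is the most
  superior slice.

## Pipeline, problem sizes, reproducibility

`run_pipeline()` chains phantom generation → localizer training →
per-volume lung-range selection (`select_lung_range()`, which repairs an
inverted first/last pair with a warning and never returns an inverted
range) → SAT and VAT segmenter training → evaluation of the held-out
volumes *within their predicted ranges*. The localization and
segmentation datasets are managed independently, linked only at
inference, mirroring how the two stages would be trained on separately
curated label sets. An 8:2 train/validation split and a 4-fold
cross-validation helper (`run_cross_validation()`,
`aggregate_folds()` formatting mean ± sample sd on the percent scale) are
provided for the segmenter. The run directory receives checkpoints, a
per-volume localization CSV, a log, and a JSON manifest recording the
seed, every numerical convention in effect (normalization, natural-log
class weights, α, κ, threshold, momentum), and per-stage metrics.

The package's own test suite and acceptance script run at deliberately
small sizes chosen to keep a full CPU run in minutes while still training
to convergence: 64×64 phantoms, 12–14 slices per volume, 20–30 volumes,
hidden width 8 for the localizer and base width 16 for the segmenter.
512×512 inputs are supported by the same code paths for integration runs.
Under these conditions the phantom localizer typically recovers lung
boundaries with a mean distance well under one slice spacing, and the
MR+ATTN segmenter exceeds 0.9 training Dice on SAT within a few dozen
epochs; `scripts/acceptance.R` recomputes these quantities from scratch
for any seed.

## Known limitations

* Per-sample SGD only (no mini-batching); fine at these sizes, slow for
  512×512 training sets.
* The MR block fuses adjacent encoder levels only.
* Mask polygon tracing assumes regions do not touch the image border
  (phantom anatomy guarantees this; the tracer pads defensively).
* The phantom's simplicity means segmentation metrics on it are
  optimistic relative to clinical data by construction.
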