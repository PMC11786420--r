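---
title: "Classifying physical activity intensity from gravity-based acceleration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying physical activity intensity from gravity-based acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actigaf)
```

# The problem

Wrist-worn triaxial accelerometers record acceleration in units of g at
around 100 Hz over days of free living. A recurring epidemiological task is
to classify each short stretch of signal into one of three physical
activity intensity (PAI) classes — sedentary (SD), light (LPA) and
moderate-to-vigorous (MVPA) — because the classes carry different health
implications. `actigaf` implements a complete pipeline for this task:

1. **ENMO** — reduce the triaxial signal to a gravity-removed movement
   magnitude;
2. **cut-point labelling** — assign SD/LPA/MVPA from cumulative per-second
   acceleration;
3. **GAF encoding** — render each fixed-length temporal window (TW) as a
   Gramian Angular Field image;
4. **ViT-BiLSTM classification** — a vision transformer encodes each image,
   a bidirectional LSTM reads sequences of image features, and a softmax
   head predicts the class;
5. **robustness analysis** — a balanced two-way ANOVA of accuracy across
   TW and PAI.

A seeded synthetic-signal simulator with analytically known ENMO stands in
for annotated free-living data, so the entire pipeline is testable on a
desktop without any external dataset.

# Signal model and preprocessing

## ENMO

For each sample the Euclidean Norm Minus One is

$$\mathrm{ENMO}_t = \sqrt{x_t^2 + y_t^2 + z_t^2} - 1\,g,$$

which removes the static gravity component without frequency-domain
filtering. Negative values (sensor noise, calibration error) are truncated
to zero by default — the convention used before image encoding — and a
signed series is available via `computeEnmo(rec, truncate = FALSE)`.

## Cumulative per-second sums and cut-points

At sampling rate $f_s$ the per-second cumulative sum over second $k$ is
$\sum_{t \in \text{second } k} \mathrm{ENMO}_t$ (units g·s). A 1-s window at
100 Hz therefore accumulates 100 samples; 5-s, 10-s and 15-s windows
accumulate 500, 1000 and 1500.

The adult wrist cut-points used for labelling are 10 and 42 on this
cumulative scale: SD below 10, LPA from 10 to 42, MVPA above 42. Two
conventions needed fixing because the published description leaves them
open:

* **Windows longer than one second.** We label by the *mean* of the
  per-second cumulative sums rather than the whole-window sum, so the
  thresholds are window-length independent: a signal of constant intensity
  receives the same label at every TW in {1, 5, 10, 15, 30} s. This is the
  only reading under which one pair of cut-points serves all window
  lengths.
* **Boundary values.** MVPA is defined strictly as "greater than 42", so
  the bands are SD $[0, 10)$, LPA $[10, 42]$, MVPA $(42, \infty)$; both
  cut-point values themselves label LPA.

Both cut-points are configuration (`intensityThresholds()`), not
constants; the cumulative "g·s" scale is unusual relative to the mg-based
convention elsewhere in the literature, and we make no physiological claim
for specific values.

Incomplete trailing seconds and windows are dropped, never padded: padding
would bias the per-second sums toward zero.

# Gramian Angular Field encoding

Each labelled window $v_1,\dots,v_T$ is encoded as follows.

1. Min-max normalise to $[-1, 1]$:
   $\tilde v_t = \frac{v_t - \min v}{\max v - \min v}\cdot 2 - 1$.
   A constant window (range below $10^{-12}$) is degenerate for this map;
   all its values are set to $-1$ with a warning.
2. Map to polar angles $\theta_t = \arccos(\tilde v_t) \in [0, \pi]$. The
   radius $r_t = t/T$ preserves the time ordering and is retained by
   `toPolar()` for completeness, but it does not enter the image.
3. Build the Gramian matrix $G_{ij} = \cos(\theta_i + \theta_j)$.
   $G$ is symmetric, has entries in $[-1,1]$, and its diagonal satisfies
   $G_{ii} = 2\tilde v_i^2 - 1$ (the double-angle identity) — all three
   properties are asserted in the test suite against a brute-force double
   loop.
4. Rescale to $[0,1]$ by the *fixed* affine map $(g+1)/2$. A per-image
   min-max here would destroy comparability across images, since step 3
   already guarantees the $[-1,1]$ range.
5. Resize the $T \times T$ matrix to the configured resolution (default
   224) by bilinear interpolation with pixel-centre alignment and edge
   replication, quantise to 8 bits (round half up), and replicate the
   grayscale plane into three channels.

Two choices deserve comment. The resize step is needed because a $T\times
T$ Gramian ($T$ = 100…3000 at 100 Hz) must become a fixed-resolution
raster and no construction is prescribed for that step; computing the full
Gramian and resizing is the most faithful reading of the printed formulas.
The three-channel expansion replicates the grayscale plane; any colormap
would be a presentation choice, so it is deliberately not part of the
encoding. The per-channel normalisation means/SDs applied before patch
embedding, `(0.3796, 0.3915, 0.8996)` / `(0.1860, 0.3054, 0.1428)`, are
dataset-derived RGB statistics treated as opaque configuration defaults.

GAF is computed on the ENMO magnitude only, not per axis: the encoded
quantity is "the signal sequence" derived from ENMO, and the magnitude is
what the cut-points are defined on.

# The classifier

## Vision transformer

Images are split into non-overlapping $P\times P$ patches
($N = (H/P)^2$ of them), each flattened and linearly projected:
$z_p = E x_p + e_p$ with learned projection $E$ and positional embedding
$e_p$. A learnable class token is prepended (the standard pooling for this
family of models; the equations themselves leave pooling open). Each
encoder layer applies, in **post-norm** order exactly as printed,

$$z' = \mathrm{LayerNorm}(z + \mathrm{MultiHeadSelfAttention}(z)),\qquad
  z'' = \mathrm{LayerNorm}(z' + \mathrm{FeedForward}(z')),$$

with a GELU two-layer feed-forward block (expansion factor 4). The image
feature is the class-token row after the final layer. Published pretrained
weights for this architecture family use pre-norm ordering; since
pretraining is out of scope for this package, only the post-norm form is
implemented, and `use_pretrained` has no equivalent here — all models are
trained from scratch.

## BiLSTM and head

The "sequence" that the BiLSTM consumes is a run of `seqLen = 4`
consecutive window images from one recording and one TW (this is the
reading under which a sequence length sits naturally alongside the image
processing parameters; the alternative — feeding one image's patch tokens
to the LSTM — is noted as unimplemented). Each image's ViT feature vector
is one LSTM time step. Forward and backward LSTM stacks (2 layers, hidden
size 128 at full scale) read the sequence, and the final hidden states of
the two directions are concatenated:
$h_\mathrm{final} = [h_T^{\rightarrow}; h_T^{\leftarrow}]$, giving 256
features at full scale. The head is dropout (0.5) followed by a linear map
to three logits and a softmax.

A sequence's label is the majority label of its windows, ties resolved in
favour of the most recent window — no labelling rule is prescribed for
multi-window sequences, and recency is the natural tie-break for
streaming data.

## Implementation and initialisation

The network is implemented directly in R on double-precision BLAS matrix
operations, with hand-derived backpropagation through every block
(attention softmax, layer normalisation, GELU, BPTT through both LSTM
directions). The test suite validates all gradients against central finite
differences and the LSTM recurrence against a step-by-step manual oracle.

Linear maps are initialised Glorot-normal
($\sigma = \sqrt{2/(n_{in}+n_{out})}$); class and positional embeddings use
the customary small-normal ($\sigma = 0.02$) init, and LSTM weights the
uniform $\pm 1/\sqrt{H}$ convention. The choice of Glorot over the
small-normal transformer init matters here: with $\sigma = 0.02$
everywhere, the class-token representation of a freshly initialised
network is dominated by the constant class/positional content and barely
depends on the image, and a 10-epoch from-scratch budget is not enough to
escape that regime. Glorot scaling keeps the representation
input-sensitive from the first step.

## Training

Minibatch Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$) on the cross-entropy
loss $L(y, \hat y) = -\sum_i y_i \log \hat y_i$, batch size 16, weight
decay 0.001 added to the gradients, step scheduler multiplying the
learning rate by 0.8 after every epoch, 10 epochs, no early stopping
(epochs are configurable). The default learning rate is $10^{-5}$, the
published fine-tuning rate; from-scratch training at desk scale uses
$10^{-3}$. Splits are 60/20/20 train/validation/test, stratified by
sequence label under a seed — stratification prevents empty-class test
sets at small n, and subject-level grouping is unavailable because the
simulator has no subjects. Training is deterministic given the seed.

# The synthetic-signal simulator

## What it emulates

An `ActivityScript` is an ordered set of constant-intensity segments, each
with an integer duration and a target per-second cumulative ENMO sum on
exactly the cut-point scale. The simulated device has a constant gravity
orientation (unit vector) and optional additive Gaussian sensor noise per
axis.

Movement is collinear with gravity: each sample is
$\mathbf{a}_t = \mathbf{g}(1 + m_t) + \boldsymbol\varepsilon_t$ with
$m_t \ge 0$, so the noise-free ENMO is *exactly* $m_t$ and the simulator
has a closed-form oracle — per-second ENMO sums equal the scripted targets
to machine precision, which the tests assert at $10^{-9}$.

Within each second, $m_t$ is a rectified-sinusoid cadence envelope times a
uniform texture, rescaled to hit the target sum exactly. The cadence rises
with intensity ($0.5 + 0.25\sqrt{\text{target}}$ Hz: roughly 1 Hz
fidgeting at sedentary targets, 1.6 Hz at light, 2.4 Hz at vigorous).
This coupling is the load-bearing design choice of the simulator: the GAF
encoding min-max normalises every window, which erases absolute amplitude,
so a simulator whose only class signal is amplitude produces statistically
near-indistinguishable images across intensities. In real accelerometry,
intensity co-varies with movement tempo; the cadence model reproduces that
covariation and makes the classes separable in image space, which is what
an end-to-end test of the classifier needs.

Noise is added *after* target calibration, so tests that require exact
labels use `noiseSd = 0`, and noisy recordings have approximately (not
exactly) the scripted sums.

## What it does not emulate

No biomechanical gait structure, no postural transitions, no device
non-wear, no diurnal scheduling, no subject-level heterogeneity, no
autocalibration error. Consequently, passing the end-to-end test shows
that the pipeline and optimiser work — windows are labelled correctly,
images carry class information, gradients flow, training converges — but
says nothing about accuracy on real free-living data, which is dominated
by exactly the heterogeneity the simulator omits.

# Evaluation and robustness analysis

`evaluateModel()` produces a 3×3 confusion matrix (rows truth) and derives
overall accuracy, per-class precision $TP/(TP+FP)$, recall $TP/(TP+FN)$,
F1 $= 2PR/(P+R)$ (0 when $P+R=0$), one-vs-rest accuracy, and one-vs-rest
ROC AUC by trapezoidal integration over the threshold sweep. "Per-class
accuracy" is ambiguous between recall and one-vs-rest accuracy, so both
are reported under explicit names. Metrics of a class absent from the test
truth are `NA`, never 0. F1 is reported per class with a macro average;
Cohen's kappa is available behind a flag. The micro-recall/accuracy
identity and the AUC implementation (against pROC) are property-tested.

`twoWayAnova()` implements the classical fixed-effects two-way ANOVA with
interaction by definitional sums of squares, with p-values from the F
survival function and $\alpha = 0.05$ echoed in the output. It accepts
*balanced designs only* (equal replicates per TW × PAI cell, at least two)
and refuses anything else naming the deficient cell: on balanced data
Types I/II/III coincide, so no silent sum-of-squares convention is chosen.
Degenerate inputs are defined explicitly: a factor with zero between-group
variance reports $F = 0, p = 1$; a positive effect with zero residual
variance reports $F = \infty, p = 0$. The replicate unit (per-run
accuracies, per-epoch accuracies, …) is the caller's choice and is
documented as such in the accuracy-table format.

# Numerical conventions, in one place

* ENMO truncation at zero is on by default; off by flag.
* Cut-point bands: SD $[0,10)$, LPA $[10,42]$, MVPA $(42,\infty)$.
* Trailing partial seconds/windows/sequence-runs are dropped with a
  warning, never padded.
* Constant windows normalise to all $-1$ with a warning.
* `toPolar()` clips values within $10^{-9}$ of $\pm 1$ and errors beyond.
* $[0,1]$ rescale is the fixed affine $(g+1)/2$.
* Resize is bilinear, pixel-centre aligned, edge-replicating; quantisation
  is round-half-up to 0–255.
* Sequence label ties break toward the most recent window.
* Split sizes come from largest-remainder rounding per class.
* Layer norm uses $\epsilon = 10^{-5}$; Adam uses $\epsilon = 10^{-8}$;
  softmax uses the max-shift; cross-entropy clamps probabilities at
  $10^{-12}$.
* All randomness (simulator, init, shuffling, dropout) is seeded, and
  library code restores the caller's RNG state.

# Problem sizes used by the tests

The test suite trains the `tiny = TRUE` configuration (image 64, patch 8,
embedding 32, depth 2, heads 2, LSTM hidden 32) on 300 simulated sequences
(100 per class, 1-s windows, targets 5/20/60 g·s, noise SD 0.01 g) for 10
epochs at learning rate $10^{-3}$ across three seeds — sizes chosen so the
whole suite runs comfortably on a single desktop core. Oracle checks use
1000 unit-norm recordings, 100 random series up to length 256 for the
Gramian brute-force comparison, 200 random balanced tables plus 1000 null
tables for the ANOVA, and 100 random confusion matrices for the metric
identities. The full-size architecture (224 px, patch 16, embedding 768,
depth 12, BiLSTM 128×2) is constructed and shape-checked but not trained.

# Known limitations

* Only post-norm encoder ordering exists; published pre-norm pretrained
  weights cannot be loaded.
* GAF is magnitude-only; per-axis encodings are not implemented.
* The Gramian Angular *Difference* Field, Markov transition fields and
  recurrence plots are out of scope.
* The ANOVA is fixed-effects and balanced-only; repeated-measures and
  post-hoc corrections are not provided.
* The simulator's realism limits are described above; its accuracy numbers
  should never be quoted as evidence about real populations.
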