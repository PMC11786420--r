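# actigaf

Physical activity intensity classification from gravity-based wrist
acceleration, via Gramian Angular Field images and a hybrid
ViT-BiLSTM classifier — implemented end to end in R.

## Who this is for

Researchers in physical-activity epidemiology and digital health who work
with raw triaxial accelerometer recordings (e.g. wrist-worn devices
sampling at 100 Hz) and want to classify short temporal windows of signal
into the three standard intensity classes — sedentary (SD), light (LPA)
and moderate-to-vigorous (MVPA) — with a deep image-based classifier
rather than hand-crafted features, and to quantify how robust the
classifier is to the choice of temporal window.

## What it computes

**ENMO.** The per-sample movement magnitude

```
ENMO_t = sqrt(x_t² + y_t² + z_t²) − 1 g
```

with negative values truncated to zero.

**Cut-point labels.** Windows are labelled from the mean of their
per-second cumulative ENMO sums (units g·s per second): SD below 10,
LPA from 10 to 42 inclusive, MVPA strictly above 42. Cut-points are
configurable.

**GAF images.** Each window `v_1 … v_T` is min-max normalised to
`[−1, 1]`, mapped to polar angles `θ_t = arccos(ṽ_t)`, expanded to the
Gramian matrix `G[i,j] = cos(θ_i + θ_j)`, affinely rescaled to `[0, 1]`,
and rendered as a fixed-resolution 3-channel 8-bit raster (default
224 × 224).

**ViT-BiLSTM.** A vision transformer (patch embedding `z_p = E·x_p + e_p`,
post-norm encoder layers
`z′ = LayerNorm(z + MHSA(z))`, `z″ = LayerNorm(z′ + FFN(z′))`) encodes
each image into its class-token feature; a 2-layer bidirectional LSTM
reads sequences of 4 consecutive image features; the concatenated final
hidden states `h_final = [h→; h←]` feed a dropout + softmax head over the
three classes. The network, including all backpropagation, is implemented
in base-R matrix algebra and trained with Adam (β₁ = 0.9, β₂ = 0.999),
cross-entropy loss, batch 16, step learning-rate decay (γ = 0.8 per
epoch), 10 epochs, stratified 60/20/20 splits.

**Evaluation and robustness.** Confusion matrix, overall and per-class
accuracy, precision/recall/F1, one-vs-rest ROC AUC, and a balanced
two-way fixed-effects ANOVA (definitional sums of squares) of accuracy
across temporal window × intensity.

**Simulator.** A seeded synthetic-signal generator with analytically
known ENMO: movement is collinear with gravity, so per-second ENMO sums
equal scripted targets exactly, and movement cadence rises with intensity
so that the normalised GAF images remain class-separable. It stands in
for annotated free-living data at desk scale.

## Worked example

```r
library(actigaf)

# 1. simulate a 60 s recording: 20 s sedentary, 20 s light, 20 s MVPA
sc  <- activityScript(durations = c(20, 20, 20), targets = c(5, 20, 60),
                      noiseSd = 0.01, seed = 42)
rec <- generateRecording(sc, fs = 100)

# 2. ENMO -> 5 s windows -> labels
ws <- segmentWindows(computeEnmo(rec), twS = 5)
ws
#> WindowSet: 12 window(s) of 5 s @ 100 Hz
#>   SD  LPA MVPA
#>    4    4    4

# 3. train the desk-scale classifier on simulated sequences
ds    <- simulateIntensityDataset(nPerClass = 100, twS = 1, noiseSd = 0.01,
                                  resolution = 64, seed = 1)
sp    <- splitDataset(ds, seed = 1)
model <- vitBilstm(tiny = TRUE, seed = 1)
fit   <- trainModel(model, sp$train, sp$val,
                    trainConfig(lr = 1e-3, epochs = 10, seed = 1))
evaluateModel(fittedModel(fit), sp$test)
#> MetricsReport: accuracy 0.9333, macro F1 0.9332
#> Confusion (rows = truth, cols = predicted):
#>       predicted
#> truth  SD LPA MVPA
#>   SD   20   0    0
#>   LPA   0  17    3
#>   MVPA  0   1   19
#>   class recall ovrAccuracy precision     f1    auc
#> 1    SD   1.00      1.0000    1.0000 1.0000 1.0000
#> 2   LPA   0.85      0.9333    0.9444 0.8947 0.9925
#> 3  MVPA   0.95      0.9333    0.8636 0.9048 0.9888
```

The report reads: 93.3% of the 60 held-out sequences are classified
correctly; sedentary sequences are never confused with the active
classes, and the few errors swap light and vigorous activity — per-class
recall is the "per-class accuracy" in the usual sense, `ovrAccuracy` is
its one-vs-rest counterpart, and `auc` is the one-vs-rest ROC area from
the predicted probabilities.

```r
# 4. robustness of accuracy across temporal window x intensity
set.seed(1)
tab <- expand.grid(tw = c(1, 5, 10, 15, 30), pai = c("SD", "LPA", "MVPA"),
                   replicate = 1:2)
tab$accuracy <- 0.95 + rnorm(nrow(tab), 0, 0.01)   # replicate accuracies
twoWayAnova(tab)
#> Two-way ANOVA (balanced, alpha = 0.05)
#>     term         ss df         ms       F       p
#> 1     tw 0.00023845  4 5.9613e-05 0.80573 0.54044
#> 2    pai 0.00010208  2 5.1042e-05 0.68988 0.51687
#> 3 tw:pai 0.00102627  8 1.2828e-04 1.73389 0.17055
#> 4 within 0.00110979 15 7.3986e-05      NA      NA
#> 5  total 0.00247660 29         NA      NA      NA
```

Here neither factor reaches significance at α = 0.05, i.e. the simulated
accuracies are consistent across windows and intensities.

A thin command-line wrapper over the same functions lives in
`inst/scripts/actigaf.R` (`simulate`, `preprocess`, `encode`, `anova`
subcommands).

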