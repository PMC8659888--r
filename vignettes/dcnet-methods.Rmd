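---
title: "Densely connected encoder-decoder segmentation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Densely connected encoder-decoder segmentation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcnet)
```

## The problem

Gross tumor volume delineation on T1-weighted MR slices is a binary
segmentation task with two hard properties: the tumor occupies a small and
*highly variable* fraction of the slice (in our phantom model, between 0.1%
and 8% of the pixels, spanning almost two orders of magnitude), and its
boundary is irregular rather than cylindrical. A segmentation network
therefore needs large receptive fields to *locate* lesions of any scale,
and fine spatial detail to *delineate* their boundary. `dcnet` implements
an encoder–decoder convolutional network designed around exactly this
tension, together with everything required to train and evaluate it:
preprocessing, a class-imbalance-aware loss, overlap metrics, an exact
rank-sum test, and a synthetic phantom generator so that the whole pipeline
is exercisable without patient data.

## Architecture

The encoder is a densely connected convolutional network. It contains five
dense blocks (DB1–DB5) of 12 layers each with growth rate 12: inside a
block, layer $k$ receives the channel concatenation of the block input and
all previous layer outputs,

$$y_k = H(y_1 \oplus y_2 \oplus \dots \oplus y_{k-1}),$$

and contributes 12 new channels. $H$ is a pre-activation unit
(BN → ReLU → convolution); the 3×3 convolutions are *dilated* (dilation 1
in the first two blocks, 2 afterwards) so the receptive field keeps growing
after down-sampling stops, and all convolutions use zero "same" padding
(outside the head no tissue exists, so zero intensity is the physically
correct padding). Between blocks, a transition (BN → ReLU → 1×1
convolution) compresses the concatenated channels to the fixed schedule
(80, 112, 118, 136, 16); after the first two blocks a 2×2 average pooling
halves the resolution, so the per-block feature sizes for a 256×256 input
are (256, 128, 64, 64, 64). The last transition is a bare convolution
(no BN/ReLU).

On the deepest 64×64 feature map a PSPNet-style pyramid pooling module
(PPM) pools to 1×1, 2×2, 3×3 and 6×6 bins, processes each pooled map with
BN → ReLU → 1×1 convolution, upsamples back bilinearly, concatenates with
the input and fuses with a BN → ReLU → 3×3 convolution. The 1×1 bin
injects truly global context — its pre-convolution content is exactly the
feature-wise global mean.

The decoder mirrors the encoder. Every encoder level is compressed to 16
channels by a 1×1 *skip* convolution,

$$t_{k} = \mathrm{Conv}(y_{k}),$$

and each decoder level concatenates the upsampled deeper decoder feature
with its skip, fuses with BN → ReLU → 3×3 convolution, and emits a
1-channel head that is bilinearly upsampled to the input resolution and
squashed with a sigmoid:

$$S_k = \mathrm{Sigmoid} \circ H(S_{k-1} \oplus t_{k-1}).$$

The deepest prediction $S_5$ comes from the PPM output alone. The five
side outputs $S_1\ldots S_5$ (pre-sigmoid) are concatenated and fused by a
final BN → ReLU → 3×3 convolution into $S_0$, the map used for
segmentation. Masks are produced by thresholding at 0.5, with the tie
assigned to foreground.

```{r architecture}
net <- dcnet_network(dcnet_config(), seed = 1)
net
```

### Design choices the reference description leaves open

Several internals are not pinned down by the reference description; the
package resolves them as follows and exposes each as a configuration
field.

* **Dense-layer internals and the parameter budget.** The architecture is
  specified to have ≈0.28 M trainable parameters. Plain 3×3 convolutions
  on the full concatenated inputs would require ≈1.2 M parameters at the
  published channel schedule — incompatible with the budget by a factor of
  four, independent of any free width. Each dense layer is therefore
  bottlenecked (DenseNet-B style): BN → ReLU → 1×1 convolution to 8
  channels, then BN → ReLU → dilated 3×3 convolution to the growth width.
  With the stem at 16 channels, pyramid branches at 4 and the decoder
  fusion width at 12, the network has `r format(count_parameters(net),
  big.mark = ",")` trainable parameters, within 2% of the budget.
* **The recursion variable.** In the decoder recursion the deeper input
  $S_{k-1}$ is interpreted as the deeper *feature* map (12 channels,
  pre-sigmoid), not the 1-channel probability map: a 1-channel recursion
  would discard nearly all information between levels.
* **The stem.** The entry into DB1 is a single 3×3 convolution from the
  grayscale input to 16 channels.
* **Dilation schedule.** Dilation factors are never stated; the default
  (1, 1, 2, 2, 2) enlarges receptive fields exactly where pooling stops.
* **Upsampling** is bilinear for features and logits; **mask resampling**
  is nearest-neighbour everywhere so masks stay binary.
* **Dropout** (rate 0.2) follows each dense-layer convolution during
  training.
* **Ablation toggles.** `dcnet_variant("B")` removes the PPM, `"C"` the
  skip connections, `"D"`/`"E"` use four/six blocks (the sixth block adds
  140 channels between the last block and the PPM), `"F"` supervises only
  $S_0$, and `"G"` replaces dense connectivity with sequential blocks of
  matched output width.

## Loss

Every level $S_0 \ldots S_5$ carries the same combined loss
$J(P) = \mathrm{CE}(P) + \mathrm{DL}(P)$, and the training objective is
the *integrated* sum $\sum_k J(S_k)$ — deep supervision that feeds a
gradient directly into every decoder level, the stated remedy for
vanishing gradients in deep decoders. The single-loss ablation uses
$6\,J(S_0)$ so both objectives share a scale.

CE is pixel-wise weighted cross-entropy

$$\mathrm{CE}(P) = -\frac{1}{V} \sum_{i,j} \big[\lambda\,\omega\,
G_{ij} \log P_{ij} + (1 - G_{ij}) \log (1 - P_{ij})\big],
\qquad \omega = \frac{V - V_{P1}}{V_{P1}},$$

with $V$ the pixel count of the slice and $V_{P1}$ the soft predicted
tumor area $\sum P$. $\omega$ is the background/foreground area ratio, so
the scarce tumor class is up-weighted; it is treated as a constant during
differentiation. Two numerical decisions matter in practice:

* $V_{P1}$ is floored at the ground-truth area $|G_1|$ (and at one pixel).
  Without the floor an under-predicting model drives $\omega$ toward
  $1/\varepsilon$ and the foreground gradient diverges — in early joint
  training this is a positive feedback loop that reliably blows the run
  up. With the floor, $\omega$ saturates at the true class ratio and the
  summed foreground gradient is bounded by about 1 per slice.
* $\lambda$, the coefficient "controlling the influence of the weight", is
  not reported for the original experiments. The package default is
  $\lambda = 1$, i.e. the unscaled background/foreground area ratio.
  Larger values speed up early foreground learning but bias the 0.5
  decision boundary toward over-segmentation (in matched phantom runs,
  $\lambda = 5$ drove the relative volume difference to +2.8 and capped
  the mean Dice score; $\lambda = 1$ trains stably and scores higher).

DL is the generalized Dice loss with class weights $1/|G_1|$ and
$1/|G_0|$,

$$\mathrm{DL}(P) = 1 - 2\,\frac{\omega_1 |P_1 \cap G_1| + \omega_0 |P_0
\cap G_0|}{\omega_1 (|P_1| + |G_1|) + \omega_0 (|P_0| + |G_0|)},$$

computed with soft intersections, which makes it smooth in $P$ and exactly
0/1 for perfect/complementary binary predictions.

```{r loss}
# worked two-pixel example: G = (1, 0), P = (0.5, 0.5)
weighted_ce(c(0.5, 0.5), c(1, 0), loss_config(lambda = 1))   # log 2
generalized_dice_loss(c(0.5, 0.5), c(1, 0))                  # 0.5
```

## Training protocol

Training uses stochastic gradient descent (learning rate $10^{-4}$, batch
size 8, momentum 0.9) in three stages of equal length: stage 1 freezes
the decoder and trains the encoder, stage 2 freezes the encoder and trains
the decoder, stage 3 trains everything. Each stage starts with a fresh
learning rate, scheduler and momentum state (the stages are described as
independent phases). Within a stage, the learning rate is multiplied by
0.1 whenever the validation Dice coefficient has not risen for ten
epochs. The parameter state with the best validation DSC seen anywhere is
retained as the checkpoint. Data are split 30/10 into training and
validation scans (the held-out subset both drives the plateau rule and
serves as the test set — the reference protocol uses it in both roles), and optional
cross-validation repeats the split/train cycle, yielding per-trial DSC
vectors that feed the exact Mann–Whitney test.

Two pragmatic additions keep the schedule robust: momentum buffers are
cleared at stage boundaries (stale cross-stage momentum destabilizes the
joint stage), and a global gradient-norm clip (default 10, configurable,
`Inf` to disable) guards against the rare outlier batches that the
area-ratio weight can still produce.

Augmentation — the standard remedy for few labeled slices — applies
rotation (uniform in ±10°), horizontal flip and integer translation
(±10 px), each independently with probability 0.5, re-sampled every
epoch. The exact mix used originally is not stated; the probabilities are
configurable. The same geometric transform acts on image (bilinear) and
mask (nearest-neighbour).

## Preprocessing

Volumes are reoriented to RAS+ by axis permutation/flip, min–max
normalized to $[0, 1]$ per volume (the simplest map satisfying the stated
contract; constant volumes map to zero with a warning), and slices are
resampled to 256×256 at 1 mm using separable natural cubic splines
(nearest-neighbour for masks). Natural splines reproduce linear ramps
exactly, which gives a sharp correctness oracle for the resampler.

## Metrics

Six overlap quantities are computed on binary masks: DSC
($2|P \cap G| / (|P| + |G|)$), sensitivity, specificity, positive
predictive value, volumetric overlap error ($1 -$ Jaccard) and relative
volume difference. Degenerate denominators follow declared conventions
(two empty masks have DSC 1 and VOE 0; SEN/PPV/RVD are reported as
missing where undefined) so that batch evaluation is total. One printed
source formula omits DSC's conventional factor 2; the package implements
the standard definition and exposes the printed variant behind
`printed_formula = TRUE` for auditing. Model comparison uses an *exact*
two-sided Mann–Whitney U test: all $\binom{n+m}{n}$ group assignments are
enumerated (via a subset-sum dynamic program over doubled mid-ranks, so
ties are handled), which is the appropriate test at cross-validation
sample sizes of four.

```{r mw}
mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))  # complete separation, 2/70
```

## The phantom generator

Real patient scans are private, so the package ships a generator whose
statistics mirror what the architecture is built for, not what real
anatomy looks like. Each phantom is a smooth low-frequency Gaussian field
(anatomy surrogate, interpolated from a 6×6 coarse grid) plus per-pixel
noise, min–max scaled into $[0, 0.55]$; the tumor is a union of one to
three ellipse-like lobes with low-order radial boundary perturbation,
whose per-pixel intensity is drawn from $\mathcal N(0.75, 0.08^2)$ —
bright on T1, but overlapping the upper background range so the task is
not pure thresholding. Tumor area fractions are drawn *log-uniformly*
from (0.001, 0.08) so that small scales are as frequent as large ones —
the scale-variation problem the multi-level design targets. Generation is
deterministic per `(seed, index)`, so datasets are reproducible pair by
pair and file by file.

What passing phantom tests does and does not show: the phantoms exercise
class imbalance, scale variation, irregular boundaries and intensity
noise, but not bias fields, partial-volume effects, multi-focal disease
far apart, or anatomy that mimics tumor intensity. Results on phantoms
bound the pipeline's correctness, not its clinical performance.

## Numerical and performance choices

All network computation runs in compiled kernels inside the package
(im2col/GEMM and direct 3×3 convolutions, fused BN+ReLU with batch
statistics shared across the dense-block layers that read the same
buffer, bilinear and adaptive pooling with exact adjoints). Activations
and their gradients are carried in single precision — the standard
deep-learning practice — while master weights, parameter gradients and
batch-norm statistics stay in double; a double-precision activation path
is retained and is what the finite-difference gradient tests run against
(they agree with analytic gradients to ~1e-4 relative). Batch-norm uses
biased batch variance and momentum 0.1 running moments. He-normal
initialization everywhere; the 1-channel heads start with bias −3 so the
initial foreground probability matches the class prior rather than 0.5.

The test suite's training study is scaled down to the generator's
conditions at 64×64 (200 training and 50 held-out phantoms, three stages
of 10 epochs, batch 8), which trains the full reference architecture in
roughly a quarter hour on one CPU core; the full 3×100-epoch protocol at
256×256 is the same code path.

## Known limitations

* The benefit of deep supervision is budget-dependent. In the scaled-down
  phantom study that ships with the test suite (three stages of 10 epochs
  instead of 100), the single-loss variant F can out-score the integrated
  loss: stage 1 trains the encoder against six frozen, randomly
  initialized heads, and under the integrated loss this demonstrably
  distorts the encoder (validation DSC falls while the training loss
  improves), a cost the short budget never amortizes. Run-to-run seed
  variability of the final mean DSC is large (of order 0.1) at these
  budgets.
* 2-D only: volumes are split into transverse slices; no 3-D convolutions.
* No pretrained weights, no test-time augmentation, no CRF/morphological
  post-processing.
* The exact augmentation proportions and $\lambda$ of the original
  experiments are unknown; defaults are this package's own calibration.
* `count_parameters()` counts convolution weights/biases and BN
  scale/shift pairs; running moments are buffers and excluded.
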