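---
title: "Methods: automated RORA segmentation in macular OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated RORA segmentation in macular OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Retinal pigment epithelium and outer retinal atrophy (RORA) is the
OCT-based consensus definition of atrophy in dry age-related macular
degeneration: a zone of choroidal hypertransmission with absent or
attenuated RPE and degenerating overlying photoreceptors. Graders delineate
RORA on each b-scan of a macular SD-OCT cube with lateral bounding boxes —
only the horizontal extent carries information, because the clinical
quantity of interest is the *en-face* atrophy footprint and its area. This
package implements a fully automated pipeline that reproduces that reading:
a convolutional encoder–decoder predicts a per-pixel atrophy probability on
each b-scan, the per-b-scan maps are max-projected along depth into an
en-face probability map, and the map is thresholded at 0.5.

## Training targets: the layer prior

The graded annotation constrains only the lateral extent of atrophy; its
vertical span is undefined. Two training formulations are implemented:

* **Layer-prior (2D) mode.** The training target for a b-scan is the
  intersection of the annotated lateral extent with the
  photoreceptor–RPE–choroid band taken from a retinal layer segmentation:
  `target(r, c) = 1` iff column `c` is inside an annotated interval *and*
  pixel `(r, c)` is labelled photoreceptors, RPE or choroid. The focal
  binary cross-entropy is computed per pixel over the whole image; pixels
  inside the lateral extent but outside the band count as negatives. This
  steers the network's attention to the layers whose state defines RORA,
  rather than letting it latch onto hypertransmission alone. Layer masks
  are consumed *only* in training — the inference path has no layer input,
  by construction of the function signatures.
* **Projection (1D) mode** — the ablation baseline. Without a layer prior
  the vertical span of the target is undefined, so the loss is computed in
  1D between the column-wise maximum of the predicted probability grid and
  the 0/1 lateral-extent vector. Gradients flow through the maximal element
  of each column (the true maximum is used, not a soft relaxation — the
  simplest faithful reading of a maximum-probability projection).

The band is the three-layer union (photoreceptors + RPE + choroid),
configurable to RPE + choroid via the `band` argument; photoreceptor
involvement is part of the atrophy definition, so the wider band is the
default. Out-of-band in-extent pixels are treated as negatives rather than
masked out of the loss: the target is a well-defined binary image and the
network is explicitly discouraged from marking atrophy outside the relevant
layers.

## The network and the loss

The segmentation network is a compact fully convolutional U-Net-style
encoder–decoder implemented directly in the package (compiled primitives
for patch extraction, pooling and upsampling; BLAS matrix products for the
convolutions; hand-written backpropagation; Adam). Three resolution levels,
3×3 convolutions with ReLU, 2×2 max pooling, nearest-neighbour upsampling
with skip concatenation, and a sigmoid 1×1 output head. Two encoder widths
ship: `tiny` (6/12/24 channels, ≈14k parameters) and `small` (12/24/48).
The clinical-scale configuration of this method uses an ImageNet-pretrained
EfficientNet-b3 encoder;
no pretrained weights ship here, and the architectural novelty being
evaluated — the construction of the training target — is independent of the
backbone width.

The loss is the focal binary cross-entropy
`FL(p_t) = −(1 − p_t)^γ · log(p_t)` with `p_t = p` for positive and `1 − p`
for negative pixels, averaged over elements, with γ = 2 by default. γ = 0
reduces exactly to plain BCE (pinned by test). Probabilities are clamped to
`[1e-12, 1 − 1e-12]` inside the loss and `[1e-7, 1 − 1e-7]` inside the
gradient.

### Hyperparameters

`train_config()` defaults are the clinical-scale recipe: Adam, learning rate
2.5e-5, batches of 32 b-scans, 50 epochs, focal γ = 2, augmentation by
horizontal flip, scaling in 0.8–1.2 (restored to the input size by centre
crop/zero pad), Gaussian blur and additive noise. That learning rate is
matched to fine-tuning a large pretrained encoder. A compact network
trained from random initialisation on a desk-scale cohort sees only a few
hundred optimisation steps in 15 epochs; at 2.5e-5 the parameters cannot
leave the initialisation basin, so `desk_profile()` — the configuration
used by the bundled experiments — trains the tiny encoder with Adam at
1e-3 and batches of 8 b-scans for 15 epochs. This is a deliberate,
documented re-scaling of the optimisation to the model size, not a change
to the method. Per-b-scan min–max normalisation to [0, 1] is applied before
every forward pass (no particular normalisation is prescribed by the
clinical-scale recipe; a
fixed affine map would tie the phantom and any real data to one intensity
calibration).

## Inference

`predict_volume()` runs each b-scan through the network, takes the
column-wise maximum along depth of each probability map (`project_enface`),
and thresholds at 0.5 (`binarize_enface`). The threshold comparison is
inclusive (`≥ 0.5`), a documented constant, and no post-processing is
applied — no morphological cleanup and no minimum-area filter — so the
known bias of maximum projection toward false positives is preserved rather
than hidden. Max projection commutes with thresholding (pinned by a
property test), so the en-face binary map equals the projection of
voxel-wise thresholded maps.

## Lesion classification

Each annotated interval becomes a lesion: width in µm is
`(end − start) × fast-axis spacing × 1000`; a lesion is cRORA iff its width
reaches 250 µm, else iRORA. The consensus wording ("larger than" /
"less than" 250 µm) leaves exactly 250 µm unassigned; the package assigns
it to cRORA (inclusive upper class, a documented constant). En-face
components are built by linking intervals on *adjacent* b-scans whose
column ranges overlap by at least one column — no diagonal or
gap-jumping links, the simplest reading of "neighbouring". On the
rasterized en-face map this equals plain 4-connectivity, which is the
brute-force oracle used in the tests. A component is an *isolated iRORA*
lesion iff every member interval is iRORA; `discovery_rate()` is the
fraction of isolated-iRORA components touched by at least one positive
pixel of a prediction, and is `NA` when no isolated lesion exists.

## Evaluation

All metrics are computed per test volume on en-face pixels and then
averaged (never pixel-pooled across volumes): Dice, precision, recall
(sensitivity) and Cohen's kappa with chance agreement from the per-volume
pixel marginals. Degenerate conventions, pinned by tests: two empty masks
agree perfectly (all metrics 1); an empty prediction against a nonempty
reference scores 0 on Dice/precision/recall; when both masks are constant
(chance agreement 1) kappa is 1 on agreement and 0 otherwise. Areas are
positive-pixel counts × slow spacing × fast spacing (mm²). Aggregation and
Bland–Altman use the sample (n−1) standard deviation; limits of agreement
are mean ± 1.96 sd of the pairwise differences. Cross-validation folds
partition *patients*, so no eye or volume of one patient ever spans the
train/test boundary.

## The synthetic phantom

No clinical OCT data ships with the package; every stage is exercised on a
generated phantom (`synth_config()` / `generate_volume()` /
`generate_cohort()`) that emulates the qualitative OCT reading criteria:

* **Geometry.** Desk scale is 16 b-scans of 64 × 128 px covering 6 × 6 mm
  en face with a 1.92 mm axial window (fast-axis pixel ≈ 47 µm); the
  Spectralis-like 49 × 496 × 512 geometry is available through the same
  configuration. All bundled experiments and tests use the desk scale: a
  30-volume cohort (24 train / 6 test) trains in minutes on one CPU.
* **Layers.** Smooth low-frequency surfaces (sinusoid mixtures) separate
  inner retina, photoreceptors, RPE and choroid over background, with
  baseline reflectivities 0.32 / 0.22 / 0.85 / 0.28 on [0, 1]. Surfaces
  undulate so that a flat-layer shortcut cannot solve the task.
* **Atrophy.** An en-face footprint is drawn as a sum of anisotropic
  Gaussian blobs thresholded at the intensity quantile that yields the
  requested area fraction — level-set borders stay smooth, multifocality
  arises naturally, and the requested area is honoured (a half-max
  threshold cannot honour a requested area, which is why the quantile rule
  is used). Inside the footprint the RPE reflectivity is multiplied by
  `rpe_attenuation` (default 0.15), the choroid by
  `hypertransmission_gain` (default 1.8), and the photoreceptor band is
  thinned by at least half. Per-b-scan annotation intervals are exactly the
  atrophic column runs.
* **Drusen.** Dome-shaped RPE elevations with a medium-reflectivity core
  and *no* transmission change, placed strictly outside the footprint —
  confounders that punish a pure-brightness shortcut.
* **Noise.** Multiplicative mean-1 gamma speckle (relative sd
  `speckle_sigma`, default 0.15) followed by additive Gaussian noise
  (sd `speckle_sigma/5`), clipped to [0, 1]; `speckle_sigma = 0` yields a
  perfectly clean volume for oracle-style tests.
* **Cohorts.** Each volume gets a distinct patient id and a derived seed;
  across diseased volumes the blob count (1 to template+1), area fraction
  (0.5–2× template) and drusen count vary, mimicking the small-to-confluent
  lesion spectrum of a clinical cohort.

What the phantom does *not* model: physical speckle correlation, vessel
shadows, motion artefacts, vendor-specific intensity curves, ill-defined
atrophy borders, or disagreement between graders (the ground truth is
exact). Passing the synthetic analogue therefore shows that the pipeline's
mechanics — target construction, optimisation, projection, thresholds,
metrics — are correct and that the model learns the intended layer-level
cues; it does not certify clinical performance.

## Numerical choices and degenerate inputs

* Network input dimensions must be multiples of 4 (two pooling levels);
  violated shapes raise an error rather than silently resizing.
* A constant b-scan normalises to all-zeros instead of dividing by zero.
* Max-pooling ties resolve to the first (top-left) element; the projection
  loss routes gradients through the first maximal element of a column.
* Interval coordinates are 0-based half-open `[start, end)` everywhere;
  en-face rows are b-scans, columns are a-scan positions. B-scan indices in
  the JSON schema are 0-based.
* `generate_volume` rejects area fractions that round to zero pixels or
  exceed 0.8 of the grid.
* Training is bit-reproducible for a fixed seed (private RNG streams; the
  global RNG state is saved and restored).

## Known limitations

* The phantom's contrast between atrophic and healthy tissue is stronger
  than many real low-quality scans; reported synthetic metrics sit above
  the clinical numbers for exactly that reason.
* The projection-mode ablation trains the same compact backbone. Because
  its gradients flow only through the maximal element of each column —
  roughly 1.5% of the pixels that the 2D loss touches — the baseline
  learns far more slowly, and within the desk-scale epoch budget it barely
  leaves its initialisation (its training loss is still falling at the
  last epoch). The ablation therefore shows the *direction* of the
  clinical-scale comparison (recall drops without the layer prior) in an
  extreme form; the size of the gap is not comparable to a long training
  run with a large pretrained encoder.
* `discovery_rate` is the only iRORA-level statistic implemented; a
  lesion-level interobserver agreement statistic is not defined in the
  package.
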