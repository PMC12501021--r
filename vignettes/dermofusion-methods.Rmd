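---
title: "dermofusion: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dermofusion: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of what it computes, which
knobs matter, and where the design was genuinely open — the level of
detail a maintainer or reviewer needs before trusting a number it
produces.

## 1. The preprocessing model

### Adaptive average filter

Each pixel is moved towards its local mean by a data-dependent amount:

    I_a(i,j) = mu_L(i,j) + r(i,j) * (I(i,j) - mu_L(i,j)),
    r = (sigma_L^2 - sigma_N^2) / sigma_L^2

where `mu_L` and `sigma_L^2` are the mean and population variance of a
`w x w` window and `sigma_N^2` an assumed noise variance. The formula as
written is undefined at `sigma_L^2 = 0` and negative when the local
variance falls below the noise floor, so we **clamp r to [0, 1]** and
treat zero-variance windows as `r = 0`. The clamp makes the output a
convex combination of the pixel and its local mean, which gives the
testable guarantee that outputs never leave the local window's value
range. At `sigma_N^2 = 0` the filter is exactly the identity.

*Window* `w`: odd, default **7 px** — small enough to preserve lesion
boundary structure at typical dermoscopy resolutions, large enough for a
stable variance estimate (49 samples).

*Noise variance*: nothing in the formulation says how to obtain it, so
the package estimates it as the **median of the local-variance map**.
Most windows of a dermoscopic image are smooth skin whose local variance
is essentially noise variance; the median ignores the minority of
high-variance windows that straddle lesion structure. A fixed value can
be supplied instead for reproducible pipelines.

### Laplacian sharpening and fusion

A 3×3 discrete Laplacian is convolved with the *smoothed* image and the
response **added** to it (`enhanced = adaptive + laplacian`), then
clipped to [0, 255]. Note this is the literal additive fusion, not the
classical `f - c * laplacian` sharpening; with the 8-neighbour kernel
(centre −8, default; the 4-neighbour variant is selectable) the additive
form still boosts local contrast at edges, and the clip keeps the result
a valid image. Borders use reflect padding everywhere, which avoids
spurious responses at the frame.

### Hair removal

Hairs are thin, dark, elongated. For each of `n_orientations` (default
**8**, uniformly covering 0–180°) linear structuring elements of length
`se_length` (default **17 px**, forced odd), the grayscale closing of the
luminance image is computed; closing fills dark structures narrower than
the element, so `max(closings) - image` is large exactly on hair-like
structure. The residual is thresholded — **Otsu** by default, a fixed
value for reproducible tests — and the mask dilated by
`dilation_radius` (default 1 px) to cover anti-aliased hair borders.
These defaults follow long-standing razor-style practice; nothing in the
source formulation fixes them, so they are configuration, not contract.

Two caveats the tests make explicit. First, sharp lesion rims can leave
a 1–2 px residual ring (a known artifact of morphological hair
detection); with Otsu thresholding some rim pixels may enter the mask.
This costs precision, never recall, and inpainting is conservative, so
the pipeline tolerates it. Second, the detector is invariant to global
additive intensity shifts only under a *fixed* threshold (the residual
is shift-invariant; Otsu's threshold is recomputed per image on an
almost identical histogram).

Inpainting replaces each masked pixel by the inverse-Euclidean-distance
weighted mean of the non-hair pixels in a window that grows until at
least `inpaint_min_neighbors` (default 4) donors are present. Donors are
always original values, so the result is independent of pixel visiting
order, and unmasked pixels are returned bit-identical. An all-ones mask
has no donors and errors.

## 2. Class balancing

Factors are `F_c = round_half_up(T / N_c)`, floored at 1, with the
dominant class fixed at factor 1; targets are exactly `N_c * F_c`.
Round-half-up reproduces six of the eight published factors for the
reference inventory; the VASC (49.4 → printed 52) and BCC (37.7 →
printed 64) rows cannot be derived from any rounding of `T / N_c` and
are handled as **explicit overrides**, which the plan records. The BCC
row is additionally inconsistent with its own printed product
(212 × 64 ≠ 8504); the planner reports the true product and the
documentation flags the row rather than attempting to reproduce it.
The planner is label-agnostic — it balances whatever classes appear in
the inventory (the reference table has eight, including SCC, although
the classification task is seven-class).

Transform parameter ranges (rotation ≤ ±30°, zoom 0.9–1.1, photometric
gains 0.8–1.2) are the package's defaults, chosen to stay within what a
clinician would accept as the same lesion; the source gives none.
Geometric transforms resample on the same canvas with reflection fill,
so canvas size and label never change.

## 3. The transformer branch

Images are resized (bilinear) to 600 × 450 and cut into non-overlapping
30 × 30 patches — 300 tokens, each linearly projected to `D` dimensions.
`D` is never stated in the source; the package defaults to **256** so
tokens match the SDEB's fused channel count, which must equal `D`
because SDEB output feeds the encoder directly.

Positional encodings are the fixed sinusoids
`PE(pos, 2i) = sin(pos / base^(2i/D))`, `PE(pos, 2i+1) = cos(...)` with
**base 1000** (as printed in the source formulation, not the
conventional 10000; the base is a parameter). The printed equations give
the same left-hand side for both lines; we assign sine to even and
cosine to odd dimensions per the standard convention.

### Spatial Detail Enhancement Block

Three parallel convolutions (3×3/64, 5×5/128, 7×7/256, each ReLU) are to
be combined element-wise — but a direct sum of 64-, 128- and 256-channel
maps is dimensionally impossible as specified. The package inserts
**per-branch 1×1 projections to the fused channel count C** (default
256) before the sum, the minimal change that makes the element-wise
reading well-defined (the prose also mentions "joined"/concatenation; we
follow the summation reading and note the conflict here). The sum then
passes through a 1×1 convolution with ReLU. Because SDEB is specified to
act *after* patch embedding, the token sequence is reshaped onto its
patch grid (15 × 20 for the full geometry) for convolution and flattened
back to tokens afterwards. Inputs smaller than the largest kernel (7)
error out. Weights are He-normal with zero biases — conventional for
ReLU stacks, unstated in the source.

### Encoder

Each of the blocks applies: layer-norm → multi-head attention →
layer-norm → **residual add** → MLP → **residual add**. Residual
connections are not written in the source equations but are implied by
standard transformer blocks and necessary for trainability at depth six;
they are included and documented here. Layer normalization is the plain
`(x - mean) / sqrt(var + eps)` with `eps = 1e-6` and no learned affine,
exactly as printed. The MLP is `W2 GELU(W1 x + b1) + b2` with hidden
width `mlp_ratio * D` (default 4) and the exact Gaussian-CDF GELU.
Heads default to 8 (D divisible by heads is enforced).

Open points resolved as configuration: the number of blocks is described
as six in one place and five in another — `n_blocks` defaults to **6**.
A remark that token count "increases" across blocks names no mechanism;
the package keeps the token count constant, which keeps the flatten
dimension well-defined (`300 × 256 = 76 800` for the full geometry).

## 4. The CNN branch

The backbone is built from a declarative stage table; both the pruned
variant (3×3/32 stem stride 2, dense blocks of 6/12/16, block 4 removed)
and the unpruned DenseNet169 reference (7×7/64 stem, blocks 6/12/32/32)
come from the same builder. The table states only layer counts, so the
standard DenseNet conventions fill the gaps: growth 32, pre-activation
BN-ReLU-Conv ordering, 1×1 bottlenecks of width 4 × growth, transition
compression 0.5, global average pooling at the end — this is a
*reconstruction*, and the source's per-stage "~ x M" parameter counts
are treated as narrative, not as assertions. With these conventions the
builder counts 12.48 M parameters for the reference and 3.25 M for the
pruned variant (ratio 0.26, comfortably under the claimed ~50 %); the
dense-connectivity identity `channels_in(l) = block_in + (l-1) * growth`
is asserted exactly in tests.

Normalization layers use the statistics of the current feature map
(instance normalization): the package processes one image per forward
pass, where batch statistics and instance statistics coincide, and using
the same computation in training and evaluation keeps inference
deterministic without running-average state.

## 5. Fusion, head and training harness

The two flattened branch vectors have different lengths (76 800 vs the
backbone width), so the specified element-wise addition is again
ill-posed; each branch gets a **linear projection to a common fusion
dimension** (default 1024) before the add — the same minimal-change
resolution as in SDEB. The head is layer-norm → dropout → dense →
dropout → dense(7) → softmax, dropout 0.1 by default.

`fit_smoke` is a correctness harness, not a trainer: Adam (lr 1e-3) on
categorical cross-entropy, gradient accumulation over mini-batches of 7,
full backpropagation through both branches via the package's
reverse-mode core (validated op-by-op against central finite differences
at tolerance 1e-5). `epochs = 0` returns the initial weights
bit-identically; the whole loop is reproducible from its seed. The
optimizer, loss and schedule are package choices; the source states
none.

All randomness — weight init, shuffling, dropout, the synthetic
generator — flows through seeded, state-restoring RNG scopes, so every
model, dataset and training run is a pure function of its seed.

## 6. Metrics

Per-class one-vs-rest counts come from the K×K confusion matrix. Two
"accuracy" notions are deliberately separated: `class_accuracy`
(diagonal over row total — the per-class figure read off a confusion
matrix, numerically identical to sensitivity) and `ovr_accuracy`
(`(TP+TN)/n`, the literal one-vs-rest formula). Published per-class
accuracy columns track the former; both are exposed and labelled. Zero
denominators yield `NaN`, never errors.

ROC-AUC is the rank/Mann-Whitney probability that a random positive
outscores a random negative with ties counted ½ (equal to the
trapezoidal area); the "TPR/FPR ratio" sometimes written as an AUC
formula is not an area and is exposed separately as `tpr_fpr_ratio`.
McNemar's test always reports the continuity-corrected chi-squared
statistic `(|b-c|-1)^2/(b+c)`; the p-value defaults to the exact
two-sided binomial when `b + c < 25` and the chi-squared tail otherwise,
with `method` selectable because small-sample practice varies. Macro
"overall" rows are unweighted means rounded to two decimals; micro
accuracy (`trace/n`) is reported alongside since published overall
accuracies are typically micro.

## 7. The synthetic generator, and what tests do (not) show

The generator emulates the *layout* of dermoscopic data, not its
biology: an irregular-boundary ellipse (low-order harmonic perturbation)
filled with a saturated colour whose hue is drawn from a per-class band,
alpha-blended onto a skin-toned background with an illumination
gradient and Gaussian noise; hair strokes are quadratic Bézier curves of
1–3 px thickness darkened by a fixed delta, with the truth mask equal to
exactly the rendered support. The seven hue bands partition the hue
circle, so classes are **linearly separable in mean colour by
construction** — a centroid classifier on mean RGB exceeds 95 %, which
is what makes the desk-scale learnability check meaningful: it verifies
that gradients flow and the architecture can fit a separable signal, not
that the model distinguishes real lesion morphology. Equally, the
hair-recall integration test shows the morphological detector finds
synthetic strokes of known darkness; real hair varies in contrast,
colour and density. No conclusion about ISIC-scale performance follows
from these tests, and none is claimed.

Problem sizes used by the suite and the acceptance script are package
choices for desk-scale verification: 70 training images (10 per class)
at 70 × 70 with the tiny configuration (7 × 7 patch grid, D = 16, two
2-head blocks, a miniature backbone), 20 training epochs; 96 × 96
canvases for preprocessing checks; one full-geometry (600 × 450 / 224 ×
224) forward pass to validate shapes and determinism at scale.

## 8. Known limitations

* The pruned backbone's absolute parameter count depends on the
  reconstruction conventions above; only the pruned-to-reference *ratio*
  is asserted.
* Morphological hair detection over-segments at sharp lesion rims
  (precision, not recall); no thin-structure verification pass is
  applied.
* Training at the full geometry is possible but slow in pure R; the
  harness is intended for the tiny configuration.
* The literal additive enhancement can saturate bright edges before
  clipping; the classical subtractive sharpening form is deliberately
  not substituted.
* No colour constancy, learned inpainting, or generative oversampling —
  out of scope by design.
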