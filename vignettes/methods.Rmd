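---
title: "Two-stage kidney-pathology analysis: models, objectives and design choices"
author: "nephrodx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage kidney-pathology analysis: models, objectives and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the approach

Renal pathologies in contrast-enhanced CT — simple cysts, solid tumors and
calcified stones — differ in size by two orders of magnitude, sit inside an
organ that occupies a few percent of the scan, and are separated from
normal parenchyma by boundaries that range from crisp (cysts, stones) to
ambiguous (tumors).  `nephrodx` implements a two-stage cascade for this
setting:

1. **Segmentation stage.** A 3D encoder–decoder assigns every voxel one of
   five classes (background, kidney parenchyma, cyst, tumor, stone) and
   attaches a per-voxel confidence score.
2. **Classification stage.** Connected pathological regions are cut out,
   standardized to $96\times96\times32$ voxel patches, and classified by a
   multi-resolution evidential network that returns Dirichlet
   concentration parameters — i.e. a class distribution *plus* a calibrated
   uncertainty — modulated by the segmentation confidence of the region.

Everything is driven by a synthetic CT phantom generator, so the full
cascade is trainable and testable on a desktop CPU without any external
data.

# The phantom generator: what it emulates and what it does not

`phantomSpec()` / `generatePhantom()` produce per-patient volumes
(64×64×16 voxels at 1×1×2.5 mm by default) containing one smooth
ellipsoidal kidney in soft-tissue background and, for pathological
patients, one lesion of the patient's class:

* **cysts** — spheres of hypodense fluid (10 ± 8 HU) with smooth borders;
* **tumors** — ellipsoids whose radius is perturbed by a random low-order
  spherical-harmonic field (degree ≤ 3, amplitude ≤ 30%), filled with a
  spatially mixed two-component enhancement pattern (60/140 ± 20 HU) to
  mimic heterogeneous solid lesions;
* **stones** — small dense spheres (700 ± 150 HU).

The intensity conventions (background −80 ± 20, parenchyma 110 ± 15 HU)
are chosen for class separability under noise and follow the qualitative
radiological appearance of each class; no quantitative attenuation ranges
were available for the source cohort, so these are package conventions,
not measured values.  The cohort class mixture defaults to the class
distribution of the public contrast-CT kidney cohort the package emulates
(normal .407, cyst .303, tumor .179, stone .110 of 3557 classed patients).
Lesion radii default to cyst 4–8 mm, tumor 5–8 mm, stone 3–5 mm; the stone
lower bound keeps every lesion above the 27-voxel ROI threshold at the
default spacing.  Everything is a pure function of (spec seed, patient
id); `generateCohort()` assigns classes multinomially under the spec seed.

What the phantoms do **not** contain: scanner physics (beam hardening,
partial-volume blur, bias fields), perirenal anatomy, multiple organs,
breathing artifacts, or the cyst–tumor boundary ambiguity of real scans.
Passing the desk-scale tests therefore demonstrates that the machinery —
losses, networks, extraction rules, uncertainty arithmetic — behaves as
specified, not that the trained weights would transfer to clinical data.

# Preprocessing

The protocol mirrors standard CT practice: kidney windowing (width 400 HU
at level 40, retained range [−160, 240] mapped to [0, 1]); resampling to a
1×1×2.5 mm reference grid (trilinear image / nearest-neighbor mask; the
through-plane spacing stays coarser than in-plane, which is what
thick-slice clinical stacks look like); optional three-stage intensity
normalization (global z-score, kidney-interior recentering, tile-wise
standardization with 16-voxel tiles — tiles are laid non-overlapping from
the origin with the final tile aligned to the far edge, and overlapping
tile estimates are averaged); symmetric zero-padding to multiples of 16
(invertible via the returned pad record); and cubic-spline through-plane
interpolation for stacks of fewer than 8 slices.  The bias-field hook is
the identity: phantoms carry no bias field, and correcting one is an
external algorithm out of scope here.

# The segmentation network

`buildSegNet()` assembles a U-Net-shaped encoder–decoder from
large-kernel depthwise-separable residual blocks:

$$\mathrm{ECB}(x) = x + \gamma \odot
  \mathrm{PW}_{1\times1\times1}\!\big(\mathrm{GELU}\,
  \mathrm{PW}_{1\times1\times1}\,\mathrm{GN}\,
  \mathrm{DW}_{7\times7\times3}(x)\big),$$

with the per-channel residual scale $\gamma$ initialized to $10^{-6}$
(near-identity at initialization), depthwise kernels He-normal, pointwise
kernels Xavier-uniform.  The anisotropic $7\times7\times3$ kernel matches
the anisotropic voxel geometry: wide in-plane context, short through-plane
extent.  The bottleneck applies atrous spatial pyramid pooling — a
globally pooled branch plus dilated $3^3$ branches at rates (1, 3, 6)
fused by a $1\times1\times1$ convolution — with each branch's dilation
capped per axis at $\lfloor(d-1)/2\rfloor$ so the kernel span never
exceeds the bottleneck grid (without the cap, any practical bottleneck
smaller than 13 voxels would be unusable).  Skip connections pass through
additive attention gates
$\alpha = \sigma(\psi^{T}\,\mathrm{ReLU}(W_g g + W_x x + b))$, and the
decoder upsamples trilinearly followed by $1\times1\times1$ mixing.

Open architectural values (level count, widths, blocks per level) are
configuration: the full-scale default is (32, 64, 128, 256); the
desk-scale `tinySegConfig()` is (8, 16, 32) with pyramid rates (1, 2, 3),
about 120k parameters, chosen to be trainable end to end on one CPU core
in minutes.

# The compound segmentation objective

Training minimizes
$L = 0.4\,L_{CE} + 0.3\,L_{Dice} + 0.2\,L_{Bnd} + 0.1\,L_{Focal}$, the
stated weighting of the four terms.  Cross-entropy and the focal term
(focusing exponent 2) are voxel means; soft Dice averages the four
foreground classes, counting a class absent from both prediction and
target as fully correct; background is excluded from Dice because it
dominates the voxel count.

**The boundary term needed a design decision.**  The printed form of the
distance-weighted boundary loss,
$\sum_c \sum_\Omega \phi_c D_c / \sum_\Omega \phi_c$ (the mean signed
distance under the predicted class-mass distribution), has a degenerate
optimum: it is minimized by concentrating *all* probability mass on the
single most interior voxel, i.e. by extreme under-segmentation.  We
observed exactly this in training — the boundary term marched to its
minimum while Dice worsened.  The package therefore keeps the normalized
form in `boundaryLoss()` as a reporting quantity (it has clean
hand-checkable semantics: uniform mass gives the plain mean of $D$, a
point mass gives $D$ at that voxel) but optimizes the *unnormalized
voxel-mean* penalty $\frac{1}{|\Omega|}\sum_\Omega \phi_c D_c$, whose
minimizer over $\phi \in [0,1]$ is exactly the true region
($\phi = 1$ wherever $D < 0$).  The signed distance is computed by an
exact Euclidean transform in voxel units (a spacing-aware variant is
available), optionally smoothed with a Gaussian of $\sigma = 1.5$ voxels,
and saturated at ±10 voxels inside the training loss so that far-field
background cannot dominate the gradient early in training.

Two numerical details matter.  Probabilities are clamped at $10^{-7}$
inside logarithms, but the gradient is *not* masked below the clamp: the
$1/p$ factors of the CE/focal gradients are tamed to $O(1)$ by the
downstream softmax Jacobian, and masking them instead creates an
unrecoverable dead regime once a class's probability underflows.  All
gradients — every operator and both compound losses — are verified
against central finite differences in the test suite.

# Pixel and region confidence

Voxel confidence combines three unit-interval terms,
$C = w_1 \max_c p_c + w_2 (1 - H/\ln K) + w_3\,\mathrm{Consistency}$,
with defaults $w = (0.5, 0.3, 0.2)$ and 5 Monte Carlo dropout passes.
The entropy enters as its normalized complement: a confidence score must
*decrease* with predictive entropy, so the raw additive entropy of the
printed formula is read as its complement (flagged as an open
interpretation; the weights are package defaults, the source gives none).
Consistency is the fraction of dropout passes whose argmax agrees with
the modal argmax.

Region confidence $S_i$ averages prediction certainty (mean voxel
confidence over the component), boundary sharpness (mean over surface
voxels of the largest face-neighbor jump of the class probability — 1 for
a binary field by construction), and spatial consistency (the component's
share of all predicted voxels of its class inside its expanded box).

# ROI extraction

Predicted masks are decomposed per pathological class into 26-connectivity
components; components smaller than 27 voxels are discarded (a 27-voxel
component is kept).  Tight boxes grow by $\lceil 0.15\,\mathrm{extent}\rceil$
per side (context is never rounded away), clip to the volume, and are
resized to $96\times96\times32$ by trilinear interpolation — unless the
per-axis scale factors differ by more than 2×, in which case the crop is
scaled uniformly and zero-padded so extreme lesions keep their aspect
ratio.  Patches are z-scored and clipped to $[-3, 3]$
($\varepsilon = 10^{-6}$).  A volume with no surviving pathological
component yields one whole-kidney ROI labelled "normal", so every patient
produces at least one classification input.  All coordinates are 0-based
half-open throughout.

# The evidential classifier

Each patch is processed at three resolutions (identity, 0.75×, 0.5×) by
scale-matched pathways: small kernels ($3^3$) with the highest widths at
full resolution, $5\times5\times3$ at 0.75×, $7\times7\times5$ at 0.5×.
Pathway blocks are adaptive residual units
$\mathrm{ACB}(x) = x + \alpha\,\mathrm{LayerScale}(\mathrm{SE}(\mathrm{PW}\,
\mathrm{Drop}_{0.15}\,\mathrm{PW}\,\mathrm{SiLU}\,\mathrm{DW}_{5\times5\times3}\,
\mathrm{GN}(x)))$ with the block scale $\alpha$ initialized to 0.1 and a
squeeze-excitation channel gate (reduction 4).  Stems downsample
aggressively (stride 4 in-plane and through-plane for the fine/medium
streams) — the patch resolution exceeds what a desk-scale classifier
needs, and the stride keeps CPU cost linear in information rather than in
voxels.

Fusion is context-aware: each stream's final map is spatially attended
(sigmoid gate), pooled and projected to a common width; the three
projections are combined with softmax weights computed from the pooled
descriptors concatenated with the scalar segmentation confidence $S$.
The printed fusion expression multiplies a pooled vector by an attention
map, which is dimensionally ambiguous; the attended-pool reading above is
the package's resolution.  The fused vector is scaled by
$\kappa + (1-\kappa)S$ with $\kappa = 0.5$, so a zero-confidence region
still classifies at half magnitude, and the head emits evidence
$e = \mathrm{softplus}(Wx + b)$, concentrations $\alpha = e + 1$,
expected probabilities $\alpha/\sum\alpha$ and uncertainty
$u = K/\sum\alpha$.  Softplus was chosen over exp/ReLU as the evidence
activation for smoothness and bounded gradients.

# The adaptive classification objective

The loss combines cross-entropy on the expected probabilities, the
digamma expected cross-entropy under the Dirichlet
($\psi_0(\sum\alpha) - \psi_0(\alpha_y)$), the closed-form KL of the
misleading evidence (true-class concentration reset to 1) from the
uniform Dirichlet, and a confidence-alignment term $(u - (1-S))^2$ that
couples evidential uncertainty to segmentation quality — the one coupling
the design requires, given that no explicit formula was stated.  The four
weights are a temperature softmax ($\tau = 2$) of per-term learning
progress, where progress is an EMA (momentum 0.9) of the relative
one-epoch loss decrease — a scale-free, recomputable statistic; weights
update per epoch and are logged with their progress statistics.  The
digamma form is verified against a $10^5$-sample Monte Carlo oracle, the
KL against Beta-quadrature and a sampling oracle.

# Training protocol

The full-scale protocol is AdamW ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\varepsilon = 10^{-8}$, weight decay 0.01), gradient clipping at norm 1,
linear warmup from $10^{-6}$ over 5 epochs then cosine decay to
$10^{-7}$; 100 epochs at rate $10^{-4}$, batch 4 for segmentation, 50
epochs at $5\times10^{-5}$, batch 16 for classification; seeds 42 (data
split) and 123 (model initialization).  Augmentation (in-plane rotation
±15°, smoothed elastic deformation, intensity scaling 0.9–1.1, gamma
0.8–1.2) is implemented and tested but disabled in the short desk-scale
runs, where it slows convergence without a generalization payoff at 120
patients.

The desk-scale settings (`tinySegTrainConfig()`, `tinyClsTrainConfig()`)
compress this to something a single CPU core finishes in minutes: 5
segmentation epochs where an *epoch* is two lesion-biased 32×32×16 crops
per training volume at batch 2 (420 optimizer steps — following the
patch-based convention in which an epoch is a fixed iteration budget
rather than one sweep of full volumes), learning rate $10^{-2}$ with one
warmup epoch, class-balanced volume sampling (patients drawn inversely to
their lesion-class frequency, so stones are seen as often as cysts), and
10 classifier epochs at batch 4 with class-stratified ordering.  The
higher learning rate is what makes a 400-step schedule productive for a
100k-parameter network; the class-balanced sampler and lesion-centered
crops are what let the two rare classes (tumor, stone) emerge at all
within that budget — with natural sampling their held-out Dice stays near
zero until several hundred additional steps.

# Evaluation

Segmentation is scored per class by voxel Dice, HD95 (the larger of the
two directed 95th-percentile surface distances, spacing-aware, on
face-connected surface voxels) and boundary IoU on 1-voxel 26-connectivity
dilated surface bands — the tightest nontrivial band, and the one a
brute-force oracle can check exactly.  Classes absent from both masks
score perfectly; classes present in only one score Dice 0, HD95 ∞,
boundary IoU 0.  Cohort-level Dice pools voxel counts over patients
before forming the ratio.  Classification reports accuracy, per-class
precision/recall/F1 (zero-division convention: 0), one-vs-rest AUC by the
midrank Mann–Whitney statistic, and the confusion matrix.

The reference experiment (`deskScaleStudy()`) generates 120 phantom
patients, splits them 70/15/15 at patient level, trains both stages as
above and reports held-out cohort Dice and ROI classification accuracy.
The test suite runs it for three seeds (42/43/44 for the data, 123/124/125
for the weights).

# Known limitations

* Phantom realism is deliberately minimal (see above); reported accuracy
  quantifies the machinery, not clinical performance.
* The desk-scale segmenter under-segments tumors relative to cysts — the
  heterogeneous enhancement pattern is the one cue that genuinely needs
  texture modeling, and 420 optimizer steps with 8 full-resolution
  channels only begin to capture it.
* The normalized boundary loss is reported but not optimized, for the
  degeneracy documented above.
* Batch statistics: the networks use GroupNorm throughout (group count
  divides the channel count), so there is no batch-size coupling; but the
  reference implementation processes one volume at a time and accumulates
  gradients, so wall-clock does not benefit from large batches.
* Checkpoints are R serializations of parameter values plus
  configuration; they are not interoperable with other frameworks.
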