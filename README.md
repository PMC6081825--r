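# nucleofuse

Nuclear instance segmentation for hematoxylin-and-eosin (H&E) histology
tiles, built around the fusion of region- and boundary-based encoder-decoder
networks.

## The problem

Profiling tumor tissue starts with finding every nucleus in an H&E section.
Two things make that hard. First, nuclear phenotypes are diverse:
hyperchromatic nuclei are uniformly dark, while *vesicular* nuclei have a
pale interior with chromatin condensed at the rim — a shape no intensity
threshold captures. Second, adjacent nuclei touch and overlap, separated
only by *perceptual* boundaries that are not real image edges. `nucleofuse`
is for computational-pathology researchers who want a tested, fully seeded
CPU implementation of the fusion approach to both problems, together with a
synthetic-scene generator that provides exact ground truth for method
development.

## The method

1. **Colour decomposition.** By the Beer–Lambert law, optical density
   OD = −log(I/255-ish) is linear in stain concentrations. A per-pixel least
   squares against a 3×2 unit-column H&E stain matrix (Ruifrok–Johnston
   defaults) yields a hematoxylin (DNA) map; min–max rescaled, it is the
   single-channel network input.
2. **Networks.** A symmetric encoder-decoder family (n = 3..10 blocks per
   side, feature plan 32/64/128, max-pool indices forwarded to the mirrored
   max-unpool) and an asymmetric ENet-style network (bottlenecks with
   normal, dilated and factorized 5×1/1×5 convolutions; a decoder shallower
   than the encoder). Output is a per-pixel 2-class softmax.
3. **Fusion.** A region network (target: instance mask) and a boundary
   network (target: boundaries computed from the mask) are trained
   independently — Adam, learning rate 5e-4, L2 weight decay 2e-4, batch
   size 4 — then frozen; a third network of the same family consumes their
   stacked foreground-probability maps and produces the final map. A
   multitask model (shared trunk, two heads) is provided as the comparator.
4. **Post-processing.** Threshold at 0.5, then marker-controlled watershed:
   Euclidean distance transform, h-maxima markers, priority-flood watershed,
   small-object cleanup — to split residual touching nuclei.
5. **Evaluation.** Object-level: one-to-one matching at IoU > 0.5 (strict),
   Precision = TP/(TP+FP), Recall = TP/(TP+FN), F1 = 2PR/(P+R), plus the
   pixel-level standard error σ/√n.

There is no deep-learning framework in this stack: the tensor engine
(im2col + GEMM convolution, batch norm, unpooling, Adam, backprop) is part
of the package, in R + RcppArmadillo, verified against finite differences.

## Worked example

```r
library(nucleofuse)

spec <- scene_spec(height = 64, width = 64, n_nuclei = 8,
                   overlap_fraction = 0.5, vesicular_fraction = 0.25, seed = 42)
scene <- generate_scene(spec)
max(scene$mask)                 # 8  nuclei placed
nrow(scene$touching_pairs)      # 4  touching pairs (exact ground truth)

train <- lapply(1:16, function(i)
  generate_scene(scene_spec(height = 64, width = 64, n_nuclei = 8,
                            overlap_fraction = 0.5, seed = i)))
cfg <- train_config(max_epochs = 20, seed = 1)
fm  <- train_fusion(train, family = "symmetric", n_modules = 3, config = cfg)
round(c(first = fm$history$region[1], last = tail(fm$history$region, 1)), 3)
#> first  last
#> 0.819 0.085

prob   <- predict_probmap(fm, scene$image)       # fused foreground map
labels <- segment(prob, postprocess_params())    # watershed instances
compute_metrics(match_objects(scene$mask, labels))
#> precision    recall        f1
#> 0.8333333 0.6250000 0.7142857
touching_separation(scene, labels)[c("separated", "total_touching")]
#> $separated      [1] 0
#> $total_touching [1] 4
```

The trained region net drops its loss ~10× in 20 epochs and the fused
pipeline recovers most nuclei (F1 0.71 on this held-out scene). Separating
the touching pairs of a single scene is the hard part and needs longer
training than a 1-minute demo; `fusion_benchmark()` runs the systematic
3-seed comparison of the fused pipeline against the region-only baseline on
pooled test sets.

The same pipeline is scriptable from the command line
(`inst/cli/nucleofuse.R`): `synth`, `train`, `predict`, `evaluate`
subcommands over PNG images, 16-bit PGM label masks, PFM probability maps
and a JSON pipeline config.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model, every
tunable parameter with units and defaults, what the synthetic scenes do and
do not emulate, numerical conventions, and known limitations.
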