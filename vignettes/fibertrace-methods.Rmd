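---
title: "Detecting and characterizing fiber bundles in tracer sections: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing fiber bundles in tracer sections: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Anatomic tracing visualizes axonal trajectories by injecting a tracer into
a cortical site and following the transported label across serial
histological sections. Under dark-field illumination the labeled fibers
appear bright on a near-black background, and anatomists chart *fiber
bundle areas* — regions where labeled fibers travel closely together —
section by section. Manual charting is accurate but extremely slow, so
only a small fraction of sections in any tracer study carries annotations.

`fibertrace` implements a computer-assisted pipeline for this task:

1. a **multi-task convolutional network** segments candidate bundle areas
   on RGB sections;
2. **post-processing filters** (minimum area, distance to the brain
   outline, and an across-section continuity prior) remove the dominant
   false-positive modes;
3. a **fiber-density estimator** characterizes each detected bundle by the
   fraction of its pixels occupied by labeled fibers;
4. **bundle-level evaluation** reports the true positive rate (TPR),
   false positives per section (FPavg), fiber-density differences against
   manual charting (dFD), FROC curves, and a one-way ANOVA of fiber
   density across white-matter pathways.

Everything runs on synthetic sections from the bundled generator, so the
full pipeline is testable end to end without access to real tracer
material.

## The model

The network couples two arms that share one encoder:

* **FSeg** — a 2D U-Net (two 3×3 convolutions + batch normalization +
  ReLU per level, max-pooling down, nearest-neighbour upsampling with
  skip connections up, channels doubling per level) ending in a two-class
  softmax per pixel. The exact per-level layer recipe is not prescribed
  by the published description; we use the classic U-Net defaults.
* **FClass** — reads the encoder bottleneck, applies two stages of
  (max-pool + two 3×3 convolutions), flattens, and passes through two
  fully connected layers and a two-node output (fiber patch vs
  background patch). The penultimate fully connected activation is the
  embedding used by the contrastive loss. We use that embedding rather
  than the two output logits because a two-dimensional cosine similarity
  would collapse the contrastive geometry; the two-node head is kept for
  patch classification.

Because no deep-learning framework is available to R in this environment,
the engine (forward passes, backpropagation through convolution, batch
normalization, pooling, upsampling and the fully connected stack, plus
Adam) is implemented in C++ (RcppArmadillo) with convolutions as im2col +
BLAS matrix products. It computes in single precision — the layer-shaped
matrix products are memory-bandwidth-bound on one CPU core, so float
roughly doubles throughput — while the R boundary and the standalone
loss oracles remain double. All analytic gradients are verified against
central finite differences in the test suite.

### Losses

*Focal loss* on FSeg handles the extreme class imbalance (bundles occupy
a few percent of a section): `FL = -alpha_t (1 - p_t)^gamma log(p_t)`
with `alpha = 0.25`, `gamma = 2`. The published formula writes `alpha_t`
without defining it; we adopt the original focal-loss convention
(`alpha` for fiber pixels, `1 - alpha` for background) and expose a
switch that disables the weighting. Probabilities are clamped to
`[1e-7, 1 - 1e-7]` before the logarithm.

*Contrastive loss* (NT-Xent) on FClass: each training patch contributes
two augmented views — (i) a nearby crop, displaced by less than 20 µm and
accepted only if its mean intensity falls in a configurable white-matter
band (iteratively resampled, falling back to the anchor), and (ii) noise
injection followed by Gaussian blurring with sigma drawn from
[0.05, 0.3]. Views of the same patch are positives; all other views in
the batch are negatives; temperature `tau = 0.5`. The printed source
formula omits the `-log` of the SimCLR definition; a bare softmax ratio
is not a loss, so we implement `-log` of the ratio. The blur sigma is
interpreted in pixels and the noise s.d. defaults to 0.05 on the 0-1
intensity scale; neither unit is prescribed, so both are configuration
surface.

The total objective is `focal + lambda_con * contrastive` with
`lambda_con = 1` by default; the published work does not state a weight,
so this is a package choice exposed in `train_config()`.

### Temporal ensembling

After `Np` supervised epochs on the labeled sections, unlabeled sections
join training: each epoch the model's predictions on every unlabeled
section are pushed into a per-section ring buffer of length `r = 3`; the
pixelwise mean of the buffer, thresholded (strict `>`, default 0.5), is
the pseudo-label for patch sampling. For the first three epochs after
pretraining the pretrained model's predictions serve as the label source.
Early stopping monitors the labeled validation loss (90:10 split) with a
patience of 25 epochs. The optimizer is Adam; the published setting
"epsilon = 1e-3" is ambiguous between Adam's epsilon and the learning
rate — an epsilon of 1e-3 would be atypical while 1e-3 is the
conventionally reported learning rate, so we read it as the learning
rate. The labeled:pseudo-labeled patch ratio within a TE epoch is not
stated; it defaults to 1:1 and is configurable. Pseudo-labeled patches
use the same focal parameters as labeled ones, with no confidence
weighting.

## Inference and post-processing

Whole sections are segmented in one pass, or in overlapping 1024² tiles
with probability averaging in the overlaps for larger sections. Tiles
carry reflection-padded context at their edges, so blended overlap zones
retain a small residual difference (order 1e-2 in probability) against a
whole-image pass; the averaging keeps the map free of seam
discontinuities, and the single-tile case is exactly equal to the plain
forward pass.
Candidate regions are connected components (8-connectivity) of the map
thresholded at 0.4 (strict `>`). Three filters then flag false
positives; every filter is evaluated on the unfiltered region set, so
their flags commute, and flagged regions are retained in the output
table for audit:

* **area** — regions strictly smaller than 2 mm²;
* **border** — regions strictly closer than 0.5 mm to the tissue-mask
  boundary;
* **continuity** — regions whose minimum pixel distance to the support of
  the averaged neighbouring-section bundle masks strictly exceeds 0.5 mm.

The continuity reference is built at a tenth of the native resolution:
sections are downsampled, coarsely aligned by the translation that
maximizes the normalized cross-correlation of their tissue masks
(sections of unequal size are zero-padded, centred, to common
dimensions), a low-resolution dense-bundle mask is produced per section,
the masks of the available rostral/caudal neighbours are averaged, and
the average is upsampled back. The published pipeline obtains the
low-resolution masks from a pretrained triplanar 3D network whose weights
and training data are not available; the low-res segmenter is therefore a
pluggable interface with two bundled implementations — the package's own
segmentation arm applied at low resolution (keeping regions whose mean
probability reaches a configurable quantile), and ground-truth injection,
which the tests use to exercise the filter's own logic in isolation.
Whether the 0.5 mm bound should be measured at low or native resolution
is unstated; we measure at native resolution after upsampling, and we
read "distance of a region from the reference" as the minimum
pixel-to-pixel Euclidean distance (the most permissive reading),
computed with a distance transform. All boundary comparisons use the
strict inequalities exactly as published (`< 2 mm^2`, `< 0.5 mm`,
`> 0.5 mm`).

## Fiber density

Within each detected bundle, the grayscale section (standard luminance
weights) is enhanced with CLAHE (clip limit 2, 64 px tiles — unstated in
the source, configurable) and binarized at the 95th percentile of the
enhanced intensities; FD is the percentage of bundle pixels above the
threshold. The population over which the percentile is taken is
ambiguous in the source. We default to all tissue pixels of the section:
a bundle-local 95th percentile forces FD toward 5% by construction and
could not reproduce the reported spread of densities (roughly 2-20%)
across bundles. The bundle-local variant is retained as an option and,
being rank-based, is invariant to monotone intensity rescalings.

`dFD` is reported as `mean(FD_manual - FD_predicted)` over matched
pairs, in percentage points, together with the mean absolute difference
(the published table header suggests an absolute reading while the text
reports a signed value). A negative `dFD` means predicted bundles are
denser, the expected signature of predicted boundaries fitting the
fibers more tightly than manual outlines.

## Evaluation

Bundle-level counting needs a correspondence rule that the published
evaluation does not specify. A true bundle counts as detected when some
predicted region overlaps it by at least 25% of the smaller of the two
areas; matching is greedy, a single prediction may cover several true
bundles, and extra predictions on an already-detected bundle are not
counted as false positives. The criterion is configurable and surfaced
prominently in `match_detections()`. FROC curves sweep the probability
threshold, re-applying the configured post-processing at each point; the
elbow is the threshold maximizing `TPR - FP/max(FP)`. Pathway
assignment requires a region to overlap a pathway ROI by strictly more
than 40% of its area; the pathway ANOVA is an ordinary one-way ANOVA of
FD on the pathway factor via `stats::lm()`.

## The synthetic generator

The generator emulates what the method needs from dark-field tracer
sections, not their photorealism:

* near-black slide (intensity ~2/255) and a dimly textured elliptical
  tissue region (mean 20/255, s.d. 8 — headroom for CLAHE);
* bundles as elliptical areas (semi-axes 0.85-1.15 mm, placed clear of
  the tissue outline) filled with quadratic Bézier strokes with a
  Gaussian cross-profile (width 30-60 µm, length 300-700 µm, peak
  140-220/255) sharing a mean orientation within ±12°; strokes are added
  until the rendered stroke coverage reaches the class target, and the
  achieved coverage is recorded per bundle;
* two density classes: dense (coverage 0.20) and moderate (0.10). These
  coverages were fixed so that the default profile's estimated FD falls
  inside the 2-20% range reported for real material — the only
  quantitative appearance anchor available, since the source publishes no
  image statistics;
* terminal fields as discs of isotropic puncta (no coherent orientation;
  verified by gradient-orientation entropy in the tests) and glare/dust
  as saturated blobs — the two principal false-positive modes;
* serial stacks: bundle areas persist across sections with a bounded
  per-section centroid drift (default 0.2 mm, confined within two steps
  of the initial position) while their strokes re-randomize; optional
  single-section "spurious" regions are injected at a guaranteed distance
  from every true bundle to exercise the continuity filter;
* per-stack pathway ROIs (three disjoint discs tagged IC/CC/UF); bundle
  centres can be drawn inside them, with IC bundles dense and CC/UF
  moderate, mirroring the reported ordering of densities across pathways.

Default geometry is 384² px at 20 µm/px (a 7.7 mm field of view); the
"tiny" fixture profile uses 256² px at 30 µm/px — the same physical
proportions — so bundle areas stay above the 2 mm² filter. What the
generator does **not** emulate: staining and digitization intensity
variation beyond a global background shift, tissue distortions and
registration error between sections, anisotropic resolution, and the
within-bundle texture of real axons. Passing tests therefore demonstrate
the correctness and internal consistency of the pipeline and the
qualitative behaviour of its components, not performance on real
histology.

## Problem sizes used by the tests and the acceptance script

Training at published scale (~22,000 patches of 256², hundreds of
epochs) is a GPU workload. The package's own experiments use a reduced
study design chosen to exercise every component:

* model: depth 3, 8 base channels, fully connected sizes (128, 64),
  128² patches;
* data: five labeled, five unlabeled, and ten held-out synthetic
  sections (two "test brains" with shifted background intensity);
* schedule: ~200 labeled patches, 20 pretraining + 20 temporal-ensembling
  epochs, batch size 8;
* the ablation (cross-entropy / focal / +contrastive / +temporal
  ensembling) runs a further-reduced design (64² patches, 16 + 8 epochs,
  3 seeds with common data and initialization across arms, held-out
  stacks with shifted background intensity standing in for a different
  animal) and compares bundle-level TPR medians. Patch sampling for the
  ablation uses `pos_fraction = 0.25` so fiber pixels stay the minority
  class — the premise of the focal-loss comparison; detection training
  defaults to 0.5.

A caveat on what the ablation can show: the published between-component
differences are a few points of TPR, while the median-over-3-seeds of a
desk-scale run carries roughly ±0.1 TPR of stochastic variation — the
cross-entropy vs focal gap is resolvable, but the contrastive and
temporal-ensembling gains (which draw their value from hundreds of
unlabeled sections and hundred-epoch schedules) are below this noise
floor at this scale. The corresponding acceptance test states the full
published ordering and is expected to expose this limit rather than hide
it.

## Numerical choices and degenerate inputs

* probability clamp 1e-7 before logarithms; strict `>` at every
  threshold (a pixel exactly at a threshold is background; a region at
  exactly 0.5 mm from the continuity reference survives);
* ties in pathway assignment go to the larger overlap; no pathway
  qualifying means `"none"`;
* empty continuity reference removes all regions with a warning;
  single-section stacks disable the prior with a warning;
* blank sections (no pixel above the tissue floor, default 10/255) raise
  a typed error;
* bundle placement uses bounded rejection sampling and reports
  over-crowded configurations as errors rather than degrading silently;
* coordinates are 0-based `(row, col)` with half-open pixel ranges;
  physical scale is a single isotropic µm/px scalar (default 1.76 µm/px,
  i.e. 0.44 µm scans downsampled ×4) converted at run time wherever a
  threshold is stated in mm.

## Known limitations

* The network engine is CPU-bound and double-precision; it is meant for
  desk-scale experiments and method development, not for training on
  full-resolution whole-slide material.
* The continuity prior's bundled low-resolution segmenter is the
  package's own model applied at low resolution — a pragmatic stand-in
  for a 3D segmenter trained on real volumes; its quantile heuristic for
  "main dense bundles" is crude.
* The coarse stack alignment is translation-only; real section stacks
  can need rotation and nonrigid correction upstream.
* Dense/moderate bundle classification is out of scope (the detection
  head treats all bundles alike), as is 3D reconstruction/rendering of
  the detected bundles.
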