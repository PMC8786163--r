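---
title: "Gene re-identification embeddings for ISH brain images: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene re-identification embeddings for ISH brain images: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task

High-throughput colorimetric in situ hybridization (ISH) produces brightfield
images of brain tissue sections in which cells expressing a probed gene's mRNA
are stained dark. Each image assays exactly one gene, but there is no other
label — so gene identity itself can serve as a free contrastive training
signal. The package learns a convolutional map from image patches into a
fixed-dimension embedding space in which patches assaying the same gene are
close, and evaluates those embeddings with a *gene re-identification* metric:
the fraction of images whose single nearest neighbour in embedding space
(Euclidean distance) assays the same gene, with all images from the query's own
donor excluded from the gallery so the score cannot be earned by recognizing an
individual brain's staining quirks.

## The loss

Training uses the batch-hard variant of the triplet loss. A batch holds
P genes x K patches. For anchor $a$ with embedding $x_a$,

$$\ell_a = \mathrm{softplus}\Big(\max_{p:\,g(p)=g(a)} d(x_a, x_p)\;-\;
\min_{n:\,g(n)\neq g(a)} d(x_a, x_n)\Big),$$

with $\mathrm{softplus}(z) = \log(1+e^z)$ (the "soft margin"); a numeric margin
$m$ replaces the softplus by $\max(0,\, \cdot + m)$. The batch loss is the mean
over anchors. The soft margin keeps pulling matched genes together even after
the hinge would have saturated. When every embedding is identical the
per-anchor loss is exactly $\log 2$, which makes that value a useful collapse
diagnostic during training.

## Architecture and optimisation

The reference design for this loss is a pretrained ResNet50 with a 128-d
output head. No pretrained convolutional backbone ships with this package, so
its working backbone is `tiny_cnn`: three 3x3 convolution blocks
(8/16/32 filters), each followed by instance normalization, ReLU and 2x2
average pooling, then global average pooling and a linear head, trained with
Adam. Two choices deserve explanation because they depart from the reference
design, both forced by training *from random initialization*:

* **Instance normalization.** Real sections differ in staining gain, tissue
  tint and scanner exposure. Normalizing each feature map per image removes
  exactly this nuisance family and is the convolutional analogue of the
  colour normalization steps common in histopathology pipelines.
* **L2-normalized embeddings.** With raw embeddings the soft-margin batch-hard
  loss admits a degenerate descent direction: shrinking *all* embeddings
  toward a point drives the loss to $\log 2$ while destroying the metric
  structure. We measured exactly this (embedding spread shrinking ~100x over
  1500 steps with the loss pinned at $\log 2$). Projecting embeddings onto the
  unit sphere removes the scale degree of freedom, the standard remedy in
  metric learning when no pretrained backbone anchors the feature scale.
  Requesting `backbone = "resnet50_pretrained"` raises an informative error
  rather than silently substituting.

The learning rate stays constant for the first 75% of the iterations and then
decays exponentially to 1e-3 of its initial value. The tuned full-scale
configuration (P = K = 17, initial rate 7e-5, horizontal + vertical flips,
128-d output) is the package default in `training_config()`; desk-scale runs
with `tiny_cnn` use a larger rate (~3e-3), a small embedding (8-16 d) and P=8,
K=4. Because small-scale triplet training is a non-convex lottery, the
end-to-end experiment trains three restarts from fixed seeds and deploys the
restart with the best *train-gene* rank-1 — a selection that uses no held-out
information.

## Pipeline

1. **Masking.** Full images are padded to squares with white (content anchored
   top-left), downsampled to a working resolution (default 224 px), and
   segmented by a luminance threshold (foreground iff luminance < 0.95 of
   white), with components under 16 px removed and a 3x3 closing applied. A
   small trainable encoder-decoder (`mask_model()`) is a drop-in alternative;
   the threshold is the default because the mask is only a means to patch
   filtering and determinism simplifies everything downstream.
2. **Patching.** Random square windows are drawn uniformly (with replacement)
   and kept iff at least 90% of their pixels are foreground; at most 50
   patches per image within 500 attempts. Accepted windows are downsampled by
   area averaging (1024 -> 256 at full scale; tests use e.g. 128 -> 64).
   Coordinates are 0-based half-open; the foreground rule is checked at image
   scale after nearest-neighbour mask upsampling.
3. **Splits.** Genes — not donors or images — are partitioned
   80/10/10 (largest-remainder rounding, ties resolved toward the earlier
   set), so evaluation is always on unseen genes while donors appear in all
   splits.
4. **Embedding and aggregation.** Patch embeddings are averaged to images,
   (gene, donor) pairs, and genes. Gene vectors are computed hierarchically
   (patch -> image -> gene-within-donor -> gene) so donors contributing many
   images do not dominate; the averaging order is otherwise immaterial for
   balanced designs and the chosen convention is asserted by the tests.
5. **Evaluation.** `rank1_accuracy()` excludes same-donor gallery images;
   queries with no same-gene image in their gallery are dropped from the
   denominator (and counted), which reproduces the printed worked examples
   exactly: 80 genes x 2 images, all donors distinct, gives a chance level of
   1/159 = 0.63%, and 10 genes x 2 images gives 1/19 = 5.26%. A Monte-Carlo
   permutation baseline cross-checks the analytic value. Nearest-neighbour
   ties break toward the smallest image id.
6. **Downstream tasks.** Binary gene-annotation prediction and per-gene
   diagnosis prediction use unpenalized logistic regression (max 500
   iterations) under stratified 5-fold CV; AUC, AUC-PR and F1 (threshold 0.5)
   are computed on pooled out-of-fold predictions, and a one-sided
   Mann-Whitney U test (positives above negatives, midrank ties) is run per
   fold with the maximum p-value reported. Annotations need at least 5
   positive genes; GO-style tasks can additionally be restricted to 40-200
   positives. The gene x donor binary presence matrix serves as a
   confounding control: an annotation whose genes were assayed in an
   idiosyncratic set of donors is predictable from the presence matrix alone,
   flagging donor-composition leakage. Demographic covariates are one-hot
   encoded per observed level (missing becomes its own level); diagnosis
   prediction stratifies folds on diagnosis with donors as the CV unit.

## The synthetic study generator

`generate_study()` renders complete ISH-like studies with known ground truth
so every stage is testable without any download. Its defaults encode what the
generator is meant to emulate:

* **Phenotypes.** Each gene draws an intensity grade 0-5 and a pattern class
  (widespread / scattered / laminar / sparse / none) from a shuffled grid so
  genes are visually separable in expectation; cell density (per 1000 px^2 of
  tissue, base value at grade 3; the grade multiplies detectable density by
  0.4 + 0.2 x grade) and cell radius (2-4 px, ~10-20 um at the emulated
  resolution) vary per gene. Grade 0 occurs only with pattern "none".
* **Tissue.** A star-shaped blob — an ellipse whose radius is perturbed by a
  low-order Fourier series — guarantees a single connected, irregular section
  occupying 30-80% of the frame; background is near-white (>= 0.97).
  "Cortical depth" for laminar patterns is distance-to-boundary split into 6
  quantile bands; band 1 is the outermost layer.
* **Nuisance.** Donor staining gain is lognormal(0, 0.5); each section adds
  its own tissue tint (N(0.88, 0.015)), staining-batch multiplier
  (lognormal(0, 0.15)), defocus blur (sigma ~ U(0, 1.2) px) and sensor noise
  (sd 0.008); tissue folds (dark streaks) and bubbles (dark rings) appear at
  Poisson rates 1.5 and 1 per image, confined to the section. These rates were
  chosen so that raw intensity statistics alone do not re-identify genes —
  the regime that motivates donor-excluding evaluation on real data — while
  the task remains learnable at desk scale.
* **Design.** Genes are dealt to donors without replacement within a donor,
  preferring the least-assayed genes, which emulates sparse designs where
  each gene is assayed in a few brains while keeping coverage balanced.
  A planted diagnosis effect shifts the rendering intensity grade (and with
  it detectable cell density) for chosen genes in schizophrenia donors only;
  recorded truth phenotypes keep the unshifted grade.

What the generator does **not** emulate: Nissl counterstain, gray/white
matter boundaries, 3-D slice consistency, cell morphology beyond round
blobs, and spatial autocorrelation of expression within a layer. Passing
tests therefore demonstrate the pipeline's correctness and its statistical
behaviour under controlled nuisance, not performance on real atlas images.

## Problem sizes used by the test suite

The end-to-end learning experiment uses a 20-gene, 4-donor study (256-px
images, two per gene-donor pair), 128->64 px patches, a gene split of
0.5/0.1/0.4 (evaluation on the 10 held-out genes, chance level 10%), and
three 1500-iteration restarts of the 8-d `tiny_cnn`. Diagnosis-recovery
experiments use 20 genes x 16 donors with a +2-grade planted effect on two
genes, featurized by a random-initialization `tiny_cnn` (a random projection
of local stain statistics — intentionally free of any training so the test
isolates the downstream module). Statistical checks (permutation-vs-analytic
baseline agreement, oracle equivalences) use 20-200 random instances each.

## Numerical choices and degenerate inputs

* Distances: Euclidean, squared Euclidean, cityblock; zero diagonal enforced;
  the Euclidean pair gradient guards against division by zero at coincident
  points (1e-12 floor).
* F1 threshold is fixed at predicted probability 0.5; constant features give
  AUC exactly 0.5 under midrank ties.
* `compare_embedding_sources()` reports p = 1 when every paired difference is
  zero and p = 0 for a non-zero constant shift (the t statistic is unbounded
  there); otherwise it defers to the exact paired t distribution.
* Queries whose gallery holds no same-gene image are excluded from the rank-1
  denominator; if *all* queries are excluded the metric is an error, not 0.
* Largest-remainder seat ties in `split_genes()` resolve toward the earlier
  set (train, then validation).
* All randomness flows from per-stage substreams of a master seed
  (`substream_seed()`), so every artifact is reproducible from its manifest.

## Known limitations

Training a CNN in base R is practical only at desk scale (64-px inputs,
tens of genes); the full-scale configuration (P = K = 17, 128-d, tens of
thousands of iterations on millions of patches) is expressible but not
practical without a GPU framework. The rank-1 metric degrades gracefully but
noisily below ~50 evaluation images; fold-level Mann-Whitney p-values are
unstable when a fold holds fewer than ~3 positives. The untrained-backbone
baseline in the learning-lift experiment is itself a random variable across
initializations; the experiment therefore averages it over the three restart
seeds rather than trusting a single draw.
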