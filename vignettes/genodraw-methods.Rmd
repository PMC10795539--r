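---
title: "Predicting fruit images from SNP panels: models, defaults and design choices"
author: "genoDraw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting fruit images from SNP panels: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

genoDraw predicts what a genotype's fruit looks like from a small panel of
SNP markers. The pipeline has two trained components and one assembly step:

1. **Image compressor.** A convolutional autoencoder is trained to
   reconstruct single-fruit RGB images through a 64-value sigmoid bottleneck.
   After training, the encoder turns each image into a 64-dimensional
   *embedding* in $[0,1]^{64}$.
2. **Target construction.** Image embeddings are grouped by genotype and
   averaged element-wise. The mean vector is the genotype's regression
   target; decoding it yields the genotype's *mean image*.
3. **Embedding predictor.** A two-layer dense network maps SNP dosages
   (0, 0.5, 1 for AA, Aa, aa) to the 64 mean-embedding values, trained with
   mean absolute error (MAE).
4. **Assembly.** The trained predictor is attached to the trained decoder,
   with no further weight updates. The composite maps a dosage vector
   directly to an image: `drawGenotype()` computes exactly
   `decode(predict(dosages))`.

The train/validation split is at genotype level (every image of a genotype
lands on one side) and stratified so that both partitions preserve the
overall shape-category distribution. Stratification uses the five-class
categorisation of the per-genotype mean fruit shape index; the category cut
points are configurable and echoed in every report.

## Architectures

**Autoencoder (default, 300 px inputs).** Six 3×3 stride-2 convolutions with
rectified-linear activation and filter counts rising from 16 to 128, a
flatten, three leaky-rectified dense layers of 8192, 4096 and 2048 units, and
a 64-unit sigmoid bottleneck. The decoder mirrors this structure
layer-for-layer (dense 64→2048→4096→8192→flatten-size, then six transposed
convolutions recovering each encoder map size exactly) and ends in a sigmoid,
so embeddings and decoded intensities are both confined to $[0,1]$. The
first dense layer consumes the flattened final convolution map; with the
default stack at 300 px that map is 5×5×128. The exact filter ladder between
16 and 128 is a package choice (16/32/48/64/96/128).

**Desk-scale profile** (`deskAutoencoderSpec()`): 64 px inputs, four
convolutions (filters 8→64), dense 1024/512/256, the same 64-value
bottleneck. All CPU-scale tests and the bundled experiments use this
profile; the full-scale architecture is built and shape-audited but not
trained in the test suite.

**Embedding predictor.** `nSnps → 300 → 64`, sigmoid on both layers
(64,564 parameters at 150 input SNPs). Sigmoid outputs feed the decoder's
embedding input directly.

## Losses and training

Three reconstruction losses are selectable in `trainAutoencoder()`:

* `mse` — mean squared error over all pixels (the default in this package's
  experiments, and fully self-contained);
* `ssim` — one minus a whole-image structural-similarity index computed from
  global image statistics, with the usual constants for a unit dynamic
  range; its analytic gradient is verified against finite differences in the
  test suite;
* `perceptual` — feature-space distances under a pretrained image
  classification network. This package deliberately does not bundle such
  weights, so requesting it is an explicit error advising `mse`/`ssim`.
  Windowed or multi-scale SSIM variants are likewise out of scope.

The optimiser is plain stochastic gradient descent with momentum 0.9.
Weights are initialised fan-in-scaled (He gain for rectifier layers, Xavier
for saturating ones); with that initialisation the desk-scale model needs a
learning rate of about 0.1 and small mini-batches (default 8) to clear the
"uniform grey" plateau within a 15-epoch budget — at a learning rate of 0.01
with batch 32 the per-epoch update count is too small and training visibly
stalls. Both settings are plain arguments; runs at paper scale (300 px,
35 epochs) would be tuned on their own data.

The predictor trains with MAE loss under SGD (learning rate 0.05,
mini-batch 16), a reduce-on-plateau scheduler (factor 0.5, patience 10) and
an early stopper (patience 25 epochs, minimum improvement 1e-4 in validation
MAE) capped at 1,000 epochs; the best-scoring weights are restored. The
plateau/stopper constants are package defaults, chosen to tolerate the slow,
stagnating MAE decline typical of these fits; they are not claims about any
particular dataset. "Improvement" is measured on the validation MAE when
validation genotypes are supplied, else on the training MAE.

## Shape descriptors

* **FSI (fruit shape index)** — silhouette height divided by width, from the
  bounding box of the extracted mask.
* **SR (shoulder ratio)** — width near the top over width near the bottom.
  Taken literally, "width at the extreme rows" is degenerate (a convex
  silhouette has near-zero width there), so the measurement rows are inset
  by a configurable fraction of the height, 10% by default. This inset is an
  interpretation made by this package, not a community standard.
* **Category** — flat, flat-globose, globose, oval, oblong by interval
  lookup of the FSI against four increasing cut points, default
  0.85/0.95/1.05/1.20, left-closed. The defaults are package choices (the
  five-class scheme exists in pomological references but the exact cut
  points vary); every report echoes the thresholds used.

Silhouettes are extracted by luminance conversion, a global Otsu threshold
(a fixed 0.5 threshold is available for soft-edged decoded images), largest
connected component, and hole filling.

## The synthetic population

The simulator exists so every downstream stage is testable without external
data. It emulates: several images per genotype with within-genotype shape
variability; a population of dozens to hundreds of genotypes; a small causal
SNP set controlling shape additively plus many neutral markers.

* **Silhouette family**: superellipse (exponent 2.5) with a linear vertical
  taper solved in closed form from the target SR, and optional sinusoidal
  radial lobing. FSI and SR are therefore analytically controllable;
  render-then-measure round trips recover the targets to ±0.02 at 300 px.
* **Genetics**: dosages drawn under Hardy–Weinberg at the architecture's
  allele frequencies; per-genotype FSI = baseline + Σ effects × dosage. On
  the 0/0.5/1 dosage scale the additive genetic variance is
  Σ effect² · p(1−p)/2, which the test suite verifies by Monte Carlo.
* **Environment**: each image adds independent N(0, envSd) noise to the
  genotype's FSI; SR is held at 1. Real apples also vary in conicity,
  lobing, colour and size; environmental noise on FSI alone keeps the
  headline metric identifiable, and the weak, symmetry-confounded SR signal
  is deliberately not simulated. The default envSd = 0.03 is a free
  simulator knob — the within-genotype variance of real orchards is not
  characterised here.
* **Default study conditions** used by the bundled experiments: 70 genotypes
  × 5 images at 64 px, 10 causal SNPs with effects ±0.04 on a 0.95 baseline,
  140 neutral SNPs, allele frequency 0.5. That gives an additive genetic
  SD of ≈0.045 against a per-image environmental SD of 0.03, i.e. strongly
  heritable genotype-mean shape — the regime in which a targeted panel can
  demonstrably beat a random one at desk scale.

What passing these tests does **not** show: robustness to photographic
nuisance (lighting, occlusion, segmentation error), to non-additive genetic
architectures, to linkage between causal and neutral markers (simulated
SNPs are independent), or to the class imbalance of real germplasm.

## Evaluation

* **Null threshold**: per-genotype mean μ and SD σ of a metric are estimated
  from the original images; 10,000 replicate datasets draw one value per
  genotype from N(μ_g, σ_g) and each replicate's MAE against the μ values is
  recorded. The replicate-MAE mean (± SD) is the boundary below which a
  model is doing better than resampling the phenotype distribution. With all
  σ equal to s this converges to the half-normal mean s·√(2/π), which the
  suite checks to 2%. Sampling uses σ as a standard deviation.
* **Wasserstein distances**: first-order, computed as the area between
  empirical distribution functions (equal-size case: mean absolute
  difference of sorted samples, used as the brute-force oracle).
* **Battery comparison**: Welch's two-sample t test — the two groups of
  independently trained models have no pairing and need not share a
  variance. The directional desk-scale check additionally uses a paired
  one-sided t test across shared training seeds.
* **Confusion analysis**: 5×5 matrix in fixed category order, accuracy =
  trace/total, and the macro-averaged F score over classes present in the
  truth — macro because class imbalance is exactly the failure mode of
  interest.
* **FSI/SR MAE** of drawn images is reported against the decoded mean
  images (the predictor's actual target); distances to the original-image
  distributions are reported alongside as Wasserstein distances, since
  either comparator is defensible.

## Numerical and degenerate-input policy

Fan-in-scaled uniform initialisation; all layer gradients are verified
against finite differences. Degenerate inputs fail fast with named
offenders: unknown or missing allele calls, duplicate identifiers,
multiallelic VCF sites, silhouettes with empty foreground, shape parameters
whose silhouette cannot occupy 45–90% of the canvas, convolution stacks that
collapse a map below 2 px, genotypes missing from the matrix or panel SNPs
missing from a dosage row. Missing-call imputation is off by default; when
enabled it uses the per-SNP mean rounded to the nearest valid dosage so the
0/0.5/1 invariant survives. Single-genotype strata go to the training side
with a warning. Per-image simulated FSI values are clamped to the
renderer's valid [0.6, 1.7] band.

## Problem sizes in the bundled tests

The suite trains the desk profile for 15 epochs (the training-regime
checks) and continues the same run to 25 epochs for the shape-retention,
target and panel experiments; it uses 10 paired targeted/random trainings
for the central comparison and 5 models per cell for the two-rung dilution
ladder (core vs 10× dilution). Paper-scale replicate counts (100-model
batteries, 15 models per ladder rung, nine rungs up to hundreds of
thousands of SNPs) are plain arguments to the same functions.

## Known limitations

The decoder reproduces silhouette shape, not texture: flesh colour and
lobule depth are not retained at a 64-value bottleneck. Mean embeddings
symmetrise asymmetric fruit, so SR signals are structurally weak — the
simulator does not pretend otherwise. The predictor is intentionally
shallow; with panels of hundreds of thousands of SNPs it degrades rather
than learns to select inputs, which is the behaviour the dilution ladder is
designed to expose. Multi-fruit photographs must be segmented to single-fruit
images upstream; fruit size is out of scope.
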