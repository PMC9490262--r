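---
title: "Quantifying tumor-stroma reaction on whole-slide images: methods and design"
author: "stromascope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-stroma reaction on whole-slide images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Tumor-stroma reaction (TSR) is the desmoplastic change of the stroma
adjacent to invasive carcinoma: collagen deposition (fibrosis),
fibroblastic/myofibroblastic proliferation (cellularity), and a shift of
stromal cells toward a common orientation. Pathologists grade each
criterion 0 (none/weak), 1 (intermediate), 2 (strong) on H&E sections, but
manual review is subjective and does not scale to cohorts of hundreds of
gigapixel whole-slide images (WSIs). `stromascope` implements a
patch-based pipeline that automates this assessment and carries the result
through to survival and gene-expression association analysis:

1. tile the slide into 256 px patches over detected tissue;
2. classify each patch pixelwise into tumor/stroma/background and score
   stroma patches 0/1/2 on the three TSR criteria (pluggable backends);
3. stitch patch results into a slide-level multilabel mask at a
   downsampled working scale and locate the tumor-stroma interface by
   mathematical morphology;
4. summarize patch scores within the interface into per-slide features;
5. associate features with survival (median split + Cox proportional
   hazards) and with gene expression (Spearman scan + over-representation
   analysis).

High-grade serous ovarian carcinoma (HGSOC) is the motivating disease;
serous borderline tumors (SBOT), which lack tumor-triggered stromal
reaction, serve as negative controls.

## Tiling and foreground detection

Tissue is separated from glass by converting RGB to CIE LAB and
thresholding the lightness channel L: tissue is darker than the
background, so a pixel is foreground iff L falls below the threshold. The
threshold is chosen automatically by Otsu's bimodal method
(`detectForeground(method = "otsu")`) or fixed by the caller. Slide-level
detection runs on a 128-fold block-mean downsample; the background
fraction of every candidate patch is then *recomputed at full patch
resolution* with the same rule, and patches with more than 50% background
are excluded (`maxBackgroundFrac`, a `TilingConfig` field).

Conventions worth stating once: pixel coordinates are 0-based, x
rightwards, y downwards, patches are half-open `[origin, origin + size)`,
the grid is enumerated row-major, and partial tiles at the right/bottom
edges are dropped rather than padded so that all patch statistics refer to
full-size tiles. Training-set extraction uses stride 128 (half-overlap,
enlarging the labeled set); inference tiling uses stride = patch size
(non-overlapping, required for stitching).

On the synthetic phantoms (below) the automatic threshold has a known
failure mode: an SBOT-like phantom is dominated by the lightest stroma
tint plus white glass, with only small dark tumor islands, so the Otsu
split lands between tumor and everything else and discards the stroma.
Phantom protocols therefore pass the fixed threshold L < 95 (glass renders
at L ≈ 99, the lightest tissue tint at L ≈ 81); Otsu remains the default
for real bright-field slides, whose tissue-background contrast is the
bimodality Otsu expects.

## Annotations

Pathologist annotations enter as a GeoJSON FeatureCollection (the dialect
mirrors what QuPath exports): per ROI one boundary polygon and any number
of scored sub-region polygons with properties `criterion` and `score`.
Rasterization tests pixel centers with the even-odd rule; overlapping
sub-regions are resolved by file order (last wins) with a warning, since
annotation protocols assume homogeneous, non-overlapping regions. The
training region algebra is: stroma = union of all scored sub-regions (any
criterion, any score); tumor = tissue ∩ ROI ∖ stroma.

## Patch models: contracts and reference backends

The deep models used in production settings (instance segmentation
networks for tumor/stroma, image classifiers per TSR criterion) are
deliberately *not* part of this package; they hide behind two S4
contracts. `SegmenterBackend` maps a patch to a per-pixel label raster
over {background, tumor, stroma}; `TSRScorerBackend` maps a patch to a
score in {0,1,2} plus a probability 3-vector summing to one. Anything
satisfying the contract drops in; the pipeline's behavior depends on
backends only through these two generics (tested by substituting constant
mock backends).

The shipped reference backends are classical, CPU-scale models sufficient
to validate every downstream stage:

* **Segmenter** — a pixelwise linear discriminant on (R, G, B, local SD in
  a 5×5 window). Because a tissue class may be multimodal in color (the
  phantom stroma has one tint per score, and real stroma varies too), the
  training pixels of each class are first split into up to 3 k-means
  subclasses and the discriminant is fitted over subclasses, collapsing at
  prediction. Fitting subsamples at most 20,000 pixels per class and is
  deterministic given its seed.
* **Scorer** — a patch-level linear discriminant on summary features:
  mean and quartile color per channel (the per-channel median tracks the
  dominant tint even when a patch mixes scores), gray-level SD, edge
  density, gradient anisotropy, and the fraction of dark nuclei-like
  pixels.

A patch's dominant class is the majority pixel label over *tissue* pixels,
with ties broken toward stroma (conservative for interface detection);
background is assigned only when a patch contains no tissue pixels at all.
TSR scores are attached to all stroma-dominant patches and filtered to the
interface later, at summarization.

## Interface detection

Patch predictions are stitched into a slide mask at scale `r`: each patch
writes its dominant class into the corresponding block; uncovered area is
background. With `I_T`, `I_S` the tumor and stroma indicator images and
`S` a structuring element (default: Euclidean disk of radius 2),

```
Tumor_core  = C(I_T, S)
Stroma_core = C(I_S, S)
interface   = and(xor[D(Stroma_core, S), E(Stroma_core, S)],
                  Stroma_core, D(Tumor_core, S))
```

with `C`, `E`, `D` closing, erosion, dilation. The XOR term is the
morphological gradient band of the stroma core — pixels within one SE
radius of its boundary; intersecting with the core keeps the stroma-side
half of the band, and intersecting with the dilated tumor core keeps only
the part that touches tumor. The composition is implemented literally
rather than algebraically simplified, and the test suite proves pixel
equality against an independent shift-based implementation of the
textbook operator definitions on random masks. The same structuring
element serves all three operators by default, with a `closeSelem`
override. Border convention: out-of-bounds neighbors are ignored (erosion
does not eat the image border); empty tumor or stroma gives an empty
interface, not an error.

Connected components are labeled 8-connected by default (4-connected by
flag), with ids in raster scan order; `topComponents()` returns the k
largest, ties broken by smaller id, mirroring the practice of reviewing
the top five regions per slide.

### The working scale

`r = 1/128` is the package default, appropriate for gigapixel WSIs where
tumor islands span hundreds of mask pixels. The scale is a free parameter
for a reason: the formula behaves correctly only when the SE radius is
small relative to tumor-island extent at mask scale. On a 2048-px phantom,
`r = 1/128` yields a 16×16 mask whose tumor islands are below the closing
scale — the closing of stroma swallows them and the interface degenerates.
The phantom protocols therefore stitch at `r = 1/8` (mask 256×256, patch
footprint 32 px, islands ≈ 30 px across vs. SE radius 2), restoring the
same scale relation the default has on real WSIs.

## Slide-level features and the phantom study

Within the interface (membership: a stroma patch whose downsampled
footprint overlaps the interface mask; the overlap fraction is
configurable, any-overlap by default), patch scores are counted with equal
weights into a normalized distribution `ratio_0/1/2` per criterion, plus
`mean = ratio_1 + 2 ratio_2` and the population SD. A slide with no
interface patches yields a flagged row (`undefined = TRUE`) rather than
silent zeros.

### What the phantom generator emulates

`generatePhantomSlide()` renders a wobbly elliptical tissue region on
near-white glass, smooth tumor blobs, and stroma filling the rest. TSR
ground truth is planted geometrically: stroma within 192 px of the nearest
tumor pixel scores 2, within 448 px scores 1, 0 beyond — the
invasive-front band the interface detector is supposed to find. Scores
drive rendering: a base tint per score (deliberately well-separated;
`hardMode` narrows the gaps threefold), fibrous streaks scaled by
fibrosis, dark dots by cellularity, oriented stripes by orientation, plus
Gaussian pixel noise. SBOT-like phantoms have tumor and stroma but all
scores 0. Everything is bit-reproducible per seed.

What phantoms do *not* emulate: real H&E color statistics, stain
variation and batch effects, nuclei morphology, necrosis, adipose tissue,
or ambiguous transitional stroma. Passing the phantom study therefore
validates the *pipeline machinery* — tiling bookkeeping, backend
contracts, stitching, the morphological formula, summarization and the
statistics — not the histological accuracy of any particular trained
model on real tissue.

### The end-to-end study and its frozen conditions

`phantomEndToEndStudy()` trains reference backends on five 1024-px
phantoms (three HGSOC-like, two SBOT-like, stride 128), then runs the whole
pipeline on ten HGSOC-like and three SBOT-like 2048-px phantoms and scores
it against ground truth at the working resolution: the truth mask is the
majority ground-truth class per patch stitched at the same `r` (a
patch-based pipeline cannot resolve structure below patch granularity);
the true band is truth-stroma within one SE radius of truth-tumor; the
far field is truth-stroma beyond twice the radius — the analytic reach of
`D(C(·,S),S)`, so far-field hits indicate genuine leakage. The study
reports pooled band recall and far-field rate over the HGSOC slides and
the per-slide mean fibrosis for both classes; HGSOC slides are expected
to exceed SBOT slides on every replicate.

Scorer training and evaluation use *homogeneous* stroma patches (≥ 75% of
stroma pixels carrying the modal score, ≥ 75% stroma), emulating
annotation protocols in which pathologists outline homogeneous single-score
regions; a mixed patch's modal label is genuinely ambiguous and no patch
classifier, learned or engineered, can be graded fairly on it.

## Association analysis

* **Median split**: values ≤ median go to "low" — a deterministic tie
  rule, stated because it changes group sizes when the median is attained.
  All-identical input cannot be split and errors.
* **Cox PH** (`survival::coxph`): univariate, or multivariable adjusted
  for age, stage IV vs III, suboptimal vs optimal debulking; HR with 95%
  CI and two-sided Wald p. A group with zero events is rejected up front
  with a clear error instead of a convergence failure.
* **Spearman gene scan**: `cor(method = "spearman")` per gene with
  average-rank ties; two-sided p from the t approximation
  `t = rho sqrt((n-2)/(1-rho^2))`. Genes with nominal p < 0.05 split by
  correlation sign feed over-representation analysis.
* **ORA**: one-sided hypergeometric upper tail against the measured gene
  universe (all genes on the matrix — the defensible background when the
  chip defines what could have been selected), Benjamini-Hochberg across
  the gene-set collection. Gene sets are read from GMT.

The synthetic cohort plants both effects. Survival: exponential with
baseline median 37 months (typical for advanced serous carcinoma), hazard
multiplied by `exp(0.69)` (HR 2) in the fibrosis-high half, uniform
administrative censoring on (0, 200] months (≈ 25% censoring); age,
stage, and debulking frequencies follow an advanced ovarian-cancer cohort
(mean age 63, 75% stage III, 76% optimal debulking). Expression: planted
genes are linear in the standardized fibrosis score with slope 0.45 plus
unit noise (ρ ≈ 0.4 — a monotone link, which is all Spearman needs; linear
is the simplest testable choice), remaining genes independent N(0,1).
Validation checks are parameter-recovery style: CI coverage of the
planted HR near 95%, null p-values uniform, planted genes separated from
the null ρ distribution, the planted gene set top-ranked at FDR < 0.05,
and ≈ 5% nominal false positives under the null.

## Numerical and degenerate-input choices

* Dice and IoU are defined as 1 when both masks are empty, so batch
  evaluation over background-only tiles stays NaN-free; the identity
  `DSC = 2 IoU / (1 + IoU)` is asserted on random pairs.
* Average precision is pixel-level and rank-based (sum of precision ×
  recall increments over distinct thresholds, ties entering together);
  constant scores give AP = prevalence. Instance-level mask AP would need
  object matching that a scalar per test set does not require.
* Extrinsic review selection uses inverse-CDF (type-1) empirical
  quantiles computed from each end of the sorted ratios, so n = 20
  distinct slides yield exactly one slide per 5% tail; all-equal ratios
  degenerate to selecting everything, with a warning. Review sampling
  draws `min(29, max(10, available))` patches capped at availability
  ("at least 10 but fewer than 30"), uniformly without replacement,
  deterministic per seed.
* Modal patch labels break ties toward the lower score; dominant-class
  ties break toward stroma; component-size ties break toward the earlier
  scan-order id. Every tie rule is deterministic so reruns are
  bit-identical.
* Study problem sizes (1024-px training phantoms, 2048-px evaluation
  phantoms, cohorts of 200-400 cases, 50/20 replicates) are chosen so the
  full validation runs on a laptop-class single core in minutes while
  keeping Monte-Carlo noise well inside the asserted margins.

## Known limitations

* The reference backends are linear discriminants on hand-designed
  features: adequate for the well-separated phantom textures, not for
  real H&E. They are scaffolding for the contracts, not a claim about
  histology.
* Interface detection inherits segmentation errors (a misclassified patch
  block can seed or erase interface), exactly as patch-based pipelines do
  in production; the far-field bound quantifies the leakage mode.
* The morphological formula loses band pixels at sharp concave corners of
  the stitched stroma core (the closing absorbs them); at the recommended
  scale relation this loss stays in the single-digit percent range.
* Phantom TSR geometry ties all three criteria to the same
  distance-to-tumor field, so criterion scorers are validated
  independently but on spatially identical label maps.
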