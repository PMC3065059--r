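---
title: "Methods: entropy-based lumen extraction and PCA-SVM calculus recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-based lumen extraction and PCA-SVM calculus recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calculoscope)
```

## The recognition problem

Prostatic calculi (corpora amylacea) are concentric glycoprotein bodies
inside gland lumina. In H&E sections they appear as round or oval regions
with a tree-ring lamellar texture, while the surrounding lumina are bright
and texturally homogeneous and the stroma is densely textured by nuclei
and fibrous tissue. `calculoscope` chains four stages — entropy-based
lumen extraction, morphological region segmentation, co-occurrence texture
description, and PCA-SVM classification under repeated 5-fold
cross-validation — and provides a phantom generator so the chain can be
validated without clinical material.

## Local entropy and its polarity

The transform is the entropy of *normalized gray values* in a sliding
`w x w` window: `p_ij = f(i,j) / sum(f)`, `H = -sum(p_ij log2 p_ij)`, with
`f > 0` enforced by adding an offset of 1 to 8-bit intensities. Two
properties drive every design choice downstream:

* A constant window attains the **maximum** `log2(w^2)`; texture lowers
  `H` by approximately `(1 / (2 ln 2)) (s/m)^2` bits, where `s/m` is the
  window's coefficient of variation. Homogeneous lumina are therefore the
  *high*-entropy class, and `extract_lumina()` keeps the side **above**
  the Otsu threshold. (A histogram-based local entropy would invert this
  polarity; this package implements the normalized-gray-value definition
  literally and consistently.)
* `H` is invariant under global intensity scaling, and changing the
  logarithm base only rescales `H` monotonically, leaving the Otsu
  partition unchanged. Base 2 (bits) is fixed for reproducibility.

The dynamic range of this entropy is narrow (a CV of 0.24 costs only
~0.04 bits from the maximum), so the separation between lumina and stroma,
while reliable, is small in absolute terms. Two consequences:

* **Window size** (`window = 9`, configurable, odd): windows must be large
  enough that the stroma's within-window variance is estimated stably
  (tight stroma mode), but small enough not to blur lumen borders; at the
  9-px default the boundary halo is 4 px. Larger windows shrink the
  *relative* lumen-stroma gap on this compressed scale and were found to
  degrade the split.
* **Degenerate-split guard** (`min_separation = 5`): Otsu always returns
  a cut, even for a field with no lumina, where it merely bisects the
  unimodal stroma distribution. The guard computes the effect size of the
  split (class-mean gap over the smaller within-class standard deviation).
  Bisecting a Gaussian scores about 2.7 and a uniform about 3.5, whereas a
  genuine lumen/stroma or calculus/lumen split scores well above 6 on
  phantoms across seeds; 5 sits between the two regimes. The same guard,
  applied to the within-lumen gray histogram, prevents calculus-free
  lumina from shedding noise-split pseudo-regions.

Borders use reflection padding; the three channel entropy maps are
composed pixel-wise, by mean by default (min and max are available; for
channel-wise scaled copies of one gray image all three coincide).

## Otsu implementation details

`otsu_threshold()` quantizes to `n_bins = 256` uniform bins and scans all
cuts exhaustively. Class means are computed from the actual pixel values
per bin (not bin centers), so the returned `omega/mu/g` satisfy
`omega0 + omega1 = 1`, `mu = omega0 mu0 + omega1 mu1` exactly, and the
two-mass closed form `g = omega0 omega1 (mu0 - mu1)^2` is reproduced
exactly. The reported threshold is the largest gray value in the low
class, so `binarize(..., "below")` recovers exactly the class the scan
assigned; ties break toward the lowest cut.

## Morphology

The structuring element defaults to a disk of radius 3 (the operators are
standard; the element is a package choice). Two operator orders are used:

* Lumen masks: **open → close → fill holes** — specks are removed before
  gaps are closed; the filled holes are exactly the calculus bodies, whose
  strong texture makes them low-entropy islands inside the lumina.
* Calculus candidates: **close → fill → open** — thresholding the
  concentric lamellae yields thin nested annuli; closing merges them into
  a solid body first, otherwise opening would erase them.

Components below `min_area = 30` px² are dropped as noise specks, and
components touching the image border are excluded from region extraction
(regions cut by the field of view cannot be scored reliably). Labeling is
8-connected by default with deterministic raster-scan label order;
4-connectivity is available.

## Texture descriptor

Each region's patch is quantized to `levels = 16` uniform gray levels over
the masked pixel range — standard co-occurrence practice that keeps the
16x16 matrices populated for small regions. Ordered (non-symmetric)
co-occurrence matrices are accumulated for offsets `(0,+1)`, `(-1,+1)`,
`(-1,0)`, `(-1,-1)` (0, 45, 90, 135 degrees at `d = 1`); pairs must lie
wholly inside the region mask. The mean of the four count matrices forms
the fifth direction *before* normalization; all five are then normalized
and scored with 14 Haralick statistics, giving the 70-vector in
direction-major order (`<feature>_<d0|d45|d90|d135|mean>`).

Notes on the statistics:

* "Variance" (sum of squares) is computed symmetrically in the two
  coordinates about the grand mean index `(mu_x + mu_y)/2`, so a
  pair-reversed (transposed) matrix scores identically; it reduces to the
  classic definition for symmetric matrices. With this choice a 90-degree
  image rotation exactly permutes the 0/90 and 45/135 feature blocks. In
  the mean-direction block the order-insensitive statistics (contrast,
  variance, homogeneity, the sum/difference-histogram statistics, cluster
  shade/prominence) are exactly rotation-invariant; energy, entropy,
  correlation and maximum probability can shift minutely because rotation
  transposes two of the four ordered matrices entering the mean. A
  `symmetric = TRUE` option removes the effect entirely.
* Cluster shade/prominence are the third/fourth moments of `i + j` about
  `mu_x + mu_y`; difference variance is the variance of the `|i - j|`
  distribution.
* Logs are base 2 with `0 log 0 = 0`; correlation is defined as 0 when a
  marginal is degenerate.

## PCA-SVM and the cross-validation protocol

Features are standardized per column to mean 0 and *population* standard
deviation 1 (the n-divisor; immaterial downstream because PCA is computed
from the correlation matrix, which is scale-free). Constant columns are
dropped with a warning. PCA retains the smallest `k` whose cumulative
eigenvalue share reaches `alpha = 0.98`.

The SVM is a C-classification RBF machine (via `e1071`/libsvm) with
`C = 1` and `gamma = 1/(p * var(X))` by default — the hyperparameters are
not part of the protocol and are configurable; no grid search is run by
default.

`repeated_kfold_cv()` shuffles with seed `seed + r` for repeat `r`, forms
`k` folds as even as possible, and accumulates one confusion-count vector
per repeat across its folds, so every sample is tested exactly once per
repeat; with 125 samples and `k = 5` each fold holds exactly 25. Two
projection protocols are implemented:

* `pca_mode = "train_only"` (default): standardization and PCA are fitted
  on the training folds only and applied to the held-out fold — the
  statistically clean protocol.
* `pca_mode = "combined"`: standardization and PCA are fitted on training
  and test features pooled. This replicates the historical protocol the
  package models, but it leaks test-set feature structure into the
  projection and is provided for fidelity comparisons only. On null data
  the default protocol stays at the majority rate, which the test suite
  asserts.

Sensitivity and specificity are always recomputed from the confusion
counts (`100 TPS/(TPS+FNS)`, `100 TNS/(TNS+FPS)`); ratios with zero
denominators are reported as `NA` with a flag. The bundled ten-run
reference table (`cv_reference_runs()`) carries reported per-run
sensitivity/specificity values that are not all consistent with the counts
in the same column (e.g. run 1: 25/28 = 89.29 vs the reported 89.5); the
package documents and preserves the reported rows but trusts the counts.

## What the phantom emulates — and what it does not

`generate_phantom()` renders, at 8-bit scale: stroma at 120 with bounded
uniform texture noise (sd 29), elliptical lumina at 230 (sd 2, semi-axes
22-34 px), and calculi as concentric-ring disks (base 160, amplitude 60,
4 rings, radii 7-11 px capped at 0.6 of the host lumen's minor axis),
tinted into three channels. Placement is rejection sampling of
non-overlapping ellipses with a fixed retry budget; failure raises rather
than silently degrading. Identical config + seed is bit-reproducible.

The stroma noise is uniform rather than Gaussian by design: dense fibrous
texture has bounded excursions, and heavy tails would scatter spurious
low-entropy pockets that break the single-threshold bimodality the
entropy/Otsu stage relies on — the phantom's role is to realize the
documented appearance model (homogeneous bright lumina against densely
textured stroma), not to stress-test it. What the phantom does **not**
model: stain variability, nucleus-shaped structures, out-of-focus blur,
lumen-lumen adhesion, calculi touching lumen walls, or magnification
changes. Passing on phantoms therefore demonstrates the pipeline's
correctness under its stated premise, not clinical performance on real
slides.

`generate_feature_dataset()` draws two Gaussian classes with unit
within-class variance: a stated informative subset (default `p/7` of the
features) shifted by `separation` sd in the positive class, the rest
correlated nuisance built from shared latent factors so PCA has real
redundancy to compress. At separation 6 the Bayes error is negligible,
which anchors the cross-validation accuracy check (>= 95%).

## Problem sizes and numerical tolerances

The test suite runs phantoms at 256 x 256 with 4 lumina, co-occurrence
oracle checks on patches up to 10 x 10 over 50 random draws, Otsu oracle
scans on 20 random images, and the classification check as ten 5-fold
repeats on a 125 x 70 table (28 positive / 97 negative, separation 6) —
sizes chosen to exercise every code path in seconds. Normalized matrices
sum to 1 within 1e-12; standardization and PCA identities are asserted at
1e-9; entropy bounds at 1e-9.

## Known limitations

* The entropy polarity is tied to the normalized-gray-value definition;
  images whose lumina are *darker* than their surroundings would need the
  configurable polarity flipped.
* Single-threshold Otsu assumes one homogeneous class against one
  textured class per field; fields mixing several texture populations
  (e.g. dense nuclear clusters plus fibrous stroma) can defeat it, which
  is why the separation guard prefers returning nothing over returning
  noise.
* Adhesion between structures is handled only by opening/closing; no
  watershed or model-based splitting is attempted.
* SVM hyperparameters are defaults, not tuned; accuracy on real data
  would require calibration against annotated slides.
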