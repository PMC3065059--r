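# calculoscope

Automated recognition of prostatic calculi (corpora amylacea) in H&E
histology micrographs.

Prostatic calculi are concentric glycoprotein concretions that sit inside
the gland lumina and show a characteristic round/oval "tree-ring" lamellar
texture. Finding them reliably matters to pathologists because their
presence identifies tissue as prostatic in origin. `calculoscope`
implements a classical image-analysis pipeline for this task, aimed at
quantitative-pathology researchers and method developers:

1. **Lumen extraction.** Each color channel is transformed by the
   *gray-value local entropy*: for every pixel, the `w x w` window values
   `f(i,j) > 0` are normalized to a distribution
   `p_ij = f(i,j) / sum f(i,j)` and the pixel receives
   `H = -sum p_ij log2 p_ij`. A homogeneous window attains the maximum
   `log2(w^2)`, so the texturally uniform lumina form the high-entropy
   class while nucleus-rich stroma scores lower. The three channel maps
   are composed (pixel-wise mean by default), thresholded by **Otsu's
   method** — the cut `T` maximizing the between-class variance
   `g = w0 (mu0 - mu)^2 + w1 (mu1 - mu)^2` — and refined by mathematical
   morphology (opening, closing, regional hole filling).
2. **Suspicious-region segmentation.** Otsu applied to the gray values
   inside the lumina isolates darker structured bodies; closing merges
   their concentric lamellae, border-touching components are dropped, and
   each remaining component becomes a candidate region.
3. **Texture description.** Per region, gray-level co-occurrence matrices
   `p(i, j, theta, d)` are accumulated for `theta = 0, 45, 90, 135` degrees
   at `d = 1`, plus their mean as a fifth direction; each normalized matrix
   yields 14 Haralick statistics (energy, contrast, correlation, entropy,
   variance, sum average, sum variance, homogeneity, difference variance,
   sum entropy, difference entropy, cluster shade, cluster prominence,
   maximum probability) — a 70-dimensional descriptor.
4. **PCA-SVM classification.** Features are z-scored, reduced by principal
   components of the correlation matrix keeping the smallest set whose
   cumulative contribution rate reaches `alpha = 98%`, and classified by an
   RBF-kernel SVM, evaluated by ten repetitions of 5-fold cross-validation
   with confusion counts (TNS, FPS, FNS, TPS), accuracy, sensitivity and
   specificity per run.

Because no original slide images are publicly available, the package ships
a **synthetic phantom generator** (`generate_phantom()`,
`generate_feature_dataset()`) that emulates the documented appearance —
textured stroma, bright homogeneous lumina, tree-ring calculi — with
ground-truth masks, so every stage is testable end to end.

## Worked example

```r
library(calculoscope)

# a phantom field with 4 lumina, 3 of which contain calculi
ph  <- generate_phantom(phantom_config(n_lumina = 4, n_calculi = 3, seed = 11))
lum <- extract_lumina(ph$image)
lum$labels$n_regions
#> [1] 4

regs <- segment_suspicious_regions(ph$gray, lum$lumen_mask)
length(regs)
#> [1] 3

region_features(regs)[, 1:5]
#> # A tibble: 3 x 5
#>   region_id energy_d0 contrast_d0 correlation_d0 entropy_d0
#>       <int>     <dbl>       <dbl>          <dbl>      <dbl>
#> 1         1    0.0255        85.4         -0.205       5.80
#> 2         2    0.0213        81.7         -0.210       5.85
#> 3         3    0.0136        60.2         -0.138       6.52
```

All four lumina and all three seeded calculi are recovered; the
concentric-ring regions show high contrast and near-maximal entropy, the
signature the classifier exploits. Classification on a synthetic labeled
table (28 positive, 97 negative, class separation 6 sd):

```r
tab <- generate_feature_dataset(28, 97, n_features = 70, separation = 6, seed = 3)
cv  <- repeated_kfold_cv(tab, k = 5, repeats = 10, seed = 5)
glance(cv)
#> # A tibble: 1 x 6
#>   n_runs mean_train_accuracy mean_test_accuracy mean_sensitivity mean_specificity ...
#> 1     10                 100               99.9             99.6              100
```

`tidy(cv)` gives the per-run confusion counts, and `autoplot(cv)` plots
the per-run metrics. Metric arithmetic is exposed directly:

```r
confusion_metrics(c(TNS = 91, FPS = 6, FNS = 3, TPS = 25))[, 1:3]
#> # A tibble: 1 x 3
#>   accuracy sensitivity specificity
#> 1     92.8        89.3        93.8
```

A thin command-line front-end with `simulate | segment | features |
crossval | run` subcommands lives at `inst/cli/calculoscope.R`.

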