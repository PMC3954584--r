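---
title: "Whole-image triage from DCT band moments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-image triage from DCT band moments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dcttriage classifies whole grayscale breast images as *normal* or
*suspicious* so that a screening queue can be split into a low-priority pool
(confidently normal) and a high-priority pool enriched in disease. The
design goal is asymmetric: a false negative (a missed cancer) is far more
costly than a false positive, so every tunable choice in the package —
feature search, vote weighting, threshold selection — puts sensitivity
first and treats specificity as the quantity to be maximized afterwards.

# The model

## Canonical frame and artifact removal

Every image is mapped to a canonical frame before any feature is computed:
a 1024×1024 raster at 200 µm per pixel (`standardize_geometry()`, bilinear
interpolation). Bright non-breast objects — chiefly the rectangular
orientation tags burned into screening films — are removed first by
`artifact_mask()`: the image is thresholded at its mean (or half-mean)
intensity and only the largest 8-connected bright component, the breast,
is kept. The Hadamard (elementwise) product of mask and image
(`apply_mask()`) zeroes everything else.

Choices the data do not force, pinned as defaults and exposed as arguments:

* **Threshold rule.** `half_mean` by default; `mean` available. The
  threshold is strict (`pixels > t`), which makes a constant image a clean
  "no foreground" error rather than an arbitrary mask.
* **Connectivity.** 8-connected components, the blob-mask convention.
* **Order of operations.** Masking happens in the raw frame (where the tag
  actually lives) and the masked image is then rescaled; `mask_first =
  FALSE` flips the order.
* **Anchoring.** When padding or cropping to the square, the lateral edge
  with the greater foreground mass keeps its column (the chest-wall side of
  a mammogram); rows are centred.

## DCT band-moment features

The transform is the separable type-II discrete cosine transform with
orthonormal scaling (`dct2d()`), so Parseval's identity holds and is tested:
the coefficient energy equals the pixel energy. The N×N coefficient grid
(N = 2^B) is partitioned by `dct_band_partition()` into B L-shaped dyadic
bands: band *i* holds the coefficients whose 0-based index maximum lies in
[2^(i−1), 2^i). Each band is the L between nested origin-anchored squares
whose sides double, i.e. one octave of spatial frequency; band *i* contains
3·4^(i−1) coefficients and the bands plus the DC position tile the grid
exactly. At N = 1024 there are ten bands, and `extract_features()` returns
**41 features**: the DC coefficient plus mean, standard deviation, skewness
and kurtosis of each band.

Moment conventions (these matter because band 1 has only three values):

* population (divisor-*n*) central moments;
* Pearson kurtosis (normal ⇒ 3), not excess;
* a zero-variance band returns skew = kurt = 0, so constant images give
  finite features;
* moments are taken on signed coefficients; `abs_coeffs = TRUE` switches to
  magnitudes.

Because only the (0,0) coefficient sees a constant offset, adding a
constant to an image moves the DC feature by N·c and leaves the other 40
features unchanged — a tested invariant.

## K-nearest-neighbour classifier

`knn_neighbors()` stores, for every image, its 25 nearest other images
(Euclidean distance on the selected features) together with their ordering
and fractional distance f = d/d_max, where d_max is the distance to the
25th stored neighbour — also when fewer neighbours are used for voting.
Classification (`knn_loocv()`) is leave-one-out: an image's own row never
appears among its neighbours. A suspicious neighbour votes +1, a normal
one −1, and the image is called suspicious when the vote total is ≥ 0, so
ties go to the safe side. The four variants:

| variant | weight per vote |
|---|---|
| unweighted | 1 |
| distance-weighted | 1 − f |
| prior-weighted | 1 / prior(neighbour's class) |
| both | (1 − f) / prior |

The functional forms of the two weightings are design choices: `1 − f`
uses exactly the stored fractional distance and down-weights the farthest
stored neighbour to zero; `1/prior` up-weights the minority (suspicious)
class, which is what drives the sensitivity-first behaviour of the
prior-weighted variant. Class priors are the label frequencies of the full
table. Features are z-standardized over the full set by default
(`standardize = FALSE` to disable): DC and a band kurtosis differ by orders
of magnitude, and unstandardized Euclidean distance would be a DC-only
metric. Distance ties break by ascending row index; if all 25 stored
distances are zero, f := 0 and distance weights fall back to 1.

`knn_search()` evaluates **every** feature subset of size 1, 2 or 3 — 41,
820 and 10660 candidates on the 41-feature table — at each neighbour count
k, and reports per k the subset with the highest sensitivity, ties broken
by higher specificity and then lexicographic position. The search
pre-computes per-feature squared-difference matrices so each subset costs
one matrix sum rather than a fresh distance pass.

## Histogram naive Bayes

`nb_histogram()` builds, per feature, one histogram per class over
*identical* equal-width bins spanning the feature's global [min, max]; the
last bin's right edge is inclusive and a zero-range feature degenerates to
a single bin. The class likelihood of a value is its bin count over the
class total — literal counts, no smoothing by default (`laplace = TRUE`
adds one). For subsets of 2–3 features the joint likelihood is the product
of per-feature likelihoods (naive independence), and the suspicious
posterior is normalized: pp = L_s·π_s / (L_s·π_s + L_n·π_n).

Leave-one-out (`nb_loocv()`) keeps the bin edges fixed — they are part of
the classifier's definition, and recomputing them per fold would silently
change bin membership — and removes only the held-out image's counts and
its contribution to the class totals and priors. Two degenerate cases have
pinned conventions: when both unnormalized posteriors are zero (the
held-out image emptied its own bin) the posterior falls back to the
suspicious prior among the remaining images; values outside the global bin
range are clamped into the end bins with a warning.

Thresholds are chosen on the training posteriors (`nb_threshold()`): for
100% sensitivity, the *lowest* suspicious posterior; allowing m false
negatives moves to the (m+1)-th smallest. The call rule is inclusive
(pp ≥ threshold) — required for the 100%-sensitivity rule to actually
achieve sensitivity 1.0, a tested invariant. Bin counts from 2 to 25 are
accepted; the default is 12. (The source descriptions of the usable bin
range disagree between 20 and 25; the package accepts the superset and
pins nothing beyond the default.)

## Metrics and ROC comparison

`confusion_metrics()` reports sensitivity, specificity, PPV, NPV,
prevalence and **prevalence gain** — PPV over baseline prevalence, the
enrichment of disease in the suspicious-called pool, which is the
operationally meaningful number for a triage step. Counts may be
non-integer so that `expected_report()` can reconstruct derived columns
from *printed* (rounded) rates and dataset compositions; undefined ratios
are `NA`, never 0. `roc_auc()` is the midrank Mann–Whitney statistic;
`roc_sweep()` sweeps every distinct score plus a point above the maximum
under the same inclusive rule the classifiers use. `delong_test()`
implements the placement-value estimate of var(AUC_a − AUC_b) with midrank
tie handling, paired or unpaired (independent variance sum), and refers
z to the standard normal, two-sided; no multiplicity correction is
applied. The degenerate identical-curve case returns z = 0, p = 1.

# The phantom generator

Real mammogram collections cannot ship with the package, so
`phantom_spec()`/`phantom_set()` generate the study conditions: a bright
half-elliptical tissue region touching the left edge; inside it, correlated
texture with isotropic power spectrum ∝ 1/f^β synthesized in Fourier space
and mapped to 20–90% of the dynamic range; for suspicious images,
Gaussian lesion blobs (amplitude in units of the texture SD); optionally a
bright orientation-tag rectangle near the right edge, outside the tissue.
Everything is deterministic given the seed, with per-image seeds derived
from the master seed by fixed increments.

The class contrast is controlled *only* by the spectral exponent difference
and the lesion parameters. Defaults: β_normal = 3 versus
β_suspicious = 2 — a one-unit slope difference, i.e. suspicious texture
carries relatively more high-frequency power, exactly the statistic the
band moments measure — and 3 lesions of amplitude 5 texture SDs. Power-law
texture was chosen over tissue models precisely because it gives analytic
control over the quantity the features estimate.

What the phantom does **not** emulate: anatomy (pectoral muscle, skin
line, ducts), scanner physics (dose, quantum noise, scatter), compression
artifacts, and the heterogeneity of real lesion morphology. Passing the
phantom-recovery checks therefore demonstrates that the pipeline's
machinery is correct and that spectral class differences of the assumed
kind are recoverable — it does not certify performance on clinical data.

# Problem sizes, calibration and numerical notes

The test suite and the acceptance script run at desk scale, chosen as the
package's own study conditions:

* **Toy frame.** Side 128 (7 bands, 29 features) for phantom work; the
  canonical 1024-pixel frame is exercised where the 41-feature contract
  itself is under test.
* **Recovery condition.** 100 normals + 100 suspicious at Δβ = 1 with
  default lesions. Both classifiers must reach sensitivity 1.0 with
  specificity ≥ 0.8: the prior-weighted KNN over the best 3-feature subset,
  and naive Bayes at the 100%-sensitivity threshold over its best single
  feature.
* **Null calibration.** Same 200-image scale with β_normal =
  β_suspicious = 3 and no lesions; both classifiers' score AUC must sit at
  0.5 within Monte-Carlo error (±0.15). Two subtleties are deliberate
  here. First, the feature subset is *pre-specified* (`dc`, `b1_sd`,
  `b2_sd`), not searched: maximizing sensitivity over 3654 subsets would
  inflate the null AUC by selection. Second, leave-one-out classifiers are
  slightly pessimistic under the null — holding an image out makes its own
  class rarer in the training data — a bias of order 1/n that is visible at
  50 images per class (score AUCs of 0.40–0.47) and negligible at 100 per
  class. The null condition therefore uses the same 200-image size as the
  recovery condition.

Other numerical conventions, gathered in one place: DCT via the even–odd
FFT reordering identity (O(N² log N)), verified against the O(N⁴)
double-sum definition; bilinear interpolation for rescaling; PGM written
big-endian for 16-bit rasters; PNG bit depth read from the IHDR header
because the decoder normalizes intensities; the DeLong p-value is
normal-based (a reference implementation refers the unpaired statistic to
a t distribution, so unpaired p-values differ slightly by construction).

# Limitations

* Headline sensitivities/specificities on the MIAS and DDSM databases are
  not reproduced here: those require the original downloads and curation
  steps that are not fully specified; the package instead verifies the
  internally checkable derived quantities (PPV, prevalence gain, expected
  negatives removed) from the printed rates and compositions.
* The feature subset searches evaluate and select on the same
  leave-one-out estimates; with 10660 candidates, the reported best
  specificity is an optimistic estimate of generalization — inherent to
  the training-set threshold design, and the reason the null calibration
  uses a fixed subset.
* Binary labels only; benign-versus-malignant separation within the
  suspicious class is out of scope, as are DDSM LJPEG decoding and
  pectoral-muscle removal.
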