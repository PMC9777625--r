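---
title: "Carotid wall texture analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carotid wall texture analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotexture)
```

## The problem

Primary aldosteronism (PA) chronically exposes the vasculature to excess
aldosterone, driving collagen accumulation and fibrosis of the arterial
wall beyond what blood-pressure load alone produces in essential
hypertension (EH). The hypothesis behind this package is that such
microstructural remodelling is visible — not as a thickness change but as
a *texture* change — in the speckle pattern of the intima–media complex
on ordinary longitudinal B-mode ultrasound of the common carotid artery.
The pipeline quantifies that texture inside a manually drawn far-wall
region of interest (ROI) and asks two questions: do individual texture
features differ between groups, and can a classifier using all of them
separate patients?

Because clinical carotid image sets are private, the package treats the
*method* as the reproducible artifact: a synthetic cohort generator with
the same structure as a real study (images, ROI polygons, clinical
covariates, group labels) feeds every downstream stage, and the test
suite establishes correctness of the feature mathematics and calibration
of the statistics on that synthetic ground truth. Passing these tests
shows the machinery is right; it does *not* show that real PA and EH
walls differ — that evidence can only come from real data.

## Feature model

All features are computed over the ROI pixel set Ω on a preprocessed
image (percentile-normalized, caliper dots inpainted).

**First order.** μ and σ are the mean and *population* standard deviation
(divisor |Ω|) of intensities in Ω.

**Haralick / GLCM block (140 features).** Intensities in Ω are quantized
into N~g~ = 16 uniform bins spanning Ω's own min–max range. For each
displacement d ∈ {1,…,5} px and direction θ ∈ {0°, 45°, 90°, 135°}
(0° = up, 90° = right), the co-occurrence matrix counts ordered pairs
(i, i + d·u~θ~) with both pixels in Ω, normalized to sum to one. Seven
measures summarize each matrix: inverse difference moment
Σ~a≠b~ P/(a−b)², correlation, contrast Σ(a−b)²P, maximum, energy ΣP²,
dissimilarity Σ|a−b|P, and entropy −ΣP log P (natural log). Choices worth
stating explicitly:

* *Directed vs symmetric counting.* Ordered (directed) pairs are the
  default; symmetric counting is a flag. Both are standard; measures that
  depend only on |a−b| are identical either way.
* *Quantization range.* Binning over Ω's own range makes every GLCM
  feature exactly invariant to affine intensity shifts of the image —
  desirable when scanner gain varies; a fixed-range mode is available.
* *Entropy sign.* −ΣP log P ≥ 0 is reported (the quantity is defined up
  to sign; a monotone relabelling is irrelevant to rank tests and tree
  classifiers).
* *Thin-ROI degeneracy.* A 5-px-thick ROI admits no vertical pair at
  d = 5. Such configurations are imputed from the largest displacement
  available for the same direction, with a warning — preferable to NA
  propagation, since thin walls are a designed feature of the data, and
  to dropping columns, which would break the fixed 152-name layout.
* *Zero-variance correlation.* On a constant ROI the GLCM collapses to a
  single cell and correlation is undefined; it is reported as 0 and
  flagged.

**Wavelet block (10 features).** An undecimated (à-trous) Haar frame: at
level i the two-tap filters h = (½, ½) and g = (−½, ½), with taps spaced
2^i^ apart, are applied separably to produce one low-pass and three
directional high-pass bands per level, all at full image size. Features
are the mean squared band values over Ω: W~i,j~ for i, j ∈ {1..3} and W₀
for the level-3 low-pass. Since |H(ω)|² + |G(ω)|² = 1 for this pair, the
decomposition conserves energy exactly under a periodic boundary — the
basis of the suite's conservation test (W₀ + ΣW~i,j~ equals the image's
mean square to 1e−10 when Ω is the whole image). The default boundary is
half-sample mirror padding, which avoids wrap-around artifacts on real
images; energies are invariant to the filters' phase and sign, so the
boundary rule is the only place this choice matters.

**Canonical layout.** Every feature vector has exactly 152 named entries:
`mu`, `sigma`, the Haralick block sorted by (d, θ, a), then `W0` and the
wavelet block sorted by (i, j).

## ROI handling

Coordinates are 0-based (row, col) with pixel centers at integer
positions; polygons are implicitly closed. Rasterization uses the
even-odd crossing rule with pixel centers on a polygon edge counted
*inside* (boundary-inclusive): an axis-aligned rectangle with corners
(0,0)–(4,9) therefore covers exactly 5 × 10 = 50 pixels. The
implementation is a vectorized crossing count; the suite proves it
equivalent to an exhaustive per-pixel oracle (which casts its ray in a
different direction) on random concave polygons.

Cropping to the ROI bounding box plus a margin is supported; a margin of
56 px is far beyond the wavelet filter reach (2 + 4 + 8 = 14 px), so all
152 features are invariant to cropping — a property the suite checks.

## Preprocessing

Intensity normalization maps the 1st/99th intensity percentiles to 0/1
with clipping; percentile (rather than min–max) anchoring keeps a handful
of saturated pixels from compressing the histogram. Whether the original
study normalized globally or per image is not recoverable; per-image
normalization is the package's choice and is what the ROI-range
quantization assumes anyway.

Caliper-dot removal thresholds at 98 % of the intensity range, keeps
connected components of at most 50 px (covering dots up to 4 px radius
while never matching anatomical bands), and fills them by harmonic
inpainting — masked pixels iterated to the mean of their 4-neighbors to a
1e−6 tolerance. The operation is idempotent and leaves images without
saturated dots untouched.

## The synthetic cohort generator

The generator emulates the study design the analysis assumes: three
groups (33 PA / 52 EH / 33 controls by default), 2–4 longitudinal images
per patient (two sides × two insonation angles), one thin far-wall ROI
strip per image, and a clinical table.

**Images.** A layered far-wall profile (tissue, dark lumen, the
intima–media strip at the group's mean level, a bright adventitia band)
is multiplied by a correlated log-normal speckle field: white Gaussian
noise on the log scale, smoothed by an isotropic Gaussian of the group's
correlation length and re-standardized, with the log-SD chosen so the
field's SD/mean equals the configured speckle contrast. This is the
simplest stationary model with independently controllable first- and
second-order statistics; it is *not* a physical ultrasound simulation (no
point-spread function, no attenuation, no view-angle geometry), so
passing tests say nothing about scanner physics.

**Group separation.** Nothing quantitative is known about the real
texture differences, so planted effect sizes are a design choice aimed at
testability: hypertensives vs controls differ strongly (mean level
140–143 vs 120, speckle contrast ≈ 0.46 vs 0.30, correlation length
≈ 1.3 px vs 2.5 px), while PA vs EH differ only marginally. Each
patient's parameters are additionally jittered log-normally (SD 0.05 on
mean level, 0.10 on contrast and correlation length): this
between-patient heterogeneity is what makes the PA-vs-EH contrast
genuinely weak — group deltas below the patient SD — while leaving the
hypertensive-vs-control deltas several patient SDs wide. ROI thickness is
drawn from 8–14 px (never below the 6-px minimum seen in practice) and
ROI length is at least 10 mm at the configured scale.

**Clinical covariates** are drawn independently per covariate from the
group marginals: Gaussians (truncated at 0) for the mean ± SD variables,
Bernoulli for sex and smoking, and log-normals for the skewed humoral
markers (aldosterone, renin, ARR), matched by meanlog = log median and
sdlog = IQR/1.349 on the log scale. Controls get NA for the aldosterone
panel, which is why that feature subset is structurally undefined for the
hypertensive-vs-control task. Independence across covariates is a
deliberate simplification — only marginals are available — so any
analysis of covariate *interactions* on synthetic data is meaningless.

## Screening and classification

Screening runs Welch's unequal-variance t-test, the two-sample
Kolmogorov–Smirnov test and the Mann–Whitney U test, two-sided, per
feature, at α = 0.05, on per-image values by default (a per-patient-mean
mode is a flag). A feature counts as significant only if *all three*
p-values clear α. Raw p-values are reported; a Benjamini–Hochberg column
is emitted as supplementary output but never gates significance. Exact
small-sample distributions are used where R's tests provide them. Note
that per-image screening treats images of one patient as independent —
the same pseudo-replication a per-image analysis of real data would
incur; the per-patient mode exists for exactly that reason.

Classification is leave-one-*patient*-out: all images of the held-out
patient are excluded from training, training rows are weighted
1/(images of that patient) so each patient contributes unit weight, and
per-image probabilities are averaged into the patient's score
(threshold 0.5, exact ties to the negative class; a hard-vote mode is a
flag). The booster is XGBoost with fixed, untuned settings (50 rounds,
depth 3, learning rate 0.3, no subsampling, single thread) recorded in
the result object and its hash. One non-default matters:
`min_child_weight = 0`, because unit-patient weighting scales the hessian
sums below xgboost's default split threshold of 1, which would silently
reduce the model to the base rate in small cohorts. ROC curves sweep the
patient scores with ties crossing simultaneously; AUC is trapezoidal.

## Calibration and problem sizes in the test suite

The suite's calibration experiment draws 200 independent null cohorts
(identical texture parameters in all groups; 30 hypertensive vs 30
control patients, one 64 × 128 image each — sizes chosen to make 200
replicates affordable while keeping the two-sample tests in their
exact-distribution regime). Welch and Mann–Whitney p-values are tested
for uniformity by a KS goodness-of-fit at α = 0.01; the two-sample KS
statistic itself is supported on ~30 values at this sample size, so its
(valid but discrete, conservative) p-values are instead checked for
sub-uniformity at the operating significance levels. The count of
features significant by all three tests is long-tailed under the null —
the 152 features are strongly correlated, so an unlucky cohort lights up
many at once — hence the suite bounds its mean (by the single-test
expectation 0.05 × 152, valid under dependence), its median (by the
binomial 99th percentile), and the frequency of exceedances (Markov).

Signal recovery uses a 10/10/10-patient planted cohort (two 96 × 160
images per patient): hypertensive-vs-control texture accuracy must reach
0.9, and must not be below the PA-vs-EH accuracy. The chance-level check
permutes patient labels on a *balanced* 5/5/10 cohort, because the
0.4–0.6 chance band is only meaningful when the two classes are equally
sized (on a 20-vs-10 design a base-rate predictor already scores 0.67).

## Known limitations

* The speckle model is statistical, not physical; absolute feature
  values have no clinical meaning.
* Planted effect sizes are arbitrary by necessity; only *structural*
  claims (calibration under the null, recovery of a planted effect,
  ordering of strong vs weak contrasts) transfer to real data.
* Clinical covariates are independent across columns and carry no
  covariate–texture correlation.
* No covariate adjustment of group comparisons is implemented, and only
  PNG input is supported.
* ROI placement is taken as given; automatic wall localization is out of
  scope.
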