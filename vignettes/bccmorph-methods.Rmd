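---
title: "Comparing nodular and micronodular BCC morphology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing nodular and micronodular BCC morphology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bccmorph)
```

## The problem

Basal cell carcinoma (BCC) presents as basaloid tumor islands in a
fibromyxoid stroma. The low-risk **nodular (N)** subtype grows as one or a
few large islands; the high-risk **micronodular (MN)** subtype as many
nodules smaller than 0.15 mm in diameter. Around each island four
morphological components can be annotated per pixel: the tumor core (**T**),
the peripherally palisaded rim where the island touches the stroma
(**TT**), the peritumoral retraction cleft (**PC**) and the surrounding
stroma (**S**).

`bccmorph` implements a two-pronged comparison of the subtypes:

1. **Morphometry.** Per component image, a horizontal gray-level
   co-occurrence matrix (GLCM) is built at offset (0, 1) with 9
   quantization levels over the fixed range [0, 255]; the background
   row/column is trimmed, leaving an 8x8 probability matrix from which the
   14 Haralick texture features are computed, together with the central
   histogram moments $m_k = \frac{1}{n}\sum_i (x_i - m)^k$, $k = 2,3,4$.
   Per component and feature, a two-sided pooled-variance t-test compares
   subtypes; the count of significantly different Haralick features (0-14)
   per component is the headline descriptive statistic.
2. **Segmentation evaluation.** Pixels carry one of eight classes
   (component x subtype). A pixel classifier is evaluated under a
   repeated 70/15/15 resampling protocol; per class, one-vs-rest
   accuracy, IoU, precision, recall and F1 are computed from the pooled
   test-set confusion matrix, aggregated as mean/SD over runs with
   unweighted macro averages, the best run is selected by macro IoU, and
   the best model's whole-dataset row-normalized confusion matrix is the
   second headline result.

The clinical images behind the original study are not public, so the
package ships a seeded synthetic generator that reproduces the
*statistical structure* the analysis assumes, letting every stage run and
be tested end to end.

## The synthetic world

`synthetic_spec()` describes a dataset; `generate_dataset()` is a pure
function of it (bit-identical rasters per seed). Defaults mirror the
clinical acquisition: 1920 x 1017 px at 0.038 um^2/px, 216 N + 201 MN
images. The `desk` preset (512 x 384 at 4x coarser sampling) is the
working scale for tests; `tiny` exists for unit-test speed.

Geometry: islands are harmonic-deformed disks. N images hold 1-3 islands
with diameter strictly above 0.15 mm, MN images 10-16 islands strictly
below it (the bound is enforced by construction, including the shape
harmonics). TT is an inner rim whose nominal width varies by +-50% per
nodule, PC a fixed-width outer annulus carved out of stroma only, S the
remainder. Per-nodule clefts appear with
probability 0.95 — the prevalence of clefts in MN images is reported only
qualitatively in the literature (191/201 images in the motivating data),
so one shared default was chosen and not revisited; images without any
cleft are flagged rather than discarded.

Texture: each component gets a stationary Gaussian field with anisotropic
correlation lengths (an oriented low-pass filter in the frequency domain),
scaled and shifted to a gray level, plus fine pixel noise. One white-noise
spectrum is shared by the four filters of an image purely to save FFTs;
the fields are correlated with each other but each is visible only inside
its own component. Per-image parameter jitter emulates slide-to-slide
variability.

Subtype divergence is a per-component scalar $d \in [0,1]$ scaling a fixed
offset vector applied $\pm d/2$ around the shared base parameters, so
$d = 0$ gives *exactly* identical parameter distributions:

* **T** ($d = 0.5$): N cores have elongated grain with one shared
  orientation per image, MN cores finer isotropic grain at slightly
  different brightness/amplitude — the elongated-vs-round cell contrast.
* **TT** ($d = 0$): identical generator parameters across subtypes. Its
  per-image jitter is the largest of the four components; this encodes
  rim heterogeneity and also dominates the small estimator bias that the
  subtype-specific rim geometry (long straight N rims vs short curved MN
  rims) otherwise induces in nonlinear GLCM statistics.
* **PC** ($d = 0.95$): strongly divergent — N clefts bright and nearly
  noise-free (mucin-like), MN clefts darker and grainy. The amplitude
  offset is large enough that the N-side draw clamps at the generator's
  noise floor; this is intentional, as it makes the difference-statistics
  (contrast, homogeneity, difference variance/entropy) respond too.
* **S** ($d = 0.18$): weakly divergent — an amplitude-only offset on the
  shared fibrous noise, with the stroma gray level centered mid-bin of
  the quantizer so that the mean level (sum average) genuinely stays at
  its null and stroma can never tie the cleft's count.

Two **equal-luma chroma effects** complete the world. Stroma hue rotates
between subtypes (`stroma_chroma_shift`) — fibrous pink vs faintly
hyalinized violet — and the tumor-core hue tilts with its divergence
(the N core's richer eosinophilic intercellular matrix reads pinker, the
MN core bluer), while the BT.601 luma is held constant in both cases.
The grayscale morphometry is blind to these shifts by construction; an
RGB classifier is not. This reproduces a striking dissociation in the
motivating results — stroma is morphometrically the most similar
component yet almost never cross-subtype-confused by the segmenter —
and keeps cross-subtype confusion of the core below its confusion with
the adjacent rim. The palisade rim shares the core's base tint and
near-core gray statistics (same basaloid cells, aligned), and rim widths
vary nodule to nodule, so windowed descriptors genuinely blend at the
T/TT boundary; rim classes are the hardest for the classifier, exactly
as in the published evaluation.

The divergence offsets were calibrated once so that the stated recovery
property holds (the per-component significance counts rank PC strictly
highest and TT strictly lowest in at least 90% of desk-scale replicate
datasets with 40 images per subtype) and then frozen; they are part of
the stated world, not tuning knobs.

What a green test does *not* establish: the generator is not
photorealistic H&E — no stain deconvolution, no nuclei, no scanner
artifacts — so absolute feature values and absolute segmentation scores
carry no clinical meaning. Only the *relative* structure (which component
differs most/least; which classes confuse) is modeled.

## Numerical choices

* **Grayscale.** ITU-R BT.601 luma, rounded half-up. The source
  convention is unstated; any fixed convention preserves the
  between-group comparisons that are the object of study.
* **Quantization.** `floor(g * 9 / 256) + 1` over the fixed range
  [0, 255] (not per-image min/max), so background always lands in bin 1
  and binning is image-independent.
* **Trimming.** Dropping the first GLCM row/column purges every pair that
  touches background, and with it genuinely dark tissue (gray 1-28).
  This conflation is inherent to the published procedure and documented
  rather than "fixed". The generator therefore clamps tissue channels to
  a minimum of 1; imported real data are used as-is.
* **Haralick conventions.** Natural logs, $0\log 0 = 0$; sum variance is
  centered on the sum average (the widely accepted reading of the 1973
  definitions; the printed sum-entropy-centered form is treated as an
  erratum); variance ($f_4$) uses the x-marginal mean; the information
  measures use $\log(p + 10^{-12})$ inside the joint/marginal product
  entropies; correlation and IMC-II return a flagged 0 when a marginal SD
  or entropy denominator vanishes; the maximal correlation coefficient
  excludes zero-marginal rows/columns and clips tiny negative eigenvalues.
* **Moments.** Implemented literally with denominator $n$ and no
  standardization, labeled as the Eq.-1 convention (`m2_variance`,
  `m3_skewness`, `m4_kurtosis`). The "first moment" of the source text is
  the mean, which is identically 0 as a central moment; it is reported
  separately by `histogram_moments()` and not tested as a feature.
* **t-tests.** Two-sided, pooled variance, alpha = 0.05, no multiplicity
  correction — the era-conventional defaults, all config-exposed
  (`var_equal`, `alpha`). Zero pooled variance resolves to p = 1 (equal
  means) or a flagged p = 0 (unequal). Empty components drop pairwise.
* **Splits.** floor(0.70 n) / floor(0.15 n) / remainder, e.g.
  417 -> 291/62/64.
* **Best run.** The source never states its criterion; macro test IoU is
  used (field standard), ties to the lower index, selectable to macro
  accuracy or F1.
* **Per-class "accuracy".** The published per-class accuracy column
  equals the normalized-confusion diagonal (recall), which is
  inconsistent with one-vs-rest accuracy; both are reported
  (`accuracy` and `recall`, the latter doubling as the
  diagonal-convention accuracy in the table analogs).
* **Tiled inference.** Overlapping pixels keep the prediction of the tile
  whose center is nearest; edge tiles are shifted inward so every pixel
  is covered.

## The baseline classifier

Training the original DeepLab v3+/ResNet-18 transfer-learning network is
out of scope (GPU-scale, weights-dependent). The evaluation calculus is
instead exercised through a pluggable contract: anything that maps an RGB
raster to an 8-class label raster. The shipped baseline is LDA on seven
local descriptors per pixel (window means of R, G, B and gray, windowed
gray SD, window means of |dx| and |dy| gray increments). It is
deterministic given its seed, desk-scale fast, and rich enough to
reproduce the qualitative confusion structure: rim classes confuse with
their neighboring core/cleft (windows straddle the thin TT band), while
stroma is almost never confused across subtypes thanks to the chroma
channel. Externally produced label maps can be evaluated through
`import_predictions()`.

The validation cell of each split is reserved by the protocol contract
but unused by the LDA baseline (it has no early stopping); a plugged-in
learner may use it.

## Protocol scales and runtime

The published protocol is 100 runs on 417 images; the package defaults to
10 runs at desk scale, with everything configurable up to full scale. The
test suite runs the acceptance criteria at their stated scales (20
replicate datasets of 40 images/side for the recovery property; 10,000
replicates for t-test calibration) and unit tests at the `tiny` preset.

## Known limitations

* The printed per-class values of the published tables depend on the
  undeposited clinical images and are **not** reproduction targets; only
  in-table arithmetic (macro averages, diagonal queries) and the
  qualitative recovery structure are.
* The published F1 column is mutually inconsistent with the IoU column
  under the one-vs-rest identity $F1 = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$
  (e.g. IoU 0.92 with F1 0.69); the package computes the identity-consistent
  values and does not emulate whatever boundary-based or
  differently-averaged F1 produced the printed column.
* Haralick features are single-offset horizontal only, as specified —
  no rotation averaging — so they are orientation-sensitive by design.
* The geometric coupling between subtype and region shape means
  zero-divergence worlds are identical only at the parameter level;
  nonlinear estimators retain a small geometry-linked bias, kept below
  the per-image jitter by design and checked by a null-rate test.
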