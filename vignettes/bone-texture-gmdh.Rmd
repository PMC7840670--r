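---
title: "Texture descriptors and a GMDH-type network for early-osteoarthritis bone patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture descriptors and a GMDH-type network for early-osteoarthritis bone patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonetex)
```

## The problem

Early osteoarthritis changes the micro-architecture of trabecular bone
before the joint shows the gross radiographic signs that clinical scoring
relies on. Those changes are visible — faintly — as texture in small
regions of interest (ROIs) cut from the tibial compartments of
high-resolution knee radiographs (14-bit detectors, patches of roughly
150×150 pixels). The statistical task is hard for a specific reason: at
the early stage the number of clinically verified cases is tiny. `bonetex`
implements a complete pipeline for this setting — texture descriptors, a
distribution-based baseline classifier, a self-organizing polynomial
network, and a leave-one-out evaluation harness — together with a
synthetic texture generator so that every stage is testable without access
to clinical data.

## The pixel-brightness baseline

Case patches are systematically brighter-or-darker than Controls (denser
bone attenuates more), so the cheapest possible classifier ignores spatial
arrangement entirely and compares pixel-brightness *distributions*. For
each group we pool the pixels of all its images into an empirical
distribution ($C_0$ for Control, $C_1$ for Case). A test image with pixel
sample $i_x$ gets two two-sample Kolmogorov–Smirnov distances
$D_0 = \sup_t |F_{i_x}(t) - F_{C_0}(t)|$ and $D_1$ likewise against $C_1$,
and is assigned to the group with the smaller distance. The associated
p-values $p_0, p_1$ (asymptotic Kolmogorov distribution at effective size
$n_1 n_2/(n_1+n_2)$ — pooled counts here are $10^4$–$10^5$, far past the
asymptotic regime) drive a rejection rule: if both fall below
$\alpha = 0.05$, the image is recognized as belonging to *neither* group
at that level. Rejected images still receive their minimum-distance label
and accuracy is reported over all images, so the rejection rate is an
independent, second figure of merit.

Two choices here were genuinely open and are fixed as follows. First,
`evaluate_ks_baseline()` excludes the test image's own pixels from its
group's pool (a leave-one-out pooling); including them biases $D$ for the
true group toward zero and inflates the baseline. Second, ties
$D_0 = D_1$ go to Control and are logged — they occur with measure zero on
real data but must be deterministic.

A consequence worth knowing: with $\sim 2 \times 10^4$ pixels per image,
the asymptotic KS test is so powerful that almost any real image differs
detectably from *both* pools, so rejection rates near 90–100% are the
expected behavior, not a bug. The rule's discriminative part (the
minimum-distance label) is unaffected.

## Zernike moments

The spatial descriptors come from projecting the patch onto the complex
Zernike basis on the unit disk inscribed in the patch:

$$A_{nm} = \frac{n+1}{\pi} \sum_{x,y} f(x,y)\, V^*_{nm}(\rho, \theta),
\qquad V_{nm} = R_{nm}(\rho)\, e^{-jm\theta},$$

with the radial polynomials $R_{nm}$ the usual alternating factorial sums.
$|A_{nm}|$ is invariant to rotation of the patch, which matters because
ROI orientation is an acquisition artifact, not biology. The feature
vector is the set of real parts for all $(n, m)$ with $0 \le m \le n$,
$n - m$ even, $n \le 16$ — 81 features. Conventions the formulas leave
open, fixed here:

* **Disk mapping.** Center $((H-1)/2, (W-1)/2)$, radius $\min(H,W)/2$;
  pixels with $\rho > 1$ contribute nothing. $\theta$ is measured from the
  +x (column) axis, counter-clockwise, with the y-axis flipped so the
  frame is right-handed.
* **Quadrature.** By default the basis is averaged over a 2×2 subpixel
  grid per pixel (`oversample = 2`). Plain pixel-center sampling leaves
  the discrete basis non-orthogonal by up to ~2% at order 16 on a 150×150
  disk; the 2×2 average brings that below 0.5% while leaving quarter-turn
  rotation invariance *exact*, because the subgrid is symmetric under 90°
  turns. `oversample = 1` restores point sampling.
* **Radial coefficients** are computed as exact integer binomials
  ($\binom{n-k}{k}\binom{n-2k}{(n-m)/2-k}$), which are exactly
  representable in doubles up to order 16; log-space factorials would
  reintroduce ~1e-10 cancellation error in the $R_{nm}(1)=1$ identity.
* **Intensity handling.** Raw gray levels enter the projection; patches
  share a fixed size and detector, so no normalization is applied by
  default. `normalize = TRUE` divides by the total gray mass $m_{00}$
  (the scale-robust variant); it rescales the whole vector by a constant.
* **Negative repetitions** are not computed: for a real image
  $A_{n,-m} = A_{nm}^*$, so the $m \ge 0$ set (81 features at order 16)
  carries everything.

## Haralick features

The second descriptor family reduces the patch to a gray-level
co-occurrence matrix (GLCM): quantize to `levels` gray bins (linear
binning of the patch's own range; default 64), count pixel pairs at
`distance` 1 along the four standard directions (0°, 45°, 90°, 135°)
accumulated into one matrix, symmetrize by adding the transpose, and
normalize to sum 1. From it the 14 classical statistics are computed:
energy, contrast, correlation, variance, homogeneity, sum average, sum
variance, sum entropy, entropy, difference variance, difference entropy,
the two information measures of correlation, and the maximal correlation
coefficient (square root of the second-largest eigenvalue of the Q
matrix). Entropies use log base 2 with $0 \log 0 := 0$; sum variance is
centered on the sum average (the standard correction of the original
paper's typo); degenerate GLCMs (zero marginal variance) return 0 for the
correlation-type statistics with a warning rather than NaN. Quantization
parameters are configurable because the source study does not state them;
the defaults follow the classical reference. Arbitrary subsets of the 14
are supported (`haralick_vector(img, subset = ...)`) since reports in this
literature sometimes use only a few.

## The GMDH-type polynomial network

The classifier at the core of the package is a Group Method of Data
Handling network: a layered structure of tiny two-input neurons

$$y = w_0 + w_1 x_1 + w_2 x_2 + w_3 x_1 x_2,$$

grown inductively. Layer 1 fits all $K = m(m-1)/2$ feature pairs by least
squares — but only on a *fit subset* A of the training rows. Each
neuron's quality is its **regularisation error** $\Delta$: the Euclidean
norm of its residuals over the whole training data, which includes the
external rows the fit never saw — that unseen component is what makes
$\Delta$ an external criterion rather than a fit statistic
(`delta_on = "external"` restricts $\Delta$ to the held-out rows only,
the classic GMDH reading; with just 8 external rows that ranking of
thousands of candidates is dominated by selection noise, which is why the
whole-data error is the default). Neurons are sorted by
$\Delta$; the best up to $F$ (the *freedom of choice*, default $F = m$)
survive, skipping any whose external outputs correlate above
$\rho_{\max} = 0.999$ with an already-kept neuron (near-duplicates add no
diversity). The next layer fits all pairs of columns of
$Z = [\text{kept outputs} \mid \text{original features}]$
($m_r = F_r + m$ columns, $K_r = m_r(m_r-1)/2$ candidates), and so on.
Growth stops when fewer than $F_0 = 2$ neurons survive, when the
layer-best $\Delta$ stops improving by a defined value, or at the
`max_layers = 20` safety cap; the best layer seen is retained and its
minimum-$\Delta$ neuron becomes the output. Scores are read against a 0.5
threshold (targets are encoded 0/1 with symmetric classes).

Parameter choices that were genuinely open:

* **The A-split.** With 39 training rows per leave-one-out round the
  split is 31 fit / 8 external (`external_frac = 0.2`), drawn stratified
  by class from the round seed, re-drawn each round. The split mechanism
  is not specified in the source; stratification keeps both classes in
  the tiny external set.
* **The stopping threshold.** A strict "any improvement" rule never
  stops in practice: with ~13 000 candidates scored on 8 external
  samples, the layer-best $\Delta$ creeps down by selection noise alone
  at every layer. `min_improve = 0.01` (one percent relative) is the
  package's reading of "improves by a defined value"; `min_improve = 0`
  recovers the strict rule. Growth also stops outright when the external
  error reaches numerical zero (below 1e-10): a perfect fit cannot
  improve, only churn.
* **The fitted design.** The printed coefficient formula multiplies a
  non-square matrix inverse; it is read as the least-squares solution on
  the design $[1, x_1, x_2, x_1 x_2]$, solved via Cholesky-factored
  normal equations with a conditioning guard — candidates with collinear
  inputs are marked unfit and skipped. A config flag
  (`interaction = FALSE`) drops the product term for the three-column
  reading.
* **Standardization.** Feature columns are z-scored from the training
  rows by default. Raw Zernike features span seven orders of magnitude
  ($|A_{00}| \sim 10^7$ versus $|A_{16,16}| \sim 10^3$); products of raw
  features through 10+ layers would be numerically disastrous.
* **Feature importance** is the frequency of each input feature among
  the leaf inputs of the *output neuron's ancestry subgraph* — the part
  of the network that actually feeds the prediction — normalized to sum
  to 1. Counting over the whole grown network would credit neurons that
  were kept but never used downstream.

The per-layer candidate fitting (up to $\sim$13 000 four-coefficient
least-squares problems) is implemented in C++ (RcppArmadillo); selection,
growth and bookkeeping stay in R.

## Evaluation

`loocv()` runs $n$ rounds, refitting the model *and every data-dependent
preprocessing step* (standardization constants, the A-split, KS pooling)
on the $n-1$ retained samples each round. Round seeds derive
deterministically from the master seed, so results are exactly
reproducible. A canary test in the suite verifies the harness cannot leak
the held-out row. Per the small-sample setting, no confidence intervals
are attached to accuracies. Comparator classifiers (random forest with
200 trees / node size 3 / 80% attribute rate / 70% sample rate; RBF-SVM
with internally cross-validated kernel width; a 7-hidden-unit logistic
network with weight decay) are thin adapters over established libraries,
run under the identical protocol, and are context rather than core — the
ANN adapter uses weight decay where the original settings cite
Levenberg–Marquardt with early stopping, which the underlying library
does not expose.

## The synthetic generator

`generate_texture()` builds a Gaussian random field by shaping white
noise in the frequency domain with amplitude $\propto f^{-\beta/2}$,
rescales it affinely to a target mean and standard deviation, clips to
the 14-bit range and rounds. The class defaults are the pooled brightness
statistics of the studied strata (Case-Lateral mean 1735.5, σ 205.8;
Control-Lateral 1901.5, σ 251.1; the medial pair likewise), with spectral
exponents β = 3.0 (Case) vs 2.6 (Control). The β values are *synthetic*:
they create a spatial-correlation difference between classes on top of
the brightness difference, so that texture-sensitive descriptors have
something to detect; they are not estimates from bone data. Finite-size
tolerances at 150×150 are 2% on the mean and 5% on σ.

What the generator does *not* emulate: real trabecular architecture
(oriented struts, plate/rod structure), detector noise, exposure drift,
or inter-patient variability. Passing tests on these fixtures therefore
demonstrate that the pipeline's machinery is correct and that it can
separate classes whose distributions differ as the studied strata do —
they say nothing about clinical accuracy on real radiographs.

A consequence of the generator's faithfulness to the stratum statistics:
the two classes differ in pooled brightness by ~166 gray levels, which a
KS test over $2 \times 10^4$ pixels detects essentially always. The KS
baseline therefore sits at or near 100% on these fixtures — far above
its accuracy on real data, where brightness is confounded — and the
GMDH network, evaluated per-round on 39 training samples, typically
lands at 97–100%. On synthetic data the baseline is close to a ceiling,
not a strawman; the interesting comparisons are against fixtures where
brightness is matched and only β differs.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script evaluate the full study size:
five independent 20 + 20-image datasets at 150×150 (order-16 Zernike
features, 40-round LOOCV each), plus smaller 32×32 datasets where only
the harness mechanics are under test. Rotation-invariance checks under
interpolated (non-quarter-turn) rotation use a 300×300 band-limited
fixture: bilinear resampling attenuates structure at the pixel scale, and
on a 150-px disk that attenuation alone moves order-8 moments by a few
percent — on the smoother 300-px grid the transform's error is well below
the 2% band being verified, so the check measures the invariance of the
moments rather than the loss of the interpolator.

## Known limitations

* The deposited clinical ROIs are not shipped; accuracy figures on real
  data are out of reach of the test suite by construction.
* The 16-bit writer emits TIFF only (the PNG bindings available to R
  cannot encode 16-bit grayscale); 16-bit PNG *reading* is supported.
* The GMDH output is a raw polynomial score thresholded at 0.5, not a
  calibrated probability.
* Multi-class targets, pseudo-Zernike bases, orders above 16, and other
  GMDH variants (COMBI, higher-degree polynomials) are out of scope.
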