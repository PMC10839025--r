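---
title: "Image-based EEG classification with GASF, keypoints, and visual words"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based EEG classification with GASF, keypoints, and visual words}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`gasfeeg` classifies single-channel EEG as *focal* (epileptogenic) versus
*normal* by turning the problem into image recognition:

1. **Epoching.** Each signal (reference setting: 20 s at 512 Hz = 10,240
   samples) is cut into non-overlapping 256-sample epochs, 40 per signal.
2. **GASF encoding.** Each epoch becomes a Gramian Angular Summation Field:
   samples are min–max rescaled, mapped to angles $\phi_i =
   \arccos(\tilde{x}_i)$, and the matrix $G_{ij} = \cos(\phi_i + \phi_j)$ is
   quantized to an 8-bit 256×256 image. $G$ renders temporal correlation
   structure as visual texture, so rhythms at different frequencies produce
   visibly different images.
3. **Keypoint descriptors.** SIFT (128 real values per keypoint) or ORB
   (128-bit binary strings) descriptors are extracted from each image.
4. **Bag of visual words.** Descriptors pooled over the *training* images
   are clustered into a 100-word k-means vocabulary; each image becomes a
   100-bin histogram of nearest-word assignments.
5. **Feature selection.** Histogram bins are ranked by a chi-square score of
   per-class feature mass against class proportions; the top 10 are kept.
6. **Classification.** RBF-kernel SVM, random forest, and k-NN are trained
   on the selected features and evaluated on a stratified 90/10 held-out
   image split (4,000 images → 3,600 / 400 at the reference scale).

A Gaussian-noise robustness harness corrupts fresh signals at a grid of
signal-to-noise ratios (5, 10, 15, 20 dB) and re-evaluates the *frozen*
clean-trained pipeline.

## Quick start

```{r quick}
library(gasfeeg)

cfg <- pipeline_config(n_per_class = 10, seed = 42, methods = "sift")
fit <- run_pipeline(cfg, verbose = TRUE)
fit$summary

sweep <- run_noise_sweep(fit, classifier = "rf")
noise_sweep_table(sweep)
```

Every stage is exported, so the chain can also be driven piecewise:
`generate_dataset()` / `read_signal()` → `segment_epochs()` /
`signal_to_images()` → `extract_keypoints()` → `build_vocabulary()` /
`feature_table()` → `chi2_score()` / `select_top_k()` →
`train_classifier()` / `evaluate_model()`. A command-line wrapper with one
subcommand per stage ships in `inst/cli/gasfeeg.R`.

## Numerical and design choices

**Rescale range.** Two min–max conventions circulate for GASF. The package
default, `rescale_mode = "symmetric"`, maps each epoch to $[-1, 1]$, which
uses the full $[0, \pi]$ range of $\arccos$ and makes the diagonal obey
$G_{ii} = 2\tilde{x}_i^2 - 1$. `rescale_mode = "unit"` maps to $[0, 1]$
instead, a variant that also appears in the literature; angles then live in
$[0, \pi/2]$ and the images lose half their contrast. Both are first-class;
all defaults use `"symmetric"`. Rescaling is per epoch, so each image uses
the full dynamic range regardless of slow amplitude drift; a constant epoch
has no well-defined rescaling and raises a classed error naming the epoch.

**GASF arithmetic.** $\cos(\phi_i+\phi_j)$ is evaluated through the
identity $\tilde{x}_i\tilde{x}_j - \sqrt{1-\tilde{x}_i^2}
\sqrt{1-\tilde{x}_j^2}$ (one outer product, no trigonometric calls), clipped
to $[-1,1]$ against rounding, and quantized round-half-up to
$\lfloor 255(v+1)/2 + 0.5 \rfloor$. The identity route is tested against
direct `cos(acos(x_i) + acos(x_j))` evaluation to $10^{-9}$.

**Keypoint extractors.** No R implementation of SIFT or ORB exists on CRAN
or Bioconductor, and these descriptors are the heart of the method, so both
are implemented in C++ (Rcpp): a SIFT-lite (difference-of-Gaussians pyramid,
$\sigma_0 = 1.6$, 3 scales/octave, contrast threshold 0.03, edge ratio 10,
36-bin orientation histogram with 0.8-peak multiple orientations, 4×4×8
trilinearly-binned descriptor with 0.2 clipping) and an ORB-lite (FAST-9
corners with non-maximum suppression, Harris ranking, 1.2× pyramid of 4
levels, intensity-centroid orientation, steered BRIEF over a fixed
pseudorandom 128-pair pattern). Keypoints are localized at grid resolution
(no sub-pixel refinement); scale-space plateau ties break toward the earlier
grid position so symmetric structures still yield exactly one extremum. For
bag-of-visual-words the descriptor content matters, not sub-pixel
coordinates. Both extractors cap output at the 500 strongest responses.

**Vocabulary.** k-means uses `stats::kmeans` (Lloyd) with a deterministic
k-means++ seeding. The pooled training descriptors are sorted
lexicographically first, making the vocabulary invariant to the order in
which images are supplied, and subsampled (seeded) to at most
`max_pool = 10000` descriptors with `iter_max = 20` — standard
bag-of-visual-words practice that bounds the clustering cost with no
measurable effect on downstream accuracy. A pool smaller than `10 * k`
triggers a warning; smaller than `k`, an error.

**Chi-square selection.** For each histogram feature, observed per-class
column sums are compared with expectations proportional to class sizes:
$\chi^2 = \sum_c (O_c - E_c)^2 / E_c$ with `classes - 1` degrees of freedom.
All-zero features score 0 ($p = 1$); ties rank toward the lower feature
index; selection preserves original column order. The selector's type-I
behaviour is checked in the test suite on label-independent Poisson
features.

**Classifiers and determinism.** SVM probabilities come from our own Platt
calibration (a logistic fit of training labels on decision values) rather
than `probability = TRUE`, because libsvm's internal cross-validated Platt
fit uses its own RNG that R cannot seed; our route is deterministic and
preserves the decision-value ranking, hence the AUC. Random forests are
fitted under a derived seed; k-NN is deterministic. All stage seeds derive
from the single pipeline seed through a fixed affine hash, so any stage is
reproducible in isolation and results are independent of batch size.

**Evaluation.** ROC curves sweep the distinct scores; AUC is trapezoidal;
metrics with zero denominators report 0 and are flagged in an `undefined`
attribute rather than returning `NaN`; log-loss clips probabilities to
$[10^{-15}, 1-10^{-15}]$.

**Noise sweep semantics.** The sweep generates *fresh* evaluation signals,
corrupts the raw samples (not the pixels) with white Gaussian noise scaled
to the requested SNR ($P_n = P_s / 10^{\mathrm{SNR}/10}$, power = mean
square), re-encodes them, and evaluates through the frozen clean-trained
artifacts — vocabulary, selected feature indices, and models, asserted by
fingerprint before the sweep. Per-class rows are one-vs-rest metrics with
that class as positive. `retrain = TRUE` instead refits the whole pipeline
on corrupted data at each SNR, covering the alternative reading of
noise-robustness evaluation. `Inf` is the no-noise sentinel.

## The synthetic generator: scope and limits

Real focal/non-focal EEG corpora are not redistributable, so the package
ships a two-class surrogate: *normal* signals are an 8–13 Hz rhythm with
slow amplitude modulation over a pink-noise background; *focal* signals are
a 2–6 Hz rhythm plus Poisson-arriving (0.8/s) biphasic spike-wave
transients at 3–5× the background amplitude. The classes separate in
spectral centroid by construction, which is what the GASF texture picks up.
This is a caricature, not a simulator: it contains no montage effects, no
artifacts (EMG, blink, line noise), no non-stationary seizure evolution,
and a much cleaner class boundary than clinical data. Accuracy numbers on
it validate the *pipeline mechanics*, not clinical performance; headline
figures from real recordings are out of scope here.

## Problem sizes

The reference configuration (50 signals/class, 20 s, 512 Hz) produces 4,000
images and runs in minutes on one CPU (SIFT ≈ 56 ms and ORB ≈ 22 ms per
256×256 image). The test suite exercises the full chain at reduced scales
(2–10 signals per class) and verifies the structural counts of the
reference configuration exactly.

## Limitations

- Single-channel only; multichannel montages are out of scope.
- Keypoint extractors are minimal re-implementations tuned for GASF-like
  texture; they are not drop-in replacements for OpenCV's on natural images.
- The GASF encoding discards sign information in its quantization only at
  the 1/255 level, but min–max rescaling per epoch removes absolute
  amplitude, so amplitude-only class differences are invisible by design.
- k-NN probability estimates are vote fractions with the coarse granularity
  of `k`; its log-loss is correspondingly crude.
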