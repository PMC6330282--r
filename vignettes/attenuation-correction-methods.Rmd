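---
title: "Attenuation correction for pediatric PET/MRI: models, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attenuation correction for pediatric PET/MRI: models, phantoms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative PET requires correcting every line of response for photon
attenuation. On PET/CT the attenuation map comes directly from CT; on
PET/MRI it must be inferred from MR images that carry no direct information
about electron density. The hardest tissue is cortical bone: it is nearly
invisible to conventional MR sequences yet attenuates strongly. In
children this is compounded by rapid developmental change — skull
thickness and mineral density grow quickly over the first years of life —
so adult templates and atlases transfer poorly.

This package re-implements, at desk scale, a comparison of four
attenuation-correction (AC) routes for pediatric brain FET-PET/MRI:

* **CT-AC** — reference: the true CT converted to 511-keV attenuation.
* **RESOLUTE-style segmentation AC** — ultrashort-echo-time (UTE) dual-echo
  MR, voxelwise R2* mapping, and a cohort-calibrated sigmoid from bone R2*
  to HU, giving a continuous bone representation.
* **DeepUTE-style CNN AC** — a 3D U-net-like encoder-decoder regressing HU
  directly from the two UTE echoes and the R2* map.
* **No-bone baseline** — air/soft segmentation only, standing in for vendor
  fat/water (DIXON) AC whose missing bone is the known failure mode.

Because the patient scans behind the original study are not public, the
package generates synthetic pediatric head phantoms with the statistical
structure the methods rely on, propagates each AC map through a simplified
PET simulator, and scores the results with the clinical metrics used in
neuro-oncology reading.

## The phantom generator

`phantom_spec()` + `build_phantom()` produce one subject:

* **Anatomy** — concentric ellipsoids: scalp shell (5 mm default), a skull
  layer whose thickness (1.5–7.5 mm) and peak density (400–1500 HU) default
  from seven pediatric age brackets, a brain interior, optional internal
  air structures (stylized nasal cavity, mastoid cells, post-surgical
  pocket), and a spherical tumor fully inside the brain.
* **Signals** — per-voxel tissue parameters drawn around configured means.
  Bone R2* is spatially variable and its HU is tied to it through a
  monotone logistic relation, so denser bone decays faster — the physical
  contrast that UTE bone mapping exploits. Echoes follow
  `S(TE) = S0 exp(-TE R2*)` at TE 0.07/2.46 ms with additive Gaussian noise
  (`noise_sigma`, default 0.05 of the soft-tissue signal; the Rician
  regime at this SNR is deliberately ignored). Tissue texture is drawn from
  the subject seed; echo noise and uptake heterogeneity from the exam seed,
  so repeated examinations share anatomy but not noise.
* **Uptake** — brain background 1.0 (arbitrary SUV-like units) with a
  smooth multiplicative heterogeneity field, a tumor peaking at
  `tumor_to_background_ratio` (default 2.5) with a parabolic internal
  gradient, low scalp/bone uptake, an optional extratumoral scalp hot spot
  exactly covered by the exclusion mask, and a mirrored-box background ROI
  restricted to brain tissue in the contralateral hemisphere.

What the phantoms do **not** emulate: realistic cranial morphology
(sutures, fontanelles, skull base), MR artifacts (B0, motion, metal),
partial-volume mixing beyond the voxel grid, or scanner-specific intensity
scales. Passing tests therefore demonstrate correctness of the *chain* and
the *mechanisms* (noise propagation, bone-versus-no-bone bias, calibration
transfer across ages), not clinical performance on real children.

## Scalar transforms

* R2* is the two-point estimate `ln(S1/S2)/(TE2-TE1)`; estimates are floored
  at 0 (noise can make the ratio invert) and clamped at 3000 s^-1, with a
  signal floor of 1e-6 of the maximum first-echo signal.
* HU→μ conversion is the standard bilinear 511-keV curve with
  μ(water) = 0.096 cm^-1 and a bone slope of 5.1e-5 cm^-1/HU, both
  configurable; the vendor's exact curve is proprietary, and the clinical
  ratios depend only weakly on the slope.
* Tissue classes for scoring pseudo-CTs use air < −500 HU < soft < 300 HU
  < bone, configurable.

## The segmentation (RESOLUTE-style) method

Calibration pools (R2*, HU) pairs from CT-confirmed bone voxels across the
training patients of each cross-validation fold (2-fold, subject-level, so
no patient is scored with a mapping calibrated on itself) and fits
`HU(r) = L + (U-L)/(1+exp(-k(r-r0)))` by nonlinear least squares
(`minpack.lm::nlsLM`, initialized at L=0, U=95th percentile HU, r0=median,
k=1/IQR).

Two numerical choices matter and were made after inspecting the noise
behaviour of the two-point estimator:

* **Echo smoothing.** At realistic noise the second echo of bone (fast
  decay, low S0) sits at or below the noise floor, and the raw voxelwise
  R2* estimate is censoring noise — floored at zero or clamped at the
  ceiling, nearly at random. The segmentation path therefore smooths both
  echoes with a separable 3-tap kernel (0.25, 0.5, 0.25 per axis) before
  the ratio. The cost is partial-volume mixing across the thin skull,
  which compresses the bone R2* scale.
* **Bone candidate threshold.** Because of that compression the calibrated
  r0 sits mid-bone, and a threshold derived from the sigmoid (such as
  r0 − 2/k) rejects about half the skull. The classifier instead uses a
  fixed, configurable threshold of 200 s^-1, between the soft-tissue range
  (tens of s^-1, modestly inflated near interfaces by the smoothing) and
  the bone range. Censored estimates are likewise dropped from the
  calibration pairs.

Classification runs inside a geometric outer-head shell (head mask from the
echo signal floor, eroded by 15 mm) — phantoms are geometric, so this
replaces the template-space regional masks used clinically. Air voxels get
−1000 HU, soft tissue 30 HU, bone the sigmoid of its R2*.

The no-bone baseline shares the air segmentation and assigns soft tissue
everywhere else.

## The CNN (DeepUTE-style) method

A 3D fully convolutional encoder-decoder over sliding windows of 16 axial
slices with channels (echo 1, echo 2, R2*), one HU output channel:
stride-2 convolutions instead of max pooling, every convolution followed
by batch normalization, ReLU and dropout (0.1 rising linearly to 0.3 along
the encoder, mirrored in the decoder), He-normal initialization, skip
connections, transposed-convolution upsampling, and a linear 1×1×1 output
head. Training minimizes mean-squared error on HU with Adam, batch size 2;
subject-level k-fold cross-validation (protocol: 4-fold) keeps each case's
prediction out-of-subject. Whole volumes are predicted densely (stride-1
windows) and overlapping predictions are averaged per voxel on the HU
scale. The R2* input channel reuses the smoothed-echo estimate of the
segmentation path: at desk scale the network has too little capacity and
far too few gradient steps to learn the denoising itself from the raw
censored estimate.

Desk-scale defaults (`deepute_desk_config()`) are sized for a single CPU:
2 resolution levels, 4 base channels, one convolution per block, training
windows at slice stride 4, 24 epochs, learning rate 6e-3. The larger
learning rate compensates for a step count roughly three orders of
magnitude below the published schedule (lr 1e-4, 100 epochs on ~60 full
resolution scans); targets are standardized internally (loss is still
recorded in HU²), so the rate is on a unit scale. He initialization is a
lottery at 4 channels: a substantial minority of inits stall on a
"no-bone" plateau within this budget. `train_config(max_restarts=)`
therefore probes each run for two epochs and reinitializes (derived seed)
when the normalized loss is still above 0.6 — the plateau and converged
populations separate cleanly there — keeping the best candidate if all
stall. With restarts the desk network usually, but not always, reaches or
exceeds the segmentation method's bone overlap on held-out noisy phantoms;
occasional converged-but-blurry runs remain, which is the honest picture
of a severely capacity- and data-limited CNN.

## PET simulation

A slice-wise 2D parallel-beam model replaces the clinical 3D iterative
reconstruction: the recorded signal per line is the Radon transform of
activity times `exp(-R(mu_true))` (in PET the photon pair traverses the
entire line, so the factor is emission-point independent). Correction
multiplies by `exp(+R(mu_ac))` and reconstructs by filtered back-projection
(spatial-domain Ram-Lak kernel, FFT convolution, bilinear backprojection,
180 angles by default). Matched-correction reconstruction is accurate to
well under 2% inside the object; using a wrong map reproduces the bias
mechanism of interest. Optional Poisson noise at a configurable count
level. Scatter, randoms, dead time, PSF and 3D effects are out of scope by
design — the simulator's job is to propagate μ-map errors into the
clinical metrics, not to model a scanner.

## Clinical metrics and agreement statistics

Background B is the ROI mean; the biological tumor volume is every voxel
strictly above 1.6×B minus the exclusion mask (no connected-component
selection — the clinical contouring tool's internals are unknown, so plain
thresholding is used and the choice is unit-tested at the boundary);
T_MEAN/B and T_MAX/B are the mean and maximum over that mask divided by B.
Each method is delineated independently. Examinations enter the cohort
only if the reference CT-AC volume exceeds 1 mL. Per-exam acceptance uses
the clinical dual limits: a difference passes at ±0.05 (T_MEAN/B), ±0.1
(T_MAX/B), ±2 mL (BTV) absolute *or* 5%/5%/10% relative.

Cohort agreement works on the log scale (the ratios are approximately
log-normal): mean log-difference with a t-based 95% CI, limits of
agreement mean ± 1.96 SD, everything exponentiated and reported as
percentages. With repeated examinations the SD combines between- and
within-subject variance from a one-way variance-components decomposition
(subject random intercept; method-of-moments on the ANOVA mean squares,
negative component truncated at zero), and the CI/p-value are computed on
subject means — the alternative of averaging exams per subject first is
available by flag. With one exam per subject both reduce exactly to the
ordinary sample SD and one-sample t-test. A degenerate SD of zero reports
p = 1 and zero-width limits rather than NaN.

## The study driver

`run_study()` chains everything: battery generation (default: 8 subjects,
2 with a repeat exam — 10 examinations at 32³/2.5 mm, echo noise 0.05,
ages cycled over the four oldest brackets, since a 1.5–2.5 mm infant skull
cannot be represented at a 2.5 mm voxel), 2-fold sigmoid calibration,
2-fold network training, map building (optionally completing a reduced CT
field of view with the bone-less map), noiseless projection with the true
μ-map, per-method reconstruction, metrics, cohort filter, agreement
tables, and a CSV/JSON report. A single global seed fans out to named
per-stage substreams, so any stage can be reproduced in isolation and the
whole report is byte-identical across reruns.

Problem sizes used by the test-suite checks: 32³ phantoms at 2.5 mm; the
generalization battery trains on 8 phantoms and tests on 2 held out, over
five seeds; the reconstruction self-consistency check uses a 64² slice
with 180 angles; the calibration recovery uses 10^4 samples; agreement
coverage uses 500 replicates of 36 examinations.

## Known limitations

* The geometric skull flatters the segmentation method: its shell mask is
  exact here, whereas clinically the regional masks and irregular anatomy
  (skull base, post-operative changes) are its main failure modes. The
  phantom study therefore understates the CNN's relative advantage.
* The uniform skull shell attenuates nearly uniformly, so the bone-less
  baseline biases tumor and background almost equally and the clinical
  *ratios* move far less than in real heads, where bone thickness varies
  regionally. Absolute activity is biased by the expected several percent.
* The desk-scale CNN is ~10^3 smaller than the published network and the
  age-to-density curve of the generator is literature-plausible rather
  than cohort-calibrated (no quantitative pediatric curve is published).
* "SUV" is treated as the raw activity unit; dose/weight normalization
  cancels from every reported ratio.
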