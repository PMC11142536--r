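---
title: "Multimodal spot classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal spot classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msifuse)
```

## The problem

Dermatopathologists annotate small circular regions ("spots", here 50 µm
in diameter) on H&E-stained skin sections as melanoma or nevus.  When a
serial section is analyzed by MALDI imaging mass spectrometry (IMS), each
spot also yields one profile mass spectrum over the tryptic-peptide range
of 700–3500 Da.  `msifuse` implements and compares three spot-level
classification strategies that share one downstream classifier and one
patient-level data split:

* **unimodal IMS** — the spots × peaks intensity matrix after spectral
  preprocessing;
* **unimodal microscopy** — a fixed-length morphology embedding of each
  spot's H&E patch;
* **multimodal** — the standardized, equal-weight concatenation of both
  blocks.

The scientific question the package operationalizes is whether the two
modalities carry complementary information: if some lesions are
molecularly ambiguous and others morphologically ambiguous, the fused
representation should beat either block alone, and should do so with
lower fold-to-fold variability.

## IMS preprocessing

The spectral chain runs, in order: resampling to a common m/z axis
(linear interpolation, zero outside the input's support), baseline
subtraction, total-ion-current (TIC) normalization, integer-lag
realignment, and peak picking on a mean spectrum.  The steps are named
functions behind a fixed order contract, so any one can be swapped.

Choices that were genuinely open, and what we picked:

* **Baseline**: a rolling minimum followed by a rolling mean over the
  same odd window (default 51 bins) — a transparent analogue of
  morphological opening.  Edge windows are truncated rather than padded.
  Output is clamped at zero.
* **Realignment**: exhaustive integer-lag cross-correlation against a
  reference spectrum, ties broken toward lag zero, vacated bins
  zero-filled.  The reference is the mean of the *training* spots'
  normalized spectra, so held-out data never shapes it.  Lags at the
  search boundary are flagged with a warning.
* **Peak picking**: strict local maxima of the training-mean spectrum
  above `snr_min` (default 3) times a noise level estimated as the scaled
  median absolute deviation of the first difference divided by √2.
  Whether the original workflow picked peaks per spectrum or on an
  aggregate is not documented; we pick on the training-set mean, which
  keeps the feature space identical across spots and makes the leakage
  contract easy to state.  The number of peaks is data-dependent and
  never hard-coded.
* **Axis resolution**: the m/z range (700–3500 Da) is a property of the
  acquisition; the bin count is not.  Synthetic runs default to 600 bins,
  which keeps peaks several bins wide at the generator's peak width;
  thousands of bins are appropriate for real profile data.
* **Zero-TIC spots** are dropped with a warning rather than failing the
  run — the analogue of excluding spectra that miss quality standards.

## Morphology embedding

Each spot's patch has a physical side of 48 µm: 96×96 px at 20×
(0.5 µm/px) and 192×192 px at 40× (0.25 µm/px).  Patches are extracted at
native resolution, bilinearly resized to the encoder input side (default
224), and channel-normalized as `(value/255 − mean)/sd` with default
constants 0.5/0.5 (the constants used by the original encoder are not
published).

The embedding stage is a *pluggable interface*: any function mapping a
preprocessed tensor to a fixed-length vector can serve as the encoder,
including an adapter around an external pre-trained self-supervised
network.  Shipping such weights is out of scope, so the default is a
deterministic hand-crafted **texture encoder**: per-channel intensity
histograms, gradient-magnitude histograms, multi-scale block mean/variance
summaries and global moments, projected to `embed_dim` (default 512)
through a fixed seeded Gaussian random projection and normalized to unit
length.  A constant patch maps to the canonical unit vector (1, 0, …, 0).
The encoder is order-free and bit-reproducible; changing the projection
seed rotates the space but preserves distance structure.

## Fusion

"Combining with equal weights" underdetermines the normalization.  We
read it as: z-score every feature within each block using statistics of
the training rows only (population SD; zero-variance features are masked
to zero), then concatenate the blocks unchanged — weights `(1, 1)`.
Alternative per-block scalings (e.g. 1/√width) can be expressed through
the `weights` argument but are off by default.  Column provenance is
retained so either block can be recovered exactly.

## Modeling and validation

All pipelines share a linear support-vector machine (via `e1071`/libsvm)
and the same validation scaffold:

* **Patient-level held-out split** (default 20% of patients, label
  stratified, at least one patient per class on each side).  Spots of a
  patient never straddle the boundary.
* **Patient-grouped nested cross-validation** on the training patients:
  outer folds (default 5) estimate generalization; inner folds (default
  5) grid-search the SVM cost `C` (default grid `10^(-3:3)`, ties toward
  the smallest `C`, i.e. the strongest regularization — the published
  grid is not available).  Peak picking and scaling are refit inside each
  outer fold from that fold's training rows; the inner grid search reuses
  the outer fold's features rather than refitting them per inner fold — a
  deliberate trade of a small amount of inner-loop purity for a k-fold
  reduction in preprocessing cost.  The outer-fold estimates and the
  held-out evaluation are fully nested.
* **Final model**: the modal `C` across outer folds (ties toward the
  smallest), refit on all training spots, scored once on the held-out
  spots.  `evaluate_heldout()` refuses any spot id seen during fitting.
* **Metrics**: ROC-AUC (staircase/trapezoid, equal to the Mann–Whitney
  pair-count statistic under ties), PR-AUC (anchored at recall 0 /
  precision 1 for trapezoid stability — conventions differ, so ours is
  stated), and threshold-0 precision/recall/F1 (a spot is called melanoma
  at score ≥ 0; with no predicted positives, precision is reported as 0
  with a warning).
* **DeLong test** for two correlated AUCs on the same held-out spots,
  in the fast midrank (structural-components) formulation with a
  two-sided normal p-value.  No p-value flooring is applied.  The test
  suite verifies exact equality with a naive O(n²) kernel computation.

Class imbalance is not reweighted (none is documented), and no
patient-level aggregation of spot predictions is performed by design.

## Visualization

`project()` maps any feature block to 2-D or 3-D under one
`projection_spec` (cosine distance by default).  The default backend is
principal-coordinates analysis (classical MDS) — deterministic and
dependency-free; a `method = "umap"` adapter shells out to a Python
`umap-learn` installation when one is present and honours the same spec
(neighborhood size 15, minimum distance 0.1, fixed random state; both
values are unstated upstream and are our defaults).  3-D coordinates map
to RGB by percentile clipping (1st/99th, to tame outlier-driven color
collapse) followed by per-channel min–max scaling — the "hyperspectral"
spot coloring — and `render_spot_map()` paints the colored discs at their
slide positions.

## The synthetic cohort generator

No patient data are distributed, so the generator is a first-class
module that emulates the *structure* of the real cohort: ~331 patients
with on average 21 annotated spots each (Poisson-truncated at 1), one
spectrum and one patch per spot, all of a patient's spots sharing one
label.

* **Spectra**: smooth decaying baseline + Gaussian peaks at fixed
  centers + i.i.d. bin noise, multiplied by a lognormal TIC factor,
  shifted by a whole-spectrum integer jitter and clipped at zero.  Class
  identity moves the mean peak heights by `ims_effect_size` along a fixed
  signed pattern; per-spot height jitter has SD `noise_sd`.
* **Patches**: a blurred-noise background whose channel means and
  nucleus-like dark-blob density shift with class along a fixed
  color/texture direction by `morph_effect_size`.
* **Patient effects**: every patient carries a random shift along each
  modality's discriminant direction (SD `patient_sd`), shared by all of
  that patient's spots.  This within-patient correlation is what makes
  patient-grouped validation different from spot-level validation — and
  what the leakage tests exercise.
* **Complementary signal**: configurable fractions of patients are
  *uninformative* in one modality (their class term is zeroed there);
  the two sets are kept disjoint when the fractions allow, so fusing the
  modalities can rescue patients that either unimodal model must guess.

The default effect size (0.3, i.e. two patient-level SDs) was calibrated
so that the complementary regime behaves as intended: informative
patients are well but not perfectly separated (per-modality AUC ≈ 0.9),
leaving visible headroom for fusion.  Larger effects saturate the
unimodal models on small held-out sets and erase the contrast the
comparison is about.

What the generator deliberately does **not** model: tryptic peptide mass
distributions, isotope envelopes, stain physics, spatial autocorrelation
between neighbouring spots, scanner or batch effects.  Green tests on
synthetic cohorts therefore demonstrate the correctness and
leakage-freedom of the pipeline machinery and the qualitative multimodal
advantage under complementary signal — not clinical performance on real
tissue.

## Problem sizes used by the test suite

Unit tests run on cohorts of roughly 12–20 patients with a 100–150-bin
axis and 16–32 px patches.  The end-to-end comparison experiments use
60-patient cohorts (~21 spots each, 30% IMS-uninformative and a disjoint
30% morphology-uninformative), a 600-bin axis, 256-dimensional
embeddings at the native 96-px patch side, a 3-point cost grid
`{0.01, 0.1, 1}`, 5 outer × 2 inner folds, and 10 independent seeds.
These sizes were chosen so a full comparison runs in well under a minute
per seed on one core while keeping ≥ 200 held-out spots per run.

## Numerical conventions and degenerate inputs

* TIC normalization errors on all-zero spectra (upstream, such spots are
  dropped with a warning); normalized sums hit the target to 1e-9.
* Baseline subtraction and peak-matrix assembly guarantee non-negative
  finite values.
* Realignment ties break toward lag 0; boundary lags warn.
* The scaler uses population SDs and masks zero-variance features.
* `roc_auc`/`pr_auc` require both classes; all-tied scores give AUC 0.5.
* The DeLong variance can be exactly zero only when the two score sets
  have equal AUCs (then z = 0, p = 1); otherwise a zero variance is an
  error rather than a silent infinity.
* Every stochastic step (cohort generation, splitting, folding, the
  encoder's projection) is governed by explicit integer seeds; fixed
  seeds reproduce results bit-for-bit.

## Known limitations

* The built-in texture encoder is a transparent stand-in, not a learned
  morphology model; absolute microscopy performance on real H&E will
  differ from any pre-trained network plugged into the same interface.
* The inner grid search reuses outer-fold features (see above).
* The default projection backend is PCoA, not UMAP; fine-grained local
  structure in figures will differ from a UMAP rendering.
* Real-data ingestion is CSV/PNG-based (per-spot spectra plus a
  manifest); imzML containers must be converted upstream.
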