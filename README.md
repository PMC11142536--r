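# msifuse

Spot-level melanoma-versus-nevus classification from paired MALDI imaging
mass spectrometry (IMS) and H&E microscopy, comparing three strategies
that share one classifier and one patient-level data split:

* **unimodal IMS** — preprocess each spot's profile spectrum
  (common-axis resampling → baseline subtraction → TIC normalization →
  integer-lag realignment → SNR peak picking on the training mean) into a
  spots × peaks matrix;
* **unimodal microscopy** — embed each spot's H&E patch (48 µm physical
  side; 96×96 px at 20×, 192×192 px at 40×) into a fixed-length
  morphology vector through a pluggable encoder (deterministic built-in
  texture encoder, 512-dimensional by default);
* **multimodal** — z-score each block on training statistics and
  concatenate with equal weights, e.g. 5558 peaks + 512 embedding
  dimensions → 6070 fused features.

Every pipeline trains a linear SVM inside patient-grouped nested
cross-validation (spots of one patient never straddle a fold or the
held-out boundary), is scored on the same held-out patients, and held-out
ROC curves are compared with the DeLong test for correlated AUCs,

> z = (AUC_a − AUC_b) / √Var(AUC_a − AUC_b),

with the variance from midrank structural components.  A synthetic
paired-modality cohort generator (class-differential Gaussian peaks over
baseline/noise/jitter/TIC variation; class-differential patch textures;
patient-level random effects; configurable per-modality uninformative
patient fractions) makes the whole comparison runnable without any
patient data.  UMAP-style 2-D/3-D projections with "hyperspectral" RGB
spot maps round out the toolkit.

The package is aimed at computational pathology / imaging-MS researchers
who want a leakage-audited reference implementation of multimodal spot
classification, or a harness to drop their own patch encoder into.

## Worked example

```r
library(msifuse)

cfg <- cohort_config(n_patients = 60, seed = 7,
                     frac_ims_uninformative_patients = 0.3,
                     frac_morph_uninformative_patients = 0.3)
cohort <- generate_cohort(cfg)
cohort
#> <msi_cohort: 60 patients, 1294 spots (652 melanoma / 642 nevus), 600-bin axis>

pc <- pipeline_config(seed = 7, k_outer = 5, k_inner = 2,
                      grid = c(0.01, 0.1, 1),
                      embedder = embedder_spec(embed_dim = 256,
                                               input_side = 96))
report <- run_experiment(cohort, pc)
report
#> Pipeline comparison (ROC-AUC):
#>    pipeline  metric   cv_mean      cv_sd   heldout
#>         ims roc_auc 0.8404187 0.15137928 0.8904724
#>  microscopy roc_auc 0.8655218 0.06748545 0.8012569
#>  multimodal roc_auc 0.9573931 0.05886211 0.9965773
#>   DeLong ims_vs_microscopy: dAUC = +0.0892, p = 0.0104
#>   DeLong ims_vs_multimodal: dAUC = -0.1061, p = 3.22e-08
#>   DeLong microscopy_vs_multimodal: dAUC = -0.1953, p = 2.15e-13
```

Read: each unimodal pipeline is held back because 30% of patients carry
no signal in that modality (held-out ROC-AUC 0.89 and 0.80); the fused
features rescue those patients through the other modality (0.997), the
DeLong test confirms the improvement on the shared held-out spots, and
the multimodal model is also the most stable across outer folds
(smallest `cv_sd`).

Projection and spot-map rendering:

```r
em <- embed_patches(cohort$patches, embedder_spec(embed_dim = 256,
                                                  input_side = 96))
coords <- project(em, projection_spec(n_components = 3, seed = 11))
cols <- hyperspectral_rgb(coords)
render_spot_map(cohort$records, cols, "spots.png")
```

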