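# pcdradiomics

Radiomic analysis of nanoparticle contrast-enhanced spectral
(photon-counting) versus conventional micro-CT, as a tested, reusable and
fully synthetic-data-driven R pipeline.

## The problem

Tumors with different lymphocyte burden accumulate an iodinated
nanoparticle contrast agent differently: leakier vasculature raises the
mean intratumoral iodine concentration, and architectural differences alter
its spatial texture. Conventional energy-integrating-detector (EID) CT
collapses the X-ray spectrum into one channel; a photon-counting detector
(PCD) bins photons at 25/34/50/60 keV thresholds bracketing the iodine
K-edge (33.2 keV), enabling per-voxel basis-material decomposition

&nbsp;&nbsp;&nbsp;&nbsp; *x* = *A*⁻¹ *b*

where *b* is the vector of energy-bin intensities, *A* the 4×3 sensitivity
matrix calibrated from vials of known concentration, and *x* the (iodine,
photoelectric, Compton) material vector — iodine in mg/mL. The package asks,
on simulated cohorts with a controlled class effect: do conventional tumor
metrics see the difference, and does the multichannel spectral feature
space classify better than the single-channel EID space?

The pipeline covers:

* **Synthetic phantoms** — co-registered 4-bin PCD + EID volumes generated
  from ground-truth material maps through the sensitivity matrix, with
  class-dependent mean iodine and texture correlation length, calibration
  vials, and per-bin Gaussian noise (`simulate_cohort()`).
* **Spectral decomposition** — vial-based least-squares estimation of *A*
  and voxelwise material decomposition with the 1 mg/mL iodine reporting
  threshold (`estimate_sensitivity()`, `decompose()`, `threshold_iodine()`).
* **Segmentation** — seeded region growing on the lowest-energy bin, one
  mask propagated to all channels (`region_grow()`, `propagate_mask()`).
* **Semantic metrics** — tumor volume, enhanced volume and percentage,
  iodine mass, mean iodine concentration (`compute_semantic()`).
* **Agnostic radiomic bank** — 851 features per channel (14 shape, and
  18 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM on the
  original image and 8 Coiflet-1 wavelet sub-bands), grouped into EID
  (851), PCD (3404) and material-map (2553) spaces (`extract_all()`,
  `extract_cohort()`).
* **Statistics & learning** — Wilcoxon–Mann–Whitney screen with
  Benjamini–Hochberg control; PCA 90% dimensionality; MRMR ranking;
  50×5 stratified Monte Carlo cross-validation with in-fold selection,
  ridge-logistic classification, pooled ROC/AUC, precision=recall
  thresholding, selection-frequency audit, k-sweep and paired signed-rank
  model comparison (`univariate_screen()`, `mrmr_rank()`, `run_cv()`,
  `compare_models()`).

## Worked example

```r
library(pcdradiomics)

cfg <- pipeline_config(n_pos = 13, n_neg = 12, grid_shape = c(48, 48, 48),
                       seed = 1)
res <- run_pipeline(cfg)

res$semantic_tests          # class comparison of the five semantic metrics
res$pca_dims                # PCA 90% dimensions per feature space
res$reports$PCD             # cross-validation report, spectral space
res$comparisons             # pairwise signed-rank AUC comparisons
```

On this seed the run prints (abridged): the mean iodine concentration
clearly separates the classes (Wilcoxon p = 5.5e-4; positive class 5.31 vs
negative 3.55 mg/mL) while tumor volume does not (p = 0.25), and the
cross-validated classifiers order as

```
EID          mean AUC 0.72
PCD          mean AUC 0.87   (signed-rank vs EID: p = 1.3e-9)
MaterialMaps mean AUC 0.85
```

i.e. the four-channel spectral feature space outperforms the single-channel
EID space, while the decomposed material maps — whose per-voxel noise is
amplified by the matrix inversion — trail despite carrying the iodine
signal explicitly. A feature selected in every one of the 250 validation
folds would show frequency 250 in `res$reports$PCD$selection_frequency`.

The numbered scripts under `analysis/` run the same study as a file-based
workflow (NIfTI volumes and CSV tables under `results/`): simulate →
decompose → semantic metrics → feature bank → univariate screen →
classification.

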