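# gliomafuse

Binary glioma grading — low-grade (WHO I–II) versus high-grade (WHO
III–IV) — from co-registered multimodal MRI (T1, T2, T1-Gd, FLAIR) with
a BraTS-style tumor segmentation, for researchers who want a fully
inspectable, CPU-sized re-implementation of a CNN + radiomics fusion
pipeline they can exercise end-to-end without any external data.

## The method

Tumor-masked axial slices of the four sequences are stacked into a
4-channel image and classified by a residual CNN. In parallel, 14
3D shape descriptors of the whole tumor are computed from the
segmentation: mesh volume, voxel volume, surface area, surface/volume
ratio, sphericity (36πV²)^⅓/A, maximum 3D diameter, the three in-plane
maximum 2D diameters, the three principal axis lengths 4√λᵢ, elongation
√(λ₂/λ₁) and flatness √(λ₃/λ₁). The backbone's feature vector is
projected to 14 values, concatenated with the 14 z-scored shape
features, and the 28-vector is mapped by a single affine layer to a
softmax over (LGG, HGG). Slice probabilities are averaged per patient;
the argmax (ties → HGG) is the patient's grade. Training: cross-entropy,
Adam (lr 0.001, weight decay 5e-4, decay rates 0.9/0.99), batch 16, with
minority-class upsampling and an LGG-only augmentation suite (flips,
wrap-around cyclic shift, ±180° rotation, salt-and-pepper noise).
Patient-level metrics: AUC (rank form), accuracy, average per-class
accuracy (SEN+SPE)/2, sensitivity and specificity, positive class HGG.
The package also includes Kaplan–Meier / log-rank survival analysis
with a trimmed-mean imputation rule, gradient-weighted class-activation
heatmaps, and a synthetic phantom cohort generator (ellipsoid-union
tumors whose size/shape distribution differs by grade) so that every
stage is testable offline.

## Worked example

Simulate a 12-patient phantom cohort, train the fusion classifier for 3
epochs on a small residual backbone, and evaluate at patient level:

```r
library(gliomafuse)

res <- run_end_to_end(run_config(
  spec    = phantom_spec(n_lgg = 6, n_hgg = 6, seed = 77),
  out_dir = "demo_run",
  train   = train_config(epochs = 3, seed = 7)))

print(res$report)
#> AUC 1.0000  Acc 1.0000  APCA 1.0000  SEN 1.0000  SPE 1.0000
#> confusion (positive = HGG): tp=2 fn=0 fp=0 tn=2

res$model$training_log
#>   epoch mean_loss
#> 1     1 0.2996603
#> 2     2 0.1892075
#> 3     3 0.1141463
```

The mean training loss falls across epochs and the 4 held-out validation
patients (the 7:3 split leaves 2 LGG + 2 HGG out of 12) are all graded
correctly — phantom grades are separable by tumor volume, so this
certifies the plumbing, not clinical performance. `demo_run/` now holds
the manifest, `features.csv` (14 shape descriptors per patient),
`split.json`, the model, `report.json`, `survival.json` and heatmap
PNGs. Individual stages are exported too:

```r
p  <- generate_patient(phantom_spec(seed = 1), "HGG", "HGG-001")
round(extract_shape_features(p$mask)[c("mesh_volume", "sphericity", "max_3d_diameter")], 3)
#>     mesh_volume      sphericity max_3d_diameter
#>       56387.600           0.928          52.545
```

A thin CLI over the same functions is installed at
`inst/cli/gliomafuse.R` (subcommands `simulate`, `features`, `run`,
`ablate`, `survival`).

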