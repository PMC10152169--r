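# facetraits

Latent facial trait analysis for prenatal-exposure studies on 3D face
meshes.

Population studies of prenatal alcohol exposure (PAE) ask whether graded
maternal alcohol consumption — six consumption levels, three
exposure-timing tiers — leaves measurable traces in children's facial
shape. `facetraits` implements the full analysis such a study needs, for
researchers working with template-corresponded 3D face meshes (identical
vertex count and triangulation across subjects):

* **Dimensionality reduction.** A spectral graph-convolutional mesh
  auto-encoder compresses each face `F` into `N` latent traits
  `z = Encode(F)` and reconstructs `F' = Decode(z)`. Four
  Chebyshev-convolution + pooling blocks (channels 32/32/32/64) run over a
  quadric-error-metric mesh hierarchy with factor-4 coarsening; a
  5023-vertex template passes through 1256×32 → 314×32 → 79×32 → 20×64
  to `N = 200` traits, and a PCA baseline with the identical
  encode/decode contract is provided for comparison.
* **Association testing.** Per trait, ordinary least squares
  `z_j ~ exposure + ethnicity + sex + age + BMI + maternal age + maternal
  smoking`, with Benjamini–Hochberg FDR (α = 0.05) across the `N` traits;
  stratified by exposure tier, consumption-level band, ethnicity subset
  and age group (9y, 13y, and growth `Z13 − Z9`).
* **Visualization.** FDR-significant traits are decoded into per-vertex
  displacement fields, combined with β/SD weights, and signed radially
  from the head's geometric center: red = inward, blue = outward; exported
  as colored PLY + CSV.
* **Prediction.** Exposure classification from covariates alone (Model A)
  vs covariates + all traits (Model B), stratified 5-fold cross-validated
  AUC, per-trait odds ratios, ANOVA F-tests.
* **Synthetic cohort generator.** Because the motivating cohort data are
  not public, the package ships a generator producing corresponded face
  meshes with known injected dose–response effects on named facial regions
  (nose tip, nose bridge, chin, lower eyelids), realistic covariates and
  drinking-timing structure — the basis of all shipped validation.

## Worked example

A scaled end-to-end run on synthetic data (about three minutes on one
core):

```r
library(facetraits)

template <- make_template(1024)
hier     <- build_hierarchy(template)       # 1024 -> 256 -> 64 -> 16 -> 4
pop      <- make_population(template, seed = 1000)

# 500 children with a nose-tip effect of 1 mm per consumption level
cohort <- simulate_cohort(500, population = pop, slope = 1, seed = 100)

model <- train_face_model(
  cohort$faces_9y,
  encoder_config(latent_dim = 50, epochs = 25, lr = 5e-3, lr_decay = 0.98,
                 seed = 42),
  hierarchy = hier)
model

# tier 2b (any first-trimester drinking) vs abstinent controls, age 9
assoc <- run_stratified_analysis(cohort, model,
                                 stratum_spec(tier = "2b", level_band = ">0",
                                              age_group = "9y"))
glance(assoc)
dplyr::arrange(tidy(assoc), fdr_p)[1:3, c("trait_index", "beta", "se",
                                          "p_value", "fdr_p", "f_z")]

# where on the face? combined heatmap of the significant traits
hm <- assoc_heatmap(model, assoc)
localization_score(hm$scalar, attr(template, "region_masks")$nose_tip)
export_heatmap(template, hm$scalar, "heatmap_tier2b.ply")

# does adding traits improve exposure prediction?
grp <- facetraits:::stratum_groups(cohort$covariates,
                                   stratum_spec(tier = "2b", level_band = ">1"))
ids <- c(grp$control, grp$exposed)
Z   <- encode_faces(model, cohort$faces_9y)[ids, ]
cov <- cohort$covariates[match(ids, cohort$covariates$subject_id), ]
compare_models(cov, Z, ids %in% grp$exposed, k = 5, seed = 1)
```

Output from this exact script:

```
#> <face_model: V = 1024, N = 50 traits, best validation MAE 0.2439 (normalised)>
#> # A tibble: 1 × 6
#>   n_traits n_significant n_nominal min_fdr_p n_exposed n_control
#>      <int>         <int>     <int>     <dbl>     <int>     <int>
#> 1       50             8        11 0.0000773       215       175
#> # A tibble: 3 × 6
#>   trait_index   beta     se    p_value     fdr_p   f_z
#>         <int>  <dbl>  <dbl>      <dbl>     <dbl> <dbl>
#> 1          10 -0.107 0.0227 0.00000309 0.0000773  256.
#> 2          11  0.200 0.0410 0.00000157 0.0000773  584.
#> 3          28  0.142 0.0384 0.000248   0.00404    600.
#> [1] 0.6078431
#> fold 1: separation detected; using ridge fallback
#> ...
#> <prediction_report: AUC A = 0.495, AUC B = 1.000 (Ne = 123, Nc = 175)>
```

Reading it: training converged (validation error is in mean-face-scaled
units); 8 of the 50 traits survive FDR in the tier-2b analysis of the
training cohort; the strongest trait moves the face by ~256 mm summed over
vertices per +1 SD (`f_z`); 61% of the strongest heatmap vertices fall
inside the injected nose-tip region (chance would be ~9%); and while the
covariates alone predict exposure at chance level (they are sampled
independently of exposure in the generator), adding the traits separates
the classes perfectly — the injected effect is deliberately strong (1 mm
per consumption level), strong enough that the logistic fit hits complete
separation and the ridge fallback engages. See the methods vignette for
the calibration rationale.

The same pipeline is available as one call from a configuration:

```r
res <- run_pipeline(run_config(n = 400, latent_dim = 32, epochs = 25,
                               seed = 7),
                    out_dir = "runs/demo")
```

which writes covariates, association TSVs, colored heatmap PLYs, the
prediction report and a hashed manifest under `runs/demo/`.

## Package layout

| Area | Functions |
| --- | --- |
| Mesh I/O & geometry | `read_mesh`, `write_mesh`, `geometric_center`, `procrustes_align`, `vertex_normals` |
| Hierarchy | `decimate_qem`, `build_hierarchy`, `apply_transform`, `write_hierarchy` |
| Auto-encoder | `encoder_config`, `train_face_model`, `encode_faces`, `decode_traits`, `cheb_conv`, `reconstruction_error`, `pca_baseline`, `generalization_specificity`, `trait_correlations`, `effect_size_f` |
| Synthetic cohort | `make_template`, `make_population`, `sample_covariates`, `assign_levels`, `assign_tiers`, `effect_spec`, `synthesize_faces`, `synthesize_longitudinal`, `simulate_cohort`, `write_cohort` |
| Association | `fit_trait_regressions`, `bh_fdr`, `growth_traits`, `stratum_spec`, `run_stratified_analysis`, `sex_phenotype_check` |
| Heatmaps | `trait_displacement_field`, `combine_significant_traits`, `radial_sign`, `localization_score`, `assoc_heatmap`, `export_heatmap`, `plot_heatmap` |
| Prediction | `fit_logistic`, `cv_auc`, `compare_models` |
| Orchestration | `run_config`, `run_pipeline`, `replicate_trainings` |

Result objects have `tidy()`, `glance()` and `autoplot()` methods.
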