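---
title: "Latent facial traits and prenatal alcohol exposure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent facial traits and prenatal alcohol exposure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`facetraits` implements a complete analysis pipeline for population studies
that relate a prenatal exposure — here, maternal alcohol consumption graded
in six levels and three timing tiers — to children's three-dimensional
facial shape. This vignette explains the models the package implements,
the choices behind every tunable parameter, what the synthetic cohort
generator does and does not emulate, and the numerical details a user
re-running or extending the pipeline should know.

## The analysis in one paragraph

Corresponded face meshes (every subject has the same vertices and
triangulation) are compressed by a graph-convolutional mesh auto-encoder
into `N` latent facial *traits* `z = Encode(F)`; a mirrored decoder maps
traits back to a face `F' = Decode(z)`. Each trait is then regressed, one
ordinary-least-squares model per trait, on an exposed/control indicator
plus covariates (ethnicity dummies, sex, child age, child BMI, maternal
age, maternal smoking), and the exposure p-values are corrected across the
`N` traits by Benjamini–Hochberg FDR at level 0.05. Significant traits are
decoded back to the face and combined — each trait's +1 SD displacement
field weighted by its regression coefficient over its SD — into a single
per-vertex displacement field, signed radially with respect to the head's
geometric center (inward negative/red, outward positive/blue). Finally,
exposure status is predicted by logistic regression from covariates alone
(Model A) and covariates plus all traits (Model B), scored by stratified
5-fold cross-validated AUC.

## Mesh representation and the sampling hierarchy

A `triangle_mesh` holds a `V x 3` millimetre coordinate matrix and an
`F x 3` face matrix. Indices are 1-based inside the package (the R
convention); PLY files use 0-based indices on disk and OBJ 1-based, both
converted at the file boundary.

Pooling in the auto-encoder needs a multi-resolution version of the
template. `build_hierarchy()` coarsens the template with quadric-error
(Garland–Heckbert) edge contraction: every vertex carries the sum of its
incident faces' area-weighted plane quadrics, boundary edges add a
perpendicular constraint plane (weight 1000 × squared edge length) so the
open rim of a face patch stays put, and the cheapest edge is contracted
onto whichever endpoint has the lower combined error, ties resolved toward
the lower vertex index so the result is fully deterministic. Because
contraction always keeps an existing vertex, the *down-transform* `D_l` of
each level is a pure row selector (one unit entry per row). The
*up-transform* `U_l` carries a coarse signal back up: each fine vertex is
assigned the barycentric coordinates of its orthogonal projection onto the
plane of its nearest coarse triangle. Weights sum to one but may be
negative when the projection falls outside the triangle; we deliberately do
not clamp them, as clamping would bias reconstructions inward near region
boundaries. With the default factor-4 chain and `V_{l+1} = ceiling(V_l/4)`,
a 5023-vertex template yields levels of 1256, 314, 79 and 20 vertices.

Each level's graph operator is recomputed from the coarse mesh itself (not
mapped down from the fine level): the binary adjacency from shared face
edges, the symmetric-normalised Laplacian `L = I - D^{-1/2} A D^{-1/2}`,
and the Chebyshev-domain rescaling `L~ = L - I`, which uses the universal
bound `lambda_max <= 2` of the normalised Laplacian instead of an
eigensolve; the spectrum of `L~` is then guaranteed to lie in `[-1, 1]`.
Isolated vertices (possible in degenerate meshes) get zero rows and a
warning rather than an error.

## The auto-encoder

The encoder applies four blocks of Chebyshev spectral graph convolution

`Y = sum_k T_k(L~) X W_k`, `T_0 = I, T_1 = L~, T_k = 2 L~ T_{k-1} - T_{k-2}`,

each followed by an ELU nonlinearity and pooling with `D_l`, producing
feature maps of 32, 32, 32 and 64 channels; a dense layer maps the coarsest
signal to the `N` latent traits (default 200). The decoder mirrors this
exactly: dense layer, then four upsample-and-convolve blocks, the last one
linear with 3 output channels. The Chebyshev order `K` defaults to 6, the
convention of spectral mesh auto-encoders; the polynomial support then
covers a 6-ring neighbourhood per block.

Inputs are normalised by subtracting the training mean face and dividing by
the global root-mean-square vertex deviation; the decoder output undoes
this. The loss is the mean absolute error of normalised coordinates. A
90/10 subject split provides a validation set, and the returned parameters
are the best-validation-epoch checkpoint.

Training uses mini-batch gradient descent with adaptive step sizes.
Both RMSprop (momentum-free) and Adam are implemented; **Adam is the
default** because, at the cohort sizes and epoch budgets this package
targets, RMSprop on the MAE loss converged too slowly to capture shape
directions that carry less than a percent of total variance — precisely the
directions an exposure analysis cares about. `encoder_config(optimizer =
"rmsprop")` restores the alternative. Default learning rate is `1e-3`
decayed by 0.99 per epoch; the desk-scale study configurations below use
`5e-3` with decay 0.98, which reached the same validation error in a
quarter of the epochs. Everything — initialisation (Glorot uniform),
splitting, batching — derives from one integer seed, and training is
bitwise reproducible.

The whole network is plain linear algebra (a small C++ kernel for
sparse-operator application, BLAS for the dense products), so the same code
runs identically anywhere R runs; there is no GPU path.

### Model quality and the PCA baseline

`pca_baseline()` provides a linear model with the identical
encode/decode contract. `generalization_specificity()` computes the two
standard shape-model scores: *generalisation* (mean per-vertex
reconstruction error on held-out faces) and *specificity* (mean distance of
faces decoded from random latent draws — a diagonal Gaussian fitted to the
training latents — to their nearest held-out face). On a curved (quadratic)
shape population the auto-encoder's generalisation should match or beat
PCA at equal latent dimension; this is asserted in the test suite at
`V = 1024, n = 300, N = 16` over 60 training epochs.

The effect size of a trait on the face is
`f(z_j) = sum_v || Decode(z_mean + sd_j e_j)_v - Decode(z_mean)_v ||`,
the total vertex displacement per +1 SD of the trait, in mm summed over
vertices. This published-style summary is a reconstruction: the exact
formula in the original supplementary material is not public, and ours is
chosen to reproduce its order of magnitude (hundreds of mm·vertices for a
5023-vertex face).

## Association testing

`fit_trait_regressions()` fits, per trait, `z_j ~ exposure + ethnicity +
sex + child_age + child_bmi + maternal_age + maternal_smoking` by QR-based
least squares (one decomposition serves all traits), with reference
categories Dutch, female and non-smoking, and two-sided t-tests on the
exposure coefficient. Records with any missing value are dropped listwise
with a logged count. Rank-deficient designs are an error that names the
collinear columns. `bh_fdr()` applies Benjamini–Hochberg step-up
adjustment (via `stats::p.adjust`) within the `N` traits of one analysis;
no correction is applied across strata, mirroring per-analysis reporting.
Traits are not standardised before regression — coefficients are in raw
trait units, with `f(z)` giving the facial scale of each unit.

Strata are defined by `stratum_spec()`: exposure-timing tier (1, 2a, 2b —
abstinent mothers are the control group of every tier), a consumption-level
band (e.g. `>1` or `{2,3}`), an ethnicity subset (multi-ethnic, Western,
Dutch-only), and the age group (9y, 13y, or growth, where growth traits are
the exact per-subject difference `Z13 - Z9` over the longitudinal pairs).
`sex_phenotype_check()` reruns the identical machinery with sex as the
predictor — a positive control on known sexual dimorphism.

p-values use the t reference; at the cohort sizes involved (hundreds per
group) t and normal references are indistinguishable. Child age enters as a
continuous covariate within each age group.

## Heatmaps

For each significant trait the displacement field
`Decode(z_mean + sd_j e_j) - Decode(z_mean)` is computed and the combined
field is `sum_j (beta_j / sd_j) * field_j`. This weighting makes the sum an
estimate of the decoded between-group shape difference restricted to the
significant traits, and makes the result invariant to latent sign flips
(flipping a trait negates both its beta and its field). A raw-beta mode is
available by passing unit SDs. The scalar heatmap is the projection of the
combined field on the outward radial direction from the template's
geometric center: negative = inward = red, positive = outward = blue, with
the colour scale clipped at the 99th percentile of |scalar| so single
vertices cannot saturate it. `localization_score()` reports the fraction of
the top-10% |scalar| vertices that fall inside a ground-truth region — on
the synthetic scenario it separates a recovered effect (score > 0.5)
from chance (score ~ mask share, ~0.09).

## Exposure prediction

`compare_models()` fits unpenalised logistic regressions: Model A on
maternal age, maternal smoking, child BMI, child age and sex; Model B
additionally on all `N` traits, both scored with the same stratified
5-fold split by out-of-fold Mann–Whitney AUC (midpoint tie convention).
Separation is detected (non-convergence or diverging linear predictors)
and raised with advice to use the ridge fallback, a small-L2 IRLS fit that
the cross-validation applies automatically when needed. Odds ratios per
trait come from the full-data Model B fit, and one-way ANOVA F-tests of
each variable against the class label are reported for both models.
Following the study design this replicates, the auto-encoder is trained
once on the cohort and its traits are reused across folds — this leaks
only unsupervised shape structure, never labels; a purist can retrain per
fold by calling `train_face_model()` inside their own fold loop.

## The synthetic cohort generator

No real cohort is shipped or downloadable, so the package ships a
generator whose *statistical structure* matches what the analysis assumes.
A deterministic face-like template (`make_template()`) — a half-ellipsoid
patch, 70 × 90 × 80 mm semi-axes with Gaussian nose and chin lobes, ~180 mm
head height — carries five named, disjoint vertex regions: `nose_tip`
(~9% of vertices), `nose_bridge`, `chin`, `lower_eyelids`, `forehead`.
The nose-tip region is deliberately sized at several percent of the surface
so that localisation scores against a top-10% vertex set have headroom
above chance.

A `shape_population` fixes the population once: smooth shape-mode fields
(Laplacian-smoothed Gaussian random fields, 15 neighbour-averaging sweeps),
with geometrically decaying scales `2.0 * 0.9^(k-1)` mm RMS over 24 modes,
plus fixed covariate fields — chin displacement for sex (0.8 mm), a smooth
fullness field per BMI unit (0.12 mm), radial growth per year of age
(0.8 mm). Cohorts drawn from one population share these fields and differ
only in subjects: mode coefficients (standard normal), covariates,
exposure, and iid vertex noise (0.25 mm SD, typical of stereo-photogrammetry
residuals). Fixing the fields is essential: a model trained on one cohort
is only transferable to replicate cohorts if they sample the *same*
population.

Covariates mimic a large urban birth cohort: four ethnicities with a Dutch
majority, near-balanced sex, BMI 17.5 ± 2.4, maternal age 30.5 ± 4.5, 40%
smoking. A third of mothers are abstinent; drinkers get a lognormal average
weekly consumption discretised into the six levels (<1/week; 1–3/week;
4–6/week; 1/day; 2–3/day; >3/day, at 7 days/week and midpoint splits), and
a drinking-timing category (30% before pregnancy only, 42% first trimester
only, 28% continued) with 99% of during-pregnancy drinkers also drinking
before. Abstinence is equivalent to all drinking flags false by
construction.

The injected effect displaces the `nose_tip` region along per-vertex unit
directions (outward-and-up, the turned-up-nose pattern) by
`slope * pae_level` mm; other regions can be added with their own
FASD-like directions (inward nose bridge, outward chin, inward lower
eyelids). At age 13 subjects are re-measured (75% longitudinal pairing):
the 9-year face plus 4 mm deterministic radial growth, the exposure effect
rescaled by an attenuation factor (default 0.3 — facial effects fade as
children grow), and fresh noise.

**The dose slope is a calibrated parameter.** The default, 1.0 mm per
consumption level, was tuned once so that the full pipeline — auto-encoder
traits, covariate-adjusted trait-wise OLS, FDR — detects at least one
FDR-significant trait in well over 80% of replicate cohorts at
`n ≈ 1500` with 50 traits, and then frozen. Two things make the required
slope larger than intuition suggests. First, the trait axes of an
auto-encoder are oblique mixtures of population modes, so a localized
effect direction is diluted across many traits and each single-trait test
sees only a fraction of it. Second, the effect must compete for
reconstruction loss with population modes carrying hundreds of times more
variance. A 1 mm/level slope (up to 6 mm at the highest consumption level)
is deliberately a strong, stress-test effect — far above the subtle
real-world signal — and the vignette's claims about power on synthetic data
therefore say nothing about power on real cohorts; what the tests *do*
establish is that every stage of the pipeline is wired correctly: null
calibration is exact, detection grows with dose, heatmaps point at the
injected region, and independent trainings agree.

What the generator does **not** emulate: photorealistic facial anatomy,
ethnicity-specific shape, questionnaire misreporting, registration error
from a real dense-correspondence pipeline, and confounding between
exposure and covariates (covariates are sampled independently of exposure,
so the covariate-only prediction model sits at chance on synthetic data,
unlike in a real cohort where confounding lifts it).

## Numerical choices and degenerate inputs

* Decimation stops with an error if contraction would destroy all faces or
  run out of edges; `target = V` is the identity.
* Barycentric up-transform rows have at most 3 non-zeros summing to 1
  within 1e-6; constant signals are reproduced exactly.
* `procrustes_align()` is Kabsch via SVD with a determinant guard against
  reflections; scaling is off by default (fixed camera geometry).
* Zero-variance traits get correlation 0 and a warning rather than NaN.
* `radial_sign()` returns 0 with a warning for a vertex coinciding with
  the center.
* Training aborts with a diagnostic on non-finite loss; `epochs = 0` is
  permitted and returns the initialised network (useful for architecture
  probes).
* The exposure-null calibration in the test suite randomises exposure
  labels over a fixed encoded cohort (a permutation null): exposure is
  independent of shape by construction, each replicate is cheap, and the
  per-trait p-values are exactly marginally uniform.

## Scaled study configurations

The shipped tests and examples run a scaled replica of the full design:
1024-vertex template (hierarchy 1024 → 256 → 64 → 16 → 4), 50 traits,
training cohorts of 300–500 subjects for 25–60 epochs, analysis cohorts of
n = 1500 (power and dose–response) up to n = 4000 (cross-training
replicability, where a large estimation sample keeps the combined-heatmap
estimator stable), all on one CPU core in minutes. These sizes are the package's
own validation choices; the architecture itself (factor-4 hierarchy,
channels 32/32/32/64, latent 200) instantiates the full-scale design, and
the shape-probe test asserts the 5023 → 1256 → 314 → 79 → 20 cascade with
intermediate signals 1256×32, 314×32, 79×32, 20×64 and 200 latent traits.

## Known limitations

* Trait-wise univariate testing leaves multivariate alternatives (PLS,
  CCA) out of scope by design.
* The auto-encoder's latent axes are not orthogonal or variance-ordered;
  single-trait power therefore depends on how the optimiser happens to
  span an effect direction. The replicability check (pairwise heatmap
  correlation across independent trainings) is the guard against
  over-reading any single training's trait indices.
* The f(z) effect-size formula and the coefficient-weighted heatmap
  normalisation are reconstructions of supplementary-only definitions and
  are flagged as such in the documentation.
* Real registration pipelines introduce correspondence error that the
  generator does not model; rigid alignment (`procrustes_align`) is a
  stand-in for dense non-rigid registration, which is out of scope.
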