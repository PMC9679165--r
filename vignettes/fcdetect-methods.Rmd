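---
title: "Surface-based FCD detection: models, parameters and design notes"
author: "fcdetect maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based FCD detection: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

Focal cortical dysplasia (FCD) is a malformation of cortical development
and a leading cause of drug-resistant focal epilepsy. Lesions are often
subtle on MRI: thickened cortex, blurred grey-white boundaries, abnormal
folding, FLAIR signal changes. `fcdetect` implements a surface-based
detection pipeline that operates on per-vertex features sampled on a
bilaterally symmetric template surface, so that every vertex has a
homotopic partner on the opposite hemisphere:

1. **Quality control** — subjects whose features are extreme across many
   cortical regions (an artefact signature) are excluded.
2. **ComBat harmonization** — site/scanner location and scale effects are
   removed per (feature, vertex), while age, sex and disease status are
   retained as covariates.
3. **Three-stage normalization** — intrasubject z-scoring, then
   interhemispheric asymmetry (left minus right and vice versa), then
   per-vertex z-scoring against healthy controls, yielding the
   "normalized" and "asymmetry" feature sets.
4. **Classification** — an ensemble of small multilayer perceptrons
   labels each vertex with a lesional probability; the ensemble mean is
   thresholded at a Dice-optimal operating point and grouped into
   connected clusters, with small clusters filtered out.
5. **Interpretation** — integrated-gradients saliency explains which
   features drive each predicted cluster; lesion-level feature summaries
   are embedded and clustered into phenotype groups.

All geometry (geodesic distances, border zones, smoothing
neighbourhoods, connected components) lives on the triangle mesh of the
template. A synthetic cohort generator reproduces the statistical shape
of a multi-site cohort so the full pipeline can be exercised and tested
without clinical data.

## Features

Eleven base features per vertex and hemisphere: cortical thickness (mm),
grey-white contrast (ratio), mean curvature (1/mm), sulcal depth,
intrinsic (Gaussian) curvature (1/mm²), and six FLAIR intensities
(sampled at 25/50/75% cortical depth, the grey-white boundary, and
0.5/1 mm subcortically). Curvature features are combinators on the
principal curvatures: `meanCurvature()` is `(k1 + k2) / 2` and
`intrinsicCurvature()` is `k1 * k2`. The package deliberately does not
compute features from MRI volumes or mesh geometry: it consumes
precomputed per-vertex inputs, as produced by standard surface
reconstruction tools or by the synthetic generator.

The default smoothing policy assigns 5 mm kernels to mean curvature and
sulcal depth, 10 mm to thickness, grey-white contrast and all FLAIR
features, and 20 mm to intrinsic curvature (so folding abnormalities are
stable across adjacent gyri and sulci). Kernel sizes are interpreted as
FWHM — the convention of the surface-neuroimaging tools this pipeline
interoperates with — with `fwhm = FALSE` available to read them as raw
sigma; the kernel is truncated at 3 sigma, which loses under 1% of the
kernel mass while bounding the neighbourhood size.

## The classifier

The network is intentionally small: 33 inputs (11 ComBat + 11
normalized + 11 asymmetry features), hidden layers of 40 and 10
rectified units, one logistic output, and dropout 0.4 on the input
layer. Class imbalance (lesional vertices are ~0.1% of cortex) is
handled two ways:

* **balanced vertex sampling** — each epoch draws 2000 lesional and 2000
  non-lesional vertices per patient (lesional vertices are re-drawn with
  replacement only when the mask is smaller than the request) and 2000
  non-lesional vertices per control;
* **focal loss** — `FL(p_t) = -alpha (1 - p_t)^gamma log(p_t)` with
  defaults `gamma = 2`, `alpha = 0.5`, concentrating training on hard
  examples. `gamma = 0, alpha = 1` recovers plain cross-entropy, which
  is how the implementation is tested. `alpha` here is a constant loss
  weight applied to both classes.

Vertices within 40 mm geodesic distance of a lesion mask (but outside
it) are *never* sampled for training: manual masks are conservative and
their borders uncertain, so the 0-20 mm and 20-40 mm border rings are
treated as unlabelable. The training loop audits every epoch's draws
against this contract and aborts on any violation.

Cross-validation uses a subject-level split (never vertex-level):
subjects are stratified by site and group into train/test halves, and
the train cohort is partitioned into 10 folds. One network is trained
per (fold, initialization) cell — 10 folds x 5 initializations = 50
members at full scale — and the ensemble prediction is the arithmetic
mean of member probabilities. The decision threshold maximizes the
vertex-pooled Dice score on the train cohort over the grid 0.01..0.99
(ties resolve to the smallest threshold). Optimizer details the
architecture leaves open are declared as defaults and exposed in
`trainingConfig()`: Adam at learning rate 1e-3, batch size 1000, at most
100 epochs with early stopping on validation focal loss (patience 10).

Predicted clusters are connected components of the thresholded field per
hemisphere; components under 100 vertices are filtered out. Evaluation
reports sensitivity (a cluster overlaps the mask by at least one
vertex), sensitivity+ (mask or its 20 mm ring), specificity (controls
with zero clusters) and cluster-count medians. "Overlap" is one shared
vertex; the threshold for calling a patient detected is deliberately
permissive because the cluster filter already suppresses small spurious
components.

## Harmonization details

`fitComBat()` implements parametric empirical-Bayes ComBat per
(feature, vertex) column: OLS location/covariate estimation with site
indicators, standardization by the pooled residual SD, EB shrinkage of
per-site locations toward a normal prior and of per-site scales toward
an inverse-gamma prior (moment-matched hyperparameters, iterative
conditional solution to relative tolerance 1e-4), and reconstruction
with site effects removed. T1-derived columns are fitted on all
subjects and FLAIR-derived columns on FLAIR-available subjects only.
Columns with essentially zero variance (e.g. the medial wall, which
carries constant 0) are passed through untouched. A cohort from a single
site is returned unchanged — there is no batch effect to estimate — and
`harmonizeNewSite()` freezes the reference intercepts, covariate
coefficients and pooled scales, estimating and removing only the new
site's location/scale. With EB disabled the new-site adjustment is an
exact fixed point (applying it twice is the identity); with EB the
second pass re-shrinks a small residual, so exactness holds only in the
non-EB mode.

## Normalization details

Intrasubject z-scoring pools both hemispheres' cortex vertices (medial
wall excluded; it carries 0 through the whole pipeline). The control
reference stores a per-vertex mean and SD for both the step-1 and step-2
outputs; SDs are floored at 1e-3 z-units to protect near-constant
vertices. The reference should be built from train-cohort controls only
and reused for test subjects — the package exposes `controlIds` for
exactly this — preventing test-set leakage through the normalization.
Subjects without FLAIR keep missing FLAIR values through harmonization
and normalization; `assembleClassifierInput()` imputes them with 0,
which is the control mean in z-units, so one network serves T1-only and
T1+FLAIR subjects alike. Each stage refuses to run twice (provenance is
recorded in the store), because double z-scoring silently changes scale.

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the pipeline
assumes, not the biology: smooth per-vertex mean maps with age and sex
effects; spatially correlated noise (white noise smoothed with a 15 mm
FWHM kernel and rescaled to exact unit marginal variance); per-site
additive shifts (in control-SD units) and multiplicative noise scales;
variable FLAIR availability; and contiguous lesions grown as geodesic
discs with archetype feature offsets added inside. Three archetypes
mirror the qualitative lesion phenotypes: "group1" (thicker cortex,
higher intrinsic curvature, lower grey-white contrast, brighter
white-matter FLAIR; 2 control-SD effects), "group2" (lower grey-white
contrast and intracortical FLAIR; 1.5 SD) and "group3" (heterogeneous,
all effects under 0.5 SD, largely overlapping healthy cortex). Principal
curvature fields k1/k2 are generated directly with folding-like
sinusoidal structure and fed through the curvature combinators; the
generated fields already carry the smooth spatial correlation the
smoothing policy would induce, so the pipeline does not re-smooth them.

The template is a pair of mirrored icospheres (default level 4, 2562
vertices per hemisphere, radius 65 mm — the scale of an adult
hemisphere) with a polar cap marked non-cortex as a medial-wall
stand-in. One resolution-driven choice deserves emphasis: the evaluation
filter keeps clusters of at least 100 vertices, which is ~0.5 cm² at
full fsaverage resolution but ~20 cm² at 2562 vertices per hemisphere.
Clinically the filter sits an order of magnitude below typical lesion
extent, and the Dice-optimal threshold trims a prediction to a core
covering only part of the mask, so lesions whose masks are near the
filter size are structurally undetectable whatever the classifier does.
The generator's default lesion radius range (33-45 mm, masks of roughly
160-295 vertices) restores the clinical filter-to-lesion ratio at the
template's resolution; smaller lesions can of course be configured, but
then the cluster filter — not the classifier — bounds sensitivity. Ages are
uniform on 3-60 years, sex is a fair coin, lesion hemispheres are a fair
coin, and the whole cohort is bit-reproducible from the seed.

What the generator does **not** emulate — realistic folding geometry,
registration error, scanner-specific spatial autocorrelation, partial
voluming, heterogeneous lesion shapes, histology — bounds what passing
tests mean: they demonstrate that the pipeline's machinery recovers
planted statistical structure under its own assumptions, not that it
detects lesions in clinical data.

## Phenotype embedding

Lesion-level summaries (mean normalized/asymmetry features over each
mask, with size-matched geodesic pseudo-lesions for controls) are
embedded in 2-D for display and clustered into K groups (default 3)
with a Gaussian mixture. The embedding here is linear (PCA on the
standardized T1-derived summaries); a nonlinear neighbour-embedding
would preserve more cluster structure in 2-D, and with a linear map the
two displayed components can collapse directions that separate groups.
For that reason the mixture is fitted on the standardized summary
features themselves, and the 2-D coordinates are only a visual aid. The
group assignment is the argmax responsibility; determinism is fixed by
the seed and a sign convention on the components.

## Integrated gradients

Attributions use the right-Riemann approximation of the path integral
of model gradients from the zero baseline (the all-features-at-control-
mean input) to the observed input, with m = 256 steps by default;
ensemble attributions are the mean over members. Two exactness
properties anchor the tests: for a linear logit the attribution equals
`w * x` at any m, and for trained networks the completeness residual
|sum(IG) - (F(x) - F(0))| must stay under 1% of the predicted change.
Per-cluster saliency evaluates the attribution at the cluster-mean
input vector.

## Numerical and convention choices

* Vertex indices are 1-based throughout, matching R and every mesh
  library it uses.
* Geodesic distance is shortest-path Dijkstra on the edge graph with
  Euclidean edge weights — the practical surface-neuroimaging
  convention — not an exact polyhedral geodesic; it is exactly testable
  against an independent Dijkstra.
* Probabilities entering losses are clipped to [1e-7, 1 - 1e-7].
* The Dice threshold grid is 0.01..0.99 in steps of 0.01; ties resolve
  downward.
* The permutation test permutes the detection outcome, uses the
  two-sided `(1 + #(|b*| >= |b|)) / (1 + B)` estimator, and applies
  Benjamini-Hochberg across factors at q = 0.05; separation in the
  logistic fit is flagged with a warning rather than silently reported.
* The cohort container is a versioned RDS file (template, demographics,
  feature sets, annotations, provenance); demographics also round-trip
  as CSV and per-vertex maps as ASCII GIFTI overlays.

## Problem sizes used in the checks

The packaged checks run on reduced but faithful conditions chosen as
the package's reference study sizes: end-to-end recovery uses a 3-site,
~200-subject cohort at template level 4 with archetype-1 lesions and a
reduced ensemble (2 folds x 2 initializations, 15 epochs); ComBat
recovery uses a 150-subject, 3-site cohort at level 2 with planted
shifts up to ±1 SD and scales 0.7-1.4; phenotype recovery uses 60
lesions at level 3; permutation calibration uses 200 null simulations
with 200 permutations each. The full-scale configuration (10 folds x 5
initializations, 100 epochs, level-4+ meshes) is exposed through the
same functions.

## Known limitations

* The pipeline consumes surface-sampled features; it neither performs
  cortical reconstruction nor volume-to-surface sampling, and cannot
  detect pathology outside the modelled cortex (e.g. hippocampus).
* The synthetic validation bounds stated above; clinical performance is
  a property of real cohorts only.
* ComBat assumes additive/multiplicative site effects per column and
  linear covariate effects; nonlinear age effects would call for a GAM
  variant, out of scope here.
* The MLP treats vertices independently; neighbourhood context enters
  only through feature smoothing and post-hoc clustering.
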