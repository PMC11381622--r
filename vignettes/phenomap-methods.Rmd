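---
title: "Phenotyping with generative topographic mapping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping with generative topographic mapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomap)
```

## The model

phenomap stratifies a subjects × variables table in two stages.

**Stage 1 — micro-clusters.** A Generative Topographic Mapping (GTM) model
assumes the data were generated from a 2-D latent space through a smooth
nonlinear map. The latent prior is a uniform sum of delta functions on a
regular `side × side` lattice of nodes $u_l$, so the marginal in data space
is a constrained mixture of $K = \mathrm{side}^2$ spherical Gaussians with
shared precision $\beta$, centred on $y_l = W\,\phi(u_l)$. The map $\phi$
consists of $M = \mathrm{rbf\_side}^2$ isotropic Gaussian basis functions on
a second lattice plus a constant bias, so the component centres are forced
to vary smoothly over the latent lattice — this is what preserves topology
and makes the fitted maps readable. Fitting maximises the penalised
log-likelihood

$$\mathcal{L}(W,\beta) \;=\; \sum_{n=1}^N \log\Big[\tfrac1K \sum_{l=1}^K
\mathcal{N}\!\big(x_n \,\big|\, W\phi(u_l),\, \beta^{-1} I\big)\Big]
\;-\; \tfrac{\lambda}{2}\lVert W\rVert^2$$

by expectation–maximisation: the E-step computes responsibilities
$r_{nl} \propto \exp(-\tfrac{\beta}{2}\lVert x_n - y_l\rVert^2)$ (rows
normalised, log-sum-exp stabilised), and the M-step solves the weighted
ridge normal equations
$(\Phi^\top G \Phi + (\lambda/\beta) I)\,W^\top = \Phi^\top R^\top X$
followed by the variance update
$\beta^{-1} = \frac{1}{ND}\sum_{n,l} r_{nl}\lVert x_n - y_l\rVert^2$.
Both steps are coordinate ascent on the same evidence lower bound, so the
penalised objective is non-decreasing; the test suite asserts this to
within $10^{-8}$ over a hundred seeded runs. A subject's micro-cluster is
its maximum-responsibility node (ties to the lowest node index), but the
full posterior row is retained — that soft assignment is the point of using
a probabilistic model.

**Stage 2 — macro-cluster phenotypes.** Ward's minimum-variance
agglomerative clustering, implemented via the Lance–Williams recurrence on
squared Euclidean distances, merges the $K$ reference vectors; heights are
reported on the Euclidean-equivalent scale ($\sqrt{2\,\Delta\mathrm{ESS}}$,
the `ward.D2` convention) so dendrograms are comparable across software.
Cutting the tree at a user-chosen $k$ labels every node, and subjects
inherit the label of their micro-cluster. Clustering operates on the raw
reference vectors in the standardized data space — not on latent
coordinates, and unweighted by node occupancy; weighting by occupancy is a
plausible variant but changes the meaning of the dendrogram heights and is
deliberately not done.

## Parameters that matter

* `side` (default 15): latent lattice side; $K = 225$ micro-clusters by
  default. Smaller cohorts warrant smaller lattices (the examples use 8,
  i.e. 64 nodes for a few hundred subjects).
* `rbf_side` (default 14): basis lattice side. The default configuration
  keeps the basis nearly as dense as the node lattice (196 RBFs under 225
  nodes). That near-1:1 ratio matters: with a much sparser basis the map is
  stiff, and reference vectors are forced into the empty space between
  well-separated clusters; those "bridge" prototypes can distort the Ward
  cut. In scaled-down analyses we therefore keep `rbf_side ≈ side`.
* `width_factor` (default 1): RBF width as a multiple of the spacing
  between adjacent centres. Widths around the spacing give smooth overlap;
  the value is not part of the reference configuration and is exposed
  explicitly.
* `lambda` (default 1): weight-decay penalty entering the M-step as
  $(\lambda/\beta) I$. It also regularises the otherwise-singular normal
  equations; `lambda = 0` is allowed but can fail on degenerate bases, and
  the error says so.
* Convergence: relative penalised-objective change below `tol = 1e-6`, at
  most `max_iter = 200` iterations. Non-convergence is reported in the fit
  trace, not raised.
* Initialisation: by default the weights solve the least-squares problem
  placing the lattice on the plane of the first two principal components
  (scaled to the PC score spread), with $\beta^{-1}$ the larger of the third
  eigenvalue and half the mean squared distance between adjacent initial
  reference vectors; a seeded random initialisation is the fallback for
  rank-deficient data. $\beta^{-1}$ is floored at $10^{-8}$ so degenerate
  clusters cannot push the objective to infinity.
* Model selection: 10-fold cross-validation on the mean held-out
  per-subject negative log-likelihood, with one shared fold partition per
  search (a paired comparison). The selection rule is a one-standard-error
  rule: among configurations within one standard error of the best mean,
  take the one with the smallest fold-to-fold standard deviation — both fit
  and stability are rewarded; a pure-mean rule is available
  (`rule = "mean"`). The stability criterion is stated qualitatively in the
  methodology this package operationalises; the one-SE formulation is this
  package's concrete choice.
* Choice of `k`: a user decision made by inspecting the dendrogram.
  `suggest_k()` (largest relative gap between successive merge heights,
  falling back to the range minimum when heights are flat) is advisory and
  never applied silently.

## Preprocessing

The chain runs in a fixed order: validity masking and unit harmonisation
(e.g. negative heart rates become missing, inches become centimetres);
missingness filtering with strict thresholds — variables with more than 25%
missing are dropped first, then subjects missing more than 30% of the
surviving variables (dropping sparse variables first avoids discarding
subjects for missingness in doomed columns; boundary cases are retained);
log(1+x) transformation of continuous modelling variables whose moment-based
sample skewness exceeds 1 and whose values are nonnegative (the guard
matters because a bare log is undefined at zero); chained-equations
imputation of the modelling variables (mean initialisation, then ten
round-robin passes of ridge-stabilised conditional regression of each
incomplete variable on all the others — observed cells are never altered
and the procedure is deterministic); and z-scoring of the continuous
modelling variables. Standardisation is an explicit, invertible step
because the spherical-noise mixture assumes comparable variable scales;
reference maps can be pushed back to original units via the stored scaler.
Whether imputation should precede or follow the log transform is genuinely
ambiguous; the narrative order (transform, then impute) is implemented.

Ordinal variables used in post-hoc description are one-hot encoded
(`encode_ordinals()`) and treated as categorical in the group comparisons.

## Characterisation statistics

Per-phenotype tables report medians with interquartile ranges (type-7
linear-interpolation quantiles, stated because quantile conventions differ
across software) for continuous variables and counts with percentages for
categorical ones. Between-phenotype differences use the Kruskal–Wallis
rank-sum test (midrank ties correction, $\chi^2_{g-1}$ reference) for
continuous variables and Pearson's chi-squared test without continuity
correction for categorical ones, thresholded at raw $p < 0.05$ with no
multiple-testing adjustment — mirroring the descriptive, hypothesis-free
role of these tables; a Benjamini–Hochberg option exists but is off by
default.

## The synthetic cohort generator

`generate_cohort()` draws latent points from `n_clusters` unit-variance 2-D
Gaussian blobs whose adjacent centres sit `cluster_separation` apart, maps
them into `n_dims` dimensions through a seeded low-order polynomial (linear
terms of unit scale, quadratic terms of scale 0.05 — enough curvature to be
nonlinear, not enough to fold the manifold), and adds spherical Gaussian
noise of sd `noise_sd`. This deliberately mirrors the generative
assumptions of the model so likelihood-based checks are well-posed. A
leading `skewed_fraction` of columns is exponentiated to exercise the skew
transform; investigative columns carry a planted between-cluster mean shift
of `investigative_effect` within-cluster standard deviations (zero makes
them exactly independent of the clusters, which underpins the type-I-error
calibration check). Schema presets reproduce the *shape* of two cohort
types — 67 modelling variables (40 genomic principal components + 27
biological assays) and a 21-variable vitals/labs table — with realistic
names only; no claim is made about real marginal distributions, covariance
structure, informative missingness or measurement artefacts. Consequently,
passing tests demonstrate correctness of the algorithms and calibration
under the model's own assumptions, not robustness to everything real
clinical data can do. A mismatched heavy-tailed generator can be emulated
by post-hoc exponentiation (`skewed_fraction = 1`) for qualitative
robustness checks.

Default generator conditions (500 subjects, 10 dimensions, 3 clusters,
separation 5, unit noise) are what we consider a realistic difficulty for a
mid-sized cohort; the recovery benchmarks use 600 subjects with a 10:1
separation-to-noise ratio and require adjusted Rand index ≥ 0.9 against the
planted labels.

## Numerical choices and degenerate inputs

* Log-sum-exp stabilisation is mandatory in the E-step; the naive
  evaluation exists only as a test oracle.
* The M-step solve raises a clear error (suggesting $\lambda > 0$) when the
  normal matrix is singular.
* Node indexing is row-major from the top-left of the lattice and shared by
  every map layer, so layers from different runs are cell-comparable. Map
  orientation is a convention; mirrored reproductions of maps from other
  implementations are expected and harmless.
* Empty nodes in investigative maps carry `NA`, never 0 — zero is a valid
  data value.
* Model JSON stores doubles as 17-significant-digit strings so a saved
  model reloads bit-exactly; map-layer CSVs do the same.
* Ward ties (exactly equal merge costs) break deterministically by scan
  order; with continuous data they have probability zero.
* Exact ties in responsibilities assign to the lowest node index.

## Problem sizes used in the checks

The shipped test-and-acceptance workload is sized for a laptop-class run:
EM monotonicity over 100 runs of a 200 × 5 cohort on a 6 × 6 lattice;
recovery over 600 × 10 cohorts on an 8 × 8 lattice (8–10 seeds); Ward
oracle equivalence up to 12 leaves (exhaustive recomputation is cubic);
topology statistics on 400-subject smooth manifolds; 200 null replicates
for the type-I error of the full pipeline. These sizes are the package's
own choices for routine verification; the algorithms themselves run
comfortably at the reference configuration (225 nodes, 196 RBFs) on cohorts
of tens of thousands of subjects.

## Known limitations

* The latent space is fixed at two dimensions — that is what makes the maps
  interpretable, but structure needing more latent dimensions will be
  flattened.
* Spherical shared-precision noise implies comparable variable scales;
  standardisation mitigates but cannot repair grossly heteroscedastic
  blocks of variables.
* Imputation is linear-Gaussian in spirit; strongly nonlinear missingness
  mechanisms (MNAR) are out of scope.
* `suggest_k()` is a height-gap heuristic; it can be misled by chained
  merges and is intentionally advisory.
* Phenotypes are cross-sectional; nothing here models how cluster
  membership evolves over time.
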