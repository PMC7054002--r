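---
title: "Methods: phylogenetically informed shape analysis with vestimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetically informed shape analysis with vestimorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestimorph)
```

vestimorph analyses the evolution of 3D shape — concretely, the shape of
the vestibular apparatus (semicircular canals and vestibular recesses) of
anthropoid primates — by combining group-structured ordination with
phylogenetic comparative methods. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The data model

Three inputs drive everything:

1. a rooted, time-calibrated phylogeny with branch lengths in Ma
   (`ape::phylo`);
2. a specimen-by-descriptor **shape table**: `n` specimens × `p` real
   descriptors with complete specimen/species/group labels. Descriptors
   are either flattened GPA-aligned landmark coordinates (`p = 3k`) or
   deformation-descriptor vectors produced by external surface
   registration — the package is agnostic, and records the provenance;
3. per-specimen scalar sizes: vestibular volume `Vol` (mm³),
   semicircular-canal volume `VolSC` (mm³) and summed canal streamline
   length `L` (mm).

All log size variables are natural logs of **cube roots** of volumes
(`ln_Vol = log(Vol)/3`), so the isometric expectation of `ln_VolSC`
against `ln_L` is a slope of exactly 1. This convention matters: reading
the volumes as plain logs changes every slope by a factor of 3.

## Superimposition (GPA)

`gpa()` removes position, orientation and optionally scale from landmark
configurations. Each configuration is centered; with `allow_scaling =
TRUE` it is divided by its centroid size, so aligned shapes live on the
unit-centroid-size pre-shape space. Rotations use the closed-form
orthogonal Procrustes solution with a determinant correction that
excludes improper rotations — reflections never enter silently; instead,
right-side (mirrored) specimens can be folded explicitly with the
`mirror` flag, which negates the x axis before alignment. Iteration
alternates rotation-to-consensus and consensus update until the consensus
moves less than `1e-8` (root summed squared displacement) or 100
iterations. Sliding semilandmarks are deliberately out of scope: only
fixed correspondences are assumed.

## Between-group PCA and classification

`fit_bgpca()` eigendecomposes the covariance of the `g` group mean
vectors about the mean of group means. Group means are **unweighted** by
group size and the grand mean is the mean of the group means — the
standard bgPCA definition; it keeps the ordination from being dragged
toward the largest group, and the study's groups are nearly balanced. At
most `g − 1` eigenvalues are non-zero, so 4 clades yield bgPC1–bgPC3.
Specimens (and any a-posteriori queries such as fossils) are projected as
`(x − x̄) V`. For reproducibility, each eigenvector's largest-magnitude
loading is made positive.

bgPCA is preferred over discriminant analysis here because it does not
sphere the within-group scatter, and therefore does not manufacture
separation when `p` approaches `n`. Two independent checks guard against
spurious grouping: `hca_confusion()` (Ward agglomerative clustering of
the raw descriptors, cut at `g`; each cluster labeled by majority group)
verifies that the group structure pre-exists in the data, and the test
suite compares every fit with a brute-force eigendecomposition.

`loo_classify()` assigns each specimen to the nearest group centroid
(Euclidean distance in the retained bgPC space) with its own group's
centroid recomputed without it. The eigenbasis is **not** refit per fold
by default: centroid-distance classification as used here holds the
ordination fixed and the folds stay cheap; `refit = TRUE` refits fully
when the conservative protocol is wanted.

`typprob()` converts the squared Mahalanobis distance `d²` of a query to
a group centroid (under the pooled within-group covariance, divisor
`n − g`) into the upper-tail chi-square probability with `df` = retained
axes. These are typicalities, not forced posteriors: they do not sum to 1
across groups, and a value below 0.05 reads as "outside this group's
variability". A small-sample F variant is available (`method = "f"`),
and a ridge (`ridge · trace/p` on the diagonal) handles a near-singular
pooled covariance. The linkage for the clustering check and the
typicality tail are configurable because neither choice is canonical;
Ward linkage and the chi-square tail are the documented defaults.

## Phylogenetic signal

Under Brownian motion the tip values of a trait are multivariate normal
with covariance `σ² C`, where `C[i, j]` is the shared root-to-tip path
length. `phylo_covariance()` builds `C`; `lambda_transform(C, λ)` scales
its off-diagonal entries by `λ ∈ [0, 1]`, interpolating between the star
phylogeny (λ = 0, no signal) and full Brownian covariance (λ = 1).

`pagel_lambda()` profiles the mean and rate analytically
(`â = (1'C(λ)⁻¹1)⁻¹1'C(λ)⁻¹y`, `σ² = RSS/n`) so the search is
one-dimensional; a bounded golden-section/parabolic search with tolerance
`1e-6` runs on `[0, 1]` and both endpoints are evaluated explicitly, so
the reported optimum is never below either boundary. The p-value is a
likelihood-ratio test against λ = 0 on 1 df — the reference
implementations report λ with a p-value without naming the test, and the
LR construction is the natural companion of an ML estimate (a permutation
alternative exists for K and K_mult).

`blomberg_k()` implements the published estimator: observed over
Brownian-expected ratio of the mean squared deviation from the
phylogenetic mean â, with expectation term
`(tr C − n/(1'C⁻¹1))/(n − 1)`. `k_mult()` generalizes it to a tips ×
traits matrix: the summed squared Euclidean distances to the mean vector,
standardized by premultiplying the centered matrix with `C^{-1/2}` (from
the eigendecomposition of `C`); it reduces to K exactly at `p = 1`.
Significance for K and K_mult comes from shuffling trait values across
tips: `p = (1 + #[K_perm ≥ K_obs]) / (n_perm + 1)`, default 999
permutations, seed mandatory. K across permutations is computed
vectorized against the fixed `C` (the GLS weights do not depend on the
permutation), which keeps 500-replicate calibration experiments cheap.

Signal statistics are computed on **species means** (one value per tip).
The species-mean convention is an assumption: with ~5 individuals per
species the within-species sampling error is small relative to
among-species divergence, and one-value-per-tip is what the estimators
define.

All matrix solves go through Cholesky; if a covariance is not positive
definite, a single jitter of `1e-10 · tr(C)/n` is tried before failing.

### A calibration caveat

The test suite measures estimator calibration under the default study
conditions (27 tips on the reference chronogram). K and K_mult center on
1 under Brownian simulations as they should. The ML estimate of λ,
however, is strongly downward-biased at intermediate true values with
only 27 tips (mean λ̂ ≈ 0.34 at true λ = 0.5; mean ≈ 0.83 at true λ = 1,
where the `[0, 1]` boundary truncates the sampling distribution). The
estimator is numerically identical to the reference implementation — this
is a small-sample property of the likelihood itself, documented here so
that single-dataset λ values at this scale are read with appropriate
caution; the likelihood-ratio p-value remains well calibrated.

## Regression battery

`ols_fit()` is classical bivariate least squares with t-based standard
errors, 95% CIs and a two-sided slope test on `n − 2` df. `pgls_fit()`
is GLS with error covariance proportional to `C`, fit at λ = 1 (pure
Brownian covariance; the method description this mirrors does not
estimate λ simultaneously). Its R² is `1 − RSS_gls/TSS_gls` with the
total sum of squares about the **phylogenetic** mean — one of several
circulating conventions, so it is stated explicitly. OLS operates on
individuals; PGLS on species means (one tip each), which is why the two
report different `n`.

`shape_size_regression()` regresses all descriptor columns jointly on
size; its R² pools sums of squares across columns and its p-value comes
from permuting the size vector (seeded, ≥ 999). `ancova()` uses the
classical two-stage partial-F construction (interaction term for slope
homogeneity; group main effect in the common-slope model for
intercepts) via `stats::lm`/`anova`. A significant intercept shift with
homogeneous slopes is an allometric **grade shift** — parallel lines at
different heights, the signature reported for hominid versus non-hominid
canal proportions. `isometry_test()` reads the verdict from the position
of the isometric slope (default 1) relative to the 95% CI.

## Ancestral states and phylomorphospace

`ml_ancestral()` computes internal-node estimates as the conditional
expectation of the joint multivariate-normal Brownian model given the
tips, with the root at the GLS mean â. This joint-conditioning form is
exact and equals the re-rooted GLS (maximum-likelihood) estimator; it was
chosen over the two-pass pruning recursion for clarity — at ≤ a few
hundred nodes the dense solve is not a bottleneck, and the test suite
pins it to an independently assembled conditional-mean oracle at 1e-8.
Reported variances are conditional variances scaled by the ML Brownian
rate; they are zero at the root by construction (the root state is the
estimated mean). Zero-length terminal branches are refused by name — they
would make a tip's state both data and parameter.

`build_phylomorphospace()` places tips at their ordination scores on a
chosen axis pair and internal nodes at their ML estimates, with the
tree's edges connecting them. Because the estimator is linear in the tip
values, the whole construction is equivariant under affine transforms of
the score plane. `backproject()` inverts the bgPCA rotation (grand mean
plus score-weighted eigenvectors); for landmark provenance the result is
reshaped to `k × 3`, giving a synthetic ancestral configuration. For
deformation descriptors the reconstruction deliberately stops at the
descriptor vector: mapping a descriptor back onto a surface requires the
external diffeomorphic registration machinery, which is out of scope.

Fossils enter these analyses as dated tips via `attach_fossil_tip()`,
which grafts a terminal branch at a stated age on the stem lineage above
a named clade (e.g. a stem hominoid attached 1 Ma above the crown
hominoid node with its tip at its last occurrence), making the tree
non-ultrametric.

## The synthetic-data generator

`sim_config()` fixes the study conditions: the 27-species / 4-clade
reference chronogram (root 40 Ma) with 5 individuals per species
(n = 135, the scale of the 142-specimen study sample); `p = 12`
descriptors; Brownian rate 0.0025 per Ma per trait (tip SD ≈ 0.32);
clade offset vectors of norm 3 along distinct coordinate axes;
within-species SD 0.2; allometry with common slope 0.62, a +0.5 hominid
intercept (grade) shift, residual SD 0.1 and `ln L` uniform on
`[3, 4.2]`. These values were chosen once to reproduce the qualitative
structure of the study system — clean clade separation (> 95%
cross-validated classification), strong phylogenetic signal, a clear
grade shift — at realistic noise levels, and the calibration experiments
run against them unchanged.

The generator simulates Brownian species means edge-by-edge (recording
internal-node states as ground truth), adds clade offsets and i.i.d.
within-species noise, and emits the same file formats the pipeline
consumes; `simulate_allometry()` draws the measurement table;
`make_fossil_specimen()` interpolates between a clade mean and the root
state with a plesiomorphy weight `w`. Everything is deterministic given
the seed, and no recovery test reads truth through the pipeline under
test.

What the generator does **not** emulate: spatial autocorrelation among
descriptors (real deformation momenta covary strongly along the surface),
unbalanced and sexed sampling, measurement error correlated with size,
rate heterogeneity across clades, and any anatomical realism in the
landmark template (a stylized three-ring configuration standing in for
canal geometry). Passing recovery tests therefore demonstrate estimator
correctness under the assumed model, not robustness to these real-data
features.

## Problem sizes and reproducibility

The calibration experiments use the sizes that make their conclusions
stable while keeping the suite quick: 200 replicates per true λ, 500 for
K (300 for K_mult at p = 5), 500 outer replicates × 199 permutations for
the test-size check, 100 random cases for the GPA, bgPCA, ancestral-state
and PGLS oracle equivalences, and 200 replicates for CI coverage and
ANCOVA power. The staged pipeline derives one named substream per
stochastic stage from a single master seed, stamps every report with the
input-file hash and seed, and reproduces byte-identical outputs when
re-run from the same configuration.

## Known limitations

* λ at n ≈ 27 is imprecise at intermediate values (see above);
* PGLS is univariate-response only, matching the per-axis regressions it
  mirrors (no multivariate shape PGLS);
* no Ornstein–Uhlenbeck or early-burst alternatives, no rate-shift
  models, no Bayesian reconstruction;
* back-projection of deformation descriptors stops at the descriptor
  vector;
* the reference chronogram's node ages are nominal round figures — it is
  a fixture for simulation and examples, not a dated phylogeny for
  inference.
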