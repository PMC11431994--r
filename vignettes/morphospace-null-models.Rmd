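---
title: "Morphospace null models for polymorphic ant workers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphospace null models for polymorphic ant workers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

Polymorphic ants such as *Camponotus japonicus* produce two worker castes —
large-headed majors and smaller minors — whose morphology varies across a
species' range. Two population-level hypotheses make opposite predictions
about how environments structure this variation in **morphospace**, the
space spanned by the retained principal components of standardized
morphological traits:

* **Environmental filtering.** Harsh or homogeneous environments select
  against extreme phenotypes, *contracting* the region a population
  occupies. The diagnostic statistic is the convex-hull volume of a
  population sample: filtering predicts volumes *below* a null expectation
  drawn from the pooled species sample.
* **Optimal transfer.** Different environments favour different optimal
  phenotypes, *displacing* a population's location without necessarily
  contracting it. The diagnostic is the Euclidean distance between a
  population's centroid and the pooled centroid: transfer predicts
  displacements *above* the null.

`antmorph` implements this inferential pipeline end to end for a
hierarchical design of sites (crossing three climate zones MTZ/WTZ/STZ with
three habitat types F/SW/UP into nine "combos"), three colonies per site,
and eight continuous traits measured on workers of each caste. Castes are
analyzed fully independently; no operation mixes them.

# The morphospace model

Traits are standardized per caste (z-scores with the n−1 sample SD), and the
8×8 correlation matrix is eigendecomposed. The first four axes are retained
and varimax-rotated (orthogonal rotation with Kaiser row normalization, via
the classic pairwise-rotation algorithm). Workers' rotated scores are the
coordinates for everything downstream. Two conventions make results
reproducible across linear-algebra backends: each loading column's
largest-magnitude entry is made positive, and the rotation matrix inherits
the same sign fix.

Rotation is a rigid motion of the retained subspace, so the total retained
variance and the row communalities are invariant (asserted at 1e−8 in the
tests); the per-component shares are redistributed. Both raw and rotated
loadings are reported, and the rotated scores are the default for the null
models — if unrotated scores are wanted, the raw loadings are in the model
object. Whether published analyses of this kind use rotated or unrotated
scores downstream is often ambiguous; hull volumes are rotation-invariant,
so the filtering test is identical either way, and only the per-component
attribution of rank-test and regression effects changes.

# Null models

For each combo and caste:

* **Observed hull distribution** — 100 replicates; each draws one member
  site uniformly, then 10 workers of that site stratified over its three
  colonies (at least 3 per colony, the remainder assigned to a colony
  chosen uniformly), and computes the exact 4-D convex-hull volume.
* **Null hull distribution** — 1000 simple random 10-worker subsamples of
  the pooled caste; no colony constraint, since the pool is the reference.
* **Centroid test** — 1000 observed stratified-subsample centroid
  displacements vs 1000 pooled-subsample displacements.

Each observed/null pair is compared with a two-sided Mann–Whitney U test
(normal approximation with tie correction and continuity correction;
an exact enumeration mode exists for small samples) at the study's
stringent α = 0.001, with the direction reported from the median
difference.

The colony stratification exists because colonies are the natural unit of
within-site correlation: a colony random intercept makes nestmates
resemble one another, and unconstrained site subsamples could be dominated
by a single colony.

**Hull volumes are computed exactly**, not by kernel-density hypervolume
estimation: every d-subset of the m subsample points defines a candidate
hyperplane; supporting hyperplanes (all points on one side) are the hull
facets; the volume is the sum of pyramid volumes from the centroid, with
cohyperplanar facets (e.g. hypercube faces) projected into their flat and
handled recursively. The cost is choose(m, d) hyperplane tests — exact,
deterministic and fast for the m ≈ 10–20, d = 4 geometry used here, and
oracle-checkable against canonical solids (unit hypercube, unit simplex)
and Monte-Carlo rejection sampling. Affinely degenerate subsamples return
volume 0 and are retained, not redrawn.

## A calibration caveat

The replicate distributions are *resamples of one finite data set*, not
independent draws from the population. Conditional on the data, the
observed distribution concentrates around the drawn sites' local geometry,
whose sampling noise (hull volume scales as dispersion⁴) the
replicate-powered U test can resolve. The consequence, measured on
synthetic data with *no* planted effects and exchangeable workers, is that
combos are flagged at rates far above the nominal α — the test is
anti-conservative by construction. This is a property of the resampling
design itself and should temper the interpretation of blanket significance
across all populations in empirical studies of this type. What the test
*does* reliably measure is effect size and direction: under
exchangeability the observed/null median ratio is centred on 1, and a
planted variance shrink of 0.5 (or a 2-SD centroid shift) is recovered
with the correct direction in essentially every simulated data set — that
recovery, not null calibration, is the property the acceptance suite
verifies.

# Rank tests and regression

Per component and caste, a **Scheirer–Ray–Hare** test assesses climate
zone, habitat and their interaction: all n values are midranked jointly, a
two-way cell-means ANOVA decomposition is computed on the ranks (unweighted
means with the harmonic mean cell size, since sites are unevenly allocated
to combos), and `H = SS_effect / MS_total` is divided by the tie
correction `D = 1 − Σ(t³−t)/(n³−n)` and referred to χ² at the effect's df.
With the study design (3×3 layout, 462 workers per caste) the residual df
is 453. Bonferroni correction multiplies each raw p by the family size
m = 12 (3 effects × 4 components) and caps at 1; m = 12 is the family size
consistent with published corrected values of this analysis
(`p_corr = 12·exp(−H/2)` at df 2 reproduces every checkable cell) and is a
configuration parameter. Raw p-values in published tables of this kind are
not always consistent with their H statistics; the corrected column is the
one this package anchors to. A descriptive diagnostic report (cell
skewness, SD ratios) is provided instead of a normality gate — a rank test
needs none.

**Robust regression** of each component's scores on annual mean
temperature, annual mean precipitation, relative humidity and elevation
(untransformed) uses Huber M-estimation: IRLS with weights
`min(1, c·s/|r|)`, tuning constant c = 1.345 (95% Gaussian efficiency),
and the scale s re-estimated each iteration as the MAD (×1.4826, with a
mean-absolute-deviation fallback when the MAD is 0). Standard errors use
Huber's correction factor on the weighted least-squares covariance. By
default every worker is a regression unit with its site's covariates
repeated — matching the conventional presentation — but this
pseudoreplicates the 22 covariate values 21-fold, so a `unit = "site"`
mode that regresses site-mean scores on site covariates is provided and
recommended for honest uncertainty.

# The synthetic generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is validated.

* Design: 22 sites allocated as evenly as possible over the 9 combos, 3
  colonies per site, 7 workers per colony per caste (21 per site per
  caste, 462 per caste — the count consistent with a 3×3 rank-test
  residual df of 453).
* Environment: per-zone temperature bands decreasing from subtropical to
  mid-temperate within the study region's overall range (−0.65 to
  21.52 °C), precipitation 27.75–191.35 mm, elevation 35–1275 m,
  longitude 88–126 °E, latitude 24–47 °N. The relative-humidity range is
  not constrained by reported values; U(40, 80)% is an invented but
  climatically plausible default.
* Traits: multivariate Gaussian noise on the trait scale with an
  exchangeable correlation of 0.6 (one dominant size factor), baseline
  means/SDs plausible for a large *Camponotus* minor worker (SD 8% of the
  mean), and a caste offset making majors distinctly larger with
  disproportionately broad heads. Values are clipped positive and rounded
  to 1e−4 mm so CSV round-trips are exact.
* Hierarchy: a colony random intercept (default 0.3 trait SD, shared by
  both castes of a colony) motivates the ≥3-per-colony subsampling rule.
  The within/between-colony variance split is not derivable from published
  summaries; 0.3 is a placeholder exposed in the configuration.
* Planted effects (`effect_plan`): per-combo variance shrink
  (filtering), per-combo centroid shift in trait-SD units (transfer), and
  an 8×4 matrix of per-trait slopes on the centered covariates. The
  defaults plant nothing.

What the generator does **not** emulate: real allometry between traits and
castes, measurement error structure, spatial autocorrelation between
nearby sites, or the actual geography beyond coordinate ranges. Passing
recovery tests therefore demonstrates that the machinery detects effects
of the stated kind and size under Gaussian hierarchical noise — not that
the real species' effects are of that kind.

Two calibration properties deserve a note. Worker-level rank tests across
combos would be pseudoreplicated by the colony intercept, so the
generator's no-effect calibration is asserted on colony means (the
independent replicates). And the null-calibration of the resampling tests
is asserted as median agreement, not flag rates, for the reason in the
caveat above; the flag-rate statement is intrinsically unattainable for
this design and is documented rather than weakened.

# Numerical choices

* PCA eigenvalues are clamped at 0; loadings sign-fixed as above.
* Varimax converges on a criterion increase < 1e−8; k < 2 returns the
  input with a unit rotation.
* Mann–Whitney switches from exact enumeration to the normal
  approximation above n+m = 16; ties use midranks throughout, and the
  exact mode is a conditional (permutation) test given the observed ties.
* Huber IRLS starts from OLS, declares convergence at max coefficient
  change < 1e−8 (≤ 50 iterations), and treats a near-zero MAD as an exact
  fit.
* All pipeline randomness derives from one master seed via fixed
  per-stage streams, so changing one stage's replicate count never
  perturbs another stage, and reruns are bit-identical.

# Problem sizes used in validation

The test suite validates at the study's own scale where that is what the
claim concerns (100 hull / 1000 null replicates, 462 workers per caste;
planted-effect recovery over 50 seeds) and at reduced scale for
smoke/reproducibility checks (5–30 replicates). The Monte-Carlo hull
oracle uses 10⁶ draws per point set on 20 sets; the rank-test type-I
calibration uses 1000 null simulations of a balanced 3×3 layout.

# Known limitations

* The resampling null models are anti-conservative at the significance
  level (see the caveat); treat flags as effect-size screening.
* The worker-level regression mode understates environmental-slope
  uncertainty; prefer `unit = "site"` when inference matters.
* The exact hull algorithm is combinatorial in m and d; it is intended
  for subsample-sized point sets, not thousands of points.
* With only 2–3 sites per combo, the combo-level observed distributions
  mix very few conditional geometries; site-level units
  (`analysis_config(unit = "site")`) are available when per-site inference
  is wanted.
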