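# antmorph

Morphospace null models for polymorphic ant worker traits.

## The problem

How do climate and habitat structure intraspecific morphological variation?
For a polymorphic ant (two worker castes, eight continuous traits measured
per worker) sampled hierarchically — sites crossing three climate zones
(MTZ, WTZ, STZ) with three habitat types (farmland F, sparse woodland SW,
urban park UP), three colonies per site — two hypotheses make opposite
predictions in **morphospace**, the space of the first four varimax-rotated
principal components of the standardized traits:

* **Environmental filtering**: selection in harsh/homogeneous environments
  *contracts* the occupied region — a population's convex-hull volume
  `V(hull(X))` falls below the pooled-null expectation.
* **Optimal transfer**: different environments favour different optima and
  *displace* a population — the centroid distance `‖x̄_pop − x̄_pool‖₂`
  exceeds the null.

`antmorph` implements the full inferential pipeline for both castes
analyzed independently:

1. per-caste standardization, PCA on the correlation matrix, varimax
   rotation, scores (`build_morphospace()`);
2. colony-stratified subsampling (10 workers, ≥3 per colony) and **exact**
   4-D convex-hull volumes; observed vs pooled-null distributions compared
   by Mann–Whitney U at p < 0.001 (`hull_test()`, `centroid_test()`,
   `run_null_models()`);
3. Scheirer–Ray–Hare two-way rank tests (climate × habitat per component,
   `H = SS_effect/MS_total/D` referred to χ², Bonferroni family m = 12)
   (`scheirer_ray_hare()`, `srh_by_component()`);
4. Huber IRLS robust regression (c = 1.345, MAD scale) of scores on
   temperature, precipitation, humidity and elevation
   (`huber_irls()`, `fit_pc_environment()`);
5. a synthetic-data generator reproducing the hierarchical design with
   planted variance-shrink, centroid-shift and environment-slope effects
   (`generate_sites()`, `generate_workers()`, `effect_plan()`).

## Worked example: the analysis workflow

The `analysis/` scripts run the whole study on synthetic data with two
planted effects — a variance shrink of 0.5 in MTZ.F and a +2 SD head-width
shift in WTZ.SW:

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_morphospace.R
Rscript analysis/03_null_models.R --seed 1
Rscript analysis/04_rank_tests.R
Rscript analysis/05_regression.R
```

Output of the first three stages (seed 1):

```
Simulated 22 sites / 924 workers ( 462 major, 462 minor )
Planted effects: hull shrink 0.5 in MTZ.F; +2 SD head width in WTZ.SW

Morphospace model (major workers, n = 462)
  retained components: 4
  variance explained (raw PC1-4): 61.87% 6.81% 5.94% 5.76%  [total 80.39%]

Hull-volume tests:  9 of 18 combos significant at p < 0.001
  smallest observed/null ratio: MTZ.F (0.07)
Centroid tests:  14 of 18 combos significant
  largest displacement: WTZ.SW
```

Reading this: the dominant size axis carries ~62% of trait variance (the
traits share a strong common size factor); the shrunk combo MTZ.F occupies
7% of the null hull volume and is flagged as filtered in both castes; the
shifted combo WTZ.SW shows the largest centroid displacement. Tables land
in `results/` (`null_models.csv`, `srh_tests.csv`, `regression.csv`,
per-caste scores and loadings). Note that centroid tests also flag some
unshifted combos — the resampling design is anti-conservative at the
significance level (see the methods vignette's calibration caveat), so
flags should be read together with the effect sizes.

The same pipeline is callable as one function:

```r
library(antmorph)
report <- run_pipeline(default_pipeline_config(seed = 1), "results")
report$null_models
```

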