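# fcreconfig

Rest-to-task functional network reconfiguration analysis for load-graded
working memory fMRI, with a validated synthetic cohort generator.

## The problem

Functional connectivity (FC) keeps a broadly similar architecture between
rest and task, but the connectome reorganizes when a task begins and as its
demands grow. **FC similarity** — the Pearson correlation, Fisher
r-to-z transformed, between two vectorized FC matrices — quantifies that
reorganization: high similarity means the resting configuration was already
near the task configuration (little, i.e. *efficient*, reconfiguration).
`fcreconfig` implements the full analysis for a spatial working memory
(SWM) paradigm with three memory loads (1/3/5 dots) in two age groups:

* **Signal conditioning** of parcellated ROI time series (430 ROIs, nine
  networks): volume trimming, joint task-activation + nuisance regression
  (double-gamma HRF, seven event classes with temporal derivatives, six
  motion parameters, CSF/WM/global signals), detrend + 0.009–0.1 Hz
  band-pass for rest realized as one exact projection, framewise
  displacement QC (max abs displacement ≤ 4 mm, max FD ≤ 2 mm, easy-load
  accuracy > 0.5).
* **Connectivity and similarity**: per-condition Fisher-z FC (rest, each
  load, optionally each load × run); global / intranetwork / internetwork
  FC similarity for rest–task, stepwise (adjacent demand levels) and
  within-load comparisons; averaged-FC validation measures. Edge sets obey
  the exact partition identity Σ|intra| + ½Σ|inter| = R(R−1)/2.
* **Inference**: group × load models
  `y ~ age_group * load + sex + task_motion + rest_motion + scanner` with
  either fixed-effects extra-sum-of-squares F tests (denominator df
  N − p; the default) or a random-subject-intercept model with
  Satterthwaite df; Tukey HSD post hocs over the six cell means; a
  per-network Bonferroni gate at 0.05/9 ≈ 0.006; covariate-adjusted partial
  Spearman brain–behavior associations with subject-resampling bootstrap
  SEs (10,000 iterations at reporting scale).
* **Synthetic cohorts**: block-structured rest covariances (within- vs
  between-network correlation per group), load-specific task covariances as
  convex mixtures toward a label-permuted topology with per-subject mixing
  weights, planted accuracy–reconfiguration coupling, motion artifacts,
  drift, nuisance leakage and evoked components — so every stage is
  testable without restricted data.

## Worked example

```r
library(fcreconfig)

spec <- cohortSpec(nYoung = 10, nOld = 10, R = 60)   # reduced 60-ROI scheme
cfg  <- pipelineConfig(spec = spec, seed = 11)
res  <- runPipeline(cfg, outDir = "demo_out")

subset(res$fits$rest_task_global$terms, term %in% c("age_group", "load"))
#>        term          F df1 df2            p
#> 1 age_group 334.268020   1  47 5.324722e-23
#> 2      load   1.843133   2  47 1.695812e-01

aggregate(z ~ pair, data = subset(res$similarity, scope == "global" &
                                  comparison == "rest_task"), mean)
#>        pair         z
#> 1 dot1-rest 0.3058492
#> 2 dot3-rest 0.3045046
#> 3 dot5-rest 0.2783133
```

The model table shows the planted age-group difference in global rest–task
similarity recovered through the full pipeline (older simulated adults
reconfigure more, so their similarity is lower), and mean similarity
declines with memory load. `res$associations` holds the partial Spearman
table pairing each similarity value with accuracy at the matching load;
`writeReport(res, "demo_out/report")` writes group × load summary tables
and, when ggplot2 is present, bar figures.

A command-line front end wraps the same functions:

```sh
inst/scripts/reconfig-swm simulate --config cohort.yaml --out cohort_dir --seed 7
inst/scripts/reconfig-swm run-all  --config cohort.yaml --out results_dir --seed 7
```

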