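---
title: "Rest-to-task functional network reconfiguration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rest-to-task functional network reconfiguration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcreconfig)
```

# The scientific problem

Functional brain networks keep broadly similar architectures at rest and
during tasks, yet the connectome reorganizes measurably when a task begins
and as its demands grow. A compact way to quantify that reorganization is
*FC similarity*: the correlation between two vectorized functional
connectivity (FC) matrices. High similarity between rest and task means the
resting configuration was already close to the task configuration — little
reconfiguration was needed, which is commonly read as *efficient*
reconfiguration. This package implements a complete analysis of FC
similarity for a spatial working memory (SWM) paradigm with three memory
loads (1, 3, or 5 dot positions, "dot1/dot3/dot5"), in two age groups, from
parcellated BOLD time series to group-level inference and brain–behavior
associations. Because the human data this design targets cannot be
redistributed, the package also ships a synthetic cohort generator that
plants the structure the analysis is built to detect; every pipeline stage
is validated against it.

# Data model

ROI time series follow a 430-region parcellation: 400 cortical regions plus
30 subcortical regions, grouped into nine networks (ECN, DMN, DAN, LN, SN,
SMN, TP, VIS, SUB) in a fixed canonical order, so that same-network region
pairs form the diagonal blocks of any FC matrix. `makeParcellation(R)`
produces proportionally reduced schemes for simulation work; all similarity
measures are invariant to the within-network ordering, so any fixed order
is adequate.

Each subject contributes one resting run (235 retained volumes, TR 2 s) and
two task runs (~175–185 retained volumes each). A task run holds three
10-trial blocks, one per load, in randomized order, separated by 4 s
baselines. A trial is: blank 1 s, fixation 0.5 s, encoding 0.5 s per dot,
maintenance 3 s, probe 2 s (response by button press within the probe
window), then an inter-trial blank jittered 2.5–4.5 s. Pooled over the two
runs, each load contributes 20 trials per subject. Onsets are expressed in
seconds from the first *retained* volume; volume $t$ (0-based) spans
$[t\,\mathrm{TR}, (t+1)\,\mathrm{TR})$.

# Signal conditioning

The pipeline starts at parcellated time series; voxel-level preprocessing
(registration, smoothing, tissue segmentation) is out of scope. Five
leading volumes are discarded from every run.

**Task runs.** Task activation and nuisance signals are removed in a single
joint ordinary-least-squares model per region. Activation regressors are
boxcars for seven event classes — encoding (one boxcar spanning all dots of
a trial), maintenance, probe, response (an impulse at the button press),
inter-trial fixation/blanks, and correct-trial / wrong-trial spans —
convolved with a canonical double-gamma hemodynamic response function
(response peak 6 s, undershoot peak 16 s, undershoot ratio 1/6,
peak-normalized), each paired with its temporal derivative (the first
difference of the convolved regressor; a simple, standard choice).
Nuisance regressors are the six rigid-body motion parameters, CSF and WM
mean signals, and the global signal. Joint rather than sequential
regression avoids any dependence on the order of the two projections;
regressors that are identically zero (e.g. the wrong-trial class in an
error-free run) are dropped and logged. The correct/wrong spans cover the
whole trial from its leading blank through the probe; spanning only
encoding-to-probe would make correct + wrong an exact linear combination of
the other activation boxcars and the model rank deficient.

**Rest runs.** After the same nuisance regression, rest data are detrended
and band-pass filtered in one step: a least-squares projection removes the
order-2 polynomial trend together with every Fourier component outside
0.009–0.1 Hz. Implementing detrend + band-pass as a single orthogonal
projection gives exact band edges, zero phase distortion, and idempotence
to machine precision — re-running the rest pipeline on its own output
changes nothing, which is also how the package's invariant tests check it.
A tapered frequency mask was considered and rejected: taper gains square on
re-application, and a separate detrend does not commute with the filter, so
that construction cannot be idempotent.

**Load blocks.** For each load, the volumes whose midpoints fall inside the
block interval (first trial onset to last trial end) are kept; within-block
inter-trial blanks are trial structure and are retained, while the 4 s
inter-block baselines are discarded. Each run's segment is mean-centered
per region (residuals are near-zero-mean anyway; this removes any residual
per-segment offset before concatenation) and segments are concatenated in
run order. No hemodynamic-lag shift is applied at extraction: the
activation regression has already absorbed the evoked lag.

**Motion.** Framewise displacement uses the Power convention,
$\mathrm{FD}_t = \sum |\Delta d_i| + 50\,\mathrm{mm} \sum |\Delta
\theta_i|$; this single definition stands in for the various
software-specific "relative motion" summaries and is labeled explicitly
wherever it is used. Inclusion requires easy-load accuracy strictly above
0.5, maximum absolute displacement ≤ 4 mm, and maximum FD ≤ 2 mm in every
run.

# Connectivity and similarity

FC is the Pearson correlation between conditioned regional time courses,
clipped to $|r| \le 1 - 10^{-7}$ and Fisher r-to-z transformed. The clip
keeps z finite on degenerate synthetic fixtures and is inert for realistic
correlations. The diagonal is undefined: it is stored as 0 and excluded
from every edge set by construction, never by inspecting values.

FC similarity between two conditions is the Pearson correlation (again
clipped and z-transformed) of the two edge-value vectors over an *edge
set*:

* `global` — all $R(R-1)/2$ distinct pairs (the lower triangle);
* `intra:n` — pairs with both regions in network $n$ (9 sets);
* `inter:n` — pairs with exactly one region in network $n$ (9 sets).

Each cross-network edge belongs to the inter sets of both endpoint
networks, so inter sets overlap pairwise and the partition identity
$\sum_n |\mathrm{intra}:n| + \tfrac12 \sum_n |\mathrm{inter}:n| =
|\mathrm{global}|$ holds exactly; it is asserted in the tests for every
scheme.

Three comparison menus are produced per subject: rest–task (dot1–rest,
dot3–rest, dot5–rest), stepwise between adjacent demand levels (dot1–rest,
dot3–dot1, dot5–dot3), and, as a stability control, within-load similarity
between the two runs' FC matrices at the same load. A scope whose edge set
has fewer than 3 edges (e.g. the intra set of a 2-region network in a
reduced scheme) yields an explicit missing record with a reason code rather
than a silent drop. Averaged FC (mean z over each of the 19 edge sets per
condition) is available as the connectivity-strength counterpart used in
validation analyses.

# Inference

**Group-by-load models.** The long table (one row per subject per load or
load pair) is fit with
`y ~ age_group * load + sex + task_motion + rest_motion + scanner`,
where the motion covariates are mean FD in the task and rest runs (rest
motion is set to zero exactly for the two stepwise pairs that involve no
rest data). Two df constructions are shipped because the printed df
conventions in this literature are ambiguous between fixed-effects and
mixed-model readings:

* `paper_ols` (default): fixed-effects least squares; each term's F is the
  classical extra-sum-of-squares F of dropping that term's columns, with
  denominator df $N - p$ where $p$ counts the estimable coefficients. In a
  143-subject, three-load, single-scanner design, $p = 9$ and the
  interaction is tested on $F_{2,420}$. Constant covariates are dropped
  with a warning (they are not estimable); a scanner assignment confined to
  one level within a group is warned about but retained.
* `lmm_satterthwaite`: a random subject intercept with
  Satterthwaite-approximated denominator df, the statistically principled
  treatment of the repeated measures.

Post hoc contrasts are Tukey-HSD-adjusted comparisons of the six
group-by-load cell means (15 contrasts). Network-level model p values are
gated by Bonferroni across the nine networks ($\alpha = 0.05/9 \approx
0.006$); global tests are reported at uncorrected $\alpha = 0.05$. This
two-tier scheme is deliberate: one global test needs no multiplicity
control, the nine per-network tests do.

**Brain–behavior associations.** Partial Spearman correlations are
computed by rank-transforming x, y, and every covariate (average ranks for
ties), residualizing the ranked x and y on the ranked covariates plus an
intercept, and correlating the residuals; $p$ comes from
$t = \rho\sqrt{(n-2-k)/(1-\rho^2)}$ on $n-2-k$ df. With no covariates this
reduces exactly to plain Spearman, and the estimate is invariant under
strictly monotone transforms of any variable — both are asserted in the
tests. Covariates are age, sex, and mean task FD; mean rest FD is added for
pairs involving rest; scanner is added for the older group. The pairing
rule matches each similarity pair with behavior at its task load, and
stepwise pairs with the higher of the two loads. Bootstrap standard errors
resample subjects (the exchangeable unit) with replacement — 10,000
iterations at reporting scale; degenerate resamples are skipped and
counted.

# The synthetic cohort generator

The generator is first-class, tested code; it defines the conditions under
which the package demonstrates recovery. Structure planted, with defaults:

* **Segregation.** Rest covariance is block-structured: unit variance,
  within-network correlation $w$ (young 0.35, old 0.25), between-network
  correlation $b$ (young 0.05, old 0.12) — older adults get lower
  segregation, and both values are spec-level defaults.
* **Reconfiguration.** The task covariance at load $\ell$ is the convex
  mixture $(1-\lambda)\Sigma_\mathrm{rest} + \lambda\Sigma_\mathrm{alt}$,
  where $\Sigma_\mathrm{alt}$ is the rest covariance under a fixed seeded
  permutation of the region labels. A label permutation preserves the
  spectrum (so every mixture is positive definite by construction) while
  genuinely rearranging the intra/inter block structure — exactly the
  change the similarity metric must detect; a random rotation would have
  destroyed the block semantics. Group-by-load weights
  $\lambda_{g,\ell}$ default to young (0.10, 0.18, 0.26) and old
  (0.28, 0.36, 0.44): non-decreasing in load, old above young at every
  load. Subject heterogeneity enters once, as a per-subject offset
  $\delta_i \sim N(0, \tau)$ with $\tau = 0.08$, chosen so that individual
  differences are comparable to about half the group gap — large enough to
  carry a recoverable brain–behavior association, small enough not to
  swamp the group structure.
* **Behavior.** Per-trial correctness is Bernoulli with
  $p = \mathrm{logit}^{-1}(a_0 - a_1\lambda_{i,\ell} - \mathrm{load}_\ell -
  \mathrm{group}_g + \varepsilon_i)$, defaults $a_0 = 3.2$, $a_1 = 6$,
  load penalties (0, 0.4, 0.8), group penalty 0, subject noise SD 0.25.
  These put mean accuracy near 0.93/0.85/0.70 for young and 0.82/0.65/0.44
  for old across the three loads — high at the easy load, near the working
  memory capacity limit at five dots — and make accuracy decrease in
  $\lambda$, planting the positive similarity–accuracy association
  ($a_1 > 0$). The group penalty defaults to zero so that the entire
  planted group difference flows through the reconfiguration mechanism;
  response times are lognormal, increasing in load and $\lambda$,
  truncated at the 1.95 s response window.
* **Artifacts.** Quadratic drift per region; an FD-locked rank-one motion
  artifact (so nuisance regression is consequential and testable); CSF/WM
  series leaking into regional data; an HRF-convolved evoked component
  built from the same event classes the conditioning models, with unit
  gain. Motion parameters are random walks scaled to a per-subject FD
  level drawn lognormally around the group mean (0.05 mm young, 0.07 mm
  old) with about 40% coefficient of variation, matching the wide
  between-subject motion spread such cohorts report; without that spread
  the FD covariates would be nearly collinear with the age-group factor.

What the generator does *not* emulate: spatially structured noise,
physiological (cardiac/respiratory) signals, scanner-upgrade effects beyond
a labeled covariate, non-stationary task strategies, or spatial
autocorrelation within networks. Passing recovery tests therefore shows the
pipeline detects the planted covariance-level structure at realistic
sample sizes and noise levels — not that it is robust to every artifact of
real BOLD data.

# Validation studies and their null arms

`groupEffectStudy()` simulates replicate 40+40-subject cohorts at 60
regions and tests recovery of the age-group effect on global rest–task
similarity through the full pipeline. Its null arm equalizes *every*
group-dependent generative parameter — $\lambda$, $w$, $b$, and the motion
level. Equalizing $\lambda$ alone is not a null: different $w/b$ change
the spread of true edge values and hence how much sampling noise attenuates
the similarity estimate, and different motion levels leak through the
FD-locked artifact beyond what the linear FD covariates absorb. Either
residual difference would be (correctly) detected by the model, which is
informative about sensitivity but useless for calibrating the false-positive
rate.

`couplingStudy()` simulates single-group cohorts (n = 100) and recovers
the planted positive partial Spearman between dot3–rest similarity and
dot3 accuracy; its null comparison reuses the same similarity values but
regenerates behavior with $a_1 = 0$, so the null is exact and costs no
additional fMRI simulation. `spearmanCalibrationStudy()` and
`bootstrapCalibrationStudy()` check the type-I error of the partial
Spearman test and the bootstrap SE against the empirical sampling SD.

Problem sizes in the shipped tests and in `scripts/acceptance.R` (60
regions; 50–100 replicates in the test suite, roughly half that in the
acceptance script; 1,000–2,000 calibration draws) are the package's chosen
simulation scale: large enough for the binomial bands asserted, small
enough to run routinely.

# Numerical choices and degenerate inputs

* Correlation clip at $1 - 10^{-7}$ before `atanh`, everywhere a
  correlation is z-transformed.
* FC requires ≥ 3 timepoints and positive variance in every region; edge
  sets require ≥ 3 edges; partial Spearman requires $n \ge k + 4$. Each
  violation is a typed, named error (or a reasoned missing record where
  the operation's contract calls for one).
* Boxcars are sampled by exact fractional overlap with each volume;
  zero-duration events become unit impulses in their containing volume.
* Ties in any ranked variable get average ranks.
* Seeds: every stochastic stage derives its stream from a global seed and
  a stage/subject label via a 31-bit hash (`deriveSeed`), so any subject or
  stage can be regenerated in isolation and full reruns are byte-identical.

# Known limitations

* The FD definition approximates, with one convention, the several motion
  summaries real preprocessing stacks report.
* `paper_ols` treats repeated measures with covariates only; it reproduces
  the fixed-effects df convention but understates subject-level
  correlation. Use `lmm_satterthwaite` when the inferential target is the
  population.
* The generator's evoked component uses the same HRF family the
  conditioning assumes; it cannot probe HRF misspecification.
* Network-level inference inherits the usual caveats of overlapping inter
  sets: the nine inter tests are not independent, and the Bonferroni gate
  is conservative.
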