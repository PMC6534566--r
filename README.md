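# fcvcm — static and dynamic functional connectivity as variance components of behavior

`fcvcm` quantifies how much inter-subject variability in behavioral
measures is explained by inter-subject variability in resting-state
functional connectivity (FC), contrasting two descriptions of the same
recordings:

* **static FC** — the ROI × ROI Pearson correlation matrix, and
* **dynamic FC** — the coefficient matrix *A* of a first-order
  autoregressive model, `x_t = A x_{t-1} + e_t`, which captures lag-one
  temporal structure that correlation averages away.

It is written for researchers in connectomics and neuro-behavioral
statistics who want a tested, end-to-end implementation of this analysis
chain: motion scrubbing (FD/DVARS), nuisance regression, FC estimation,
inter-subject similarity kernels (whole-brain and network-block), a
multi-kernel variance component model, delete-one jackknife inference with
FDR control, and a synthetic cohort generator with exact ground truth for
validation.

## The model

With `Y` the subjects × measures behavioral matrix (covariates regressed
out, measures rank-normalized) and `F` a subjects × subjects similarity
kernel — `F(i, j)` = correlation between subject *i*'s and subject *j*'s
vectorized FC —

    Y = C + E,   Vec(C) ~ N(0, Σ_c ⊗ F),   Vec(E) ~ N(0, Σ_e ⊗ I)

and the behavioral variance explained by FC is the trace ratio

    M = Tr(Σ_c) / (Tr(Σ_c) + Tr(Σ_e)),
    M_i = Σ_c(i,i) / (Σ_c(i,i) + Σ_e(i,i))   per measure.

Σ̂ matrices come from a MINQUE-type moment estimator (double-centered
kernels, reweighted working covariance; see the methods vignette), with a
univariate REML implementation as an independent cross-check. Model
comparisons (dynamic vs static, combined vs dynamic, per-measure T
statistics, task/self category contrasts and their interaction) use the
delete-one jackknife with a normal approximation, and Benjamini–Hochberg
FDR where families of tests arise.

## Worked example

The default configuration generates a 120-subject synthetic cohort
(40 ROIs in 8 networks, 2 runs × 600 frames, 24 behavioral measures of
which 10 are task-performance and 10 self-reported), runs the full
pipeline, and writes `report.json` plus flat tables:

```r
library(fcvcm)
report <- runAll(defaultCohortConfig(seed = 1), outDir = "out")
#> [fcvcm] cohort ready: 120 subjects (7.78s)
#> [fcvcm] FC estimated: mean AR R2 = 0.687 (1.61s)
#> [fcvcm] M(static) = 0.107, M(dynamic) = 0.212, M(combined) = 0.268 (0.02s)
#> [fcvcm] dynamic vs static: dM = 0.103 (z = 4.34, p = 1.43e-05) (5.28s)
#> [fcvcm] network-block fits done (1.12s)

head(report$ranking[, c("measure", "T", "dMi", "category", "rank")], 5)
#>   measure    T   dMi category rank
#> 1 task_09 4.39 0.248     task    1
#> 2 task_06 4.06 0.332     task    2
#> 3 task_04 3.82 0.307     task    3
#> 4 task_08 3.55 0.208     task    4
#> 5 task_02 3.06 0.203     task    5
```

Reading these numbers: the AR model reproduces about 69% of the
Frobenius mass of the data covariance (`R2 = 0.687`), dynamic FC explains
about twice the behavioral variance of static FC (`M = 0.212` vs `0.107`;
jackknife z = 4.34), and the best-ranked measures — those preferentially
explained by dynamic FC — are task measures, by construction of the
synthetic cohort's ground truth. The combined two-kernel fit (`M = 0.268`)
attributes 84% of its explained trace to the dynamic kernel, and does not
beat the dynamic-only fit beyond jackknife error — the static kernel's
information is largely contained in the dynamic one.

Lower-level entry points: `computeCensorMask()`, `regressNuisance()`,
`staticFC()`, `dynamicFC()`, `fcSimilarityKernel()`, `fitVCM()`,
`jackknifeCompare()`, `blockDecompositionKernels()`, `blockContributions()`,
and the generator family `makeParcellation()`, `sampleSubjectAR()`,
`simulateRun()`, `simulateMotion()`, `simulateBehavior()`, `buildCohort()`.

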