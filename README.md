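# migtensor

Spatio-temporal tensor co-clustering of migration flow networks.

## What problem this solves

Migration scholarship has long posited *migration systems*: sets of origin
and destination geographies that keep exchanging people over time with a
shared temporal rhythm. Snapshot community detection on yearly flow
networks finds a different partition every year and so describes change,
not stability. `migtensor` instead treats the whole record as one
three-way array and finds the systems that persist across it, for anyone
analyzing origin–destination count panels: county-to-county
administrative extracts, harmonized international flow estimates, or any
directed weighted network observed over time.

## The model

The data tensor `X ∈ R^{I×I×K}` holds the number of movers from geography
*i* to geography *j* in period *k*. Each migration system is one
nonnegative rank-one component, and the model is the nonnegative
canonical polyadic (CP) decomposition

    X ≈ Σ_f λ_f · a_f ∘ b_f ∘ c_f ,   A, B, C ≥ 0,

where `a_f` weights the system's origins, `b_f` its destinations, and
`c_f` its activity per period. Diagonal cells `X(i,i,k)` carry no
between-unit flow information, so the fit minimizes the *masked*
least-squares objective

    ‖ W ⊛ (X − Σ_f a_f ∘ b_f ∘ c_f) ‖_F² ,

with a binary weight tensor `W` that zeroes every diagonal cell (and any
declared-missing cell, e.g. privacy-censored small flows). The solver
alternates EM-style imputation of masked cells with HALS nonnegative
column updates, giving a monotone objective; factor columns are
normalized to unit Euclidean norm and the absorbed scales `λ_f` rank the
systems by importance. Downstream tools extract per-system memberships,
within-system membership probabilities, top-k association matrices
`ã_f b̃_fᵀ`, temporal shock flags, pre/post-event aggregate matrices, and
whole-region classifications.

## A worked example

```r
library(migtensor)

## a synthetic county-scale extract with three planted systems,
## one carrying a displacement-event spike in 2005
sim <- generatePlanted(plantedSpec(seed = 1))
x   <- sim$tensor
x
#> FlowTensor: 30 geographies x 29 periods (1990..2018)
#>   masked-in cells: 25230 of 26100; total off-diagonal flow: 102794

## how many systems? residuals flatten after rank 3
rankScan(x, 1:6, seed = 1)
#>   rank relResidual
#> 1    1   0.7039886
#> 2    2   0.5011592
#> 3    3   0.1141248
#> 4    4   0.1115467
#> 5    5   0.1096249
#> 6    6   0.1077297

fit <- fitNCPD(x, rank = 3, seed = 1)
fit
#> CPModel: 3 migration system(s), 30 geographies x 29 periods
#>   lambda: 1960, 1389, 1384
#>   final masked objective: 96746.3 after 14 outer iteration(s) (converged)

extractSystem(fit, 1, kTop = 5)
#> MigrationSystem 1 (lambda = 1960)
#>   top origins:      G15, G07, G09, G27, G22
#>   top destinations: G22, G02, G13, G18, G21

## the most important system carries the planted 2005 shock:
## its intensity that year is 8.1x the median of all other years
shockScan(extractSystem(fit, 1))
#>   period index   score
#> 1   2005    16 8.08426

## recovery against the planted truth (factor match score, 1 = perfect)
factorMatchScore(fit, sim$truth)
#> [1] 0.9994531
```

The residual table reads as: one and two components leave 70% and 50% of
the masked flow mass unexplained, the third drops the residual to 11%
(the Poisson noise floor), and further components buy almost nothing —
the drop-ratio elbow (`elbowRank`) lands on 3, the number of planted
systems. The `shockScan` row says system 1's 2005 intensity is 8.1 times
its typical level: the planted displacement event, found and dated.

A command-line interface wraps the same pipeline
(`inst/scripts/migtensor`, subcommands `simulate`, `fit`, `scan`,
`extract`, `classify`, `aggregate`, `benchmark`), writing factor CSVs, a
JSON systems report and full reproducibility metadata per run. See the
vignette (`vignettes/migration-systems.Rmd`) for the model's assumptions,
parameter meanings and limitations.

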