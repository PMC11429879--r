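# tAgeClock

Transcriptomic age prediction from bulk RNA-seq counts with a Poisson
maximum-likelihood clock.

Aging research needs biomarkers that read biological age off molecular
profiles. Linear penalized regressions (Elastic Net) dominate the clock
literature but assume linear feature–age relationships, need heavy
hyperparameter tuning, and fail when features are missing from a test
sample. `tAgeClock` implements a count-native alternative for bulk RNA-seq:

1. **Training** — normalize counts to frequencies
   (count / library size), smooth each gene's frequency-vs-age trend with
   LOWESS (tri-cube locally weighted linear regression, neighborhood
   fraction τ, default 0.7), rank genes by the absolute Spearman
   correlation |ρ| of frequency with age, and tabulate the top *N*
   (default 12) genes' expected frequencies on a discrete age grid
   (default 1, 3, 6, …, 27 months).
2. **Prediction** — for a test sample with total count *T* and observed
   count *k<sub>g</sub>* at reference gene *g*, score every grid age *x*
   by the summed Poisson log-likelihood

   ℓ(x) = Σ<sub>g</sub> [ k<sub>g</sub> log(f<sub>g,x</sub> T) −
   f<sub>g,x</sub> T − log k<sub>g</sub>! ]

   and report the maximizing grid age as the transcriptomic age (tAge).
   Reference genes absent from the sample are simply dropped; zero counts
   are observations.

The package is aimed at people building or auditing aging clocks: it ships
a leave-one-out cross-validation harness with an auditable fold log,
accuracy metrics (MAE, Pearson r, R² both as r² and as coefficient of
determination), a residual-bias diagnostic (LOWESS trend and Spearman ρ of
age acceleration vs. age), the standard two-pass Elastic-Net baseline
protocol (8 × 11 hyperparameter grid via glmnet), and a seeded synthetic
cohort generator so every claim is testable without downloading data.

## Worked example

```r
library(tAgeClock)

sim <- simulateCohort(cohortSpec(seed = 1))   # 40 samples, 2001 genes
ref <- buildReference(sim$cohort, tau = 0.7, nGenes = 12)
ref
#> ClockReference: 12 genes, 10 grid ages ( 1-27 months )
#>   tau = 0.7 ; frequency floor = 1e-09
#>   |rho| range: 0.919 - 0.950
#>   top genes: sig0081_linear_dn, sig0029_linear_dn, sig0061_linear_dn, ...

head(predictAge(sim$cohort, ref), 3)
#>   sample predicted_age_months genes_used max_loglik
#> 1   s001                   24         12  -43.84374
#> 2   s002                    9         12  -38.09204
#> 3   s003                   18         12  -43.72355

loocvClock(sim$cohort, tau = 0.7, nGenes = 12)
#> ValidationReport (clock): 40 samples
#>   MAE = 0.400 months; Pearson r = 0.993
#>   R2 (squared Pearson) = 0.985; R2 (coeff. of determination) = 0.985
```

The reference selects 12 of the 200 planted age-associated genes (|ρ| ≈
0.92–0.95); under leave-one-out cross-validation the clock predicts 85% of
samples to the exact grid age and is off by 0.4 months on average — well
under the 3-month grid spacing. `residualBias()` on the same report gives
the age-acceleration trend and its Spearman ρ; `loocvElasticNet()` runs
the linear baseline on the identical cohort for comparison.

A thin command-line front end over the same functions lives at
`inst/cli/tageclock` (`simulate`, `build-ref`, `predict`, `loocv`
subcommands; every output embeds its resolved configuration).

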