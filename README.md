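# kdeebm

Event-based disease progression modelling with kernel-density mixtures,
for biostatisticians and clinical researchers who want to know *in what
order* a set of biomarkers or cognitive test scores becomes abnormal over
the course of a progressive disease — using only cross-sectional data.

## The model

A disease is modelled as a monotone accumulation of *events*: per-marker
transitions from a control-like to a patient-like distribution. For `M`
markers measured on `N` subjects, the likelihood of an ordering `S` sums
each subject over all latent stages `m` (number of events accrued):

```
Pr(X | S) = Π_j  Σ_{m=0..M}  Π_{i≤m} Pr(x_{s(i)j} | E)  ·  Π_{i>m} Pr(x_{s(i)j} | ¬E)
```

The pre-/post-event densities `Pr(x | ¬E)` and `Pr(x | E)` come from
per-marker two-component mixture models. Two kinds are provided:

* **Gaussian** — the classic choice, fit by constrained maximum
  likelihood with the mixture weight bounded to `[0.1, 0.9]`;
* **kernel-density (KDE)** — both components are Gaussian-kernel density
  estimates with a shared Scott's-rule bandwidth
  (`h = sd · n^(-1/5)`, pooled groups), fit by a classification EM with
  controls anchored to the pre-event component. This is the right tool
  for cognitive scores with ceiling/floor effects, where Gaussian
  mixtures systematically produce wrong orderings.

The maximum-likelihood ordering is found by multiply-restarted greedy
ascent; uncertainty comes from Metropolis MCMC over permutations
(positional variance diagrams) and from bootstrap refits. Each
subject-visit gets a maximum-likelihood stage in `0..M`, and longitudinal
follow-ups can be audited for self-consistency (stages should not
decrease over time, within ordering uncertainty).

## Worked example

```r
library(kdeebm)

cohort <- simulate_cohort(m = 6, n_patients = 80, n_controls = 40,
                          shape = "ceiling_floor", seed = 1)
fit <- fit_ebm(cohort, mixture = "kde", mcmc_samples = 5000,
               burn_in = 500, seed = 1)
fit
#> <ebm_fit: 6 events, kde mixtures, fit on 120 baseline rows>
#> Maximum-likelihood ordering:
#>    1. bm1
#>    2. bm4
#>    3. bm3
#>    4. bm6
#>    5. bm2
#>    6. bm5
#> log-likelihood -770.614; MCMC 5000 samples, acceptance 0.00

tidy(fit)
#> # A tibble: 6 × 5
#>   event ml_position mean_position sd_position mixture_weight
#> 1 bm1             1             1           0          0.55
#> 2 bm4             2             2           0          0.533
#> 3 bm3             3             3           0          0.508
#> 4 bm6             4             4           0          0.317
#> 5 bm2             5             5           0          0.308
#> 6 bm5             6             6           0          0.192

score_recovery(fit$ml_order, sim_truth(cohort)$order)
#> # A tibble: 1 × 2
#>   kendall_tau mean_positional_error
#> 1           1                     0
```

The fit recovers the planted ordering exactly (Kendall tau 1). The
`mixture_weight` column is each marker's fraction of post-event subjects:
it decreases down the sequence, as later events have occurred in fewer
patients. `sd_position` of 0 throughout, and the near-zero MCMC
acceptance rate, say the posterior is concentrated on a single ordering
at these sample sizes. `autoplot(fit)` renders the positional variance
diagram; `stage_cohort(fit, cohort)` returns per-visit stages, here
putting all 40 controls at stage ≤ 1 and 67 of 80 patients above it.

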