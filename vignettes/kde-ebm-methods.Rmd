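---
title: "Event-based progression modelling with kernel-density mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based progression modelling with kernel-density mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A progressive disease is modelled as a monotone accumulation of *events*:
group-level transitions of individual biomarkers (here, typically cognitive
test scores) from a control-like to a patient-like distribution. The
unknowns are the ordering $S$ in which the $M$ events occur and, per
subject, the latent stage $m \in \{0, \dots, M\}$ — how many events have
already occurred. From a purely cross-sectional sample $X = \{x_{ij}\}$
($i$ indexing markers, $j$ subjects) the likelihood of an ordering is

$$
\Pr(X \mid S) \;=\; \prod_{j=1}^{N} \sum_{m=0}^{M}
  \prod_{i=1}^{m} \Pr\!\big(x_{s(i)j} \mid E_{s(i)}\big)
  \prod_{i=m+1}^{M} \Pr\!\big(x_{s(i)j} \mid \neg E_{s(i)}\big),
$$

with a uniform prior over subjects' stages and over orderings. The
per-marker densities $\Pr(x \mid E)$ (post-event) and
$\Pr(x \mid \neg E)$ (pre-event) come from two-component univariate
mixture models fit per biomarker. Once those mixtures are fit, the
likelihood uses no diagnostic labels: controls simply populate the early
stages. A subject is staged by the argmax of the $M + 1$ stage terms of
its own row (ties broken toward the lowest stage, the conservative,
least-progressed choice).

The implementation sums stage terms as cumulative log-products combined by
log-sum-exp; in linear space the products of hundreds of densities
underflow. Densities are floored at $10^{-300}$ so likelihood ratios stay
finite, and a missing score contributes the pair $(1, 1)$ — the same
factor to every stage term — so it cancels instead of biasing the stage.
Model fitting uses each subject's baseline visit only; staging accepts all
visits.

## Mixture models

**Gaussian mixture.** The classic choice: pre- and post-event Gaussians
initialised from the control/patient labels, equal initial weights, and
the joint negative log-likelihood minimised under box constraints — the
mixture weight is kept inside $[0.1, 0.9]$ so neither component vanishes
when the groups overlap, and component standard deviations are bounded
below by $10^{-3}$ times the pooled SD so discrete scores cannot collapse
a component. The box-constrained problem is solved with L-BFGS-B with at
most 200 iterations.

**Kernel-density mixture.** Cognitive scores are often strongly
non-Gaussian — graded tests pile controls at the ceiling and patients at
the floor — and a Gaussian mixture then badly misplaces events. Both
components are instead Gaussian-kernel density estimates over the observed
values, sharing a single bandwidth fixed once by Scott's normal reference
rule, $h = \hat\sigma\, n^{-1/5}$, computed on the pooled control +
patient values; what distinguishes the components is the per-point kernel
weight vector.

Fitting is a classification EM. Assignments start at the diagnostic
labels; each sweep refits the two component KDEs from the current
assignments (kernel weights normalised to sum one), sets the mixture
weight to the assigned fraction clipped to $[0.1, 0.9]$, and reassigns
patients. Three constraints, each adopted after the unconstrained
alternatives failed in a characteristic way, shape the reassignment:

* **Controls are anchored to the pre-event component.** They define what
  "normal" looks like. If they are free, the update collapses into kernel
  smoothing of the initial labels — with one shared bandwidth and the
  mixture weight equal to the mean responsibility, the mixture density is
  identically the pooled-data KDE whatever the responsibilities, so
  nothing in the likelihood pushes the components apart and a mixed
  cluster keeps its label-average responsibility forever.
* **Assignments are hard.** With soft kernel weights every slightly
  mis-assigned point seeds the wrong component with its own kernel mass,
  which raises that component's density at its own location and attracts
  it further: the leak self-reinforces and drives the mixture weight into
  its bound.
* **The post-event support is contiguous.** Patients are reassigned as
  the block running from the abnormal extreme (per the direction of
  abnormality, inferred from group medians) up to the first point where
  the pre-event density wins. Without this, a component can capture an
  interior slice of the normal mode — a local optimum that is
  statistically valid but scientifically meaningless.

The sweep converges when the assignment is stable (almost always within
tens of sweeps; 500 is the cap, after which the fit is returned with a
warning). Because both groups mix normal and abnormal values, patients may
end up pre-event on any marker — that is the point of the model. A final
guard swaps component roles if the post-event component's weighted mean
lands on the normal side of the pre-event mean, which can happen on
markers where almost no patient has progressed. The per-iteration negative
log-likelihood is recorded in the fit diagnostics; it is non-increasing on
all fixtures exercised by the test suite (with the weight inside its
bounds it is exactly constant, by the pooled-KDE identity above).

Direction inference (lower- vs higher-is-abnormal) compares group
medians. It exists because real batteries mix timed tests (higher is
worse) with accuracy scores (lower is worse); it is diagnostic metadata
plus the orientation for the contiguity walk, not part of the likelihood.
When medians tie the direction is *undetermined* and reassignment falls
back to the unconstrained density comparison.

## Search and uncertainty

The ordering search combines greedy ascent from 16 random restarts (best
single-pair swap, first-best in scan order, until no swap improves the
log-likelihood) with Metropolis MCMC over permutations started at the
greedy optimum: proposals swap two uniformly chosen positions and are
accepted with probability $\min(1, \exp \Delta \log L)$ — the uniform
prior over orderings cancels. Defaults are 10,000 retained samples after
1,000 burn-in; all of this is configurable and seeded, and two runs with
the same seed are bit-identical. The retained samples condense into the
positional variance diagram: the $M \times M$ matrix of how often each
event occupies each position, rows in maximum-likelihood order. Each
sample being a permutation makes the matrix doubly stochastic — rows and
columns sum to one to within $10^{-12}$, a property the test suite asserts
on every run it makes.

Bootstrap cross-validation re-estimates the full model (mixtures and ML
ordering, no MCMC) on resamples of the baseline cohort drawn with
replacement within each label group, so both groups keep their size and
every replicate can initialise its mixtures; a replicate leaving a marker
with fewer than two usable values per group is redrawn, at most ten
times. The replicate orderings aggregate into a second positional
frequency matrix. Its mean positional entropy exceeds the MCMC
posterior's on the same data — the bootstrap is the conservative
uncertainty estimate, since it also propagates sampling variability of
the mixtures themselves.

## Longitudinal self-consistency

With follow-up visits available, a fitted model can be audited against
the progressive nature of the disease: within-subject stages should not
decrease over time, up to the model's own ordering uncertainty. All
ordered visit pairs $(v_1 < v_2)$ per subject are counted, and a pair is
consistent when $\text{stage}(v_2) \ge \text{stage}(v_1) - \tau$. The
tolerance $\tau$ has no agreed quantitative definition; here it defaults
to the per-event positional standard deviation under the positional
variance diagram, averaged over events and rounded to an integer number
of positions. That makes $\tau$ shrink to 0 for a confident model (strict
non-decrease) and grow where the ordering itself is uncertain. An
explicit `tolerance` argument overrides it.

## The simulator

`simulate_cohort()` draws cohorts from exactly the generative model above:
a planted ordering, patient stages uniform on $\{1, \dots, M\}$, controls
at stage 0, and per-marker scores from a normal or abnormal distribution
according to stage. Three distribution families cover the regimes that
matter for the mixture comparison:

* `gaussian` — $N(0,1)$ vs $N(\delta, 1)$ with separation $\delta$
  (default 4): the regime where the classic Gaussian mixture is adequate.
* `skewed` — mirrored log-normals, right-skewed normal scores against
  left-skewed abnormal ones.
* `ceiling_floor` — scores clamped to $[0, \delta]$: normal draws
  $N(\delta - 0.5, 1)$, so roughly 31% of control scores sit exactly at
  the ceiling; abnormal draws $N(0.5, 1)$ pile at the floor. This is the
  regime that defeats Gaussian mixtures.

Longitudinal mode adds visits whose true stages increase by Poisson(1)
steps (capped at $M$), so generated trajectories are monotone by
construction; optional missing-completely-at-random injection exercises
the $(1,1)$ cancellation path. Scales used throughout the tests — 100
patients and 50 controls for 8 markers, 94/23 for the 17-marker battery
emulation, 20 simulation repeats, 25 bootstrap replicates, MCMC chains of
2,000 when many fits are run — were chosen as the smallest sizes at which
the qualitative contrasts are stable across seeds.

What the simulator does *not* emulate: correlated markers (real cognitive
tests share variance through general severity and collateral deficits —
the model's independence assumption is wrong for them in the same way it
is wrong for the real data), practice effects at follow-up, informative
missingness, and covariate structure (age, education). Passing
recovery tests therefore demonstrates correctness of the machinery under
the model's own assumptions, not robustness to their violation.

## Known limitations

* Events are assumed independent given the stage; correlated test scores
  violate this and the ordering of highly correlated subscores should be
  read with that in mind.
* The two-component mixture permits no more than one transition per
  marker; U-shaped or non-monotone marker trajectories are out of scope.
* Median-based direction inference can flip on markers where almost no
  patient has progressed; the component-order guard catches most but not
  all consequences, and such markers carry little ordering signal either
  way.
* The bandwidth is global per marker; a variable bandwidth would suit
  sparse tails better but is deliberately not implemented.

## A worked run

```{r, eval = FALSE}
library(kdeebm)

cohort <- simulate_cohort(m = 8, n_patients = 100, n_controls = 50,
                          shape = "ceiling_floor", seed = 1)
fit <- fit_ebm(cohort, mixture = "kde", seed = 1)
tidy(fit)
autoplot(fit)

stages <- stage_cohort(fit, cohort)
plot_stage_histogram(stages, m = 8)

boot <- bootstrap_model(cohort, n_boot = 100, seed = 1,
                        reference_order = fit$ml_order)
plot_positional_variance(boot$pvd)
```
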