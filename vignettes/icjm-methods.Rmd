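---
title: "Interval-censored cause-specific joint modelling and risk-based biopsy scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-censored cause-specific joint modelling and risk-based biopsy scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icjm)
```

## The problem

Men on active surveillance (AS) for low-risk prostate cancer are monitored
with frequent PSA measurements and periodic biopsies. Progression (Gleason
score 7 or higher) is only observable at a biopsy, so the progression time is
*interval censored* between the last negative and the first positive biopsy.
Some men start treatment before progression is ever confirmed, a *competing
event* that removes them from surveillance. Fixed protocols biopsy everyone
on the same calendar, burdening slow progressors with unnecessary invasive
procedures. This package implements a joint model that links the PSA (and,
optionally, biopsy core-ratio) trajectory to the cause-specific hazards of
progression and early treatment, produces dynamic patient-specific
progression risks, and converts those risks into personalized biopsy
schedules that trade the expected number of biopsies against the expected
delay in detecting progression.

## Model

**Longitudinal part.** PSA is modelled on the `log2(PSA + 1)` scale with a
subject-level mean

\[ m_i(t) = \beta_0 + u_{0i} + \sum_{p=1}^{3} (\beta_p + u_{pi})\,C^{(p)}(t)
   + \beta_4 (\mathrm{Age}_i - 62), \]

where \(C(t)\) is a natural cubic spline with 3 degrees of freedom (two
interior knots at the 33.3%/66.7% quantiles of the pooled measurement and
event times, boundary knots at 0 and the 99th percentile) and the
measurement error is a scaled Student-t with 3 degrees of freedom — PSA has
occasional outlying values that a normal error would over-penalize. The
natural-spline basis is linear outside the boundary knots, which matters
because the hazard uses the *yearly change* \(m_i(t) - m_i(t-1)\): for
\(t < 1\) the lagged value is a linear extrapolation before entry. The
optional second marker, the fraction of biopsy cores containing cancer, is a
binomial mixed model with logit mean quadratic in time. All random effects
(4 for PSA, 3 for the core ratio) are jointly multivariate normal with
unstructured covariance \(\Omega\).

**Survival part.** Each event \(k \in \{\mathrm{PRG}, \mathrm{TRT}\}\) has a
proportional cause-specific hazard

\[ h_i^{(k)}(t) = h_0^{(k)}(t)\exp\{\gamma_k w_i + \alpha_{1k} m_i(t) +
   \alpha_{2k} (m_i(t) - m_i(t-1)) [+ \alpha_{3k}\,\mathrm{logit}\,
   \mathrm{E(core\ ratio)}_i(t)]\}, \]

with \(w_i\) the log baseline PSA density. The yearly change (rather than
the instantaneous slope) is used as the velocity summary because it is the
clinically interpreted quantity.

**Baseline hazard.** The package offers two log-linear families:
a B-spline (9 cubic basis functions, knots at event-time quantiles, with a
second-order random-walk roughness penalty whose precision gets a Gamma
hyperprior) — the flexible default — and a Weibull
(\(\log h_0(t) = c_0 + c_1 \log t\)). The Weibull form is the simulator's
generating choice because it admits closed-form cumulative hazards, which
anchor the test suite's oracles.

**Likelihood.** Conditional on the random effects, the event factor has
three branches by censoring type \(\delta\): right-censored subjects
(\(\delta = 0\)) contribute survival of progression to the last biopsy and
of treatment to the censoring time; interval-censored progressions
(\(\delta = 1\)) contribute
\(\int_{T^-}^{T^+} h^{PRG}(s) e^{-H^{PRG}(0,s)}\,ds \cdot
e^{-H^{TRT}(0,T^+)}\); observed treatments (\(\delta = 2\)) contribute the
treatment density times survival of progression to the last biopsy. All
integrals use the 15-point Gauss–Kronrod rule; the \(\delta = 1\) branch
nests a 15-point inner rule for \(H^{PRG}(0,s)\) at each outer node. The
user-facing quadrature functions additionally bisect panels adaptively (via
the embedded 7-point Gauss estimate) to a \(10^{-10}\) tolerance; the
compiled likelihood used inside the sampler keeps the plain nested rule,
and both paths are cross-checked in the tests.

## Estimation

`icjm_fit()` runs Metropolis-within-Gibbs:

* adaptive Gaussian random-walk blocks for the PSA fixed effects, the
  core-ratio fixed effects, the per-event survival coefficients (covariate,
  association and baseline coefficients jointly), and \(\log\sigma\);
  proposal covariances are estimated adaptively and scales follow a
  Robbins–Monro recursion toward an acceptance rate of 0.234 (0.44 for the
  scalar block), tuned only during the adaptation phase;
* per-subject random-effect updates with proposals shaped by the current
  \(\Omega\), accepted subject-wise (all subjects advance in one vectorized
  likelihood evaluation);
* conjugate inverse-Wishart Gibbs draws for \(\Omega\) and Gamma draws for
  the B-spline roughness precision.

Priors are deliberately weakly informative substitutes chosen by this
package (they are configurable): N(0, 10\(^2\)) on all coefficients,
half-t(3, 2.5) on \(\sigma\), inverse-Wishart(\(q+2\), 0.1 I) on
\(\Omega\). Initialization uses population least squares for the fixed
effects, per-subject ridge estimates for the PSA random effects, crude
event rates for the baselines, and zeros for the survival coefficients;
this keeps the nested-quadrature likelihood finite from the first
iteration without requiring a separate mixed-model fit.

## Dynamic prediction

For a new subject with biomarker history to \(t_y\), last negative biopsy
\(t_b\) and current visit \(t_v\), the progression-specific cumulative risk
at \(t_p\) is

\[ \Pi(t_p \mid t_b, t_v) = \frac{\int_{t_b}^{t_p} h^{PRG}(\nu)
   \exp[-H^{PRG}(\nu) - H^{TRT}\{\max(\nu, t_v)\}]\,d\nu}
   {\exp[-H^{PRG}(t_b) - H^{TRT}(t_v)]}. \]

When \(t_p = t_v\) the treatment factor cancels and only the progression
hazard remains; when \(t_b = t_v\) the expression reduces to the
overall-survival form. `progression_risk()` implements all three variants
(they agree identically on overlapping domains, which the tests assert to
\(10^{-8}\)). Monte-Carlo curves (`risk_curve()`) average over posterior
parameter draws with one matched random-effects draw each: the
random-effects posterior \(p(u \mid T^{PRG} > t_b [, T^{TRT} > t_v],
\mathcal{Y}, \theta)\) is sampled by a random-walk Metropolis chain per
parameter draw, all chains advancing in lock-step with a shared
Robbins–Monro-tuned scale (target 0.234, the standard multivariate
random-walk optimum for this 4–7-dimensional block). During scheduling, the
cheaper target conditioning only on \(T^{PRG} > t_b\) is used, since the
conditioning event then no longer changes between visits.

Numerically, each draw's cumulative hazards are accumulated with one
Gauss–Kronrod panel per grid segment (default resolution: visit spacing / 4)
and evaluated between grid points by cubic Hermite interpolation whose
derivative — the hazard itself — is stored exactly at the grid points. For a
constant hazard this representation is exact, which is what lets the
scheduler's oracle tests demand near machine-precision agreement.

## Scheduling

At each future visit \(t_e\), a biopsy is planned when the conditional risk
since the last planned biopsy \(\tilde t_b\) reaches the threshold
\(\phi\) (a value exactly equal to the threshold triggers a biopsy). Instead
of resampling random effects after every planned biopsy, the conditional
risk is reformulated from the single base curve conditioned on the last
*conducted* biopsy,
\(\Pi(t_e \mid \tilde t_b) = [\Pi(t_e) - \Pi(\tilde t_b)] /
[1 - \Pi(\tilde t_b)]\); the tests verify this ratio reformulation against
an explicit reset-and-resample oracle. A biopsy at the horizon (10 years by
default) is always planned, and it counts toward the expected number of
biopsies. Schedules are regenerated from scratch whenever new biomarker
data arrive; no state is cached across updates. No minimum gap between
biopsies is imposed by default (an optional `min_gap` exists).

Each candidate \(\phi\) yields an expected number of biopsies
\(E\{N_b\}\) and expected detection delay \(E\{D_d\}\) computed from the
same curve; `optimal_threshold()` grid-searches \(\phi \in \{0.01, \dots,
0.99\}\) (step 0.01) minimizing
\(\sqrt{\lambda_1^2(E\{N_b\}-1)^2 + \lambda_2^2 E\{D_d\}^2}\) with
\(\lambda_1 = \lambda_2 = 1\), subject to \(E\{D_d\} \le 1.5\) years, with
ties broken toward the larger threshold (fewer biopsies) and a
minimal-delay fallback when the constraint is infeasible. The two
components are on different scales (count vs years); equal weights are a
convention, not a claim of equivalence, and both weights are exposed.

## The simulator

`simulate_cohort()` generates cohorts from the model itself: random effects
from MVN(0, \(\Omega\)), PSA every 3 months with scaled-t(3) error, clinic
visits every 6 months, protocol biopsies at entry, years 1 and 2, and
biennially after. The two latent event times are drawn *independently given
the random effects*, each by inverse-transform sampling of its own
cause-specific cumulative hazard — this is the data-generating process the
interval-censored likelihood actually describes: a treated subject may have
progressed latently since their last biopsy, and treatment may strike
between a latent progression and the biopsy that would have detected it.
(The marginal law of the first event and its type is the familiar
competing-risks one.) Training subjects are
interval-censored by applying the biopsy protocol and an administrative
censoring drawn from a 5-year uniform accrual window with data cut at the
10-year horizon — a choice made here to yield a realistic mix of censored
subjects. Test subjects get an entry biopsy at time zero and are resampled
to a fixed quota of progressing/non-progressing subjects.

The generating parameters (`default_params()`) fix the survival log hazard
ratios at the logs of published point estimates for an AS cohort
(progression: 1.66 per unit log PSA density, 1.14 per unit log2(PSA+1),
18.52 per unit yearly change; treatment: 1.25, 1.52, 9.13). The
longitudinal fixed effects, \(\Omega\), and the Weibull baselines are
synthetic substitutes calibrated once so that cohorts look like a
slow-growing AS population: median PSA near 5 ng/ml growing roughly 0.3
ng/ml per year, about 10% early-treatment events (tunable through
`trt_hazard_scale`, monotonically), and roughly a quarter of training
subjects with detected progression within 10 years. Biopsies sample 12
cores. What the simulator does *not* emulate: real PSA assay artefacts,
dropout and noncompliance, imperfect (false-negative) biopsies, and the
true covariance structure of a clinical cohort — so passing tests show
internal consistency of estimation, prediction and scheduling under the
model, not transportability to any particular cohort.

## Scheduling experiment

`run_schedule_experiment()` reproduces the schedule comparison at package
scale: each replicate simulates 300 training and 200 test subjects (100
progressing / 100 not), fits the PSA-only model with the Weibull baseline
and the generating knots (the standard correctly specified simulation
setup), and plans one personalized schedule per test subject at the first
protocol decision point (one year, using the entry biopsy as the last
negative biopsy and the PSA history accrued by then). Planning once and
scoring the static schedule against the latent truth is this package's
design choice: it matches the schedule-evaluation contract exactly and
keeps each replicate's cost at a few tens of seconds; fully dynamic
re-planning at every visit would only add information to the personalized
arm. Reported biopsy counts include the entry biopsy. The default
experiment scale in the tests and the acceptance script (10 and 3
replicates, single short chains, 50 posterior draws per prediction) was
chosen so the whole suite completes on a laptop-class machine; all scales
are arguments.

## Numerical choices and edge cases

* Quadrature: 15-point Gauss–Kronrod everywhere; adaptive bisection (tol
  \(10^{-10}\)) in the reference path; plain nested rule in the compiled
  likelihood. Weibull shapes below 1 have an integrable singularity at 0
  and converge to about \(10^{-9}\) absolute rather than \(10^{-10}\).
* A subject whose likelihood turns non-finite (hazard overflow) contributes
  \(-\infty\) with a warning, so proposals into overflow regions are
  rejected rather than crashing the chain.
* `delta = 1` requires a strictly positive censoring interval; zero-length
  intervals are rejected at construction and at file reading, with line
  numbers.
* Risk curves are nondecreasing in \([0,1]\) by construction (integrals of
  nonnegative integrands); the threshold sweep treats risks within
  \(10^{-12}\) of \(\phi\) as reaching it.
* Schedules whose total risk at the horizon is numerically zero have
  undefined expected metrics; they are flagged with a warning and `NA`.
* Seeds: every stochastic entry point takes a seed; chain \(c\) of a fit
  uses `seed + 7919 (c-1)`, replicate \(r\) of the experiment offsets the
  simulation seed by `1000 r`, keeping all derived seeds well below
  \(2^{31}\).

## Known limitations

Estimation assumes the visit/biopsy process is noninformative given the
random effects; the sampler is a random-walk scheme and mixes slowly for
the weakly identified yearly-change association (wide, right-skewed
posteriors are expected at n = 300); the two-marker model samples the
core-ratio association only when core data are informative at biopsy times;
and the label semantics are asymmetric by design — progression is
interval-censored, treatment exactly observed — so the two events are not
exchangeable.
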