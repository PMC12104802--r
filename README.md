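# icjm — interval-censored cause-specific joint models and personalized biopsy schedules

Men on active surveillance (AS) for low-risk prostate cancer are monitored
with PSA tests every few months and periodic biopsies. Progression (Gleason
score ≥ 7) is only visible at a biopsy, so the progression time is
**interval censored** between the last negative and the first positive
biopsy; some men start treatment early, a **competing event** that ends
surveillance before progression can be observed. Fixed biopsy protocols
(annual, or years 1 and 2 then biennial) biopsy everyone on the same
calendar regardless of risk.

`icjm` is for biostatisticians building risk-based surveillance: it fits a
Bayesian joint model of the longitudinal biomarkers and the two competing
events, produces dynamic patient-specific progression risks, and turns them
into personalized biopsy schedules.

## The model

Longitudinal part (per subject *i*): PSA on the log2(PSA+1) scale with a
3-df natural cubic spline in time and scaled t(3) errors,

    m_i(t) = (b0 + u0i) + sum_p (bp + upi) C_p(t) + b4 (Age_i − 62),

optionally joined by a binomial mixed model for the biopsy core ratio
(quadratic logit trend); all random effects share one multivariate normal
distribution with covariance Ω.

Survival part: cause-specific proportional hazards for progression (PRG)
and early treatment (TRT),

    h_i^k(t) = h0_k(t) exp{ γ_k w_i + α1k m_i(t) + α2k [m_i(t) − m_i(t−1)]
                            (+ α3k logit E(core ratio)_i(t)) },

with *w_i* the log baseline PSA density, the *yearly change* of the
expected PSA as the velocity summary (linearly extrapolated before year
one), and a Weibull or penalized B-spline baseline. The likelihood has
three branches by censoring type δ ∈ {0 censored, 1 interval-censored
progression, 2 observed treatment}; all cumulative hazards use 15-point
Gauss–Kronrod quadrature (nested for the δ = 1 interval integral).

Dynamic prediction for a new patient conditions on their biomarker history,
last negative biopsy t(b) and current visit t_v, samples the patient's
random effects by adaptive Metropolis–Hastings (Robbins–Monro scaling), and
evaluates the progression-specific cumulative risk

    Π(t_p | t_b, t_v) = ∫_{t_b}^{t_p} h^PRG(ν) exp[−H^PRG(ν) − H^TRT(max(ν, t_v))] dν
                        / exp[−H^PRG(t_b) − H^TRT(t_v)].

A biopsy is planned at the first visit where the conditional risk since the
last planned biopsy reaches a threshold φ (risk resets to zero after each
planned biopsy, via a ratio reformulation of the same base curve). The
per-patient optimal φ minimizes √[(E{Nb} − 1)² + E{Dd}²] — expected number
of biopsies vs expected detection delay — subject to E{Dd} ≤ 1.5 years.

A simulator generates full cohorts from the model (PSA every 3 months,
visits every 6 months, protocol biopsies at entry, years 1, 2, then
biennially, ~10% early-treatment events), so estimation, prediction and
scheduling are all testable without patient data.

## Worked example

```r
library(icjm)

# 1. simulate an AS cohort from the built-in generating model
config <- sim_config(n_train = 150, n_test = 20, seed = 42)
sim <- simulate_cohort(config)
table(vapply(sim$train, function(s) s$delta, 0L))
#>   0   1   2
#> 109  30  11

# 2. fit the PSA-only joint model (short chains for illustration)
fit <- icjm_fit(sim$train,
                mcmc_config(n_chains = 2, n_adapt = 400, n_burn = 200,
                            n_iter = 800, seed = 1),
                model = "psa", baseline = "weibull",
                knots = config$params$knots)
#> ICJM fit (psa model, weibull baseline): 150 subjects, 1600 draws
#> Survival coefficients (posterior mean [95% CI], Rhat):
#>              mean   lower  upper  rhat    ess
#> PRG_gamma   1.477   0.500  2.773 1.036 79.357
#> PRG_alpha1  0.151  -0.363  0.704 1.039 42.418
#> PRG_alpha2  7.374  -0.657 15.761 1.403 14.415
#> ...

# 3. dynamic risk prediction for one test subject at their one-year visit
subj <- sim$test[[1]]
ctx <- prediction_context(psa = subset(subj$psa, time <= 1),
                          age = subj$age,
                          log_psa_density = subj$log_psa_density,
                          t_b = 0, t_v = 1)
set.seed(2)
curve <- risk_curve(ctx, thin_draws(fit, 100), horizon = 10, type = "visit")
#> Progression-risk curve (visit form): 100 draws, t_b = 0.00, grid up to 10.00
#>   risk at horizon: 0.563 [0.290, 0.874]

# 4. personalized schedule with the optimal risk threshold
opt <- optimal_threshold(curve, visit_grid = seq(1, 10, by = 0.5),
                         max_delay = 1.5)
opt$schedule
#> Biopsy schedule (phi = 0.18): 4 planned biopsies, E{Nb} = 2.18, E{Dd} = 1.40 y
#>   times:  3.5,  6.5,  8.5, 10.0

# 5. score against the simulated truth (this subject progresses at 7.13 y)
evaluate_schedule(subj$truth$t_prg, subj$truth$t_trt, opt$schedule)
#> $nb 3      $dd 1.37
evaluate_schedule(subj$truth$t_prg, subj$truth$t_trt, fixed_schedule("pass", 10))
#> $nb 5      $dd 0.87
```

The fit prints posterior means, 95% credible intervals, split-Rhat and
effective sample sizes for the six survival coefficients (PSA-only model):
the log hazard ratios of log PSA density (`gamma`), the log2(PSA+1) value
(`alpha1`) and its yearly change (`alpha2`) on each event's hazard. The
risk curve gives this patient a 56% ten-year progression risk, so the
threshold rule plans only four biopsies (versus five conducted under the
biennial protocol by detection), detecting his progression with a delay of
1.4 years versus 0.9 — the biopsies-vs-delay trade the scheduler is
designed to navigate patient by patient.

A thin command-line wrapper over the same functions lives at
`inst/cli/icjm.R` (subcommands `simulate`, `fit`, `predict`, `schedule`,
`experiment`; every subcommand takes `--seed`).

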