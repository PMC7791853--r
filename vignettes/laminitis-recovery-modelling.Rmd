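---
title: "Modelling recovery from endocrinopathic laminitis: scoring rubrics, the decay NLME, and SAEM"
author: "laminitr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling recovery from endocrinopathic laminitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminitr)
```

## The problem

Hyperinsulinaemia-associated laminitis (HAL) is the most common form of
equine laminitis. Evaluating treatments requires a quantitative description
of how clinical signs resolve under standard care. Two severity instruments
are in use: the classical Obel grade (an ordinal 0–4 based on clusters of
signs) and the composite Meier ("modified Obel") score, which awards points
to five clinical criteria — weight shifting (0/2), forelimb lift (0/1/2),
gait at the walk (0/1/2/6), gait at the circle (0/1/2/3) and digital pulse
(0/2) — and sums them to a 0–12 total. `laminitr` implements both rubrics
as executable procedures, simulates longitudinal score cohorts with the
hierarchical structure assumed by the recovery model, fits that model by
SAEM, and provides the cohort-level summaries used to describe recovery.

## The scoring rubrics as code

`meier_exam()` validates a per-visit examination record: every criterion
takes exactly one enumerated level, and a horse with severe difficulty
walking is never forced to circle — `gait_walk = "severe"` requires and is
required by `gait_circle = "not_assessed"` (the assessment is skipped and
contributes 0 points, the walk's 6 points carrying the locomotor severity).
Bilateral criteria (forelimb lift, digital pulse) score the *worse*
forelimb. Summing limbs instead would allow totals above 12, contradicting
the instrument's stated 0–12 scale, so the max-across-limbs reading is
adopted. `enumerate_attainable_totals()` brute-forces all 936 valid level
combinations and confirms the attainable totals are exactly 0–12; a total
of 12 is reachable only through the severe-walk branch (2 + 2 + 6 + 2).

The Obel rubric is prose; `grade_obel()` encodes it as a decision table
with highest-grade-wins precedence, and an examination matching no grade
description maps to 0 ("appears sound"). Grade 0 is treated as a real
grade, since cohort medians of 0 are meaningful. `check_inclusion()`
implements the study entry rule: Obel at least 1/4 *and* Meier at least
5/12.

## The recovery model

For horse $i$ at day $t_{ij}$ the total score is modelled as

$$y_{ij} = \theta_{0i}\, e^{-\theta_{1i} t_{ij}^{\theta_{2i}}} + \epsilon_{ij},
\qquad \epsilon_{ij} \sim N(0, \sigma^2),$$

with individual parameters
$(\log\theta_{0i}, \log\theta_{1i}, \theta_{2i})' \sim
N(\boldsymbol\theta, \boldsymbol\Omega)$,
$\boldsymbol\Omega = \mathrm{diag}(\omega_0, \omega_1, \omega_2)$.
$\theta_{0i}$ is the day-0 severity, $\theta_{1i}$ the decay rate, and
$\theta_{2i}$ a power on time ($\theta_2 = 1$ is plain exponential decay).
$\theta_{2i}$ enters on the natural scale and is not constrained positive
in the fitter; instead the fraction of conditional draws at or below 0 is
reported (`frac_theta2_nonpositive`). At $t = 0$ the convention
$0^{\theta_2} = 0$ is used so the day-0 mean is exactly $\theta_{0i}$.
Scores are treated as continuous even when integer-valued — an explicit
model simplification whose main consequence is discussed under
*Limitations*.

The default parameter values carried by `population_params()` are the
reference estimates for a 64-horse fast-improvement group scored on days
0, 4, 9, 14, 25 and 42:
$\log\theta_0 = 2.07$, $\log\theta_1 = -1.95$, $\theta_2 = 1.16$,
$\omega = (0.025, 0.361, 0.087)$, $\sigma = 0.99$ score units. These are
also the default generating conditions of the simulator.

## The synthetic-cohort generator

The study's raw clinical data are not public, so the generator emulates the
conditions the model assumes: `sample_individual_params()` draws each
horse's parameters independently normal around the population values
(draws with $\theta_{2i} \le 0$ are resampled and counted);
`simulate_trajectory()` adds i.i.d. Gaussian residual; by default scores
are clipped to $[0, 12]$ and rounded to integers, because clinical scores
are integers and cannot leave the scale. The fitter can consume either the
rounded or the continuous version.

Roughly a fifth of clinical cases do not follow the smooth decay.
`simulate_slow_improver()` reproduces only their *observable* constraints —
a day-14 score still in 4–10, and scores that rise and fall over the 42
days — because the true mechanism is unknown. The implementation slows the
decay so the structural day-14 value lands in the band, adds one
Gaussian-shaped relapse bump (amplitude drawn from 1.5–3.5 score units,
centre between days 18 and 38), and then enforces the band and
non-monotonicity; this mechanism is an invention of the package and should
not be read as biology. `simulate_study_cohort()` mixes 64 fast and 16 slow
horses, the composition of the clinical cohort.

`allocate_signs()` decomposes integer totals into the five criterion
scores. The fill order encodes the clinically observed resolution order —
weight shifting and foot lift resolve earliest, then the digital pulse,
then gait at the walk, with circling impairment persisting longest — and a
seeded jitter occasionally moves one point from walk to circle to emulate
the near-parallel recovery of the two locomotor signs. Row sums always
equal the totals; the decomposition of 12 is the unique severe-walk one.

What the generator does *not* emulate: covariate effects (age, breed,
endocrine status), observer effects (the study used 25 veterinarians),
correlation between random effects, integer measurement as a genuine
ordinal process, and any mechanism for the slow group. Passing tests
therefore demonstrate that the estimation machinery is correct under the
model's own assumptions, not that the model is correct for real horses.

## SAEM implementation

`saem_fit()` implements stochastic approximation EM for this
exponential-family complete-data model:

* **S-step.** Each horse's $(\log\theta_{0i}, \log\theta_{1i},
  \theta_{2i})$ is updated by component-wise random-walk
  Metropolis–Hastings targeting its conditional posterior; 5 transition
  kernels per iteration by default. Proposal scales adapt during burn-in
  toward a ~40% acceptance rate.
* **SA-step.** Sufficient statistics (sums and squared sums of the
  individual parameters; squared residuals) are smoothed with step sizes
  $\gamma_k = 1$ for the 300 burn-in iterations and
  $\gamma_k = 1/(k - k_{\text{burnin}})$ for the 100 smoothing iterations.
  During burn-in, variance updates are annealed (never allowed to fall
  below 0.95 of their previous value) to prevent premature collapse of the
  random-effect variances before the chain has explored.
* **M-step.** Closed-form: fixed effects are the smoothed means, variances
  the smoothed central second moments (floored at $10^{-6}$ for numerical
  stability), $\sigma^2$ the smoothed residual mean square. Under the
  combined error model (residual SD $a + b\,|f|$, one of several
  conventions in use for "additive plus proportional" error — the choice
  of convention is the package's) the two coefficients are updated by
  numerical maximization against the smoothed statistics.

Standard errors come from the observed Fisher information via Louis'
identity, computed in a dedicated post-estimation phase: with the final
estimates frozen, the individual parameters are sampled from their
conditional posteriors (300 further MH iterations by default) and the
analytic complete-data scores and Hessians are averaged. Because horses
are independent, the score-variance term is accumulated *per horse*
($\mathrm{Var}(s) = \sum_i \mathrm{Var}(s_i)$), which removes the $n^2$
noisy cross-horse products of the naive estimator and keeps the
information matrix numerically positive definite; entries whose
information is still too weak are reported as NA with a warning rather
than silently stabilized. The SE of $\sigma$ is obtained from that of
$\sigma^2$ by the delta method, and CV% is $100\,SE/|\hat\theta|$. The
marginal log-likelihood is estimated by per-horse importance sampling
with independent Gaussian proposals at the conditional posterior means
and variances (taken from the same post-estimation draws), with the
Monte-Carlo standard error reported; when all random-effect
variances have collapsed the closed-form fixed-effects likelihood is
returned exactly. AIC is $-2\hat\ell + 2k$ with $k$ the number of
estimated parameters (7 for the full additive model; 5 with $\theta_2$
fixed at 1, which also drops its random effect). The additive error model
is the default; the combined model is provided for AIC comparison via
`compare_models()` but was not retained in the reference analysis.

Initial values come from the two-stage fit when feasible, else from
moments (log mean day-0 score; a rate from the half-score day;
$\theta_2 = 1$). Convergence is monitored as the relative drift of every
parameter across the smoothing phase; drift above 5% raises a warning with
the full iteration trace attached. Degenerate inputs — fewer than two
horses, fewer than two visits per horse, constant scores — are rejected
with diagnostics.

With the default schedule a 64-horse, 6-visit fit takes a few seconds;
the default iteration counts were chosen for cohorts of this desk scale
and are configurable through `saem_settings()`. The package's own checks
use the same scale: single fits and 3-replicate recovery runs at n = 64,
plus one 20-replicate unbiasedness study at a slightly shortened
schedule.

## The two-stage oracle and cross-checks

`oracle_fit_two_stage()` is a deliberately independent estimation route:
per-horse Levenberg–Marquardt least squares, then population moments of
the per-horse estimates. It exists to cross-check SAEM, to provide initial
values, and to illustrate *why* the mixed-effects route is needed: a horse
whose post-baseline scores all sit at the zero floor carries no
information about its own decay shape, so its least-squares estimate lands
anywhere on a likelihood ridge. Such horses are detected (fewer than two
post-baseline scores clearly above the floor) and skipped with a warning;
the skipping makes the oracle usable but introduces an exclusion bias on
the decay-rate mean whenever fast decayers are common. Under the reference
between-horse rate variance ($\omega_1 = 0.361$) a substantial minority of
horses are individually unidentifiable at the study's visit schedule, so
the package's dual-route agreement checks are run at $\omega_1 = 0.1$,
$\omega_2 = 0.02$, $\sigma = 0.1$ — conditions under which every horse is
identifiable and the two routes must agree closely. Recovery under the
reference conditions themselves is checked directly against the generating
truth by refitting replicate simulated cohorts (3 replicates in the
acceptance suite; a 20-replicate unbiasedness study in the property
suite).

## Cohort summaries

`partition_fast_slow()` splits horses on the day-14 score: at or above 4
is slow, below is fast. The threshold is derived from the reported group
ranges (fast horses scored 0–3 on day 14, slow horses 4–10); the source
description never states the cut numerically, so it is fixed here as a
package default and exposed as an argument. `median_trajectory()` uses the
midpoint convention for even-sized groups and type-7 (inclusive) quartiles
— neither convention is dictated by the source, both are stated here for
reproducibility. `mann_whitney_u()` computes the rank-sum U with midrank
ties, an exact two-sided P by exhaustive enumeration when both groups have
at most 8 observations, and otherwise a normal approximation with tie
correction and continuity correction. Two-sided P values are reported
throughout.

Because a simulated cohort's median at a late visit day sits close to the
0/1 boundary (with $\sigma \approx 1$, pure residual noise alone puts a
third of true-zero scores at 1 after rounding), summaries quoted for *the
default cohort* in the package's own checks are stabilized across
replicate simulated cohorts — the reported value is the median of the
per-cohort medians — rather than read off a single random cohort.

## Numerical choices, in one place

* $0^{\theta_2} := 0$, so day-0 means are exact.
* Variance floor $10^{-6}$ in the M-step; proposal floors in the
  importance-sampling proposal variances ($10^{-6}$).
* $\theta_{2i}$ draws $\le 0$ in the *generator* are resampled and
  counted; the *fitter* leaves $\theta_{2i}$ unconstrained and reports the
  non-positive fraction.
* Negative pre-clip scores clip to 0 (and high ones to 12) before integer
  rounding; rounding uses R's banker's rounding.
* Mann–Whitney exact P uses midranks, so it remains valid under ties;
  the two-sided P is twice the smaller tail, capped at 1.
* The combined-error M-step optimizes $(a, b)$ with box constraints
  $a \ge 10^{-4}$, $b \ge 0$.

## Limitations

The Gaussian-residual continuous-score model is wrong at the zero floor:
observed zeros late in recovery sit systematically below their
predictions, and `fit_diagnostics()` measures and flags exactly this bias
rather than hiding it. No ordinal or censored likelihood is provided. No
covariates are modelled. The slow-improver generator is a constraint
-matching invention. The oracle's exclusion rule biases its decay-rate
mean when fast decayers are common, which is why it is a cross-check and
initializer, never the estimator of record.
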