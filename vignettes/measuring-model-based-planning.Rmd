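---
title: "Measuring model-based planning in a gamified two-step task: models, design choices and what the synthetic tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring model-based planning in a gamified two-step task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The task and the measurement model

The package simulates a single-choice two-step task. On each trial the
player chooses one of two containers; the left container mostly holds
purple balls, the right mostly pink, and the chosen container releases its
majority colour with probability `p_common` (a *common* transition; 0.8 or
0.7 in the deployed variants) and the minority colour otherwise (*rare*).
Whether the released ball is a "good ball" (rewarding) is Bernoulli in that
colour's slowly drifting reward probability. A good ball can additionally
hit the diamond — a secondary reward whose probability depends on the
block's difficulty level. The transition structure is displayed on-screen,
so it never has to be learned.

Model-based planning is measured exactly as in the wider two-step
literature: a logistic regression of *staying* (repeating the previous
first-stage choice; switch = 0, stay = 1) on the previous trial's reward
(−1 unrewarded, +1 rewarded), transition (−1 rare, +1 common), and their
interaction. The Reward × Transition interaction is the model-based index
(MBI): only an agent that propagates reward through the transition model
treats a rare-transition reward differently from a common-transition one.
The reward main effect is the model-free index (MFI) and the intercept the
overall stay tendency.

Two estimators are provided and deliberately kept distinct:

* **Pointwise** (`fit_pointwise`): per-subject Newton maximisation of the
  Bernoulli-logit likelihood, with a small ridge (default `1e-3`) on all
  four coefficients. Short windows (25-trial bins) frequently exhibit
  separation; the ridge keeps estimates finite and a `separation_flag`
  records whenever the unpenalised problem diverges (detected by running
  the unpenalised iteration and checking for divergence or |β| > 10). The
  solver is verified against an independent brute-force oracle (dense grid
  search plus simplex/BFGS polish) to 1e-4 in the test suite.
* **Hierarchical** (`fit_hierarchical`): the primary estimator, a
  mixed-effects logistic regression with fixed effects
  {intercept, reward, transition, reward × transition} and a correlated
  per-subject random intercept and slopes, fit by Laplace-approximate
  maximum likelihood (`lme4::glmer`, bobyqa). Per-subject coefficients are
  fixed effects plus conditional modes (empirical-Bayes estimates); these
  are *shrunken* relative to pointwise estimates, and the suite checks
  `var(hierarchical) <= var(pointwise)` on shared data. Fixed-effect
  inference is Wald. On a convergence failure the model is refit with a
  diagonal random-effect covariance; `converged = FALSE` marks a second
  failure. The hierarchical fit is unpenalised — shrinkage is intrinsic.

Design-construction rules that needed a decision because they are commonly
left unstated: lagged pairs never span block boundaries (the drift, and
possibly the difficulty, changes there — a divergence risk to keep in mind
when replicating analyses that may have chained across blocks), and a
missed trial breaks the lag chain on both sides (neither the missed trial
nor its successor contributes a row).

# The diamond-hit model and a structural identifiability fact

`fit_hit_model` enters the previous trial's diamond hit into the stay
model. Because a dud ball can never hit the diamond, `hit = 1` implies
`reward = 1`, and therefore the lagged hit regressor is constant on all
previously-unrewarded rows. That makes the Reward × Hit column an *exact*
linear combination of the others — under ±1 coding, `r·h = 1 − r + h`
identically, and the same holds for any coding — and likewise for the
three-way term. A naive full-factorial specification is rank-deficient and
backends silently drop columns. The package instead specifies the
identified parametrization directly: fixed effects
{intercept, reward, transition, reward × transition, hit,
transition × hit}. The `prev_hit` main effect is estimated purely from
hit-vs-no-hit variation among previously-rewarded trials, so it *is* the
substantive "does the secondary reward potentiate or interrupt learning"
contrast (negative = reduced staying after a rewarded hit), and
`prev_transition:prev_hit` plays the same role for the model-based
component. The generative check in the suite turns on the agents'
`hit_distraction` mechanism (a multiplier on the learning rate on hit
trials) and confirms the `prev_hit` effect goes negative.

# The synthetic world

The generator states one fixed world; its defaults are not tuned.

**Task defaults** (`task_config()`): 80:20 transitions; 200 trials in two
100-trial blocks, easy then medium; hit rates easy 52% and medium 45% (the
deployed blocks' average hit rates; within-level variation across the
deployed level layouts is not modelled — hitting is a pure Bernoulli draw
and aiming skill is out of scope). The free-play-only hard level has no
published rate; 30% is this package's one-time choice. Missed trials are
injected i.i.d. per trial at `miss_rate` (real missingness is dominated by
dropout, which is not modelled — an exclusion-testing knob, not a
behavioural claim).

**Drifts**: the default drift is a Gaussian random walk with per-step sd
0.025 *reflected* at bounds [0.25, 0.75] (the classic task's reward
structure). Reflection, not clipping, because clipping piles probability
mass at the bounds; the folded walk's stationary law is uniform on the
interval, which the ensemble test exploits (grand mean ≈ the midpoint).
The two deployed drift conditions are only known by their summary moments,
so `drift_preset("A")` / `"B"` emulate them by moment-matching: a smooth
reflected walk is affinely rescaled, clipped, and resampled until the
realised mean and sd are within `tol` (default 0.005) of the targets
(A: purple 0.845/0.053, pink 0.748/0.049; B: purple 0.774, pink 0.501 with
package-chosen sds 0.10/0.05 reflecting the described shapes). Trend shape
beyond moments is deliberately not matched — the raw sequences were never
published. Drifts are re-randomised per block.

**Agents** (`hybrid_agent`): the community-standard hybrid learner, reduced
to the single-choice task: model-based value propagates the learned colour
values through the (displayed) transition probabilities, the model-free
value is a per-container delta rule, the two are mixed by the model-based
weight `w ∈ [0, 1]`, and choice is softmax with an additive stickiness
bonus. One learning rate is shared by both value systems (both update from
the same binary reward), there is no eligibility-trace parameter (no second
stage), values start at 0.5, and `p_common_belief` defaults to the true
`p_common` because the structure is visible on-screen. Degenerate agents
(uniform-random, fixed-side, win-stay-lose-shift) serve null calibration
and exclusion tests.

**Population** (`population_spec`): `w = plogis(η)` with
`η = intercept + b_c·trait + effects(age, gender, education) + noise`.
Trait ~ N(0,1) stands in for a compulsivity-like symptom dimension; age ~
N(45.4, 14.5) truncated to 18–84, 64% women, 64% post-secondary educated
(mirroring a large citizen-science cohort). Covariate effects on the logit
scale (−0.10 per age SD, −0.08 woman, +0.10 educated) are the package's
one-time realistic choices reproducing the canonical directions. Nuisance
agent parameters: learning rate ~ Beta(3,3), inverse temperature ~
Gamma(10, 2) (mean 5), stickiness ~ N(0.2, 0.3). The parameter-recovery
mode (`w_dist = "uniform"`) draws `w` uniformly and *fixes* the nuisance
parameters at their population means — the standard recovery design, so
that the recovery correlation isolates `w`.

## Calibrating the latent trait

The target trait–MBI correlation (default −0.12, the external-validity
anchor this class of task is powered around) refers to the correlation
between the trait and the *estimated* MBI, which is attenuated relative to
the trait–η correlation by everything between η and the estimate
(the logistic squash, agent-parameter heterogeneity, finite-trial
estimation noise). The attenuation was measured once by simulation —
`cor(logit w, pointwise MBI) = 0.362` at n = 3000 subjects under the
default task and population — frozen as a package constant (0.36), and the
trait slope is then solved analytically:
`b_c = s0·q/sqrt(1 − q²)` with `q = target/0.36` and `s0` the sd of the
remaining η components. Targets with `|target| ≥ 0.36` are rejected as
infeasible at spec-construction time. The calibration was fixed before any
acceptance measurement and is not revisited.

# What a green test does and does not establish

The synthetic world supports *property* claims: the estimators are
calibrated on null agents (type-I rate of the Wald test for the
interaction ≤ 8% at nominal 5%), discriminate high from low `w`, recover
`w` with r ≥ 0.5 at 200 trials, reproduce a built-in trait association
within its sampling band, and show split-half reliability rising and
plateauing with trial number on stationary agents. None of this is a claim
about human data: the agents are stationary (no practice, fatigue or order
effects — which is exactly what makes the flat binned-MBI control
informative: in humans a decline across bins is an order effect, not a
property of the estimator), missingness is i.i.d. rather than
dropout-shaped, and the hybrid agent is a stand-in the task's human
designers never committed to.

# Numerical choices

* Newton iterations stop at gradient norm < 1e-8 (steps damped to length
  10, divergence declared at |β| > 50); ridge enters as λ‖β‖² with
  λ = 1e-3 by default.
* `glmer` runs with bobyqa, `calc.derivs = FALSE` and singular-fit checks
  off (boundary fits are legitimate under null between-subject variance).
* Moment-matching iterates rescale-and-clip 40 times per attempt, then
  resamples (cap 500 attempts) before failing with a diagnostic.
* Split-half parity uses the *stay* trial's 0-based index within session
  (even indices vs odd); subjects need ≥ 2 rows per half or are dropped
  with a count. The CI is Fisher-z; the ICC CI is the standard F-based
  interval. Reliability bands close on the left (0.4 fair, 0.7 good,
  0.9 excellent).
* Exclusion comparisons are strict (> 20% missed, > 95% same choice),
  matching the "more than" phrasing of the filters.
* All simulation is driven by a single master seed; per-subject seeds are
  drawn with `sample.int(.Machine$integer.max, n)`, making every artifact
  byte-reproducible.

# Runtime scaling in the test suite

Two stated checks are scaled down purely for runtime, not substance: the
Wald-calibration loop runs 100 replicates of 40 null subjects × 100 trials
(nominal type-I error does not depend on cohort size), and generative
mixed-model recovery uses 80 subjects × 100 rows. The trial-number curve
uses the pointwise estimator (the package's documented fast route for
25-trial windows). The binned-flatness control is tested jointly with a
repeated-measures ANOVA rather than as twelve simultaneous 2-SE checks,
whose family-wise false-alarm rate would be ~46% by construction.

# Known limitations

* No reaction times, no aiming physics, no within-level hit-rate
  heterogeneity, no dropout process.
* No hierarchical-Bayesian estimation variant and no likelihood-based
  fitting of the agent parameters themselves; estimation is exclusively
  the stay-regression family.
* Replication against deposited human datasets requires a user-supplied
  column map onto the trial-log schema; nothing is scraped or bundled.
* The trait calibration constant is tied to the default task and
  population; materially different configurations (e.g. 25-trial sessions)
  attenuate differently, and `synth_population` makes no attempt to
  re-calibrate on the fly.
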