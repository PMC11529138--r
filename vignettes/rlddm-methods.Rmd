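---
title: "Modelling probabilistic selection with the reinforcement-learning drift diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling probabilistic selection with the reinforcement-learning drift diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlddm)
```

## The task

The probabilistic selection task (PST) presents three fixed symbol pairs —
conventionally AB, CD and EF — in randomised blocks of 60 trials (20 per
pair, left/right position balanced in probability). Choosing the better
symbol of a pair yields positive feedback with probability 0.8 (AB), 0.7
(CD) or 0.6 (EF); choosing the worse symbol yields positive feedback with
the complementary probability. Learning is criterion-terminated: after each
block, the session ends if the proportion of optimal choices in that block
reaches 60% (AB), 55% (CD) and 50% (EF) simultaneously; otherwise another
block is run, up to six blocks (360 trials). Participants who never reach
criterion are conventionally excluded.

Two details of the stopping rule are under-determined by the usual verbal
description, and this package makes them explicit:

* **Accuracy means optimal choices, not rewarded choices.** Feedback is
  probabilistic, so "percent correct feedback" would conflate learning with
  luck; the per-pair thresholds mirror the reinforcement asymmetries, which
  only makes sense for choice accuracy.
* **Criteria are evaluated on the just-completed block only**, not
  cumulatively. This matches the blockwise flow of the task; a cumulative
  rule would make early guessing drag on later blocks.

One behavioural subtlety that the simulator makes visible: because sessions
stop early on *good* blocks, the observed session accuracy of even a
zero-learning (random) agent is biased slightly above chance. Tests that
probe chance-level behaviour therefore disable the stopping rule.

## The model

Each symbol `s` carries a learned value `Q[s]`, initialised at 0.5 (rewards
are coded 0/1, so 0.5 is the uninformed value and makes the initial drift
exactly zero). After feedback `R` for the chosen symbol, the delta rule
updates only that symbol:

    Q <- Q + eta * (R - Q)

In the dual-rate variant the learning rate is `eta_pos` when the prediction
error `R - Q` is positive and `eta_neg` when it is negative (no update at
exactly zero). The printed form of the extended delta rule lists both rate
terms additively; applying both on every trial would double-count the
prediction error, so the standard sign-gated reading is implemented.

Choices and response times arise from a Wiener diffusion between two
boundaries separated by `a`, starting unbiased at `a/2`, with unit
diffusion coefficient and non-decision time `t0`. The trial drift rate is
the scaled value difference of the presented pair,

    v(t) = (Q[better] - Q[worse]) * v_scaling

taken linearly (the mapping is an open design choice; the linear form is
the one the model equations print). Responses are coded by boundary: the
upper boundary is the pair's optimal symbol, the lower its suboptimal one.
`v_scaling` plays the role of the softmax inverse temperature: larger
values mean stronger exploitation of the learned value difference. No bias,
collapsing-bound or inter-trial variability parameters are included; the
model's free parameters are exactly the learning rate(s), `v_scaling`, `a`
and `t0`.

### Parameters at a glance

| parameter | units | support | preset group mean | role |
|---|---|---|---|---|
| `eta` / `eta_pos` / `eta_neg` | — | [0, 1] | 0.10–0.30 | fraction of prediction error incorporated |
| `v_scaling` | 1/value/s | ≥ 0 | 1.8–2.5 | value-difference-to-drift gain (exploitation) |
| `a` | evidence | > 0 | 1.6–2.1 | boundary separation (response caution) |
| `t0` | s | ≥ 0 | 0.35 | encoding + motor latency |

## Numerical core

**Density.** The Wiener first-passage-time (wfpt) density is evaluated
through the standardised density `f(u | w)` with `u = (t - t0)/a^2` and
relative start `w = 1/2`, using the small-time and large-time series
expansions with automatic regime switching; the number of terms is chosen
for truncation error below 1e-7. Both series are summed in log space
(signed log-sum-exp), which keeps log-densities finite and accurate over
decision times from 0.1 ms to tens of seconds — far into the tails, where
the leading term alone underflows double precision. Density is identically
zero for `rt <= t0`.

**Simulation.** First passages are simulated by Euler–Maruyama with step
`dt = 1e-4` s (configurable), augmented with the exact Brownian-bridge
probability of an unobserved within-step crossing. The bridge correction
removes the `O(sqrt(dt))` absorption bias of naive Euler checks; simulated
upper-boundary fractions match the closed-form absorption probability
`1/(1 + exp(-a v))` and the full RT histograms match the wfpt density to
Kolmogorov–Smirnov distance below 0.01 at 1e5 draws (these agreements are
asserted by the test suite, not assumed).

## Hierarchical inference

`fit_rlddm()` estimates subject-level parameter vectors drawn from
condition-specific group distributions, sampling on transformed scales:
logit for learning rates, log for `v_scaling`, `a` and `t0`. By default the
learning rate(s), `v_scaling` and `a` vary by condition and `t0` is shared,
matching the usual PST modelling setup; this is configurable through
`condition_varying`.

**Priors** (unstated in the source analyses; package defaults, overridable
via `rlddm_priors()`): group means are normal on the sampling scale —
logit-rates centred at `qlogis(0.2)` with SD 1.5, `log(v_scaling)` at
`log 2` (SD 1), `log a` at `log 1.6` (SD 0.8), `log t0` at `log 0.35`
(SD 0.8) — and group spreads are half-normal (scale 1 for rates, 0.5
otherwise). These are weakly informative on the natural scales: e.g. the
rate prior's 95% interval spans roughly 0.01–0.82.

**Likelihood.** Each trial contributes the wfpt density of its
response-coded (boundary, RT) at the drift implied by the delta-rule
Q-state reconstructed from the subject's observed choice/feedback history,
mixed with a uniform outlier contaminant over the observed RT range
(probability `outlier_mix_prob`, default 0.05, split equally across
boundaries). The contaminant is the established mechanism for absorbing the
residual slow/fast outliers that survive the hard 200–4,000 ms filter, and
it keeps the posterior proper when `t0` approaches the fastest observed
response.

**Sampler.** Adaptive Metropolis-within-Gibbs, chosen because the
trial-recursive likelihood rules out conjugate or gradient-ready forms:

* subject vectors: joint random-walk Metropolis with per-subject proposal
  covariance learned from the subject's own burn-in history (Haario-style
  adaptive Metropolis, scalar scale tuned towards ~30% acceptance);
* group means: conjugate normal Gibbs draws;
* group spreads: random-walk on the log scale plus joint *scale moves* that
  rescale a spread together with its subjects' deviations (the subject
  prior terms and Jacobian cancel analytically);
* per-condition *translation moves* that shift a condition's group mean and
  all of its subjects' parameters by a common vector drawn from an
  adaptively learned covariance.

The blocked translation moves matter. In short criterion-terminated
sessions the data largely constrain the *product* of learning rate and
drift scaling (early in learning, drift grows roughly like
`eta * v_scaling * t`), so the posterior has a pronounced ridge between
those parameters; chains updated subject-by-subject get stuck at different
points along it. Translations move the whole hierarchy along the ridge and
bring split-Rhat for the group means from ~2 down to near 1 at modest chain
lengths. All adaptation freezes at the end of burn-in, keeping the retained
chain Markovian.

Defaults are 10,000 draws including 1,000 burn-in per chain, two chains,
and a split-Rhat warning threshold of 1.05. Convergence is reported, never
silently ignored: short exploratory chains will warn.

**Model comparison** uses the deviance information criterion,
`DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`, where `D(theta_bar)`
plugs in the posterior mean of the subject-level parameters on the sampling
scale (the classic form, focused on the subject level). Directional
contrasts report the posterior probability that a group-level difference
has a stated sign, and the associated Bayes factor uses the posterior-odds
convention `BF = (1 - p)/p`, which reproduces the conventional printed
pairs (p = .061 → BF ≈ 15; p = .013 → BF ≈ 76; p = .377 → BF ≈ 2).

## The synthetic study generator

`generate_study()` produces complete two-condition studies with the exact
statistical structure the fitting code assumes: subject parameters drawn
from condition group distributions (normal on the sampling scales), full
criterion-terminated sessions simulated with the learning diffusion agent,
and subjects failing criterion flagged — not dropped — so exclusion stays a
downstream decision. Two presets are provided:

* `"null"`: both conditions share `eta_pos = 0.15`, `eta_neg = 0.10`,
  `v_scaling = 2.5`, `a = 1.6`, `t0 = 0.35` s;
* `"paper_like"`: control as in `"null"`; the second condition has a higher
  positive-error learning rate (0.30), lower drift scaling (1.8) and higher
  boundary (2.1) — the qualitative effect directions reported for brief
  mindfulness inductions on this task. The *magnitudes* are invented
  package defaults (the published posteriors are not numerically readable),
  and the between-subject spreads (0.4 on logit rates, 0.25, 0.15, 0.10 on
  the log scales of `v_scaling`, `a`, `t0`) are chosen once to give
  realistic subject heterogeneity.

With these settings the generator lands close to the descriptive statistics
typical of online PST samples — mean accuracies near 70–75%, mean RTs near
0.9–1.4 s, and roughly 1–2% of responses outside the 200–4,000 ms window —
without any of those quantities being fitted.

What the generator does *not* emulate: demographic covariates, meditation
experience, attentional lapses beyond the diffusion process (no extra
measurement noise is added to RTs), posture/keyboard effects, or any
within-session drift in parameters. Passing recovery tests on these data
therefore demonstrates the correctness and calibration of the machinery
under the model's own assumptions, not robustness to real-data
misspecification.

Reproducibility: every subject's parameters and session derive from seeds
computed from (master seed, subject index), so single subjects can be
re-simulated bit-for-bit from the stored truth table
(`resimulate_subject()`).

## Validation scales

The automated checks run at sizes chosen to exercise the full pipeline at
desk scale:

* simulator/likelihood agreement on a 6-point grid of `(a, v)` with 1e5
  first passages per cell;
* parameter recovery on a `paper_like` study of 20 subjects per condition,
  fitted with 2 chains of 2,000 draws (500 burn): group-mean intervals are
  required to cover the generating values for at least 3 of the 4
  condition-varying parameters, and all three effect directions must be
  recovered with directional posterior probability above 0.9;
* model recovery on 10 replicate pairs of single- and dual-rate studies
  (20 subjects each, short single chains), requiring DIC to prefer the
  generating structure in at least 8 of 10.

## Known limitations

* The sampler is random-walk based; posteriors for studies much larger than
  a few thousand trials will need longer chains than the defaults for
  stable spread estimates (group-mean mixing is good, spread mixing is the
  slowest component).
* The learning-rate/drift-scaling ridge is a property of the task, not of
  the sampler: control-like subjects who reach criterion within one or two
  blocks identify the product far better than the components. Expect wide,
  correlated marginals for those parameters at small trial counts even at
  convergence.
* DIC is the only comparison criterion implemented, for comparability with
  the hierarchical-DDM literature it mirrors; it shares that criterion's
  known optimism about effective parameter counts.
* The diffusion simulator's bridge correction makes absorption unbiased at
  `dt = 1e-4` for the parameter ranges used here, but extremely small
  boundaries (`a` below ~0.2) would warrant a smaller step.
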