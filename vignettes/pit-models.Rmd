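---
title: "Modelling Pavlovian-instrumental transfer: task, models, and hierarchical fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Pavlovian-instrumental transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pitfit)
```

## The paradigm

Pavlovian-instrumental transfer (PIT) measures how reward- and
punishment-predictive cues, learned passively, modulate instrumental
behaviour learned by trial and error. The task encoded by `task_config()`
has four stages:

1. **Instrumental training.** Four shell stimuli — two "good" (G1, G2), two
   "bad" (B1, B2) — and two actions, *collect* (six or more keypresses) or
   *refrain*. Collecting a good shell or refraining from a bad one is
   rewarded with probability 0.80; the incongruent actions with probability
   0.20; every non-rewarded trial is punished. Blocks 1 and 2 (20 trials
   each) introduce G1/B1 and G2/B2; block 3 mixes all four and ends once
   accuracy over the last 10 block-3 trials reaches 80%, or after 40 trials.
2. **Pavlovian training.** Three audiovisual cues are deterministically
   paired with reward (CS+), nothing (CS0), or punishment (CS-), 8
   presentations each. No behaviour is recorded, so no model is fitted to
   this stage; cue valences enter the analysis as known labels.
3. **Transfer.** The instrumental task continues in extinction (no
   feedback) with a task-irrelevant CS behind each trial; each of the 12
   shell-by-cue combinations appears 6 times (72 trials).
4. **Forced choice.** Each unordered cue pair, 3 times; the subject picks
   the better cue, verifying that the Pavlovian contingencies were learned.

Schedules are built with their full block-3 length and truncation by the
learning criterion happens at simulation/analysis time, which keeps
schedules side-effect-free and replayable. Screen side is generated but
carries no model semantics, and the two shells of a category are collapsed
to "good"/"bad" everywhere in the modelling, since they share parameters.

## The model space

All models share a two-action softmax over action weights,
$p(\text{collect}) = \sigma(W(\text{collect}) - W(\text{refrain}))$.
During instrumental training the weight is the expected value plus a
collect bias, $W^I(S,a) = Q(S,a) + b(a)$, with $b(\text{refrain}) \equiv 0$
for identifiability, and values follow a Rescorla-Wagner delta rule after
feedback $r_t \in \{-1, +1\}$:

$$Q_{t+1}(S,a) = Q_t(S,a) + \epsilon(r_t)\,\bigl(\rho(r_t)\, r_t - Q_t(S,a)\bigr).$$

The six instrumental models factor this into: a single learning rate
$\epsilon$ versus separate $\epsilon_{rew}/\epsilon_{pun}$; a single
sensitivity $\rho$ versus separate $\rho_{rew}/\rho_{pun}$; and presence or
absence of the bias $b$ (models M1-M6; see `model_spec()`). The three
transfer models extend the four-parameter winner M4: the end-of-training
weights carry into extinction and the cue adds a constant Pavlovian factor
$f(S^P)$ to the collect weight,

$$W^{PIT}(S^I, S^P, a) = W^I_T(S^I, a) + f(S^P, a) + \eta(S^I, a),$$

with $f(\cdot, \text{refrain}) \equiv 0$. M4+M7 transfers values losslessly
($\eta \equiv 0$); M4+M8 decays the carried $Q$ by a rate
$\alpha \in [0,1]$ once after every transfer trial; M4+M9 instead adds a
free per-shell-category noise $\eta(S^I)$ to the collect weight
($\eta(\cdot,\text{refrain}) \equiv 0$, like the bias and factors).

Values are initialized at zero for every stimulus-action pair. The design
here was genuinely open (no stated initial value); zero matches the
zero-mean group prior and makes the first choice maximally uncertain under
the symmetric softmax.

### Parameter transforms

The group-level Gaussians live on an unconstrained scale, so each
parameter carries a transform: learning rates and the decay rate pass
through the logistic sigmoid (rates in $(0,1)$), sensitivities through the
exponential (positive gains), and biases, factors and noise terms are
unconstrained. Constraining $\rho > 0$ is this package's choice; nothing in
the model requires a signed sensitivity, and the exponential keeps the
reward target $\rho r$ sign-interpretable.

### Two-stage transfer estimation

The transfer models condition on the *fitted* end-of-training quantities:
M4 is estimated on the instrumental trials, each subject's final value
table and bias are frozen (`carryover_values()`), and only the transfer
parameters are free on the extinction trials. This mirrors weights being
"fitted at the end of the instrumental stage" and keeps the transfer
comparison about transfer mechanisms rather than re-opened learning
parameters. Joint estimation (shared instrumental parameters re-estimated
on both stages) is available via `fit_transfer(..., joint = TRUE)` for
sensitivity analysis. The per-category noise of M4+M9 is treated exactly
like every other parameter — one unconstrained value per subject under one
group Gaussian per parameter.

## Hierarchical fitting

`em_fit()` implements the two-step iterative scheme:

* **MAP step.** Each subject's unconstrained parameters maximize choice
  log-likelihood plus the group Gaussian log-prior (BFGS with
  finite-difference gradients; best of `n_restarts` restarts, the first at
  the prior mean, the rest drawn from the prior). The Hessian of the
  negative log-posterior at the optimum is computed by central finite
  differences and jittered to positive definiteness when needed (logged in
  the fit object).
* **EM step.** Treating subject parameters as latent, the Laplace
  approximation gives the standard moment update: group mean = average MAP
  estimate; group variance = average of (MAP estimate squared + the
  corresponding diagonal of the inverse Hessian) minus the squared mean,
  floored at $10^{-6}$. The covariance is diagonal by design — one mean
  and one variance per parameter, matching the evidence penalty.

Iteration starts from the wide uninformed prior N(0, 10) on every
parameter and stops when the relative change in the summed log-posterior
drops below `tol` ($10^{-3}$ by default; `max_iter` 100). Group labels
never enter the prior: all subjects shrink toward one shared distribution,
so downstream between-group contrasts are not biased by separate shrinkage
targets. Degenerate subjects (e.g. all-collect) are fitted as usual; the
prior bounds the otherwise flat directions.

Model evidence (`lme()`) is the Laplace approximation with a group-level
complexity penalty:

$$\mathrm{LME} = \sum_n \log P(D_n \mid \theta_n) + \sum_n \log
N(\theta_n \mid \Theta, \Sigma) + \tfrac12 d N \log 2\pi - \tfrac12 \sum_n
\log |H_n| - d \log N.$$

The formula is implemented exactly in this form, including the
$\tfrac12 dN\log 2\pi$ term; `group_penalty = FALSE` exposes the variant
without the $-d\log N$ term for comparison with textbook Laplace sums.
Comparisons (`compare_models()`) are blocked by stage: M1-M6 against each
other on instrumental data, and the three transfer models against each
other conditional on M4.

## The synthetic-cohort generator

`simulate_cohort()` draws each subject's unconstrained parameters from
independent Gaussians and simulates all four stages in the generative
direction of the same equations the likelihood scores, recording the truth
for recovery scoring. The reference generating conditions
(`reference_cohort_parameters()`) place the reward learning rate well
above the punishment learning rate (natural means about 0.62 vs 0.18),
sensitivity near 2, a small positive collect bias, and Pavlovian factors
ordered CS+ > CS0 > CS- symmetrically about zero, with between-subject
spread of order one on the unconstrained scale — a cohort that learns the
task within the first two blocks and shows the canonical monotone transfer
signature. These values were chosen once as plausible for this class of
task and are not adjusted per experiment.

Two pieces of behaviour are deliberately conventional, because the models
are defined over the binary choice only:

* **Keypress counts.** Collect trials emit the 6-press threshold plus a
  Poisson(1) overshoot; refrain trials a Poisson(1) count truncated below
  the threshold. Thresholding the count recovers the action exactly, and
  per-cue keypress means respond to collect-probability differences, which
  is all the model-free measures need. Real keypress distributions within
  the response window are not modelled.
* **Forced choice.** A valence-ordering chooser with a 2% lapse rate
  reproduces the near-ceiling accuracy regime without introducing a new
  learning model.

Passing tests on these cohorts therefore show that the pipeline recovers
what it generates under the task's information constraints — not that real
subjects obey the model, and not anything about reaction times, vigour
dynamics, or attrition.

## Numerical choices and problem sizes

* Log-softmax is evaluated in a stable form (`log1p(exp(-|x|))`), so
  likelihoods stay finite for weight differences up to overflow scale.
* Non-positive-definite Hessians receive the minimal diagonal jitter that
  clears the smallest eigenvalue, and the jitter is recorded per subject.
* The recovery experiments in the test suite use one 60-subject cohort for
  parameter recovery (EM capped at 12 iterations, 2 restarts) and 20
  replicate 60-subject cohorts per block for model recovery (EM capped at
  4 iterations, 2 restarts), sizes chosen to exercise the full pipeline at
  the study's cohort scale while keeping the suite fast.

## Known limitations

* With paper-scale instrumental training (~50-60 trials once the block-3
  criterion truncates), the reward learning rate is weakly identified at
  the individual level: good-shell choices saturate early, so little of
  the sequence carries information about $\epsilon_{rew}$. Rank
  correlations for $\epsilon_{rew}$ plateau well below those for $\rho$
  and $b$ regardless of the generating spread; recovering it reliably
  takes several hundred trials per subject. Similarly, with 24 transfer
  trials per cue the per-subject estimation noise for a Pavlovian factor
  is of the same order as a modest between-subject spread, so rank
  correlations for a weakly dispersed factor (the CS0 factor under the
  reference conditions) sit near 0.5 while the strongly dispersed CS+ and
  CS- factors recover well.
* In two-stage transfer estimation the carryover weights are estimates,
  and the per-category noise terms $\eta$ of M4+M9 absorb their systematic
  error: recovered $\eta$ group means can sit a few tenths away from zero
  even when the generating means are zero. The Pavlovian factors are
  robust to this (the compensation is category-specific, not
  cue-specific).
* The evidence formula's $\tfrac12 dN \log 2\pi$ term rewards dimensionality
  and differs from some textbook Laplace formulations; it is kept as the
  package's canonical criterion (with the flag above) for comparability.
* Specific-versus-general transfer distinctions, outcome devaluation, and
  vigour/reaction-time models are out of scope.
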