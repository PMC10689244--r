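---
title: "Models and methods behind metabandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metabandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metabandit` is a simulation-and-analysis workbench for studying
meta-reinforcement learning in a probabilistic reversal task: a slow,
across-session learning loop (weight updates of a recurrent network)
that shapes a fast, within-session loop (trial-by-trial value updating
carried purely by recurrent activity). Every analysis stage can be
exercised against synthetic data with known ground truth. This vignette
documents the models, the default parameters and why they were chosen,
the numerical decisions, and what the synthetic benchmarks do and do not
establish about real data.

## The task environment

The environment is a two-port bandit with reward *baiting* (a concurrent
variable-interval schedule). On every trial each port independently
receives a reward assignment with probability $A_L$ or $A_R$ unless a
reward is already loaded there; a loaded reward stays until that port is
next chosen. Assignment pairs cycle
$(0.60,0.10)\to(0.10,0.60)\to(0.525,0.175)\to(0.175,0.525)\to\dots$ with
uncued block transitions every 60–80 trials (uniform). A scheduled
transition is *postponed* until the fraction of high-side choices over
the recent 60 included choice trials reaches 50%, so that each block ends
with the subject actually exploiting the high side.

Because baits accumulate, the probability that a reward is available on
a side after $k$ successive opposite choices is
$1-\prod_x (1-A(x)) = 1-(1-A)^{k+1}$ under constant $A$. Two session
metrics follow: the **optimality score** (mean availability on the
chosen side — insensitive to assignment randomness) and
**P(choose high)** (fraction of choices on the higher-$A$ side).

Decisions where the procedure was open:

* Bait draws happen at the start of every trial, for both sides,
  consistent with the availability product counting the current trial.
* Both baited flags start clear at session start; choice-run counters do
  not cross session boundaries.
* The postponement window counts *included choice* trials only; miss and
  alarm trials (no choice) neither help nor hurt the criterion.
* Trials are discrete events; lick timing, inter-trial intervals and
  pretraining are not modeled. Time matters only through the agent's
  4-or-5-step within-trial clock.

## The recurrent actor–critic agent

The agent is two parallel 50-unit simple recurrent networks (no gating)
with $\mathbf{y}_t=\tanh(W_x\mathbf{x}_t+W_y\mathbf{y}_{t-1}+\mathbf b)$.
Both receive the same three inputs — previous reward, previous left
choice, previous right choice — active only at the single step
immediately after the previous choice; the session's first trial gets
all-zero inputs. The actor head emits two action logits (softmax
sampling at the trial's final step); the critic head emits a scalar
state value. Each trial runs 4 or 5 steps (uniform), emulating variable
inter-trial intervals.

Training is advantage actor–critic (A2C) with truncated backpropagation
through time:

* policy loss $-\ln\pi(a_t\mid s_t)\,\delta_t-\beta_e H(\pi)$ at action
  steps, with the TD error $\delta_t=R_t-V(s_t)$ as the advantage;
* value loss $\beta_v\cdot\tfrac12 (R_t-V(s_t))^2$ at every step;
* $R_t$ the discounted n-step return truncated at the 50-step unroll
  boundary, bootstrapped with the critic's value at the next segment's
  first step (zero at session end).

Hyperparameters are the study conditions: learning rate $5\times10^{-4}$,
$\gamma=0.5$ per step, $\beta_e=0.5$, $\beta_v=0.01$, unroll 50 steps,
500 trials/session, 300 training sessions plus a frozen 301st
evaluation session. Weights are strictly frozen within a session —
per-segment gradients are stored and applied only at the session
boundary, which is what forces trial-by-trial value updating into the
recurrent dynamics rather than into the weights.

Numerical/design choices:

* Gradients treat $\delta_t$ and the bootstrap value as constants (the
  two partial-derivative terms of the actor-critic gradient). The
  finite-difference oracle in the test suite differentiates exactly the
  same function, so the check is sharp at $10^{-5}$ relative error.
* Value loss is step-granular. Whether the value target should instead
  be trial-granular is genuinely ambiguous ("state value for the next
  trial"); with $\gamma=0.5$ per step the two readings differ little,
  and the step-granular form matches the step-denominated unroll.
* RMSProp decay 0.99 and epsilon $10^{-5}$ (not dictated by the
  training recipe; exposed in `train_config()`). Stored segment
  gradients are applied sequentially in order at the boundary; a single
  averaged step is available via `update_mode = "averaged"`.
* Initialization is Glorot-uniform with zero biases.
* Unit inactivation zeroes the selected units' activations at the
  trial's final recurrent step — the activity pattern the softmax
  readout sees, mirroring suppression through the prechoice period.
  Inactivation trials are scheduled at ~13% with at least four
  consecutive control trials after each.

The forward pass and BPTT are compiled (RcppArmadillo); all sampling
stays in R so a single `set.seed()` makes training bit-reproducible. A
300-session training run takes roughly half a minute on one CPU core,
so the meta-learning benchmarks run at the full 300 × 500 scale.

## Behavioral models

**History logistic regression.** The log odds of a left choice are
modeled by five lags of signed reward history $r_L-r_R$ and choice
history $c_L-c_R$ plus a bias; fitted by maximum likelihood without
regularization. The first five choice trials are dropped (incomplete
regressors), not zero-padded. A session's 5-vectors of reward- and
choice-history weights are its *policy axes*; angles between sessions'
axes measure policy stability. Summed weights separate reward-following
(positive reward sum) from reward-independent alternation (negative
choice sum).

**Split control/inactivation regression.** One model with separate
weight sets interacted with the trial-class indicators, L2-penalized;
the penalty is picked by fivefold contiguous cross-validation on a
100-point log grid of inverse penalty strength in $[10^{-4},10^4]$.
Control response rows are subsampled to the inactivation count, with
the minimum number of iterations that covers every control row;
weights are averaged over iterations and $|\mathrm{bias}|$ is taken per
iteration before averaging.

**Forgetting Q-learning model.** Chosen value moves toward the outcome
with learning rate $\alpha_{rew}$ (rewarded) or $\alpha_{unr}$
(unrewarded); unchosen value decays by $(1-\omega)$. Choice follows a
logistic in $\beta_{\Delta Q}(\beta_0[+\beta_c C_{t-1}]+Q_L-Q_R)$; the
$\beta_c$ term (deep-RL variant) captures outcome-independent
alternation. The fit minimizes the L2-penalized negative log-likelihood
with bounded L-BFGS-B; $\lambda$ is chosen on a 20-point log grid in
$[10^{-4},10^2]$ by tenfold contiguous-block cross-validation (blocks,
not shuffles, because choices are serially dependent). Within the CV
loop each fit is warm-started from the previous $\lambda$'s solution;
the final refit uses ten random restarts. Initial values are
$Q_L=Q_R=0.5$ (midpoint of the admissible range; configurable), and
$\beta_{\Delta Q}$ is bounded below at zero. Parameter recovery on
teacher-generated sessions (500 trials) has median absolute errors
below 0.1 for the learning and forgetting rates.

## Trial-difference decoding

Action values and population activity are both slowly autocorrelated,
so regressing one on the other per trial inflates accuracy: two
independent slow variables correlate by chance. The decoders therefore
regress *changes* between adjacent retained trials:
$\Delta Q(t+1)-\Delta Q(t) = \sum_i \beta_i (a_i(t+1)-a_i(t)) + \beta_0$,
and likewise for $\Sigma Q$ and $Q_{ch}$. Estimation is ordinary least
squares (rank deficiency falls back to the least-norm solution with a
warning); accuracy is the correlation between held-out predictions and
observed differences over tenfold contiguous, unshuffled
cross-validation. "Adjacent" means adjacent within the retained
(included) trials, skipping excluded ones.

Chance floors: within-session (value differences shuffled 100 times
across rows) and cross-session (foreign sessions' value series,
circularly rotated at a random offset — offset zero allowed — and
re-indexed to the session length). Fixed-size subsampling (default 55
cells) repeats covering draws without replacement until every neuron is
used, topping up the last draw by re-sampled cells, and averages the
accuracy.

A session's decoder weight vector over the neurons registered as shared
with a partner session is its *coding axis*; cosine similarity between
paired sessions measures representational stability, and the paired
coding-axis/policy-axis angles are related by Spearman correlation with
a permutation p-value — a deliberate, clearly-labeled resampling
substitute for mixed-effects inference, which is out of scope here.

## The synthetic-data generator

The generator supplies ground truth for every stage:

* **Behavior**: the forgetting-Q teacher plays the real environment
  (defaults $\alpha_{rew}=0.6$, $\alpha_{unr}=0.2$, $\omega=0.1$,
  $\beta_{\Delta Q}=3$, $\beta_0=0$ — a regime producing clear but
  imperfect reward-following, with P(choose high) around 0.7).
  Miss/alarm trials are inserted at a configurable rate with
  `included = FALSE`; the teacher's values do not update on them. A
  history-kernel teacher generates choices directly from the logistic
  history model where the ground-truth policy axis must be controlled
  exactly.
* **Activity**: $a_i(t)=\sum_s w_{is}\,\mathrm{signal}_s(t)
  +\mathrm{drift}_i(t)+\varepsilon_i(t)$ with signals standardized,
  Gaussian coding weights, white noise at the coding scale and drift at
  twice the coding scale. The drift is a random walk lightly smoothed
  with an exponential kernel (timescale 3 trials): slow in levels —
  enough to inflate a per-trial decoder on unrelated slow variables —
  but nearly unstructured in trial-to-trial increments, which is
  precisely the regime the trial-difference decoder targets. A heavily
  smoothed walk would leave even the increments slow and would
  misrepresent the phenomenon being emulated.
* **Longitudinal studies**: two disjoint "planes" per subject imaged on
  alternating sessions (so comparable pairs are two sessions apart),
  behavior from a kernel teacher whose reward kernel rotates by
  $45^\circ \times 0.65^{k-1}$ per session step ("rotate then freeze"),
  coding axes rotating on the same decaying schedule, value signals
  from a fixed forgetting-Q observer run forward on each session's
  choices (deterministic, no fitting), and 10% per-session neuron
  dropout feeding the shared-neuron registration. Coupling the two
  rotation schedules is what makes coding-axis stability track policy
  stability in the benchmark.
* **Inactivation schedules**: after each flagged trial, `min_gap`
  forced controls; eligible trials are flagged with probability
  $q=\mathrm{rate}/(1-\mathrm{rate}\cdot\mathrm{min\_gap})$, which
  yields the requested long-run rate (infeasible rates are refused).

## What the benchmarks show — and what they do not

Problem sizes in the shipped checks: 100,000 Monte-Carlo episodes for
the baiting closed form; 1,000 realized blocks for the scheduler; three
seeds × 300 sessions × 500 trials for meta-learning; 50 repeats of 30%
silencing; 10 sessions for value-model recovery; five 5,000-trial
sessions for kernel recovery (the median fit is compared, since a
single draw's worst-coefficient sampling error straddles the ±0.1
band); three drift-only null populations for spurious-correlation
suppression; and a 3-subject × 12-session longitudinal study for the
axis geometry.

The synthetic populations are linear, Gaussian and stationary apart
from the scripted drift and axis rotation. They do not emulate calcium
indicator dynamics, deconvolution artifacts, nonlinear or sparse
coding, behavioral non-stationarity within sessions, or registration
errors across sessions. Passing benchmarks therefore establishes that
the *pipeline* is correct and unbiased under its own assumptions — not
that those assumptions hold in any particular recording. The
within-session chance floor, in particular, is honest only to the
extent that real drift has little increment structure at the trial
timescale; epochs are generated as separate labeled tables rather than
as continuous time series.

## Known limitations

* The agent uses a single worker and no gated units by design; results
  for LSTM/GRU agents or asynchronous training are out of scope.
* The value-model optimizer is multi-start local search; on rare
  sessions it settles on a local optimum (visible as an outlying
  parameter estimate). Medians across sessions are the intended summary.
* The split control/inactivation fit shrinks both weight sets toward
  zero; its absolute weight scale is not comparable to the
  unregularized fit, only contrasts within it are.
* Mixed-effects hypothesis testing is out of scope; permutation and
  bootstrap summaries stand in as plumbing.
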