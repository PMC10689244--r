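# metabandit

Simulation and analysis toolkit for **meta-reinforcement learning in a
baited reversal bandit**. The scientific setting: a subject (mouse-like
or artificial) chooses between two ports whose reward assignment
probabilities reverse without cue every 60–80 trials, and assigned
rewards are *baited* — they persist on a port until it is next chosen.
Across many sessions, a slow learning process shapes a fast one: the
subject (or a recurrent network with frozen within-session weights)
acquires a trial-by-trial reinforcement-learning policy carried by
activity dynamics rather than by synaptic change. The package provides
all the machinery to simulate this setting and quantify it:

* **Task environment** — baited two-port bandit, uncued block reversals
  with a performance-gated (postponed) transition rule, and the
  performance metrics that go with it: the *optimality score*
  $\frac1n\sum_t P_{rew,C}(t)$ with
  $P_{rew}(t) = 1-\prod_x(1-A(x))$ under baiting, and
  $P(\text{choose } A_{High})$.
* **Recurrent actor–critic agent** — two parallel 50-unit tanh
  recurrent subnetworks (actor, critic), trained with A2C
  ($L_\pi=-\ln\pi(a|s)\,\delta-\beta_e H(\pi)$,
  $L_v=\beta_v\,\tfrac12(R_t-V(s_t))^2$, $\delta=R_t-V(s_t)$) and
  truncated BPTT (unroll 50 steps), weights frozen within each
  500-trial session and updated only at session boundaries; plus unit
  inactivation experiments at the action-selection step.
* **Behavioral models** — 5-lag reward/choice history logistic
  regression (plain, and control/inactivation split with ridge + CV),
  policy axes and their angles, and a forgetting Q-learning model
  ($Q_{ch}\mathrel{+}=\alpha\,(R-Q_{ch})$,
  $Q_{unch}\mathrel{*}=(1-\omega)$) fitted by penalized maximum
  likelihood with cross-validated $\lambda$, yielding per-trial
  $\Delta Q$, $\Sigma Q$, $Q_{ch}$.
* **Trial-difference decoding** — linear decoders of value signals from
  *changes* in population activity between adjacent trials (suppressing
  spurious slow-autocorrelation coupling), within- and cross-session
  chance floors, 55-cell covering subsampling, coding axes and their
  cross-session geometry, and the coding-axis/policy-axis relation.
* **Synthetic data** — teacher-generated behavior with ground-truth
  values, linear-readout populations with drift and noise, longitudinal
  multi-plane studies with rotate-then-freeze schedules, and
  inactivation-trial schedulers.

Who it is for: computational neuroscientists who want a fully testable,
ground-truthed reimplementation of this analysis stack — to validate
analysis choices, run power/recovery studies, or train and dissect
small meta-RL agents on one CPU.

## Worked example

Train an agent, quantify its policy, and decode value signals from its
recurrent units:

```r
library(metabandit)

run <- train_agent(task_config(), train_config(), seed = 1)  # ~30 s
late <- run$sessions[292:301]
mean(sapply(late, p_choose_high))
#> [1] 0.598
fit <- fit_history_logit(late[[10]])
summed_history_weights(fit)
#>     sum_r     sum_c
#>  2.460450 -1.268448
```

After 300 sessions the agent chooses the high-probability side well
above chance, its summed reward-history weight is positive (it follows
reward history, the signature of trial-by-trial RL) and its summed
choice-history weight is negative (reward-independent alternation — an
adaptation to baiting, where the unchosen side accumulates reward).

Fit the value model to the frozen evaluation session and decode the
value difference from the recurrent population:

```r
rl <- fit_rl_model(run$sessions[[301]], variant = "deepRL")
act <- extract_unit_activity(run$rollout, "prechoice_mean3")
dec <- fit_value_decoder(trial_diff_design(act, rl$values$dQ), target = "dQ")
dec
#> <decoder_fit> dQ 100 neurons, 499 rows, CV r = 0.907
set.seed(2)
chance_within(trial_diff_design(act, rl$values$dQ), 100)$chance
#> [1] 0.00440585
```

The cross-validated trial-difference accuracy is far above its shuffle
floor (which sits at zero): the recurrent population robustly encodes
the value difference that drives the policy.

Synthetic ground truth works the same way for every stage, e.g.
parameter recovery:

```r
g <- gen_behavior_session(teacher_spec(alpha_rew = 0.6, alpha_unr = 0.2,
                                       omega = 0.1), seed = 12)
unlist(fit_rl_model(g$session, "mouse")$params)
#>   alpha_rew   alpha_unr       omega     beta_dq       beta0
#>  0.7291403   0.2589550   0.1702191   2.6983218  -0.0246020
```

See the methods vignette (`vignettes/metabandit-methods.Rmd`) for the
models, defaults and numerical decisions, and `inst/cli/workbench.R`
for a command-line wrapper over the simulate / train / analyze
orchestration functions (`wb_simulate()`, `wb_train_agent()`,
`wb_analyze()`).

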