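# observeTD

A seedable simulator and fixed-point analysis of a temporal-difference
(TD) account of **observing behavior** — the robust preference of animals
for stimuli that reveal the size of an upcoming reward even when the
information cannot change the outcome, together with the puzzling pattern
of phasic dopamine activity that accompanies it (a small activation at the
target announcing informative cues, a small depression at the target
announcing uninformative ones, despite equal objective value).

The package is for computational-neuroscience researchers who want to
simulate the observing task and its variants under this model, reproduce
its qualitative signatures, or swap in their own hazard/choice assumptions.

## The model

Learning is standard episodic TD(0) on the trial graph
(fixation → target/choice → cue → reward):

    V(s) <- V(s) + alpha * delta,    delta = r + V(s') - V(s)

with no within-trial discount and the terminal state pinned at 0. The one
departure is Pavlovian: *task engagement* (the working memory carrying the
state across the cue–reward delay) is lost stochastically at a per-second
hazard that decreases with the currently predicted value,

    rho(v) = min(1, a * exp(-v / b)),    P(disengage in state) = 1 - (1 - rho)^tau,

with `tau` the state duration in seconds. Disengagement drops the system
into a fixed, non-updating state of value `v_d` until the reward
re-engages it (update signal `v_d - V(s)` for the abandoned state; a
recorded but non-training error `r - v_d` at reward). Low-value,
uncertainty-bearing states are abandoned more often, so the
non-discriminative cues are subjectively undervalued, and the softmax/Luce
rule

    p(informative) = 1 / (1 + exp(-beta * (V_info - V_rand)))

(or its log-value, ratio-based variant) turns that into an observing bias.
The asymptotic values solve a self-consistency system in which each
state's backup is mixed with `v_d` at the state's own disengagement
probability; `solve_self_consistent()` solves it by damped iteration.

## Worked example

```r
library(observeTD)

task <- build_observing_task()        # q = 0.5, rewards 1 and 0.04 units
solve_self_consistent(task)
#> <fixed_point_result> bias = 0.5597 | iterations = 42 | residual = 9.99e-11
#>      START   TGT_INFO   TGT_RAND     CHOICE  CUE_LARGE  CUE_SMALL CUE_RAND_A
#>     0.4693     0.4808     0.4568     0.4703     0.9678     0.0320     0.4759
#> CUE_RAND_B        END
#>     0.4759     0.0000
```

Every pre-cue state is objectively worth 0.52; under disengagement the
random cues settle at 0.476 while the large-reward cue keeps 0.968 of its
value, so the informative target ends up worth more than the random one
(0.481 vs 0.457) and the asymptotic observing bias at `beta = 10` is 0.56.
The target-period prediction errors are the anomalous dopamine pattern:
`V(TGT_INFO) - V(START) = +0.012`, `V(TGT_RAND) - V(START) = -0.012`.

The same thing learned trial by trial:

```r
run <- run_acquisition(n_sessions = 25, seed = 1)   # 480 trials/session
run
#> <observing_run> 25 sessions x 480 trials | task: standard | beta = 10
#>   mean bias, last 5 sessions: 0.594
late <- run$sessions[run$sessions$session > 20, ]
clopper_pearson(sum(late$n_info), sum(late$n_choice))
#> pooled bias sessions 21-25: 0.601 [0.567, 0.635]
```

The bias (fraction of free-choice trials on which the discriminative
option is chosen) emerges slowly over sessions and its exact
Clopper-Pearson interval ends up excluding 0.5. Other experiment drivers:
`run_reversal()` (contingency switch without value reset),
`run_aversive()` (punishments under valence vs salience hazards),
`run_initial_values()` (over-/under-observation transients),
`bias_vs_reward_prob()` (difference- vs log-rule bias as reward thins),
`dopamine_trace()` / `truncate_signal()` (the modeled dopamine signal).
Tasks and parameters serialize to YAML/JSON via `write_config()` /
`read_config()`; a ready-made config ships in
`inst/extdata/observing-task.yaml`, and a command-line front end in
`inst/cli/observetd.R` exposes the drivers as subcommands
(`simulate`, `acquisition`, `reversal`, `aversive`, `initial-values`,
`fixed-point`, `dopamine-trace`).

See the vignette (`vignettes/observing-model.Rmd`) for the model's
assumptions, parameter meanings, numerical choices, and known limitations.

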