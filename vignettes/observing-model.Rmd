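---
title: "A TD model of observing behavior with value-dependent disengagement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A TD model of observing behavior with value-dependent disengagement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(observeTD)
```

## The phenomenon and the model

In an observing task a thirsty subject has, on every trial, a fixed chance
$q$ of receiving a large reward $r_L$ and otherwise a small reward $r_S$.
Nothing the subject does changes this. On *forced-informative* trials it is
shown a target followed by one of two discriminative cues that announce
which reward is coming; on *forced-random* trials a different target is
followed by one of two cues that carry no information (either cue is
followed by $r_L$ with probability $q$); on *free-choice* trials the
subject picks which pair of cues it will see. Subjects reliably prefer the
informative option — "observing behavior" — even though both options have
the same expected reward $q\,r_L + (1-q)\,r_S$, and putative dopamine
neurons show a small phasic increase at the informative target and a small
decrease at the random target, mirroring that preference.

This package implements an account on which no notion of "information
value" is needed. Learning is plain episodic TD(0) on the trial graph: each
state $s$ (fixation, targets, choice moment, cues) carries a value $V(s)$
updated on every transition by

$$V(s) \leftarrow V(s) + \alpha\,\delta, \qquad
  \delta = r + V(s') - V(s),$$

with no within-trial discounting, the terminal state pinned at $V = 0$, and
the reward attached to the transition into the terminal state. The single
departure from the standard model is Pavlovian: maintaining task engagement
(the working memory that carries the state forward between cue and reward)
is itself controlled by the current predicted value. While the system
occupies a state of value $v$ it disengages at a per-second hazard

$$\rho(v) = \min\!\big(1,\; a\,e^{-v/b}\big),$$

so the probability of disengaging somewhere inside a state of duration
$\tau$ seconds is $1 - (1-\rho)^\tau$. On disengagement the system drops
into a fixed, **non-updating** state of value $v_d$; the abandoned state
receives the update signal $\delta = v_d - V(s)$; nothing else is updated
until the reward arrives, which re-engages the system and produces a TD
error $\delta = r - v_d$ relative to the fixed state (recorded for the
modeled dopamine signal, but training nothing, since the disengaged state
never updates). Trial initiation always re-engages.

Because the hazard falls with value, the cue that surely predicts $r_L$ is
rarely abandoned, while the non-discriminative cues (value
$\approx q\,r_L + (1-q)\,r_S$) are abandoned at an intermediate rate and
are dragged toward $v_d$ each time. Disengagement on the small-reward cue
is *benign*: its value is already close to $v_d$, so the drag costs almost
nothing. The net effect is a subjective undervaluation specific to the
non-discriminative branch, and therefore a preference for observing on
free-choice trials, chosen by the softmax/Luce rule

$$p(\text{informative}) =
  \frac{1}{1 + e^{-\beta\,(V_{\mathrm{info}} - V_{\mathrm{rand}})}},$$

or its log-value variant, which depends on the *ratio* of the values and is
used for the reward-probability analysis below.

```{r fixed-point}
task <- build_observing_task()           # q = 0.5, r = 1 / 0.04
fp <- solve_self_consistent(task)
round(fp$values, 3)
fp$bias
```

The solver shows the signature directly: the random cues settle near 0.476
instead of their objective 0.52, the large cue barely moves (0.968 vs 1),
and the asymptotic observing bias at the default $\beta = 10$ is about
0.56. The prediction errors at the two targets at the fixed point are
$V(\mathrm{TGT_{INFO}}) - V(\mathrm{START}) \approx +0.012$ and
$V(\mathrm{TGT_{RAND}}) - V(\mathrm{START}) \approx -0.012$: positive for
the informative target, negative for the random one, exactly the anomalous
pattern in the recordings — and once free choices favor the informative
option, $V(\mathrm{START})$ sits above the midpoint of the two target
values, so the negative error is the larger in magnitude.

## Parameters, defaults, and why

| parameter | meaning | default | units |
|---|---|---|---|
| `q` | probability of the large reward | 0.5 | — |
| `r_large`, `r_small` | reward magnitudes | 1, 0.04 | reward units (ml) |
| `alpha` | learning rate | 0.1 | — |
| `beta` | softmax inverse temperature | 10 | 1 / reward unit |
| `param_a` | hazard at zero value | 0.1 | 1 / s |
| `param_b` | hazard value scale | 0.5 | reward units |
| `v_disengaged` | value of the fixed disengaged state | 0 | reward units |
| durations | fixation 1 s, targets 1 s, cues 2.25 s, choice 0 s | | s |

The hazard form above is a stand-in with the contract that matters — two
fixed parameters, a per-second rate, monotone decreasing in value — and it
is pluggable (`engagement_params(hazard_fn = ...)`), so any other
decreasing hazard can be substituted without touching callers. All of the
qualitative results in this vignette depend only on that contract. The cue
duration of 2.25 s encodes that reward follows the cue after a couple of
seconds; durations are configuration, not constants. The trial-type
mixture defaults to 1/3 each, so a 480-trial session contains 160 choice
trials in expectation. Sessions default to 25 per acquisition run, and the
asymptotic preference is monotone in `beta`; `beta = 10` (the top of the
grid over which that monotonicity is tested) was chosen as the default to
make the small disengagement bias clearly visible at session resolution.
`v_disengaged = 0` identifies the disengaged state with "no prediction".

Two modeling choices deserve emphasis:

* **The hazard is evaluated once per state, at the value held on entry,**
  for every within-trial state except two: the instantaneous choice
  moment, and the trial-initiation (fixation) state. The latter exemption
  follows from the same assumption that makes the intertrial interval
  safe: starting a trial re-engages the system, so no hazard accrues
  before the targets. It also matters quantitatively: letting the
  fixation state disengage would depress the pre-target baseline itself,
  and the random-target prediction error would no longer be negative.
* **The re-engagement error trains nothing.** The disengaged state is
  declared non-updating, so the error at reward delivery after
  disengagement is recorded for the dopamine trace only. This is the
  reading most consistent with a fixed $v_d$; the alternative (training
  some state at reward) would leak value into the disengaged state's
  neighborhood and is not implemented.

## The simulation experiments

`run_acquisition()` reproduces the slow, session-scale emergence of the
bias; `run_reversal()` swaps the target contingencies mid-run without
resetting values (the bias crosses 0.5 and settles near the mirror-image
asymptote); `run_aversive()` runs the punishment version under the two
hazard families — a *salience* hazard (even in value) protects engagement
for large-punishment predictions, disengagement then *raises* the
subjective value of the random branch toward $v_d = 0$, and subjects
prefer the random cues, while the asymmetric *valence* hazard yields more
observing; `run_initial_values()` shows the initial-value transients: at a
small learning rate (default 0.01 there, so the transient spans sessions)
starting all values at 0 under a rich schedule ($q = 0.9$) passes through
the high-hazard region and transiently *over*-observes relative to its own
long-run level, while starting at 1 under a thin schedule ($q = 0.1$)
suppresses the hazard early and *under*-observes.

```{r acquisition}
run <- run_acquisition(n_sessions = 8, seed = 1)
run$sessions[, c("session", "n_choice", "bias", "ci_low", "ci_high")]
```

Per-session bias is banded with the exact Clopper-Pearson 95% interval
(`clopper_pearson()`), computed from beta quantiles with the usual
boundary conventions. Sessions are seeded from the master seed by a
counter scheme, so any session is reproducible in isolation; with a fixed
seed the full trial and prediction-error streams are byte-identical across
runs.

For display of the modeled dopamine signal, `truncate_signal()` floors
negative responses at 25% of the maximal positive response, mimicking the
smaller dynamic range of dopamine neurons below baseline; the truncation
never enters learning.

## Numerical choices

The fixed point of the self-consistency equations is found by damped
iteration (`new = (1 - gamma) * old + gamma * backup`, default
$\gamma = 0.5$, tolerance $10^{-10}$ on the undamped residual, cap
$10^5$ iterations) because the softmax coupling at the choice state can
oscillate undamped; the solution is damping-invariant and is verified
against (i) exact path-enumeration expectations when the hazard is off and
(ii) long-run simulation (time-averaged values at $\alpha = 0.02$ over
$10^5$ trials) when it is on. Five random restarts flag non-uniqueness;
none has been observed on these tasks. During simulation the log-rule
softmax clamps values at $10^{-6}$ before taking logarithms, since early
learning can transiently produce non-positive values; the exported
`choice_prob()` refuses non-positive input instead.

Problem sizes in the test suite were chosen to keep every Monte-Carlo
check at three standard errors or better while remaining quick: $10^4$
trials per seed for convergence checks, $10^5$ trials for the
solver-vs-simulation comparison, 15–25 sessions and 10–20 seeds for the
session-level experiments.

## What the simulations do and do not show

The generator emulates the programmed structure of the task — trial-type
mixture, cue contingencies, reward schedule, state durations — under the
model's own assumptions. It does not emulate fixation breaks or eye
movements, motivational drift within a session, variable intertrial
intervals, reward-magnitude adaptation of the dopamine response, or
partial/graded disengagement; agreement of the simulations with the
package's own fixed-point analysis therefore validates the implementation
and the internal logic of the account, not the account's fit to any
particular animal.

Two finite-learning-rate effects are worth knowing about, because they are
properties of the *agent*, not bugs. First, with a constant $\alpha$ the
value iterates fluctuate forever (sd $\approx \sqrt{\alpha/2}\,
\mathrm{sd}(r)$ per state), so "converged values" always means
time-averaged (and, in tests, seed-averaged) iterates. Second, the softmax
feeds those fluctuations back into which states get visited. The
informative target's value is the high-variance one (it is updated toward
whichever cue value follows, 0.97 or 0.03), and a softmax learner
under-samples a high-variance option while its value is transiently low —
the classic "hot-stove" risk aversion. At $\beta = 10$, $\alpha = 0.1$
this shifts the *no-mechanism* (hazard-off) choice bias to about 0.46
rather than 0.5, and biases the expected values of the choice-coupled
states by up to $\pm 0.02$. The effect shrinks roughly as
$\sqrt{\alpha}$, is absent at $\beta = 0$, and *opposes* the disengagement
bias, so the simulated observing bias at the defaults (about 0.53)
understates the fixed-point asymptote (0.56).

## Known limitations

* The printed parameter values of the original task study are not
  reproduced; all parameters are configuration with the defaults above.
* Disengagement is complete and stochastic; prediction-error-driven or
  graded disengagement, and disengagement at the choice itself, are out of
  scope.
* Only two reward magnitudes and three trial types are supported; the
  choice state has exactly two options.
* The model makes no prediction about reward-magnitude adaptation.
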