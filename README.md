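# selfbci

Self-calibrating brain–machine-interface control from error-related
potentials (ErrP), in R.

## The problem

An ErrP-driven BCI moves a cursor on a grid and decodes, from a short EEG
epoch after every action, whether the user judged that action correct or
erroneous. Classically the decoder needs a supervised calibration session
before any control is possible. This package implements, end to end in
simulation, a protocol that needs none: the device exploits the constraint
that each candidate goal cell `t` induces an optimal policy, hence a
labeling `l_t(s, a)` of every (state, action) pair, and *simultaneously*
infers the intended goal and learns the decoder from unlabeled signals.

The core statistic is a leave-one-out pseudo-likelihood over goal
hypotheses,

```
P(D_M | t)  ∝  ∏_i  p( l = l_t(s_i, a_i) | e_i, D_-i, t ),
```

where for each hypothesis the two signal classes are fitted under its own
labeling and each triplet is scored held-out (all signals sharing its
(state, action) pair are left out of the fit). The score is corrected by the
ratio of the error class's responsibility-weighted mean signal power over
the correct class's — error potentials are more energetic, which breaks
label-symmetric ambiguities — and the goal is accepted once its minimum
pairwise normalized score `W^t` against every rival exceeds a threshold
β sustainedly. Until then an uncertainty-reward planner (value iteration
over the grid MDP) steers the cursor toward the assessments that best
disambiguate the remaining hypotheses; afterwards the device exploits the
decided goal greedily, reaches it, labels its history by the decided policy,
and carries those signals over as prior data for the next goal.

A synthetic two-class ErrP feature generator (correlated 3-channel × 19-
sample structure, difference-wave class mean, configurable Bayes accuracy
and power gap, imperfect simulated user) closes the loop without any
recordings; the evaluation module provides the task metrics, moving-average
error rate, label-quality and ten-fold-accuracy analyses, incremental
calibration curves, and the simulated supervised-calibration comparison.
See `vignettes/self-calibration-methods.Rmd` for the model, the estimator
design, and its limitations.

## A worked example

One full 500-action self-calibration session at the default study
conditions (5×5 grid, 25 hypotheses, 57 features, 75 % single-trial Bayes
accuracy, 5 % user lapses, β = 0.9):

```r
library(selfbci)
cfg <- selfcal_config(seed = 3)
run <- run_selfcal_experiment(cfg)
print(run)
#> <selfcal_run> 500 steps, 5 target(s) reached (5 correct)
task_metrics(run)
#> $steps_to_first_target
#> [1] 143
#> $n_correct_targets
#> [1] 5
#> $n_incorrect_targets
#> [1] 0
lq <- label_quality(run)
#> labels correctly self-assigned: 92.8%
#> ten-fold accuracy, true labels: 0.712; learned labels: 0.670
```

Reading it: with no calibration phase at all, the device needed 143 actions
to identify and reach the first goal (subsequent goals come much faster
thanks to the transferred signal models), reached five targets in the
session, all correct, and the labels it assigned to its own unlabeled
signals agree with the ground truth 92.8 % of the time — so a classifier
refit on them performs within a few points of one trained on the truth. The
window-10 error rate falls from 0.84 over the first ten actions (near-random
exploration) to 0.03 just before the goal decision.

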