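---
title: "Self-calibrating ErrP-based cursor control: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-calibrating ErrP-based cursor control: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfbci)
```

## The problem

A brain-machine interface driven by error-related potentials (ErrP) decodes,
from a short EEG epoch after each device action, whether the user judged the
action correct or erroneous. Ordinarily the decoder must first be calibrated
on labeled trials. `selfbci` simulates and analyses a protocol that removes
the calibration phase entirely: a cursor moves on a W x H grid (default
5 x 5) with five actions (up, down, left, right, goal-reached), the user
silently assesses each action against the goal they have in mind, and the
device *simultaneously* infers which goal that is and learns the decoder of
the user's assessment signals.

The leverage comes from the task structure. Each candidate goal `t` induces
an optimal policy, hence a labeling `l_t(s, a)` of every (state, action)
pair: actions that reduce the Manhattan distance to the goal (or goal-reached
on the goal cell) are "correct", everything else is an "error". If the user
has goal `t` in mind, the signals collected at pairs labeled correct by `t`
must look like one class and the rest like the other. Goal inference is
therefore a model-selection problem over 25 labelings of the same signal set.

## The task score

Write `D_M` for the history of triplets (state `s_i`, action `a_i`, features
`e_i`). Each hypothesis `t` is scored by a leave-one-out pseudo-likelihood:
the product over triplets of the held-out probability of the label that `t`
assigns,

    P(D_M | t) ~ prod_i p( l = l_t(s_i, a_i) | e_i, D_-i, t ),

where the class models behind `p(l | e)` are fitted on the rest of the
history *under t's own labeling*. A hypothesis whose labeling matches the
real class structure predicts its own held-out labels well; a labeling that
mixes the classes does not. Three estimator choices make this score usable
when features are high-dimensional (d = 57 by default) and the history is
short; all three are visible in `pseudo_loglikelihood()` and documented
here because they are the package's central design decisions.

**Shared, shrunk covariance.** Class covariances estimated per hypothesis
and per class (d x d from a handful of epochs) are essentially noise, and a
score built on them ranks hypotheses by covariance-fitting luck. Both
classes of every hypothesis therefore share one covariance per step: the
pooled covariance of all signals so far, shrunk halfway to a scaled identity
(`lambda = 0.5`), exactly the regularization the supervised classifier
(`class_posterior()`) uses. All Mahalanobis geometry is computed once in
these whitened coordinates.

**Smoothed class means.** With a flat prior on class means, the implied
a-priori class separation is infinite and the label posteriors saturate on
small-sample noise: early in a session every hypothesis can look decisively
right or wrong. Class means are therefore shrunk toward the pooled mean by
`prior_strength` (default 20) pseudo-assessments, the scale of a couple of
dozen trials. Early label posteriors then stay near 1/2 and the score only
becomes opinionated as real evidence accrues; the damping washes out as
class counts grow.

**Leave-one-pair-out.** Signals recorded at the *same* (state, action) pair
share one unknown label and are exchangeable. Holding out only the scored
signal lets repeated assessments of one pair vouch for each other inside a
mislabeled class - concretely, a device parked on a wrong goal emitting
goal-reached probes would absorb its own refutation. All signals of the
scored signal's pair are therefore held out together.

The label posterior itself is the logistic of the equal-covariance
discriminant between the two held-out class means. Using a common Gaussian
core for both classes keeps the contrast free of class-size-dependent
normalization: a predictive that is fatter for the smaller class (as two
independently marginalized class predictives are) biases central signals
toward whichever class is larger, irrespective of the hypothesis's
correctness. As class counts grow the per-class fits converge to the
shrinkage Gaussian classifier, so the self-calibrated decoder and the
supervised one coincide in the limit - which is what makes the prior
transfer between targets (below) equivalent to supervised calibration.

The package also provides `t_predictive_logdensity()`, the heavy-tailed
multivariate Student-t posterior predictive obtained by marginalizing a
class Gaussian under the non-informative Jeffreys prior (df `n - d`,
location the empirical mean, scale `Lambda (n+1) / (n (n-d))` with `Lambda`
the scatter matrix). It is the reference robust class-conditional density
for well-populated classes (`n > d + 1`) and is exactly reproduced by both
the closed-form univariate Student-t and numerical quadrature in the tests.

## Power information and the decision rule

Label-symmetric hypothesis pairs - labelings that are exact complements of
one another on the visited pairs - have *identical* pseudo-likelihoods by
construction, because swapping the labels just swaps the two fitted class
models. Two asymmetries break these ties. First, error potentials carry
more signal energy on average, so each hypothesis's score is multiplied by
the ratio of the responsibility-weighted mean power (`e'e`) of its error
class over its correct class (`power_ratio()`); responsibilities come from
the hypothesis's per-class lambda-shrunk Gaussian fits. Second, pairs where
the two rivals agree on the label but predict different signals - the
goal-reached action at cells neither considers its goal, or edge moves wrong
for both - contribute genuine evidence, provided the device visits them
(next section).

The decision statistic is `W^t`, the minimum over rivals `x` of
`P(t) / (P(t) + P(x))` on the power-corrected scores: `W^t > 1/2` for at
most one hypothesis, and the device considers the goal identified when some
`W^t` exceeds `beta` (default 0.9). Because the scores are re-estimated from
a growing history, a single threshold crossing can be a transient: the
device commits only after the same hypothesis has held `W > beta` for
`decision_persistence` (default 20) consecutive updates, and during that
window it provisionally follows the candidate's policy - approaching the
candidate cell and probing goal-reached on it, which confirms a correct
candidate and refutes a wrong one within a few assessments.

## Planning

While exploring, actions are chosen by value iteration (discount 0.95,
tolerance 1e-6, deterministic tie-break in the fixed action order) on an
uncertainty reward over (state, action) pairs. The reward is the
posterior-weighted dispersion of the signal means the hypotheses predict for
the pair - a second-order approximation of the mutual information between
the goal and the next signal. Unlike the entropy of the mixture *label*
distribution (the cold-start fallback before class models exist), the
dispersion also values the label-agreeing, model-disagreeing pairs that are
the only separators of label-symmetric rivals. Two modifiers shape the
trajectory: each pair's reward is divided by one plus its visit count
(repeated assessments of a fixed label are exchangeable, so their marginal
information decays), and is weighted by `2 - q` with `q` the mixture
probability that the pair is correct, so the globally ambiguous,
error-labeled probes are bought early. Early in a session, before the models
carry information, a uniformly random action is taken with probability
`exp(-M / 60)`; behaviour thus starts near-random (about 80% errors on this
grid) and anneals into targeted probing, which is what produces the
declining moving-average error rate over a target. Once a goal is decided
the device follows its optimal policy greedily and performs goal-reached on
it; the target then ends, the history is labeled by the decided policy and
transferred as fixed prior data, and inference restarts for the next goal
with better-initialized class models.

## The synthetic signal generator

`signal_generator()` emulates what the method needs from EEG and nothing
more: two feature classes differing in mean, the error class more energetic,
and an imperfect user. The default `"erp"` structure is d = 57 features as
3 channels x 19 time samples with a Kronecker covariance - cross-channel
correlation 0.75 (volume conduction), AR(1) temporal correlation 0.8 (band-
limited EEG at the decimated rate) - giving an effective dimensionality of
about 6, as in real ERP windows; the class-mean difference is a smooth
positive-then-negative difference wave scaled so the Bayes-optimal
single-trial accuracy is 0.75 (the middle of the observed single-trial
range) and mixed toward the covariance's leading eigenvector so the
error/correct power ratio is 1.3 (a realistic energy surplus for a
fronto-central difference wave over background EEG). The simulated user's
assessment is flipped with probability 0.05 - occasional lapses - and the
emitted signal always comes from the class of the (possibly flipped)
assessment. An `"isotropic"` structure with closed-form accuracy/power
relations exists for oracle tests, and a waveform mode (`sample_epochs()`)
synthesizes raw 3-channel epochs whose difference wave peaks a third and
two-thirds into the window, exercising the full feature-extraction path.

What the generator does *not* emulate: non-stationary signals, artifacts,
1/f noise, session effects, or users who change their mind mid-target.
Passing closed-loop tests on this generator shows the inference machinery
works under the model's own assumptions at a realistic difficulty; it does
not certify performance on recorded EEG. One visible consequence: the
incremental-calibration curve (`calibration_curve()`) plateaus after a few
tens of trials on synthetic data, whereas real sessions need an order of
magnitude more - stationary Gaussian classes are simply easier to learn
than real EEG.

## Feature extraction

`extract_features()` reproduces the reference recipe: channels Fz, FCz, Cz,
window [200, 800) ms after action onset, temporal decimation by 8. The
sample-window convention - half-open `[ceiling(fs t0), floor(fs t1))`,
keeping every k-th sample from the window's first sample - is the unique
floor/ceiling x open/closed variant that yields 19 samples per channel (57
features) at 256 Hz, and is frozen by a test. A zero-phase order-4
Butterworth band-pass is available as a preprocessing hook; the reference
pipeline assumes epochs already filtered at acquisition.

## Numerical and procedural choices

* All score arithmetic is in log space; the posterior, confidence and
  decisions are computed from log scores directly.
* Value iteration stops when the sweep-to-sweep change is below
  `tolerance (1 - gamma) / gamma`, guaranteeing the stated distance to the
  fixed point; ties in the greedy policy break in the fixed action order.
* Degenerate inputs: a history of fewer than 2 triplets gives the uniform
  posterior; an all-identical signal set falls back to identity whitening;
  a class with fewer than two members makes the power ratio 1.
* Ten-fold cross-validation is stratified with a fixed fold seed. The
  calibration-curve plateau is the first point from which the mean accuracy
  stays within one percentage point of the running maximum for five
  consecutive increments.
* In supervised replays (`simulated_supervised_control()`), held-out signals
  are consumed in order, matched by the true label the user's assessment
  would have; steps to the first target are charged the calibration trials.
* Closed-loop defaults (`prior_strength = 20`, `decision_persistence = 20`,
  annealing constant 60) were set by closed-loop simulation experiments at
  the default generator difficulty during development, and are documented
  constants, not adaptive quantities.
* Problem sizes used in the shipped tests and the analysis script - 50
  single-target runs for the recovery checks, 16 full 500-action sessions
  for the headline metrics, 20 supervised replays - were chosen so the whole
  analysis reruns in a few minutes on one core.

## Known limitations

* The label-symmetry breakers (power ratio, shared-label probes) are weak
  when the true power gap is small; opposite-corner confusions are the
  dominant residual failure mode, exactly the ambiguity the protocol's
  authors flag for symmetric environments.
* The conditional (label-posterior) form of the pseudo-likelihood discards
  the task-conditional signal marginal. At realistic dimensionalities that
  term is estimation noise, but in very low dimensions with abundant data it
  would carry usable clustering evidence.
* The exploration reward is a one-step, second-order information proxy, not
  a Bayes-adaptive plan; it can linger on uninformative regions when the
  posterior is nearly degenerate.
* Everything here is synthetic-data methodology; interfacing recorded EEG
  requires only `read_epochs()`/`extract_features()`, but the defaults have
  not been tuned on recordings.
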