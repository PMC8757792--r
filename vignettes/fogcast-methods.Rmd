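---
title: "Forecasting freezing of gait from stepping force data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting freezing of gait from stepping force data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogcast)
library(dplyr)
```

## The problem

Freezing of gait (FoG) is an episodic inability to continue stepping that
affects many people with advanced Parkinson's disease. Sensory cueing can
help abort or soften an impending freeze, but continuous cueing is
impractical — which motivates *forecasting*: predicting, from the recent
movement signal alone, that a freeze is about to happen, so a cue can be
delivered just in time.

`fogcast` implements a forecasting pipeline for vertical ground-reaction
force (GRF) recorded at 100 Hz while a subject steps in place on a force
platform. Time is measured in centiseconds (cs); at 100 Hz one sample is
exactly one centisecond. The pipeline has five stages, each usable on its
own: simulation of labeled cohorts, per-sample freeze labeling,
windowing into classification problems, ensemble classification with
leave-one-subject-out (LOSO) evaluation, and streaming real-time
prediction.

## Windowing: turning forecasting into classification

A labeled trace is cut into samples by a sliding window with four
parameters:

* **IL** (input length): the stretch of raw force values used as the
  feature vector;
* **GL** (gap length): the forecast horizon between the end of the input
  and the prediction target;
* **TL** (target length): the stretch whose freeze status defines the
  label (default 1 cs — the window's label is the freeze state of the
  single sample GL after the input ends);
* **OL** (offset): the stride between consecutive window starts
  (default 28 cs, roughly a quarter of an average stepping cycle, so no
  part of a cycle is skipped).

Indexing is 0-based and half-open: a window starting at sample `s` has
input `[s, s + IL)` and, with TL = 1, target sample `s + IL + GL`. With a
larger TL the label is 1 if *any* target sample is frozen. Raw force
values are the features; no detrending or normalisation is applied at the
windowing stage. Windows whose span exceeds the trace are discarded, not
padded.

GL is the scientific dial: GL = 0 asks "is a freeze happening immediately
after the data I can see", larger GL asks the same question further into
the future. How fast performance decays with GL measures how early the
pre-freeze signature is visible.

## The classifier ensemble

Three classifiers are trained on identical rows and combined by vote:

* **Gaussian naive Bayes** (`fit_gaussian_nb()`), the benchmark,
  implemented directly: class priors are relative label frequencies, and
  each (feature, class) pair gets an independent Gaussian with
  maximum-likelihood (biased) mean and variance. Prediction maximises
  `log P(y) + sum_i log N(x_i; mu_yi, sigma2_yi)` in log space.
* **Random forest** (`fit_rf()`, via ranger): maximum depth 200 and a
  class weight of 100 on the freeze class against 1 on no-freeze,
  countering the heavy class imbalance of forecasting problems. The tree
  count is not part of that configuration and defaults to 100.
* **Multilayer perceptron** (`fit_mlp()`): 5 hidden layers of 100
  rectified-linear units, logistic output, L2 penalty `1e-4`, trained by
  L-BFGS with analytic backpropagation gradients. No installed R package
  offers a multi-hidden-layer perceptron with an L-BFGS solver, so the
  network is implemented in the package. Activation, penalty and the
  500-iteration cap are package defaults, explicitly configurable —
  they are choices, not canonical settings.

**Vote rules.** The *minority* rule predicts a freeze when at least one
member fires; *majority* requires two of three. For every input the
minority prediction dominates the majority prediction, so minority voting
can only lower false negatives and raise false positives — a
sensitivity/specificity dial that needs no retraining. For a cueing
device a false positive is a spurious cue; a false negative is a missed
freeze, which is the costlier error, so minority voting is the default.

**Scoring.** Windows are scored with macro-averaged F1 over the freeze and
no-freeze classes (`f1_macro()`). A class absent from both truth and
prediction contributes F1 = 1; a class present but never correctly
predicted contributes 0, so the score is always defined. Evaluation is
leave-one-subject-out: the ensemble is trained on the pooled windows of
all other subjects and scored on the held-out subject, so reported scores
describe generalisation to an unseen patient. Per-subject scores are
summarised by their median; missing folds are excluded, never imputed.

Classifier comparisons use the Kruskal–Wallis H test on per-subject F1;
the GL trend is summarised by the Spearman rank correlation between GL
and the median F1 (`gl_correlation()`, with an option to correlate all
per-subject points instead of the medians — both are reported because the
choice is not obvious).

## The synthetic cohort generator

No public stepping-force FoG dataset exists, so the package ships a
generator (`simulate_cohort()`) whose defaults emulate the cohort the
pipeline is designed for: 9 subjects, ~90 s and longer trials at 100 Hz,
a mean stepping cycle of 113 cs (SD 30), about 3 freeze episodes per
trial (SD 1.6), episode durations with mean 12.08 s and SD 13.5 s, and a
pooled freeze fraction near 34%.

**Waveform.** One stepping cycle is modelled as a half-sine loading bump
above body weight (weight acceptance), a quarter-cycle dwell at body
weight, a half-sine unloading trough (push-off), and a second dwell —
half-rectified alternating loading rather than a pure sinusoid. The
dwells matter: they give normal stepping brief flat stretches at body
weight, so a window much shorter than one cycle can be genuinely
ambiguous between quiet standing within a step and an actual freeze.
Distinguishing the two robustly requires seeing about one full cycle —
which is what makes the input length an interesting parameter rather
than "shorter is always enough". Per-cycle lengths are drawn around the
configured mean, and measurement noise is additive Gaussian.

**Freezes and the pre-freeze lead.** During a freeze the stepping
oscillation is replaced by output flat at body weight plus an optional
trembling component (3–8 Hz, small amplitude); with trembling and noise
disabled a freeze is exactly constant at body weight. Each onset is
preceded by a `degradation_lead` (default 150 cs) over which the bump
amplitude decays linearly toward the freeze level and cadence slows.
This lead is the generator's own construct — real pre-freeze dynamics
are far less regular — and it is the entire source of forecastability:
with GL beyond the lead there is, by construction, no signal left, which
is exactly the property the GL-sweep tests exploit.

**Episode scheduling and calibration.** Episode durations are drawn from
a log-normal moment-matched to mean 12.08 s / SD 13.5 s (strong right
skew), truncated below at 1 s. Three calibration details keep the
realised statistics on target:

1. The three cohort targets are mutually inconsistent at exactly 90 s
   trials (3 episodes × 12.08 s is already 40% of 90 s), and the
   protocol records *at least* 90 s. The default trial length is
   therefore 10700 cs — the mean length the targets jointly imply
   (3 × 12.08 s / 0.34). The pooled freeze fraction is an emergent
   quantity reported against `target_freeze_fraction` by
   `cohort_stats()`, not a third independent dial.
2. Every trial contains at least one episode; clamping the drawn count at
   1 would inflate its mean, so the latent count mean is moment-matched
   (solved numerically) to make the clamped mean equal the configured
   mean.
3. When drawn episodes cannot fit the trial, the shortest episode is
   dropped rather than all durations redrawn — redrawing conditions the
   kept durations on being short and biases the realised mean noticeably
   low, whereas a trial's dominant freezes are its defining events.

Episodes are separated by at least one cycle plus the degradation lead,
and the first onset leaves the same margin at the start, so every episode
has a clean pre-freeze window. A configuration whose episodes can never
fit raises an explicit infeasibility error.

## The automatic labeler

Real deployments need per-sample freeze labels. The reference labeling
procedure for this kind of data is not publicly documented, so the
package provides a transparent amplitude-envelope labeler
(`label_trace()`) and validates it only against the simulator's ground
truth: a sample is frozen when the rolling peak-to-peak range of the
force (window 113 cs) falls below 40% of the trace's baseline stepping
amplitude — estimated as the 90th percentile of the rolling ranges, which
is robust to traces that are frozen for long stretches — and the
low-amplitude run lasts at least 1 s. On default cohorts the labels agree
with ground truth on about 97–98% of samples, with disagreements
concentrated at episode boundaries (the envelope window smears onsets by
up to half a window). All downstream modules accept externally supplied
labels, so a different labeler can be swapped in; no claim is made that
this labeler matches any particular manual or video-based procedure.

## Streaming prediction

`stream_predict()` replays a trace sample-at-a-time through a ring buffer
of length IL and emits a prediction every OL centiseconds — the deployment
OL (e.g. 10 cs) is independent of the training OL (28 cs). No emission is
possible before IL samples have arrived; each emission uses only samples
preceding its forecast horizon, so predictions are causal, and streaming
output is label-identical to batch windowing of the same trace (a tested
invariant). `timeline_error_rates()` scores a timeline's minority and
majority outputs (FP/FN counts and rates) and reports the member-mean
counts alongside; comparing the two rows shows the vote-rule trade-off.

## Numerical choices and edge cases

* NB variances are floored at `1e-9` times the mean pooled feature
  variance (or `1e-12` if that is zero), keeping constant features
  finite in log space.
* All classifier ties break toward class 0 (no freeze); the minority
  vote layer restores sensitivity at the ensemble level.
* The MLP standardises inputs internally (centre/scale stored in the
  model) as a conditioning choice for L-BFGS; this is invisible to
  callers and does not constitute feature preprocessing at the windowing
  stage.
* Traces shorter than one window yield an empty dataset with a warning,
  not an error; LOSO folds with no valid windows or single-class
  training pools are recorded as missing, never as zero.
* Forces round-trip CSV bit-exactly: written with 17 significant digits
  and re-parsed with R's own `strtod`.

## Problem sizes used by the tests and the acceptance script

Cross-validated sweeps in the test-suite and in `scripts/acceptance.R`
run on a 9-subject cohort of 90 s trials with a reduced ensemble — 50
trees and a 2 × 32-unit network (the full 5 × 100 architecture at its
500-iteration cap is exercised on small datasets). These sizes are the
package's chosen benchmark configuration for cross-validated sweeps;
sweep conclusions (GL decay, optimal IL, vote-rule ordering) are
structural and do not depend on the reduced sizes.

## What passing tests do and do not show

The synthetic cohort reproduces the *statistics* of a stepping cohort
(cycle length, episode counts and durations, freeze fraction, a
pre-freeze lead) but not the physiology: real pre-freeze degradation is
irregular and patient-specific, freezes tremble and drift rather than
sitting flat at body weight, and real traces contain artefacts, weight
shifts and sensor drift that the generator does not model. Consequently
the near-ceiling F1 scores on synthetic cohorts say that the pipeline's
machinery is correct — windows, labels, folds, votes and scores do what
they claim — not that comparable accuracy is attainable on clinical
data. The qualitative findings the package is designed to reproduce
(performance decays with forecast horizon; cycle-scale input lengths are
optimal; minority voting trades false positives for false negatives) are
properties of the method that the synthetic experiments demonstrate
end-to-end.
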