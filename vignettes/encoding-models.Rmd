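---
title: "Whole-arm Poisson encoding models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-arm Poisson encoding models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachenc)
```

## The scientific question

Neurons in the arm region of primary somatosensory cortex have classically
been modeled as encoding the kinematics of the hand. `reachenc` implements
the analysis program that asks whether they instead encode the kinematic
state of the *whole arm* — hand plus elbow — and whether active reaches and
passive limb displacements are represented by a single kinematic model.
Because the interesting comparisons live in the statistics (cross-validated
model comparison, circular tuning metrics, classifier indices), every stage
is driven by a synthetic two-link-arm generator with ground-truth Poisson
neurons, so each claim can be checked against a known answer.

## Encoding models

Spike counts per analysis bin are modeled as Poisson with a log link,

$$ f \sim \mathrm{Poisson}(\lambda), \qquad \lambda = \exp(X\beta), $$

fit by maximum likelihood (IRLS, no regularization) and evaluated by
predicting held-out counts $\hat f = \exp(X\hat\beta)$. Six covariate sets
are built by `build_design()` (dimensionalities include the intercept):
hand position and velocity in Cartesian coordinates with the shoulder at
the origin (P = 7); hand plus elbow (P = 13); hand kinematics plus the six
handle force/torque channels (P = 13); hand position in spherical
coordinates about the shoulder and its time derivatives (P = 7); joint
angles and angular velocities (P = 2 per joint + 1; the planar arm has two
joints, so P = 5); and 5-component PCA projections of surrogate muscle
lengths and of their derivatives (P = 11).

Goodness of fit is the deviance pseudo-R²,

$$ pR^2 = 1 -
  \frac{\sum_\tau f\log(f/\hat f) - (f - \hat f)}
       {\sum_\tau f\log(f/\bar f) - (f - \bar f)}, $$

with $\bar f$ the *training-set* mean count (so a test score of 0 means "no
better than predicting the training mean", with no leakage from the test
fold) and the convention $0\log(0/x) = 0$. Values near 0.2 are already good
fits for single-bin spike counts.

Models are compared under repeated 5-fold cross-validation (20 repeats,
n = 100 fold scores), split at the *trial* level with identical folds for
all models. Because training sets overlap across folds, paired fold
differences are tested with the corrected resampled t-test:
$t = \bar d \big/ \sqrt{(1/(KR) + \frac{1/K}{1-1/K})\,\hat\sigma_d^2}$ with
$KR - 1$ degrees of freedom; at K = 5, R = 20 the variance multiplier is
0.26, i.e. the standard error is about five times the naive one. Pairwise
winners require $p < \alpha/6$ (Bonferroni factor 6, covering the six
candidate models historically compared).

## Tuning, preferred directions and the circular VAF

Direction tuning uses 16 bins of 22.5°; cosine tuning
$f = b_0 + b_1\sin\theta + b_2\cos\theta$ gives the preferred direction
$\mathrm{PD} = \mathrm{atan2}(b_1, b_2)$ and modulation depth
$r = \sqrt{b_1^2+b_2^2}$. PDs are estimated by bootstrap: each iteration
resamples rows to an exactly uniform direction histogram (equal draws per
bin, the per-bin count being the median occupied-bin count — the resampling
scheme is not pinned down by the source methods, so the median rule is this
package's choice) and refits the cosine; the estimate is the circular mean
of the bootstrap PDs. Tuning significance compares the mean bootstrap depth
with the 95th percentile of a shuffle null (same uniform resampling, rates
permuted). Only neurons significantly tuned in both workspaces enter
PD-shift analyses.

For each cross-validation fold, actual and model-predicted PDs are fit per
workspace on the fold's test rows, and the quality of a model's predicted
PD shift $\Delta\hat\theta$ against the actual $\Delta\theta$ is the
circular VAF, $\mathrm{cVAF} = \cos(\Delta\theta - \Delta\hat\theta)$,
averaged over neurons per fold and summarized with the corrected resampled
confidence interval over the 100 folds.

## Active vs passive and the separability index

The center-out experiment analyzes the 120 ms after movement onset, where
onset is found from handle acceleration: locate the first acceleration peak
at/after the search start (bump time on passive trials, go-cue + 200 ms on
active ones) and sweep backward until acceleration drops below 10% of the
peak; the onset is the last sample still at or above threshold (the
source's sweep rule is ambiguous about including the boundary sample; this
package includes it, at sample resolution). The separability index is the
mean test accuracy of a two-class pooled-covariance LDA (equal priors,
stratified repeated 5-fold CV) predicting movement type from a neuron's
window-averaged rate; the kinematic analog uses the 12-dimensional
hand+elbow position/velocity window averages. Model consistency retrains
the encoding model either within one condition or on both, scoring both on
the same test rows *with the same within-condition null mean* — using each
model's own training mean would inflate the both-trained score purely
through the other condition's rates and is avoided deliberately.

## The synthetic generator

The generator emulates the two behavioral designs with a planar two-link
arm (upper arm 0.16 m, forearm-plus-handle 0.22 m, shoulder at the origin,
x to the right, y forward; z is carried as an identically zero third
coordinate so the design matrices keep their full dimensionality).

* **Two-workspace task:** each trial picks one of two 10 × 10 cm squares —
  near-contralateral center (−5, 15) cm, far-ipsilateral (5, 25) cm — and
  chains minimum-jerk reaches (0.6 s each, 3 per trial) to uniformly drawn
  targets after a 0.3 s hold. The elbow follows closed-form inverse
  kinematics, so hand and elbow signals decorrelate only across workspaces:
  precisely the manipulation the task exists for.
* **Center-out task:** 4 targets at 8 cm, alternating active/passive
  trials. Passive trials deliver a 2 N, 130 ms force pulse in a target
  direction; the hand responds as a damped point mass (0.6 kg; damping 9
  and 10.5 N·s/m along x and y, a mild anisotropy standing in for arm
  impedance) plus a constant 0.3 N postural-yield drift toward the body
  while the pulse acts. The point-mass parameters were set so the passive
  window-mean hand speed (0.108 m/s) matches the active reaches
  (0.117 m/s), as the behavioral design prescribes; the drift is the
  direction-independent component that makes passive arm kinematics
  systematically different from active ones — without it the four-direction
  design is mirror-symmetric and *no* linear classifier can separate the
  conditions from window-averaged kinematics. Start/target positions jitter
  by 2 mm, bump amplitude by 10%, reaction times are uniform on
  250–350 ms.

Ground-truth neurons fire as Poisson with
$\eta = \beta_0 + g_c\,(x^\top\beta)$, the linear predictor clipped at
log 50 counts per 50 ms bin (a 1000 spikes/s ceiling, applied identically
at generation and prediction; on 120 ms windows the cap scales to the same
ceiling). Baselines are log-uniform on 10–40 Hz (20–50 Hz for the strongly
tuned mixed population). Coefficient SDs per covariate were chosen once for
severalfold rate modulation over the tasks' ranges (hand position 3 /m,
velocity 4 s/m). Two deliberate population choices matter downstream:

* the whole-arm recovery population raises elbow coefficient SDs to 8 so
  that elbow *drive* is comparable to hand drive despite the elbow's
  smaller excursions — the package's reading of "whole-arm ground truth",
  consistent with the proximal-limb bias of area 2 receptive fields;
* the active/passive mixed population fixes every neuron's coefficient
  magnitude (random tuning direction) so that condition gating
  (gains 2 / 0.5 on the tuned drive, the efference-copy-like mechanism) is
  not confounded with tuning strength.

What the generator does *not* emulate: muscle force or musculoskeletal
dynamics (muscle lengths are straight-line origin–insertion distances on
the links; the two elbow muscles attach on the link axes so their lengths
are monotonic in elbow angle), spike-sorting artifacts, non-Poisson count
dispersion, history dependence, neural correlations, reaction to the bump
after 120 ms, or 7-DoF arm redundancy. Passing the recovery tests therefore
shows the *pipeline* is sound — that the statistics recover known structure
and stay calibrated under nulls — not that real cortex satisfies the
generative assumptions.

## Numerical choices

* IRLS converges on relative log-likelihood change < 1e-8, capped at 100
  iterations with step-halving; non-convergence is flagged, propagated, and
  the neuron excluded from comparisons rather than raising.
* Collinear design columns (e.g. the constant z-coordinates, or the
  spherical polar angle of planar data) are detected once by pivoted QR and
  carried with coefficient zero, so every stated dimensionality is
  preserved.
* Muscle-model PCA bases are fit on the training fold only and applied to
  its test fold.
* Angles live on (−π, π]; direction bin k is the half-open interval
  [k·22.5° − 11.25°, k·22.5° + 11.25°); circular means use the resultant
  vector and are flagged `NA` when the resultant is (near-)zero.
* One master seed deterministically spawns per-stage seeds
  (`derive_seed()`), making every stage individually reproducible; all
  seeded entry points force their arguments before seeding so that a
  caller's random argument expressions are not silently replayed.
* Bootstrap sizes: 1000 iterations by default for PD estimates and tuning
  significance; the bundled analyses and acceptance suite use 100–200,
  which pilot calibration showed is where the procedure's behavior
  stabilizes at these bin counts.

## Problem sizes and runtime

The bundled analyses and the acceptance suite run on one CPU in a few
minutes: the recovery experiments use 150–200 trials and 24–50 neurons
(5400–7200 analysis bins) with the full K = 5, R = 20 protocol; the
calibration checks use 200 simulated neurons and 1000 null replications of
the corrected t-test. These sizes were chosen as the smallest at which the
recovery contrasts are decisively resolved.

## Known limitations

* The joint-kinematics model has P = 5 here (two planar joints), not the
  P = 15 of a 7-DoF arm; results for that model are not comparable to a
  redundant-arm setting.
* The egocentric model of planar data carries two aliased columns (polar
  angle and its derivative are constant at z = 0); they are dropped by the
  rank check, effectively making the model 5-parameter on synthetic data.
* The shuffle-null tuning test is slightly anti-conservative when the
  empirical direction distribution is far from uniform (sparse bins add
  resampling noise asymmetrically); its false-flag rate is ~10% under
  uniform directions at the bundled sizes.
* LDA separability is a *linear* index: condition differences that are
  mirror-symmetric across directions are invisible to it by construction.
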