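---
title: "Methods: automatic balance assessment from trunk-sway IMU data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic balance assessment from trunk-sway IMU data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Supervised balance training is effective for people with vestibular deficits
and other balance concerns, but progression decisions in home-based programs
rest on self-assessments, which are known to diverge from a physical
therapist's (PT's) judgment. `swayrate` implements an automatic alternative:
estimate the PT's ordinal rating $y \in \{1,\dots,5\}$ of a 30 s standing
balance exercise repetition from the pitch/roll angular-velocity signal of a
single trunk-worn IMU sampled at 100 Hz, as a mapping $f : \mathcal X \to
\{1,\dots,5\}$ learned from labeled repetitions. Rating 1 means the exercise
was performed independently with limited sway; 5 means the position could not
be maintained even with assistance.

Three representations $\mathcal X$ of the same two-channel signal are
compared under one training and evaluation protocol:

1. **Hand-engineered features.** Eleven kinematic sway descriptors spanning
   the three classical families (RMS sway in all directions, sway-path
   length, 95% confidence-ellipse area), fed to a random forest.
2. **Time series.** The standardized multichannel signal, fed to a
   1-D convolutional network.
3. **Trajectory image.** The pitch-vs-roll trajectory drawn into a binary
   60×60 raster, fed to a 2-D convolutional network.

## Ground truth from a rater panel

Each repetition is rated by one to eight PTs; ground truth is the panel
**mode**. The mode can tie; the package breaks ties toward the rating closest
to the panel mean, then toward the **higher** (more severe) rating. The
severity-first tie-break is a deliberate package choice: in balance training
an overestimate of difficulty is safer than an underestimate. Repetitions
with no PT rating ("missing label") or with fewer than
$\mathrm{round}(30\,\mathrm s \times f_s) - 1$ samples ("premature
termination") are excluded before modeling; the one-sample tolerance is a
package choice, since no tolerance is stated for the collection protocol.

Panel agreement is summarized by Krippendorff's alpha computed from the
coincidence matrix, which handles variable panel sizes and missing ratings.
The nominal difference function is the default (the conventional choice);
the ordinal difference function is available via `metric = "ordinal"`.

## Kinematics

Only angular velocity is stored by the sensor. The angle trajectory is
reconstructed by cumulative trapezoidal integration at the sample period,
followed by removal of the per-channel least-squares linear trend. Linear
detrending is the simplest defensible drift suppression for signals that
otherwise receive no preprocessing; a high-pass filter would contradict the
"no preprocessing" posture of the pipeline and introduce a cutoff parameter
with no empirical anchor.

One numerical consequence is worth recording. For a pure sinusoidal velocity
$A\cos(2\pi f t)$ the integral is $\tfrac{A}{2\pi f}\sin(2\pi f t)$, but the
least-squares slope of a sine over a finite window is $O(1/T)$, not zero, so
the detrended angle is tilted slightly and its **maximum** exceeds the true
amplitude by about 3% at $f = 1$ Hz, $T = 30$ s. The amplitude itself is
still recovered almost exactly by the standard $\sqrt 2 \times \mathrm{RMS}$
estimator (error $\sim 0.1\%$), which is what the package's integration
checks use. This is inherent mathematics of detrending, not integration
error.

The eleven features are, in order: per-axis and resultant RMS of the angle
trajectory (deg); per-axis and resultant RMS of the velocity (deg/s); path
length $\sum_i \sqrt{\Delta p_i^2 + \Delta r_i^2}$ in both domains; the 95%
confidence-ellipse area $\pi\, \chi^2_{2}(0.95) \sqrt{\lambda_1 \lambda_2}$
of the sample covariance in both domains (deg², (deg/s)²); and a combined
resultant RMS over the concatenation of the two domains' per-sample magnitude
series, $\sqrt{(\mathrm{RMS}_{ang}^2 + \mathrm{RMS}_{vel}^2)/2}$. The
descriptor families are fixed by the feature-based balance-assessment
literature; the exact eleven-element expansion into angle and velocity
domains is this package's documented contract. The combined feature is
defined without per-recording normalization: normalizing each domain by its
own RMS would make the entry a constant and break the linear-scaling
invariant that all RMS/path features satisfy. Ellipse coverage (0.95, the
conventional posturography level) is configurable. Seven of the eleven
entries are invariant under joint pitch/roll rotation; only the four per-axis
RMS entries are orientation-dependent.

## Representations

**Time series.** The default input has four channels in two depth-wise
groups — reconstructed pitch/roll angle and measured pitch/roll velocity —
because position-like and velocity-like quantities carry different
information and the first conv layer should not mix them. A literal
two-channel velocity-only mode is retained for ablation, since the wording
of the original protocol admits both readings. Channels are standardized
with training-set mean/SD only, and brought to the fixed nominal length
$T = 30\,\mathrm s \times f_s$ by symmetric zero-padding or truncation.

**Image.** Pitch maps to x, roll to y (row 1 at $+$roll), linearly over
$[-h, +h]$ per axis, where the half-widths $h$ are fitted on training
trajectories only (max-abs policy by default, a percentile policy is
available) and serialized with the model. Consecutive samples are connected
with Bresenham segments so the raster depicts the *drawn* trajectory rather
than a scatter; pixels are binary to avoid an arbitrary intensity scale.
Segments are drawn from the lexicographically smaller endpoint so the image
is invariant under sample-order reversal. Rotation augmentation (3 copies
per training image, angles from {30, 60, 120, 150, 210, 240, 300, 330}°)
rotates the underlying coordinates *before* rasterization — exact and free
of pixel-interpolation artifacts, realizing the same augmentation intent as
rotating the rendered image. Augmentation never touches validation or test
data.

## Models and training protocol

Both CNNs share one architecture: a depth-wise grouped convolution (8
filters per group, kernel 3 or 3×3) → max pooling → ReLU → batch
normalization → flatten → fully-connected (width 64) → batch normalization →
ReLU → dropout 0.5 → fully-connected → 5-way softmax, trained with Adam
(learning rate $10^{-4}$, batch 32) on cross-entropy for a fixed epoch
budget (2000 in the full protocol), with L2 weight decay tuned on validation
macro-AUROC over {0, 10⁻⁴, 10⁻³, 10⁻²}. Unstated details resolved as
package choices: pooling is size 2, stride 2 (the conventional minimal
reduction); the hidden width 64 is the smallest round width that overfits
the 8-example capacity fixture; and the returned parameters are the
best-validation-epoch snapshot within the budget, consistent with selecting
hyperparameters on the validation set. The engine is implemented in base R
with BLAS matrix products (im2col convolution); its backpropagation is
verified against numerical differentiation in the test suite.

The random forest (bagged CART, Gini impurity, $\mathrm{mtry} =
\lfloor\sqrt{11}\rfloor$) outputs class probabilities as ensemble vote
fractions. Its tree count is selected by grid search under
leave-one-participant-out cross-validation on the training participants,
maximizing fold-averaged macro-AUROC with ties toward the smaller forest;
the full protocol's selection was 1000 trees. Sub-forest evaluation (the
first $n$ trees of the largest forest) makes the grid search exactly
equivalent to refitting per grid value.

Splits are always by participant — all repetitions of a participant land in
exactly one of train/validation/test (6/2/2 participants by enrollment
order) — eliminating within-person leakage.

## Evaluation

Accuracy and macro-averaged one-vs-rest AUROC (rank-based, ties counted
half) are reported as mean ± SD over repeated restarts (30 in the full
protocol) on a fixed test set, compared with paired two-sided t-tests at
$\alpha = 0.05$ (runs are paired by seed and share test examples).
Degenerate difference vectors are resolved analytically: identical per-run
values give statistic 0 / not significant; a constant nonzero difference is
the $t \to \infty$ limit. Classes absent from the test truth are excluded
from the macro average — necessary on small test sets, and documented
because it changes the class weighting. Baselines: the **majority
classifier** predicts the training-set mode label with identical scores
everywhere (macro-AUROC exactly 0.500); the original report used the test
mode, but the training mode is the leak-free choice and is used here.
**Self-assessment** uses the participant's own rating as a one-hot-scored
prediction. The **random-PT** reference draws one panel rating per
repetition uniformly (1000 resamples) as a practical upper bound for a model
trained on mode labels.

## The synthetic world

The study's human-subject recordings are not deposited, so the package
ships a generator that emulates the statistical structure the method
assumes, making every downstream stage testable. It is a stated world, not
a tuning knob; all defaults live in `sim_config()` and are:

* latent severity: participant ability and exercise difficulty, each
  uniform on [0, 1]; repetition severity
  $\mathrm{clamp}(a + d - 0.5 + \varepsilon, 0, 1)$ with
  $\varepsilon \sim N(0, 0.05^2)$. Clamping concentrates labels at both
  scale ends, qualitatively matching the reported dominance of ratings 1, 2
  and 5 (per-class counts were not reported, so the distribution is
  qualitative only);
* sway: independent pitch/roll band-limited Gaussian noise (flat spectrum
  0.1–3 Hz, the conventional postural-sway band, realized by FFT masking of
  white noise), resultant RMS $0.5 + 6.0 \times \mathrm{severity}$ deg/s,
  pitch:roll RMS ratio 1.4 (anterior–posterior sway typically exceeds
  medial–lateral). A biomechanical inverted-pendulum model was deliberately
  not used: the downstream method consumes magnitude/shape statistics, and
  the band-limited model keeps the target RMS analytically exact in
  expectation;
* step-outs: Poisson-count (mean $2 \times \mathrm{severity}$) half-sine
  transients, 0.5–1.5 s, amplitude 3–5× the stationary RMS, random
  direction; counts recorded as metadata only, mirroring the collection (but
  non-use) of step-out information;
* raters: panel size $1 + \mathrm{Binomial}(7, (4.28-1)/7)$ (support 1..8,
  mean 4.28 as reported); each PT bins severity + $N(0, 0.12^2)$ perception
  noise against thresholds (0.2, 0.4, 0.6, 0.8); the self-assessment bins
  severity − 0.15 + noise, producing the documented systematic
  underestimation;
* reproducibility: every repetition and panel derives an independent
  sub-seed from the master seed via a counter-based hash, so identical
  configurations regenerate byte-identical datasets (manifest and signal
  files).

What the generator does **not** emulate: non-Gaussian and nonstationary
sway (fatigue, adaptation), spectra that change shape with severity,
exercise-condition-specific signatures (vision, stance, head movements
affect only difficulty, not spectral content), rater idiosyncrasies beyond
i.i.d. noise, and correlated panel membership. A green parameter-recovery
test therefore establishes that the pipeline recovers a severity signal of
realistic magnitude structure from realistic label noise — not that the
models would attain any particular performance on human data; the original
study's test-set numbers are explicitly not reproduction targets.

## Numerical choices and degenerate inputs

* Ellipse area of a rank-deficient covariance returns 0 with a warning
  rather than failing, so constant trajectories featurize cleanly.
* Raster bounds are floored at $10^{-9}$ so an all-zero training channel
  cannot produce a zero-width axis.
* Batch normalization uses $\varepsilon = 10^{-5}$ and momentum 0.1;
  inference uses running statistics.
* Macro-AUROC with a single-class truth raises an error rather than
  returning a value; the training loop falls back to negative validation
  loss for snapshot selection when the validation split is single-class.
* Softmax is computed with the max-subtraction stabilization; cross-entropy
  clamps probabilities at $10^{-12}$.
* `filter_valid` counts a repetition that is both unlabeled and short under
  "missing label" only, so exclusion reasons sum to the number excluded.

## Scaled-down testing

The acceptance suite runs the full protocol shrunk to a single CPU: 3
restarts instead of 30 and an epoch budget of 15 (well under the 300-epoch
ceiling the scaled protocol allows; the noise-free recovery task converges
within a few epochs), with 300 trees for the forest. Thresholds are not
scaled. The capacity oracle and all metric oracles run at full stated size.

## Known limitations

* The CNN engine is CPU-only and unbatched at inference; a 2000-epoch,
  30-restart full reproduction is hours of compute, not minutes.
* Which exact eleven features the cited feature-based approach used is not
  derivable from the text it appears in; the package's list is a documented,
  tested contract, not a claim of bit-compatibility.
* Whether the original image representation encoded angle, velocity, or
  both is not stated; the package defaults to both channels and exposes the
  choice.
* The ordinal structure of the labels is not exploited by the losses
  (cross-entropy treats classes as nominal), matching the protocol it
  implements.
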