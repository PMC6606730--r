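---
title: "Methods: multimodal emotion-intensity recognition with Choquet-integral fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal emotion-intensity recognition with Choquet-integral fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Emotional state is described on the two-dimensional valence/arousal plane:
valence runs from unpleasant to pleasant, arousal from calm to excited. Both
dimensions are quantized into five intensity levels, and two independent
five-level classification sub-models — one per dimension — are trained and
applied synchronously. Two signal modalities contribute evidence:

* **EEG** — 30 channels in a 10–20 montage containing 12 left/right
  symmetric electrode pairs plus six midline electrodes;
* **eye movements** — a stream of fixation, saccade and blink events plus a
  pupil-diameter series.

Each modality gets its own multiclass SVM; the two classifiers' per-class
confidences are then combined by *decision-level fusion* with the discrete
Choquet integral, whose fuzzy measures express how much each classifier —
and each coalition of classifiers — should be trusted for each class.

## Preprocessing

**Frame blocking and windowing.** EEG is only short-term stationary, so each
trial is cut into frames of $N$ samples advanced by $N - M$ samples and each
frame channel is tapered with the Hamming window
$\omega(n) = 0.54 - 0.46\cos(2\pi n /(N-1))$. Defaults are $N = 500$ and
$M = N/2 = 250$ at 250 Hz (2-s frames, 1-s overlap). Trailing samples that
do not fill a frame are dropped so every frame has exactly $N$ columns; the
frame count is $\lfloor (S - N)/(N - M)\rfloor + 1$ for a trial of $S$
samples.

**Filtering.** A 32nd-order linear-phase FIR band-pass (windowed-sinc design
with Hamming taps, 0.5–60 Hz) removes drift and mains/high-frequency noise.
"Order 32" is read as 33 taps; the group delay of $(L-1)/2$ samples is
compensated so the filtered trial stays aligned, and edges use reflection
padding to suppress transients.

**Artifact rejection.** Manual artifact screening is replaced by a
reproducible amplitude rule: a trial is rejected iff any sample exceeds a
configurable threshold (default 100 amplitude units).

**Pupil illumination removal.** Pupil diameter mixes emotional dilation with
the light reflex. Given an aligned luminance regressor, the
illumination-driven component is identified as the principal direction of
the standardized (pupil, luminance) pair most aligned with luminance and its
pupil contribution is removed by least-squares projection onto the luminance
series. With a single regressor this specializes exactly to regressing
luminance out of the pupil, which drives the pupil–luminance correlation to
zero; a plain two-variable PCA subtraction would leave a residual
correlation of $\sqrt{(1-r)/2}$ and was therefore not used.

## Features

**Time–frequency EEG features (420 per frame).** Six bands are used: delta
(0.5–4 Hz), theta (4–8 Hz), slow alpha (8–10 Hz), alpha (8–12 Hz), beta
(12–30 Hz), gamma (30–40 Hz). Per channel and band the package computes

* **APS** — the mean of the single-frame periodogram PSD over the band's
  frequency bins (the frame is already Hamming-windowed; no Welch
  sub-segmentation, since frames are only 500 samples), and
* **AE** — the mean squared amplitude of the band-filtered frame (time
  domain, unwindowed). At trial level the band filter is applied once to the
  whole trial and energies are then framed, which avoids per-frame filter
  transients; the two routes agree up to edge effects and the test suite
  checks their consistency.

For the 12 symmetric pairs, **DAPS** is the *signed* left-minus-right APS
difference in the five bands other than slow alpha. The sign is kept because
hemispheric asymmetry direction is what carries valence information.
Together: $30\cdot 6 + 30\cdot 6 + 12\cdot 5 = 420$ named features per
frame; the per-trial feature is the mean over frames (dimensionality is
preserved and the estimate is stabilized).

**Eye-movement features (20 per trial).** Duration mean and (population)
standard deviation for blinks and fixations, the same plus mean rotation
angle for saccades (7), then event frequencies for the three types and
duration max/avg/min and rotation-angle max/avg for fixations and saccades
(13). The "rotation angle" of a fixation is interpreted as its gaze
dispersion. Population standard deviations make the single-event case
well-defined (0). Eight optional pupil spectral features — periodogram PSD
mean and Gaussian-form differential entropy
$\tfrac12\ln(2\pi e\,\sigma^2_{band})$ in the bands 0.6–1.0, 0.4–0.6,
0.2–0.4 and 0.01–0.2 Hz — can be appended (`include_pupil = TRUE`) but the
default vector follows the 20-dimension layout. The very low band edges make
FIR filtering impractical at 60 Hz, so band variance is computed from a
brick-wall spectral isolation; a zero-variance band returns a configurable
entropy floor (−20 nats) instead of $-\infty$.

**Normalization.** Features are mapped to $[0,1]$ by absolute-value min–max
scaling, $y = (|x| - \min|x|)/(\max|x| - \min|x|)$, per feature and (when
participant ids are given) per participant. Constant features map to 0 with
a warning. Inside cross-validation the statistics are fitted on training
folds only and applied to the held-out fold with clipping, so no test
information leaks into the model.

**Spatial features.** Infomax ICA (natural-gradient ascent with a logistic
nonlinearity after PCA whitening, full-batch iterations, seeded random
orthogonal initialization) is fitted per trial. A filter is *valid* when the
per-column argmax indices of the absolute mixing matrix $|A|$ form a
permutation of all channels — every component projects maximally onto a
distinct electrode. Valid filters are aligned (rows permuted so component
$i$ sits at channel $i$, sign fixed so the peak loading is positive, rows
unit-normalized for a stable average) and averaged into a mean filter. A
trial projected through the mean filter gives $\hat S$, whose SVD
$\hat S = U\Sigma V^\top$ yields the spatial features
$ES = [\lambda_1 v_1, \dots, \lambda_{30} v_{30}]$. Because the matrix $ES$
has no fixed length for a classifier, the summary vector is the singular
values $\lambda$ (30 values), optionally with the leading column of $ES$
appended; spatial features are not concatenated with the time–frequency
features by default.

## Decision-level fusion

A *fuzzy measure* $\mu$ on the classifier index set $X = \{x_1,\dots,x_n\}$
satisfies $\mu(\emptyset) = 0$, $\mu(X) = 1$ and monotonicity under
inclusion. The discrete Choquet integral of confidences
$f : X \to [0,1]$ is

$$\zeta_\mu(f) = \sum_{i=1}^n \left[f(x_{(i)}) - f(x_{(i-1)})\right]
  \mu(A_{(i)}),$$

with $f$ sorted ascending, $f(x_{(0)}) = 0$ and $A_{(i)}$ the set of the
$n-i+1$ largest-valued indices. It generalizes the weighted mean (additive
measures), the minimum and the maximum, and is bounded by
$[\min f, \max f]$. For each class $j$ a global confidence
$\Phi^j_\mu = \zeta_{\mu^j}(\Phi^j_1,\dots,\Phi^j_n)$ fuses the per-classifier
confidences with the class's own measure $\mu^j$; the predicted class is the
argmax, ties resolving to the lowest class id.

**Confidence factors.** libsvm's built-in probability calibration is
nondeterministic (it uses its own internal RNG for the calibration CV), so
the package derives confidences deterministically: each pairwise SVM
decision value is mapped through a logistic function and the pairwise
estimates are coupled into a per-class probability vector by solving the
quadratic pairwise-coupling system exactly (rows sum to 1, entries clipped
to $[0,1]$).

**Measure learning.** The measures are fitted by minimizing the squared
deficit of the margin between the true class's global confidence and a
competitor's, with target margin 1. The printed two-class objective is
generalized one-vs-rest: for every training sample the competitor is the
strongest competing class; so the objective stays a quadratic in the stacked
coefficient vector (one block of $2^n - 2$ coefficients per class, ordered
singletons first, then pairs, …), the competitor is fixed as the strongest
class under uniform mean fusion. Expanding the squares gives a convex QP
($m(2^n-2)$ variables) with $[0,1]$ boxes and one inequality per cover
relation of the subset lattice — exactly the monotonicity conditions. A
small relative ridge keeps the quadratic matrix positive definite; the
active-set solver's solution is clipped, repaired upward along the lattice
(numerical violations only) and validated. If the solver fails or does not
improve on it, the uniform (additive) measure is used — it is always
feasible, so learning can never do worse than mean fusion on the training
objective.

**Out-of-fold training profiles.** Measures learned on in-sample SVM
confidences systematically over-trust weak modalities, because even an
uninformative SVM looks confident on its own training set. `emofuse()`
therefore computes the training profiles by internal stratified 5-fold
cross-validation (as in stacked generalization): each training sample's
confidence profile comes from classifiers that did not see it. The final
per-modality classifiers are still trained on all training data.

## Stimulus selection

Each clip's normalized score on a dimension is its mean rating divided by
the population standard deviation. Clips are then assigned to the five
intensity levels by anchor-nearest selection: anchors −2.5, −0.7, 0, 0.7,
2.5 for arousal and −1.5, −0.4, 0, 1, 3 for valence (the valence anchors are
deliberately asymmetric: induced valence skews positive). Levels are
processed in order 1→5, each taking the 8 clips with the smallest
|score − anchor| without replacement — a clip near two anchors goes to the
lower level, deterministically — for 40 selected clips. Distance ties break
toward the lower clip id. The population-SD convention is a choice
(`sd_type` switches to $n-1$).

## The synthetic-data generator

No recordings ship with the package; the generator produces trials with the
statistical structure the method assumes, so every stage is testable.

* **EEG.** Each channel is a sum over the six bands of band-limited noise
  (spectral synthesis, unit RMS) with baseline amplitudes
  (delta 8, theta 6, slow alpha 3, alpha 5, beta 3, gamma 2 units),
  multiplied by a slow lognormal burst envelope (one per channel) and the
  arousal gain, plus white sensor noise (SD 2). The burst envelope gives the
  bursty super-Gaussian amplitude statistics of real EEG — which is also
  what makes the channels identifiable to ICA. Arousal levels scale the
  broadband amplitude by 0.8, 1.0, 1.2, 1.45, 1.7; valence levels shift the
  alpha-range left/right amplitudes by a relative offset of −0.40, −0.15, 0,
  0.20, 0.45 (left ×(1+a), right ×(1−a)). The offsets are asymmetric about
  zero on purpose: features are normalized on absolute values, so a
  sign-symmetric choice would make levels 1/5 and 2/4 indistinguishable
  after normalization.
* **Eye movements.** Two competing exponential clocks (saccades and blinks,
  rates keyed to arousal: blinks 0.15→0.40/s, saccades 1.0→2.0/s across
  levels) generate the event stream; fixations fill the waiting gaps, scaled
  by a valence-keyed factor (1.35→0.78), and durations are log-normal.
  Saccade rotation angles rise with valence (8°→16°). Events are
  chronologically ordered and non-overlapping by construction.
* **Pupil.** A 60-Hz series: slow oscillatory components in the four pupil
  bands (lowest-band amplitude keyed to arousal), plus `illum_coupling`
  (default 0.8) times a slow luminance drift — returned alongside as the
  regressor — plus white noise.
* **Ratings.** Per-clip rating samples with positive dispersion whose
  normalized scores span the anchor ranges by construction (extreme clips
  are pinned and pushed outward if sampling noise leaves an anchor
  uncovered).

Defaults are the emulated study conditions: 55-s trials at 250 Hz, 30
channels, 40 trials per level. What the generator does **not** emulate:
volume conduction and spatially correlated channels (channels are
independent), non-stationary artifacts (blinks/EMG in the EEG), inter-trial
and inter-participant variability beyond the sampling noise, and any real
relation between video content and physiology. Passing tests therefore show
that the pipeline recovers the class structure it is designed for, not that
the accuracy figures transfer to real recordings.

## Numerical choices

* Band-limited synthesis and the very-low-frequency pupil bands use
  brick-wall spectral isolation; analysis filters for AE use windowed-sinc
  FIRs (order 128 by default, capped below half the frame length).
* Periodogram band averaging includes bins with
  $low \le f \le high$ (closed interval); a band narrower than the
  resolution is an error naming the band.
* ICA: convergence when the mean squared natural-gradient norm drops below
  1e-9 (default cap 2000 iterations); the learning rate (0.1) halves on
  numerical blow-up and anneals by 0.8 when the gradient norm grows by more
  than 20 %. Non-convergent fits are flagged and excluded from the filter
  bank. Argmax ties in the validity judgment resolve to the lowest row
  index.
* QP: relative ridge 1e-7 on the quadratic matrix diagonal; learned
  measures are accepted only if they do not lose to the uniform measure on
  the training objective.
* Degenerate inputs: constant feature columns normalize to 0 with a
  warning; event types with no events yield zero statistics with a warning;
  zero-variance pupil bands return the entropy floor; a singular projected
  trial yields trailing zero singular values (not an error).

## Problem sizes used by the tests and the acceptance script

The test suite exercises the full pipeline on 200 trials of 20 s (40 per
level) for the recoverability property and 100 trials of 55 s (20 per
level) for the fusion property; the acceptance script reruns the complete
workflow on 100 trials of 55 s with 10×5 cross-validation per dimension.
These sizes keep a desk-scale run in minutes while leaving every stage
nontrivially exercised; accuracies at these sizes are reported as the
synthetic-condition results, not as reproductions of any recorded-data
figures.

## Known limitations

* The measure-learning competitor is fixed before solving the QP; a jointly
  optimal competitor assignment would require alternating optimization.
* Per-trial ICA on short trials (≪ 30 s) can fail the validity judgment;
  the bank then builds from fewer filters, and the hard error when no
  filter is valid asks for longer or cleaner trials.
* The spatial-feature summary (singular values, optionally the leading
  component) is one defensible reduction of the matrix $ES$; nothing in the
  design fixes how $ES$ should feed a classifier, so the choice is exposed
  as a parameter.
* Arousal and valence sub-models are trained independently; correlations
  between the dimensions are not modelled.
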