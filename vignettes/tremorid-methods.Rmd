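---
title: "Methods: two-stage tremor classification from hand accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage tremor classification from hand accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Parkinson's disease (PD) and essential tremor (ET) both produce
pathological hand tremor, and their clinical presentations overlap: PD
tremor is typically a unilateral rest tremor around 4--6 Hz, ET typically a
bilateral postural/kinetic tremor around 4--8 Hz, but rest tremor occurs in
a sizeable minority of ET patients and most PD patients also show action
tremor. `tremorid` implements a two-stage statistical pipeline that
classifies a patient's *tremor assessment* -- 54 single-axis accelerometer
recordings: 6 static tasks (two rest, two postural, two load-bearing)
$\times$ 3 trials $\times$ 3 axes, 20 s each -- into PD or ET. A seventh,
kinetic finger-to-nose task is recorded clinically but excluded from the
pipeline, because it superimposes voluntary motion with no usable ground
truth for the involuntary component.

## Preprocessing

Raw recordings (clinically 1500 Hz) are decimated to 100 Hz, which
comfortably covers the informative tremor band (< 20 Hz). Decimation is
preceded by a linear-phase Hamming-windowed-sinc low-pass (cutoff
0.45 $\times$ 100 Hz = 45 Hz, $100 \times \text{factor} + 1$ taps, delay
compensated), giving > 50 dB suppression above the new Nyquist without
phase distortion. Each signal is then demeaned -- removing the
accelerometer's calibration offset and the posture-dependent gravity
component -- and converted to a short-time spectrogram: a 100-point
Hamming window slid with 90 points of overlap, zero-padded to a 256-point
FFT, magnitude squared, one-sided. A 2000-sample signal yields exactly
$129 \times 191$ pixels (bins $\times$ frames); bin $k$ sits at
$k \cdot 100/256$ Hz. Each window contributes its own periodogram column
(no frame averaging): that is the only reading of a "Welch" description
that produces a two-dimensional grid of this size.

Whether the network should see linear or log power is not dictated by the
method; we take $\log_{10}(P + 10^{-12})$ and standardise each grid to
zero mean and unit variance. The per-grid standardisation makes the
arbitrary accelerometer calibration irrelevant and stabilises
optimisation; an all-zero (degenerate) grid maps to zeros rather than NaN.

## Stage 1: convolutional network with task hints

A small CNN maps one scaled spectrogram to $(p_{PD}, p_{ET})$. The
published description fixes: 2 convolutional layers followed by 3 dense
layers; ReLU after the first dense layer, Leaky-ReLU (slope 0.1) after the
second; softmax output; mean softmax cross-entropy minimised by Adam at
learning rate $10^{-4}$; exactly 44 training epochs (no early stopping);
and a 6-bit one-hot *task hint* concatenated with the first dense layer's
output to form the second dense layer's input. The hint tells the network
which behavioural condition (rest/posture/load) produced the signal, since
the two diseases express tremor differently across tasks.

The exact filter counts and dense widths are not recoverable from the
text; this package's declared choice is conv1 = 8 filters $5\times5$,
conv2 = 16 filters $3\times3$ (each followed by ReLU and $2\times2$ max
pooling), dense widths 128–64–2 — the smallest architecture of that shape
that trains comfortably on one CPU. Batch size (32), seeded uniform
fan-in weight initialisation ($U(\pm\sqrt{6/\text{fan-in}})$), and ReLU
conv activations are likewise declared defaults, all configurable via
`stage1_config()`. The network, its backpropagation and Adam are
implemented natively (RcppArmadillo): no deep-learning framework is
available in the target environment, and the exact forward/backward
semantics are needed for Grad-CAM anyway. All gradients are verified
against finite differences in the test suite.

## Stage 2: quadratic discriminant over the 54 votes

The 54 per-signal network outputs of one assessment are collected in
canonical order (trial-major, then task in hint order, then axis x/y/z)
into a feature vector $f$ — either probabilities ($p_{PD}$ per signal,
the default and the stronger variant) or binarised votes
($p_{PD} > 0.5$, ties to 0). Each class is modelled as a multivariate
Gaussian and an assessment is classified by the likelihood ratio

$$\Lambda(f) = \frac{N(f;\,\mu_{PD}, \Sigma_{PD})}{N(f;\,\mu_{ET}, \Sigma_{ET})},$$

computed in log space via Cholesky factors; $\Lambda > 1$ (uniform
priors; configurable threshold, strict inequality with ties voting ET)
votes PD. With 54 dimensions and tens of training assessments the sample
covariances are singular, so they are shrunk toward their diagonal:
$\Sigma_c = (1-s)S_c + s\,\mathrm{diag}(S_c) + \varepsilon I$ with
$s = 0.1$ by default and $\varepsilon = 10^{-6}\times$ mean diagonal of
$S_c$ (floored at $10^{-8}$ when a class has zero variance, so degenerate
fits remain proper). A naive-Bayes variant — independently estimated
per-feature Gaussians, i.e. a fully diagonal quadratic discriminant —
is provided through the same interface.

Patient-level decisions fuse all of a patient's test assessments by
logical AND: the patient counts as correctly classified iff every
assessment is. For confusion matrices a patient label is also needed;
we use the unanimous label when assessments agree and the majority label
otherwise (a tie takes the label opposing the truth, keeping the patient
on the incorrect side, consistent with the AND rule).

## Evaluation protocol

Splits are always by patient — every visit and both hands of one patient
fall on one side — eliminating identity leakage. The spec's per-class
rounding rule contradicts its own worked example on balanced cohorts, so
the declared rule is: total test count = round-half-away-from-zero of
$n \times$ fraction, apportioned per class by largest remainder, floor of
one test patient per class, error if a class's training side would empty.
Monte-Carlo evaluation repeats train/evaluate over seeded splits
(30 repeats by default, over test fractions such as 25–75%) and reports
mean and per-repeat patient accuracy, the pooled patient-level confusion
matrix (PD positive, ET negative), sensitivity, specificity, and the
assessment-level ROC/AUC over pooled log-likelihood ratios (patient-level
ROC is undefined under the AND rule and not emitted). A first-visit
variant trains on all visits of training patients but scores only visit-1
assessments of test patients. All randomness fans out from one master
seed through a documented counter scheme (`derive_seed()`).

Feature importance uses the wrapper ranking: each of the 54 features
alone, patient-wise 5-fold cross-validated accuracy of the second-stage
classifier, ranked descending with ties broken by canonical index and
labels formatted `Trial-Task-Channel`.

## Explainability

Grad-CAM: the target class's score is backpropagated — with the other
output node zeroed — to the last convolutional layer's post-activation
maps; channel weights are the spatial mean gradients. With a two-node
softmax head the score is taken as the class **log-odds**
($z_{\text{target}} - z_{\text{other}}$): the two logits' common mode
cancels in the softmax and carries no class evidence, yet it can
dominate the spatially averaged raw-logit gradients and collapse every
rectified map to zero, so the discriminative scale is the faithful one
(common-mode shifts of the output layer provably leave the maps
unchanged; the test suite asserts this invariant). the rectified weighted sum is upsampled
bilinearly to the spectrogram grid and min–max normalised to [0, 1]
(an all-zero map stays zero and is flagged). Maps are computed for every
signal of every *correctly classified* assessment — whole-cohort scope by
default, since the published group counts exceed a test-set's size — and
accumulated per true class into streaming per-pixel means and variances
(Welford). The groups are compared per pixel by the two-sample z
statistic

$$z = \frac{\bar g_{ET} - \bar g_{PD}}{\sqrt{\sigma^2_{ET}/n_{ET} + \sigma^2_{PD}/n_{PD}}},$$

and significance masks are thresholded on the standard normal CDF at
$\alpha = 0.02$ split over the tails: ET pixels where $\Phi(z) > 0.99$,
PD pixels where $\Phi(z) < 0.01$ — disjoint by construction. A
D'Agostino–Pearson $K^2$ normality check per pixel is computed and
reported but does not gate the analysis (the z test's large-sample
justification does not hinge on it); pixels with constant saliency are
flagged and skipped.

## Synthetic cohort: what it emulates and what it does not

The clinical data are private, so the package ships a generator whose
output has the statistical structure the classifier assumes. Tremor is
modelled as $A\,[\sin\varphi(t) + h\sin 2\varphi(t)]$ with
$\dot\varphi = 2\pi f(t)$ and $f(t)$ a Gaussian random walk reflected at
the class band edges — the simplest process giving band-limited,
pseudo-rhythmic, non-stationary oscillation. Per patient we draw a base
frequency inside the band, a log-normal amplitude scale, and laterality;
per task the amplitude follows a class task profile (rest-dominant for
PD, posture/load-dominant for ET); the three axes share the oscillator
through fixed projection weights plus independent white noise (set by an
SNR in dB relative to the patient's base amplitude, default 20 dB —
an assumption, not an estimate; the study reports no amplitude
statistics) and a slow (< 0.5 Hz) sinusoidal postural drift. PD
asymmetry is encoded by attenuating the non-dominant hand; ET patients
are always bilateral; second visits redraw waveforms from mildly
perturbed patient effects.

Two profile sets are provided. `paper_like` uses the clinical bands
(PD 4–6 Hz, ET 4–8 Hz, overlapping) and phenomenological task profiles;
`easy` uses disjoint bands (4–5.5 vs 6.5–8 Hz) and stronger task
contrast, making the classes separable by construction — the
configuration the acceptance tests rely on. A green acceptance run
therefore establishes that the pipeline can extract a signal that is
present, leakage-free and end to end; it does *not* establish clinical
accuracy, which would require the private cohort. The generator does not
model neuromuscular dynamics, voluntary movement, sensor saturation or
artifacts.

## Numerical and design notes

* Strict decision tie: a likelihood ratio exactly at threshold votes ET.
* ROC ties are grouped, so the trapezoid AUC equals the Mann–Whitney
  statistic with ties counted 1/2; verified against brute-force pairwise
  concordance.
* The acceptance suite runs the cohort at a 500 Hz raw rate (not the
  clinical 1500 Hz) and 10 training epochs — scale-downs for runtime
  only; the 1500 Hz decimation path is covered by tone-oracle unit
  tests.
* Checkpoints (`save_stage1()`) carry a format version; loading a
  mismatched version is an error.
* The empty-target acceptance report: the build contract for this
  package declares no numeric acceptance targets (clinical accuracies
  being out of scope), so `scripts/acceptance.R` smoke-runs the
  installed pipeline and emits an empty JSON object.

## Known limitations

* Stage-1 conv shapes are declared assumptions; the original figure-level
  architecture is unrecoverable from text.
* The generator's SNR, drift and axis weights are stated, not estimated.
* Patient-level ROC curves are not defined under AND fusion.
* The wrapper ranking considers features independently (as published);
  it does not measure joint subset value.
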