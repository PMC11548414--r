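---
title: "Decoding directional SSVEP commands: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding directional SSVEP commands: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ssvepbci)
```

## The problem

A steady-state visual evoked potential (SSVEP) brain-computer interface maps
flickering visual targets to device commands: attending to a stimulus
flickering at frequency $f$ entrains an oscillatory EEG response at $f$ (and
its harmonics), strongest over occipital cortex. This package implements the
offline side of a four-command system -- forward, backward, left and right
mapped to 10, 12, 15 and 20 Hz flicker -- from stimulus-sequence generation
through artifact removal, spatial filtering and classification. Because no
participant recordings ship with the package, a forward-model simulator
produces ground-truthed sessions with the statistical structure the pipeline
assumes, so every stage can be validated end to end.

## Stimulus protocol

The flicker sequence assigns frame $i$ (0-based) the grayscale value

$$s(f, i) = a \sin\!\left(\frac{2\pi f i}{f_r} + \frac{\pi}{2}\right) + b,$$

with $f_r$ the display refresh rate (60 Hz by default). High modulation
depth uses $(a, b) = (0.5, 0.5)$ (full 0-1 contrast); low depth uses
$(0.149, 0.464)$, confining luminance to $[0.315, 0.613]$ around mid-gray.
The recorded protocol does not state which depth was used, so `high` is the
default and `low` is selectable. Sequences are evaluated exactly at integer
frame indices; at $f = 10$, $f_r = 60$ the period is exactly 6 frames and
frame 0 is 1.0.

A session consists of 100 trials in 2 blocks of 50 with a 60 s break, each
trial 12 s: 1 s directional prompt, 5 s flicker, 4 s action (recall) window,
2 s rest. Directions are balanced (25 each) and ordered by a seeded
permutation; `session_schedule()` enforces divisibility of the trial count
by 4 and by the block count.

## Signal model of the simulator

`simulate_session()` mixes four source groups instantaneously and linearly
(the same generative assumption the ICA stage inverts):

* **SSVEP**: per trial, a sinusoid at the trial frequency plus its 2nd
  harmonic at half amplitude (4 + 2 uV at the unit-weight channel),
  occipital/parietal-dominant topography (O1/O2 = 1, P3/P4 = 0.6, falling
  off anteriorly), a fresh uniform phase per trial and +/-20% amplitude
  jitter. The random phase matters: it forces decoders to use band power,
  not phase locking. Amplitudes are order-of-magnitude physiological
  choices (scalp SSVEPs are typically a few microvolts).
* **Background**: 16 independent $1/f$ sources mixed through a random
  spatial matrix (a stand-in for volume conduction, which spatially
  correlates background activity), scaled to 10 uV RMS per channel, plus
  0.5 uV white sensor noise. The $1/f$ spectrum has a 1 Hz knee -- flat
  below it -- matching the low-frequency flattening of aperiodic EEG
  spectra and keeping the variance finite.
* **Blinks**: 80 uV raised-cosine pulses of 0.3 s at homogeneous-Poisson
  times (10/min), frontal-dominant topography (Fp1/Fp2 = 1). Blinks occur
  in all trial phases: participants are instructed not to blink during
  stimulation, but artifacts still occur.
* **Line interference**: a 2 uV 50 Hz sinusoid with a spatially uniform
  topography.

Event markers are written at every phase onset at
`round(onset_s * srate)`. What the simulator does **not** model: dipolar
lead fields, nonstationary drifts, alpha reactivity, muscle artifacts, and
inter-individual topography variation. Passing the end-to-end tests
therefore shows the pipeline is correct under its own assumptions, not that
the reported accuracy transfers to real participants.

## Preprocessing

Filtering is zero-phase throughout: each filter runs forward and backward,
each pass starting from steady-state initial conditions (the classical
filtfilt `zi` construction), over data padded at both ends with an odd
reflection tapered smoothly to the endpoint value. Symmetric waveforms
stay symmetric (peak shift at most one sample). The 50 Hz notch is a
2nd-order IIR biquad with Q = 30, padded with three of its ~0.1 s ring
time constants; the acquisition band-pass is a 4th-order Butterworth at
8-50 Hz, padded with three filter lengths. One caveat worth knowing:
narrowband attenuation is a steady-state property, and a tone that starts
or stops inside the record leaves an onset transient of a few notch time
constants that no zero-phase IIR can remove; on 20-minute recordings the
affected edge samples are a negligible fraction and lie outside any trial
epoch. Canonical sub-bands (alpha 8-12, beta1 12-20,
beta2 20-30, gamma 30-50 Hz) are available via `split_bands()`. Analysis
uses the eight channels F3, F4, C3, C4, P3, P4, O1, O2. Epochs are cut
time-locked to the prompt marker, 12 s (3000 samples at 250 Hz), half-open
windows, 0-based sample indices; the 5 s stimulus phase spans samples
[250, 1500). Classification defaults to the stimulus phase; the action
phase is selectable (`phase = "action"`) since delayed responses carry
signal too.

## ICA artifact removal

`fastica()` is the symmetric fixed-point algorithm: whiten, then iterate
$w \leftarrow E[z\,g(w^\top z)] - E[g'(w^\top z)]\,w$ over all components
jointly with symmetric decorrelation, with $g = \tanh$ by default
(`cube` available), tolerance $10^{-5}$, at most 500 iterations.
Non-convergence is recorded on the model rather than raised: on realistic
EEG most background dimensions are near-Gaussian and thus unidentifiable,
so the rotation within that subspace may keep wandering while the
identifiable (artifact, SSVEP) components are long stable. For long
recordings the pipeline fits the demixing on up to 50 000 evenly spaced
samples (200 s at 250 Hz) and applies it to everything.

Ocular components are flagged by a documented two-factor rule rather than a
trained classifier: the score is the geometric mean of the component's
frontal topography dominance (fraction of squared mixing weight on Fp1,
Fp2, F7, F8) and the fraction of its source power below 4 Hz; components
scoring above 0.6 are flagged. Both factors lie in [0, 1]. On simulated
sessions the blink component scores ~0.9 while the nearest non-artifact
component stays below ~0.5, because spatially mixed background sources do
not concentrate on frontal channels and have only ~40% of their power
below 4 Hz.

One ordering subtlety is worth documenting. The flagging rule needs the
sub-4 Hz blink energy, which the 8-50 Hz band-pass removes. The default
pipeline keeps the conventional stage order (notch, band-pass, then ICA),
where the ICA stage is a near-no-op for blinks -- they are already
attenuated by the band-pass, and little is flagged. Artifact
characterization and the flagging guarantees are therefore stated on
acquisition-band (notch-only) data, and `ssvep_decode(ica_stage =
"before_bandpass")` runs the ICA stage there instead. Both orders yield
equivalent downstream accuracy on simulated data; the choice matters only
for what the ICA report contains.

## CSP features

For two signal classes with trace-normalized average covariances
$\Sigma_+$ and $\Sigma_-$,

$$\Sigma = \frac{1}{N}\sum_i \frac{X_i X_i^\top}{\mathrm{tr}(X_i X_i^\top)},$$

common spatial patterns solves $\Sigma_+ w = \lambda \Sigma_- w$ and scales
the eigenvectors so that $W(\Sigma_+ + \Sigma_-)W^\top = I$. The
implementation whitens the composite covariance and eigendecomposes the
whitened $\Sigma_+$, giving eigenvalues $\lambda^+_j = w_j^\top \Sigma_+
w_j \in (0,1)$ sorted descending; the $m$ first and $m$ last filters are
retained and each segment yields the normalized log-variance features

$$f_p = \log\frac{\mathrm{Var}(w_p^\top X)}{\sum_{i=1}^{2m}\mathrm{Var}(w_i^\top X)},$$

which satisfy $\sum_p e^{f_p} = 1$ and are invariant to segment scaling.
Ties are left in eigensolver order and each filter's sign is fixed so its
largest-magnitude weight is positive, making results deterministic. If a
covariance is ill-conditioned (condition number beyond $10^{10}$) a ridge
$\Sigma \leftarrow (1-\gamma)\Sigma + \gamma\,\mathrm{tr}(\Sigma)/C\, I$
with $\gamma = 10^{-6}$ is applied -- numerical safety with negligible
bias.

The four-class problem is composed one-vs-rest: for each target frequency,
class "+" is that frequency's trials and class "-" the pooled rest, with
$m = 1$, so each segment contributes $4 \times 2 = 8$ coefficients. The
one-vs-rest pairing is an inference from the system's block diagrams, not
an explicitly stated protocol, and is documented as such.

**Why per-frequency bands are the default.** All four commands share one
occipital topography, and a sinusoid's contribution to a broadband spatial
covariance, $a a^\top A^2/2$, does not depend on its frequency -- with a
single 8-30 Hz band the four class covariances would be essentially
identical and one-vs-rest CSP would carry no information. The
frequency-specific arrangement used by SSVEP packages (and by the
OpenViBE CSP workflow this mirrors) band-passes each target's data
narrowly around its own frequency (default $f \pm 1$ Hz, 4th-order
zero-phase Butterworth) before that target's CSP. A broadband mode
(`band_mode = "broadband"`, default 8-30 Hz, alpha + beta) remains
available for montages where class topographies differ. CSP is trained on
0.5 s sliding segments (0.1 s step) rather than whole epochs: many short
segments stabilize the covariance average and match the unit the
classifier sees.

## Classification and evaluation

Features are z-scored with training-side statistics only. Three
classifiers, with all unstated hyperparameters chosen here and exposed in
`train_classifier()`:

* LDA (`MASS::lda`), with a tiny jitter fallback if the within-class
  covariance is singular;
* SVM with RBF kernel (`e1071::svm`), cost 1, $\gamma = 1/(d \cdot
  \overline{\mathrm{Var}})$;
* a single-hidden-layer MLP (`nnet::nnet`), 32 logistic hidden units,
  softmax output, weight decay $10^{-4}$, at most 500 iterations, seeded
  initial weights. (The installed single-layer MLP uses sigmoid rather
  than ReLU units; with 8-dimensional features and 32 units the
  distinction is immaterial.)

The 75:25 split is stratified and, by default, performed at the **trial**
level with the CSP bank fitted on training trials only. Sliding windows
with a 0.1 s step overlap by 80%, so a segment-level split leaks
near-duplicates of training segments into validation and inflates
accuracy; the segment-level mode (`split_level = "segment"`) is kept
because it reproduces the apparent original protocol, but the honest
default is trial-level. Evaluation reports the 4x4 confusion matrix,
per-class accuracies (diagonal over row sum), their unweighted mean (the
headline "average accuracy"), and overall accuracy; trial-level
evaluation takes a majority vote over each trial's segments (ties broken
by canonical class order), which empirically denoises segment
predictions.

## Problem sizes and determinism

The reference benchmark is one simulated 100-trial session (20 min of
16-channel data at 250 Hz, 4600 segments), which decodes in about one to
two minutes on a single core; tests and the acceptance script use this
size for end-to-end checks and 4-16-trial sessions for component checks,
with FastICA capped at 100 iterations in the 20-session flagging study
(the identifiable components converge far earlier). All randomness --
schedule order, simulator noise, splits, MLP initialization -- flows from
explicit seeds, and repeated runs with one seed produce byte-identical
metrics files.

## Known limitations

* The simulator's linear instantaneous mixing makes the ICA stage's job
  easier than real EEG, where convective muscle artifacts and
  nonstationarity violate the model.
* Accuracies on simulated sessions characterize the pipeline, not human
  performance; they sit in the same regime as published four-command
  SSVEP systems by construction of the simulator's signal-to-noise ratio,
  not as a claim about any participant.
* Filter-bank CSP, canonical correlation analysis features, and online
  (information-transfer-rate) evaluation are out of scope.
* EDF output is plain EDF: events travel in a tab-delimited sidecar, not
  EDF+ annotations. XDF support is read-only and limited to one EEG plus
  one marker stream.
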