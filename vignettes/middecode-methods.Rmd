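---
title: "Decoding motion-in-depth from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motion-in-depth from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`middecode` implements a time-resolved multivariate decoding analysis for
EEG responses to stereoscopic motion-in-depth (MID) stimuli. Two binocular
cues can signal that an object approaches or recedes: *changing disparity*
(CD), the temporal derivative of binocular disparity carried by binocularly
paired dots, and the *interocular velocity difference* (IOVD), the
difference between the two eyes' retinal velocities carried by unpaired,
coherently moving dot fields. The package covers the full chain:

1. **Stimulus synthesis** (`make_cd_sequence()`, `make_iovd_sequence()`,
   `make_static_sequence()`) — geometrically faithful random-dot stereogram
   frame tables with their defining invariants exposed to tests.
2. **Synthetic EEG** (`session_spec()`, `generate_session()`) — a forward
   model with condition-locked components in realistic noise, providing
   ground truth for every downstream stage.
3. **Preprocessing** (`preprocess_epochs()`) — 30 Hz low-pass, linear
   interpolation from 1000 to 125 Hz.
4. **Bootstrap pseudo-epochs** (`build_pool()`, `draw_mean_epochs()`).
5. **Per-timepoint pairwise linear-SVM decoding** (`decode_timecourse()`,
   `cross_decode_timecourse()`, `relabel_and_decode()`).
6. **Group statistics** (`cluster_test()`, `bonferroni_pointwise()`).
7. **Orchestration** (`run_experiment()`) over the nine-comparison matrix.

Real recordings for this paradigm are not publicly archived, so the package
is validated end-to-end against its own synthetic sessions, where injected
effects are known exactly.

# Stimulus model

Dots live in an annulus (inner radius 1°, outer 6°) at one dot per square
degree — 110 dots per eye per frame — with a Gaussian profile
(σ = 0.05°); one "dot width" is operationalised as 4σ = 0.2°. A trial
is one 250 ms linear ramp at 60 frames/s per eye (15 frames).

* **CD**: every frame is a fresh, binocularly correlated dot field; the two
  eyes differ only by ±disparity/2. The disparity ramp spans +32 to
  −32 arcmin (toward; positive = uncrossed/far), so the stimulus-averaged
  disparity is exactly zero. Base positions are rejection-sampled so both
  monocular positions stay inside the annulus.
* **IOVD**: the eyes see independent dot fields translating with equal
  speed and opposite sign, the right-eye shift ramping between
  ±128 arcmin. Dots live 50 ms (3 frames); deaths are staggered so about
  a third of dots is reborn each frame at a fresh position. Each eye is
  confined to alternating 0.5°-tall horizontal strips (left eye even
  strips counted from the annulus bottom). Dots that drift past the
  annulus chord at their height wrap within the union of chords — a
  package choice that preserves both the strip assignment and uniform
  density.
* **Border polarity rule**: a right-eye dot within one dot width of a strip
  border, with a left-eye dot within one dot width of the same border and
  of its horizontal position, takes the polarity opposite its nearest such
  neighbour, so near-coincident interocular pairs cannot form a spurious
  disparity match. The change is realised as a polarity *swap* with an
  off-border right-eye dot, which keeps the 50:50 black/white balance
  exact — a flip alone would not.
* **Static control**: CD construction with the ramp replaced by a constant
  ±32 arcmin pedestal (near or far); stereomotion velocity is zero.

The contrast ramp at the annulus edge (0.5° cosine) is recorded as a
per-dot `contrast_weight`; rendering is out of scope.

# Synthetic EEG forward model

Each epoch (−200..800 ms, 64 channels, 1000 Hz) is

\[ X_e = \sum_c \ell_c(\text{cond}_e)\, j_{c,p}\, A_c\, \mathbf{t}_c\,
   h_c(t) + N_e \]

with, per component \(c\): a unit-norm smooth random topography
\(\mathbf{t}_c\) (Gram-Schmidt-orthogonalised across components), a Hann
window \(h_c\) on \([t_\text{on}, t_\text{on}+\Delta]\), a signed condition
loading \(\ell_c\), and a per-participant lognormal(0, 0.2) amplitude
jitter \(j_{c,p}\). Noise \(N_e\) is spatially mixed 1/f background
(periodogram slope −1 over 2–30 Hz, RMS 10 µV), a 10 Hz alpha oscillation
with fixed topography and fresh phase per epoch (5 µV), and white sensor
noise (2 µV). Labels, jitter, topographies and noise draw from independent
RNG streams derived from one master seed, so sessions replay exactly.

The default component set mirrors the latency structure the analysis is
meant to resolve: a cue-selective component at 120 ms, cue-specific
direction components at 320 ms (CD) and 296 ms (IOVD), a direction
component *sharing one topography across both cues* at 500 ms — this
shared component is the only channel through which a cross-trained decoder
can transfer — and, for static sessions, a brief disparity transient at
288 ms.

**Calibration.** Component amplitudes (16 / 9 / 9 / 4 / 6 µV) and the cue
duration (250 ms) were fixed once, by pilot simulation, so that
first-significant-cluster onsets recover the injected latencies to within
the 8 ms analysis grid's ±24 ms tolerance with six participants and ten
bootstrap iterations. A Hann bump rises quadratically from its onset, so
onset recovery — not peak decodability — is the binding constraint; with
these settings mid-window decoding saturates near ceiling, which we accept:
the tested quantities are onsets, chance levels and error rates, not peak
heights. Amplitudes of this size are at the upper end of plausible evoked
responses; treat the generator as a test harness with EEG-like statistics,
not a biophysical simulation (no volume conduction, no artifacts, no
between-channel geometry).

# Preprocessing

The 30 Hz low-pass is a 4th-order Butterworth applied forward-backward
(zero phase) with 100-sample odd-reflection padding; only the cutoff is
part of the analysis design — the order and the zero-phase realisation are
package choices exposed in `preproc_config()`. Epochs are then downsampled by linear interpolation
onto \(t_k = -200 + 8k\) ms. A 125-point grid covering −200..800 ms
inclusive is arithmetically impossible; we fix the sample count at 125
(−200..792 ms), matching the per-timepoint analysis everywhere.

# Bootstrap pseudo-epochs

Per condition, epochs form a sampling pool (1260 total for a default
session, 315 per condition). One bootstrap iteration draws, per class,
21 *disjoint* sets of 10 epochs — a partition of a random 210-epoch
subsample — and averages each set into a pseudo-epoch. Epochs are reused
across iterations but never within one. This is a deliberate design
choice: if the 21 draws may share epochs, all pseudo-epochs of a class
concentrate around the finite pool's noise mean, the leave-one-out test
item shares raw epochs with the training set, and pure-noise sessions
decode far above chance. With disjoint draws the 42 pseudo-epochs of an
iteration are independent under the null and the chance level is unbiased
— the property the shuffle-control checks in the test suite verify.

After averaging, each channel is standardised to mean 0, SD 1 *over the
whole draw set* (one affine transform per electrode, shared by every
pseudo-epoch and class). This equalises electrode scales — every electrode
contributes comparably to the classifier — without letting class
information enter the transform. We explicitly did not standardise each
pseudo-epoch over its own time axis: that subtracts the epoch's
condition-dependent evoked mean from its baseline samples and makes the
pre-stimulus period decodable well above chance, which would corrupt
every latency estimate. The per-epoch contract remains available as
`zscore_epochs()`.

Pooled comparisons (direction pooled over cue, cue pooled over direction)
keep member conditions separate inside each superclass and draw 5 epochs
from each member per pseudo-epoch, so pooled classes are always balanced.

# Decoding

At each of the 125 timepoints the features are the 64 channel values of
each pseudo-epoch. The classifier is a soft-margin linear SVM
(C = 1, the customary libsvm default). The default engine is an
in-package SMO solver for the linear C-SVC dual (compiled; maximal
violating pair selection, libsvm-style stopping at KKT violation 1e-3);
`engine = "libsvm"` routes the same problem through e1071. The two agree to
solver tolerance and the test suite cross-checks them against each other
and against a brute-force margin oracle.

Leave-one-out folds hold out one pseudo-epoch *per class* (21 folds, 40
training epochs, 2 test classifications each) — the stated 40-epoch
training set is incompatible with holding out a single item from 42, and a
per-class holdout keeps training balanced. Plain 41-train LOO is available
via `fold_scheme = "single"`. Exact decision-value ties predict the class
with the lower sort order. Per-timepoint accuracies are averaged over
iterations (default 1000; reduced in tests).

Cross-trained decoding fits on all 42 pseudo-epochs of the training pair
and evaluates all 42 of the test pair; train and test never share data by
construction. `relabel_and_decode()` reruns the identical machinery under
replacement labels (shuffle control, percept/response analyses),
stratified-subsampling the majority class when the relabeling is
unbalanced.

# Group statistics

Group inference per comparison: one-sample t against 50% at each timepoint,
clusters formed from maximal runs exceeding the one-sided
\(\alpha = 0.05\) critical value (df = n−1), cluster mass = summed t, and a
sign-flip permutation null (each participant's whole centred timecourse
flips together) of the *maximum* cluster mass. Cluster p-values use the
add-one estimator \((1 + \#\{M_\text{null} \ge m\})/(1 + B)\), avoiding
p = 0. Decoding below chance is not interpretable here, hence the one-sided
default; a two-sided variant is a flag. Zero-variance timepoints yield
infinite t sentinels that join runs with mass capped at 100. A
Bonferroni-corrected pointwise alternative (`bonferroni_pointwise()`,
threshold \(\alpha/125\)) is provided because both corrections are in
common use for decoding timecourses and they can disagree near cluster
edges; the cluster test is the default.

# Problem sizes used in the tests

The full protocol (10 participants × 1260 epochs × 1000 iterations) is the
generator's default. The test suite exercises reduced designs chosen as
the smallest that keep every structural constant intact: one full default
participant for the wiring and shuffle-control checks; six participants ×
four blocks (840 epochs — the smallest pool admitting the 21 × 10
partition) at ten iterations for latency recovery; 60 simulated null
groups of 12 participants for the family-wise error check (simulated at
the accuracy-matrix level, where the sign-flip test's only assumption —
symmetry about chance — is controlled); 500–5000 permutations depending on
context. The acceptance script runs one default participant with 50
iterations.

# Known limitations

* The generator's components are fixed-latency, fixed-topography bumps;
  real MID responses drift in latency across participants, which would
  blur group onsets rather than shift them.
* Channel "geometry" is an index, not a montage; spatial mixing is a random
  orthogonal operator, so scalp-topography realism is out of scope.
* The static-disparity transient (24 ms) is near the resolution limit of
  the 30 Hz low-pass; its recovery is noisier than the main components'.
* Cross-decoding transfer depends entirely on the shared-topography
  component; it demonstrates the analysis can detect shared information,
  not that real CD/IOVD pathways converge.
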