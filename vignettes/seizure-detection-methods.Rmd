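---
title: "Detecting high-amplitude stereotypic seizures in post-HI EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting high-amplitude stereotypic seizures in post-HI EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hasdetect)
```

## The problem

After a hypoxic–ischemic (HI) insult, the immature brain frequently develops
high-amplitude stereotypic evolving seizures (HAS) during the secondary phase
of injury: trains of repetitive, stereotyped discharges, delta-dominant,
lasting at least 10 s with amplitudes above 20 µV. Detecting these events
automatically in continuous 256 Hz EEG is complicated by maturational
differences (preterm delta is slower than term delta), by therapeutic
hypothermia (which partially suppresses seizure rate and amplitude), and by
non-seizure activity — background EEG, movement artifact and electronic noise
— that can rival seizures in amplitude.

`hasdetect` implements a complete, reproducible pipeline for this task:

1. a **synthetic cohort generator** producing labelled fetal-sheep-like EEG
   for four groups (G1 HI-normothermia term, G2 HI-hypothermia term,
   G3 sham-normothermia term, G4 HI-normothermia preterm);
2. **power-trend computation and seizure centering**, turning coarse
   per-minute seizure marks into exactly centred fixed-length epochs;
3. three **convolutional front-ends** — Morlet wavelet-scalogram images
   (WS), a three-column wavelet/Fourier dominant-feature matrix (WF), and
   raw segments (1D);
4. compact **CNN classifiers** trained with RMSProp; and
5. an **evaluation harness** covering leave-one-group-out and stratified
   k-fold designs with confusion-matrix metrics and ROC/AUC summaries.

## The synthetic cohort generator

Real recordings of this kind are not publicly deposited, so the package
ships a generator that reproduces the statistical structure the classifiers
exploit. It is first-class, tested code — not a fixture.

**Background.** Zero-mean 1/f^a coloured noise, shaped in the frequency
domain. Term background uses a = 1 with a 30 Hz low-pass edge; preterm uses
a steeper a = 1.6, a 10 Hz edge, and trace discontinuity modelled as
alternating burst (4–10 s) / interburst (2–8 s) amplitude modulation with
the interburst level at 25%. Default RMS is 10 µV (term) and 8 µV
(preterm), well below the 20 µV seizure threshold.

**Seizures.** A HAS is synthesised as a train of stereotyped discharges: a
fixed (per-event) carrier at a dominant frequency inside the delta band with
a sharpening third harmonic, gated into discharges whose repetition rate
evolves — slowing from the upper to the lower part of the band across the
event — under a single smooth crescendo–decrescendo (root-Hann) envelope
symmetric about the event midpoint. Durations default to 15–90 s and peak
amplitudes to 40–250 µV; every event re-measures above the definitional
minima (≥ 10 s, > 20 µV). The envelope is deliberately unimodal and
symmetric so that the event's centre of weight — the quantity the centering
algorithm recovers — coincides with the ground-truth centre; see
"Limitations" for why this matters.

**Group structure.** HAS rates per channel-hour default to 6 (G1), 6 × 0.65
(G2, the hypothermia suppression factor, which also scales G2 amplitudes),
0 (G3, sham — enforced; a config requesting sham seizures is rejected), and
6 × 0.815 (G4). The relative rates mirror the per-channel-hour seizure
burden of the four cohorts; `animals_per_group` and `record_duration` are
the scale dials, so a desk-scale cohort is simply a shorter, smaller one
with the same structure. Classifier datasets cut one segment per seizure
plus randomly placed non-seizure segments at the canonical ratio of
27,060:3,955 ≈ 6.84 non-HAS per HAS, distributed over groups by the
reference non-HAS shares.

**Artifacts.** Non-HAS material includes movement lurches (large, slow),
50 Hz mains bursts, and brief electrode spikes, at a default 2 events per
channel-hour with amplitudes of 30–120 µV — overlapping weak seizures in
energy, which is precisely what makes the detection problem non-trivial.

**The separability dial.** `contrast` divides the background RMS, raising
the seizure-to-background amplitude ratio while keeping seizure and
artifact amplitudes physiological. At `contrast = 10` a trivial energy
threshold separates seizures from artifact-free background almost
perfectly, which anchors the scaled-down learning tests. (An earlier design
that multiplied seizure amplitudes instead was discarded: it produced
non-physiological microvolt ranges that served no modelling purpose.)

Everything is a pure function of `(config, seed)`: identical seeds give
byte-identical cohorts.

## Power trend and seizure centering

Long experiments are monitored through a per-minute power trend: for each
complete minute, a rectangular-window periodogram is computed and the power
in 1–20 Hz (bins inclusive) summed; the trend value is
`20·log10(intensity)` in dB (base-10, as the dB unit implies). Trailing
partial minutes are dropped.

A seizure marked on this trend is located only to the minute. The centering
procedure refines it: take the raw EEG one minute either side of the marked
minute's midpoint (`sig_1`); zero-mean, normalise to unit peak, and raise
elementwise to the 10th power (`sig_2`) — the normalisation only prevents
floating overflow and cannot change the result, because every later step is
scale-equivariant and the final argmax is scale-invariant; since the
zero-meaned data are raised to an even power we compute `|x|^10` explicitly,
which is identical. `sig_2` then passes through a moving median absolute
deviation with a window of 8000 samples (31.25 s at 256 Hz), centred and
truncated at the edges (`sig_3`). The argmax of `sig_3` is the seizure's
centre of weight; ties resolve to the earliest index, and a perfectly flat
trace falls back to the excerpt midpoint. The rescaling of `sig_3` to
`sig_1`'s range is for QC plotting only.

The centred epoch is then cut as `[centre − ⌊L/2⌋, centre + ⌈L/2⌉)` with
L = 51,302 samples — 200.4 s, i.e. 3.34 min — zero-padding (with a flag) at
record edges. Non-seizure epochs are sampled uniformly over all window
starts whose half-open interval avoids every seizure interval; they may
freely contain artifacts and noise, and may overlap one another.

The movmad itself is implemented in C++ with an incrementally maintained
sorted window (exact median; median absolute deviation by selection over
the two sorted deviation sequences around the median), and is tested for
exact agreement with a brute-force `median()` oracle.

## The three front-ends

**Pseudo-frequency.** A Morlet scale a at sampling rate fs corresponds to
the pseudo-frequency `Fc · fs / a` with Fc = 0.8125. The scale grid
1, 6, …, 496 (1 to 500 in steps of 5; 100 scales) therefore spans 208 Hz
down to 0.42 Hz at 256 Hz. (The alternative convention Fc = 0.8 would put
scale 80 at exactly 2.56 Hz but fails to reproduce the 0.42–208 Hz
endpoints; we keep 0.8125 throughout and note the discrepancy here rather
than split conventions.)

**WS.** The segment is zero-meaned and transformed with the real Morlet
wavelet `exp(−x²/2)·cos(5x)` over the full scale grid (FFT convolution,
zero-padded edges); coefficient magnitudes are rendered as a 500 × 333 RGB
PNG (time on x, scale increasing downwards), per-image min–max normalised,
with a fixed 64-level jet palette and 300 dpi metadata. Rendering is
deterministic to the byte. Signs are discarded in images only.

**WF.** An L × 3 matrix: signed CWT coefficients at scale 80
(pseudo-frequency 2.6 Hz, near the delta-band mean frequency), a 0.2–4.5 Hz
band-limited Fourier reconstruction (forward DFT, conjugate-symmetric
zeroing outside the band, inverse DFT; imaginary residue checked), and the
raw segment itself, presented to the 2D network as L × 3 × 1.

**1D.** The raw segment, L × 1. For the WF and 1D front-ends a fixed global
scale of 1/100 maps microvolts to order-one units; no per-segment
normalisation, denoising or augmentation of any kind is applied.

## Architectures and training

The flagship classifier is a 17-layer CNN for 333 × 500 × 3 scalogram
images: seven convolution blocks (kernel 3, stride 1, pad 1; batch norm +
ReLU; 32, 48, 64, 96, 128, 192, 256 filters), each followed by a stride-2
max-pool with kernels [3 2], 2, 3, [3 2], [2 3], [4 5], 2, then fully
connected layers 1536 (the flatten width) → 24 → 2 and a softmax +
classification head. Spatial arithmetic follows
`out = ⌊(in + 2·pad − kernel)/stride⌋ + 1`; propagation reproduces the
per-block sizes 166×250, 83×125, 41×62, 20×31, 10×15, 4×6, 2×3 and the
flatten width 2·3·256 = 1536, and construction fails loudly (naming the
layer) if an input shape collapses a dimension.

The WF and 1D classifiers are 14 layers deep under the same counting
convention (conv/pool stack + the fully-connected block): six convolution
blocks with pooling only along the time axis (kernel and stride [4 1], so
no pool reduces time by more than 4× and the 3-column feature axis of the
WF matrix survives to the flatten point). The same schedule builds for the
full L = 51,302 and for reduced desk-scale lengths (L ≥ 1024). The exact
filter counts of these two schedules are this package's own design, honouring
the stated depth, input shapes and the requirement to avoid aggressive
inner-layer size reduction.

Training uses RMSProp with learning rate 1.00 × 10⁻³ and squared-gradient
decay 0.9, 60 epochs at full scale, two-class cross-entropy (implied by the
softmax head), batch size 32 (unspecified upstream; configurable), and a
stratified 90/10 train/validation split of the training partition (fraction
unspecified upstream; configurable, and set to 0 where every labelled
segment is needed for training). Convolution is vectorised im2col matrix
multiplication; gradients are verified against finite differences in the
test suite. All randomness — initialisation, splits, epoch shuffling — is a
function of the config seed, so training is reproducible bit for bit. Runs
abort with a diagnostic on non-finite loss; single-class or empty datasets
are rejected.

The deliberately trivial reference detector is an energy threshold: each
segment reduced to log-RMS amplitude, one threshold chosen on the training
set. It is the yardstick the CNNs must beat when the non-HAS class contains
high-energy artifacts.

## Study designs and metrics

Three designs are built over any labelled segment manifest:

* **Study 1** — leave-one-group-out with the sham group in training:
  train G1+G2+G3 test G4; train G1+G4+G3 test G2; train G2+G4+G3 test G1.
* **Study 2** — the same three schemes without G3.
* **Study 3** — stratified 5-fold over all groups pooled (80/20), folds
  dealt per class after a seeded shuffle, remainders to the earliest folds;
  the partition is identical for every detector given the seed.

Fed the reference cohort composition (31,015 segments = 3,955 HAS +
27,060 non-HAS), these builders reproduce the reference partition sizes
(e.g. study-1 scheme-1 training 20,491/2,311/18,180, ratio 1.95; per-fold
test 6,203 = 791 + 5,412), which the test suite asserts.

Metrics: sensitivity `100·TP/(TP+FN)`, selectivity (true-negative rate)
`100·TN/(TN+FP)`, precision `100·TP/(TP+FP)`, accuracy
`100·(TP+TN)/total`. Precision is TP/(TP+FP) — the only definition
consistent with the reference performance rows, all 33 of which the suite
recomputes at two decimals. Zero-denominator ratios are reported as `NaN`,
never 0 or 100. ROC curves sweep the unique scores and integrate by
trapezoid; the AUC equals the Mann–Whitney pairwise statistic (ties counted
half), cross-checked against both an exhaustive pairwise oracle and pROC.
Across schemes, summaries report mean ± SD with the population (n-divisor)
SD — the convention that reproduces the reference summary values — and
mean ± SD ROC bands come from vertical averaging on a fixed FPR grid.

## Desk-scale profile and problem sizes

Full-scale defaults (51,302-sample segments, 500 × 333 images, the printed
filter schedule, 60 epochs) are impractical for routine testing, so
`desk_profile()` fixes a reduced profile used by the test-suite and the
pipeline's `"desk"` scale: 1,024-sample segments (4 s), 50 × 33 images,
filter schedules 8/12/16 (WS) and 8/8/12/12/16/16 (WF/1D), 8 epochs,
batch 32. The scaled-down learning check trains all three detectors on a
five-fold split of ≈1,000 high-contrast segments (two animals per group,
one-hour records, 12 seizures and 12 artifacts per channel-hour,
contrast 10) and compares them with the energy baseline; the artifact-rich
non-HAS mix is what gives the baseline a measurable error rate for the
CNNs to beat.

## Numerical choices and degenerate inputs

* movmad windows are centred; even windows extend one sample further left.
  Even-count medians average the two middle order statistics, matching
  `stats::median()`.
* Argmax ties: earliest index. Flat centering traces: excerpt midpoint.
* Prediction ties (softmax exactly 0.5): the conservative call, non-HAS.
* Constant segments produce all-zero scalograms (valid, not an error);
  all-zero scalograms render as a uniform image.
* EDF encoding is 16-bit with symmetric physical range; the encode map is
  the exact inverse of the standard EDF decode map, so round-trip error is
  bounded by half a digital step. The original (non-whole-second) sample
  count is carried in the per-signal reserved field so padding is dropped
  on read. mV physical dimensions are converted to µV on read.
* Sampling rates other than 256 Hz are read with a warning and never
  resampled.
* The float32 segment store halves disk use; EEG dynamic range is far below
  float32 precision, and a second round trip is bit-exact.

## Limitations

* **Centering precision depends on event duration.** The movmad trace of
  the 10th-power signal behaves like the windowed median amplitude raised
  to the 10th power. Its argmax is sharply determined when the event's
  duration is comparable to the 8000-sample window (~30–45 s at 256 Hz);
  much shorter events produce plateaus of exact ties and much longer ones
  produce broad interior plateaus, leaving the centre under-determined by
  several seconds. The recovery test therefore uses window-matched
  durations; for real data, the same caveat applies and the QC plots exist
  precisely so an expert can check the centring.
* **What the generator does not emulate.** Electrode impedance drift,
  inter-channel correlation, state cycling, post-insult background
  suppression trajectories, and status epilepticus (merged seizures) are
  not modelled. Passing tests demonstrate the pipeline's correctness and
  its ability to learn the modelled structure — not clinical-grade
  performance on real recordings, whose headline accuracies depend on data
  this package does not ship.
* **Architecture fidelity.** The 17-layer WS schedule is fully specified
  upstream and reproduced exactly; the 14-layer WF/1D schedules are
  documented designs under stated constraints, since their full tables are
  not available in the source text.
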