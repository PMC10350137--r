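---
title: "Measuring sleep from wrist accelerometry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sleep from wrist accelerometry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(somnokit)
```

`somnokit` measures sleep from raw tri-axial wrist acceleration: it turns a
multi-day 30–100 Hz trace into quality-controlled 30-second epochs, assigns
each epoch one of the five AASM sleep stages (wake, N1, N2, N3, REM) with a
deep sequence classifier or a random-forest baseline, finds the nightly
time-in-bed window in free-living data, and summarises each night as seven
sleep parameters. This vignette documents the models behind each step, the
parameters that matter, and the design decisions that were genuinely open —
including where the package deliberately deviates from the most obvious
construction and why.

## The measurement problem

Polysomnography scores sleep in 30-second epochs from brain, eye and muscle
signals. A wrist accelerometer sees none of those; it sees movement and
posture. Stage inference from the wrist is therefore indirect: wake shows
frequent large movements, N1 occasional repositioning, N2 and REM near
stillness (REM with small phasic twitches), N3 almost none. Classification
exploits those intensity and texture differences plus the strong temporal
structure of a night (stages come in bouts; transitions are constrained).
Everything downstream — time-in-bed detection, sleep duration, efficiency,
WASO — is arithmetic over the per-epoch labels.

## The synthetic-data generator

No cohort data ship with the package; instead the generator reproduces the
statistical structure the pipeline assumes, with known ground truth.

**Stage sequence.** A first-order Markov chain over (W, N1, N2, N3, R) at
30-s resolution. The default transition matrix encodes mean bout lengths of
about 2 min for within-night wake, 1 min for N1, and 10 min for N2, N3 and
REM, with a wake-biased initial distribution; these are fixture constants
with plausible AASM bout structure, not estimates of any population.

**Movement.** Per stage, the wrist signal is a unit gravity vector whose
orientation performs a slow random walk, plus Gaussian sensor noise, plus
sparse movement bursts: Poisson-timed, exponentially damped (τ = 0.25 s)
impulses in uniformly random directions with stage-specific rate and
amplitude. Sparse bursts reproduce the heavy-tailed, bout-like character of
real wrist actigraphy; with all movement sources at zero the vector
magnitude is exactly 1 g, which the tests assert. Default intensities order
the stages W > N1 > (N2, R) > N3 in mean ENMO, with N2 and REM deliberately
similar in energy but different in texture (rare larger bursts vs more
frequent tiny twitches).

**Separability knob.** `movement_profile(contrast = c)` interpolates every
per-stage parameter geometrically between the across-stage geometric mean
(`c = 0`: all stages statistically identical) and the preset (`c = 1`).
This gives the test suite a clean null: at `c = 0` no classifier can beat
chance, whatever its capacity. A `"high_contrast"` preset provides widely
separated signatures for learning sanity checks that should be easy.

**Free-living structure.** Days run noon-to-noon. Each night gets a
time-in-bed interval from clock-time means with night-to-night Gaussian
jitter and a weekend shift; afternoon naps occur with a configurable
probability; off-wrist gaps arrive as Poisson events with log-normal
durations and are cut from the trace (the truth hypnogram stays complete).
A diary reports bed/rise times with N(0, 10 min) error.
`simulate_cohort()` additionally draws per-subject habitual bed/rise
offsets (sd 45 min), because reliability analyses are about between-person
variance: a cohort in which everyone shares one schedule has essentially
none, and every ICC is near zero by construction.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: EEG-defined stage semantics (labels are only
linked to movement through the profile), device-specific noise signatures,
posture-stage correlations (orientation drift is stage-independent),
circadian modulation of bout structure within the night, and populations
with fragmented or disordered sleep. Tests on this generator validate the
pipeline's mechanics and its statistical machinery, not clinical accuracy.

## Preprocessing rules

The raw trace is resampled to 30 Hz by per-axis linear interpolation onto a
grid anchored at each contiguous segment's first sample; gaps longer than
5 s are never interpolated across — they split segments, because inventing
signal across an off-wrist gap would fabricate data. Values are clipped to
±3 g. Consecutive 30-s epochs (900 samples × 3 axes) are cut per segment,
dropping trailing partial windows. An epoch is *stationary* when each
axis's within-epoch sd is below 13 mg; maximal stationary runs strictly
longer than 60 min are flagged non-wear ("greater than 60 minutes" is read
strictly, so an exactly-60-minute still period stays wear). A recording is
excluded when it cannot be parsed, when its mean truncated ENMO
(max(‖a‖₂ − 1 g, 0), averaged over wear epochs) exceeds 200 mg — a
recording-level reading of the threshold; a per-sample bound would reject
normal movement — or when the median stationary-epoch magnitude leaves
1 g ± 30 mg (full sphere-fit autocalibration is out of scope; this check
catches grossly uncalibrated devices).

## The deep sleep stager

Per 30-s epoch, a 1D-convolutional encoder produces a fixed-length feature
vector; a bi-directional LSTM consumes the whole night of epoch vectors; two
fully-connected layers output 5-class logits. Training minimises
inverse-frequency class-weighted cross-entropy (N2 dominance otherwise
collapses the minority stages), one whole night per gradient step, Adam at
`lr = 3e-3`, 12 passes by default. All seeds are plumbed; at a fixed thread
count runs are bit-reproducible.

The encoder is a pre-activation residual network: a stride-2 stem
convolution, then `encoder_blocks` blocks of
BN → ReLU → conv(stride 2) → BN → ReLU → conv, each with a 1×1 stride-2
projection shortcut, a final BN–ReLU, and global average pooling. The
default desk-scale configuration uses 4 blocks with channels
(8, 12, 16, 20), kernel 7, LSTM hidden size 16 and a 32-unit FC layer; a
`"paper_scale"` preset with 8 blocks (17 convolutional layers) and wide
channels exists for completeness but is not exercised by the tests.

Two choices here were forced by experiments rather than taken from the
architecture family's description:

* **Normalisation statistics.** Batch normalisation uses the statistics of
  the sequence being scored (the night, or the pretraining minibatch) both
  in training and at inference. Conventional running-average statistics
  produced a severe train/inference mismatch at this data scale — nights
  differ enough in composition that features learned relative to per-night
  statistics misalign with global averages, and held-out predictions
  collapsed to a single class. Per-sequence statistics make inference
  deterministic per night and remove the mismatch. The cost is that a
  night's features are normalised relative to that night, which is also a
  reasonable modelling position for wrist data (movement scale varies per
  person and device).
* **Gravity removal.** The encoder first subtracts each window's per-axis
  mean. The raw signal is dominated by the ~1 g gravity component, whose
  orientation varies across windows with posture; without centering, every
  pooled feature is mostly orientation, and both supervised training and
  especially self-supervised pretraining stall. In this simulator
  orientation carries no stage information; on real data posture cues are
  still available to the baseline's angle features.

**Collapsing.** Five-class posteriors collapse to wake/REM/NREM or
wake/sleep by *summing probabilities first* and then taking the argmax:
argmax-then-collapse would let a single large wake probability defeat
posterior mass spread across the three NREM stages. `collapse()` applies
the same pooling to hard labels.

**Self-supervised pretraining.** `pretrain_ssl()` optimises the sum of
three binary cross-entropies through linear heads on the pooled encoder
output: detect time reversal, segment permutation (4 equal segments,
non-identity shuffles), and time warping (resampling factor 0.5–2, then
crop/edge-pad to 900 samples), each applied independently with probability
0.5. On burst-containing windows reversal is detectable from the
asymmetric impulse shape, and warping from the altered noise bandwidth (or
the padded tail); on near-still windows the tasks are undecidable, so the
pretraining corpus should be movement-rich — matching the free-living,
daytime-dominated data such encoders are pretrained on in practice.
Permutation remains near chance on this simulator (segment boundaries in
quiet, centered windows are nearly invisible); it is kept because it costs
nothing and the task mix is part of the method.

## The random-forest + HMM baseline

`extract_features()` computes 30 classical per-epoch statistics: per-axis
mean/sd/range; ENMO mean/sd/MAD; pairwise axis correlations (defined 0 for
constant axes); arm-angle mean and mean absolute successive difference;
roll/pitch mean and sd; magnitude moments, peak-to-peak, skewness, excess
kurtosis; dominant frequency in 0.3–15 Hz and its power, 1–3 Hz band
power, and spectral entropy — computed on the summed per-axis periodograms
(each axis mean-removed, Hann-windowed) rather than on the vector
magnitude: the magnitude rectifies any oscillation orthogonal to gravity
onto twice its frequency (‖(A sin ωt, 0, 1)‖ varies with sin² ωt), whereas
the per-axis sum is orientation-invariant and reports the fundamental. A probability
random forest (500 trees by default, √p features per split) classifies
epochs; its out-of-bag class probabilities calibrate the HMM so smoothing
is not fitted on optimistic training predictions. Smoothing treats the true
stages as hidden states: transitions are add-one-smoothed bigram counts of
the training labels, the emission matrix is the row-normalised confusion of
out-of-bag argmax predictions against truth, and decoding is exact Viterbi
in the log domain with emission likelihoods
`Σ_j P(output = j | state = i) · p_model(j)`, floored at 1e-6. The test
suite proves the decoder equal to exhaustive path enumeration for k ≤ 3,
T ≤ 8 over 100 random instances.

## Free-living windows and sleep parameters

Smoothed wake/sleep labels are scanned for maximal sleep runs; runs are
merged whenever the gap between them is at most 60 minutes (inclusive);
merged windows shorter than 30 minutes are discarded; each remaining window
is assigned to the noon-to-noon interval containing its midpoint, and the
longest window per interval (ties to the earlier start) is the night's
time-in-bed. The 30-minute floor is applied *after* merging, not in the
detector: brief awakenings legitimately fragment raw sleep runs into
sub-30-minute pieces, and filtering first would delete real sleep before
the merge can reassemble it — with oracle labels, filtering first recovered
only 15/100 simulated nights within ±15 min, merging first recovers
100/100. Non-wear epochs inside a window remain part of time-in-bed but
contribute no sleep, and windows with more than 20% missing epochs are
flagged low-confidence.

Within a window, on epoch counts (0.5 min each): TST = REM + NREM epochs;
sleep efficiency = 100 × TST / time-in-bed; sleep onset = first sleep
epoch; WASO counts wake epochs from onset to the window end (a fixed,
auditable convention — counting only to the final awakening would make
WASO depend on a second boundary definition); REM/NREM ratios are
percentages of TST. A window with no sleep reports TST = 0, SE = 0 and
WASO missing. These definitions make the partition identities exact —
REM + NREM = TST and pre-onset wake + WASO + TST = time-in-bed — and the
suite asserts them on 1,000 random hypnograms. Weekly summaries average
over valid days (≥ 22 h wear), and are valid with ≥ 3 such days including
a weekday and a weekend day. Weekly mean duration is categorized as short
(< 6 h), normal (6–7.9 h) or long (≥ 8 h); the efficiency low/high split
is a parameter (cohort median by default) because no universal cut-point
exists.

## Validation machinery

Confusion matrices put truth in rows in declared class order. Cohen's
kappa is unweighted, with the degenerate p_e = 1 case defined as 1 when
observed agreement is perfect and 0 otherwise. Macro-F1 skips classes that
are neither present nor predicted (a night without REM should not be
penalised for REM); balanced accuracy averages recall over classes present
in the truth. Bland-Altman limits use bias ± 1.96 sd with the n−1
denominator. Subject-wise cross-validation partitions subjects, never
splitting one subject's nights, and reports both the subject-wise mean ± sd
(subjects weighted equally — with one validation night per subject the
weighting question is moot, which is why equal weighting was chosen) and
pooled epoch-to-epoch metrics. The ICC is ICC(2,1) — two-way
absolute-agreement, single measure — because degraded and complete weekly
means are paired measurements of the same quantity; it is computed directly
from the two-way ANOVA mean squares and checked against that definition in
the tests.

`wear_missingness_sim()` starts from subjects with complete 7-day wear,
keeps `d` random days, and removes one contiguous block of 24 − h hours at
a uniformly random start from each kept day (wear gaps are contiguous in
practice; uniform per-epoch censoring is available as an option), then
compares censored weekly mean sleep duration against the complete-data
means by ICC, averaged over replicates. The grid's minimal criterion — the
fewest days, then fewest hours, with ICC > 0.75 — depends directly on the
cohort's between-subject variance; with the generator's default 45-min
habitual-timing spread, full-wear cells sit near 1 and heavy censoring
collapses towards 0, with monotone improvement in wear hours.

## The chance-level control

One subtlety deserves its own section. At `contrast = 0` every stage emits
statistically identical signal, so one might expect any classifier to sit
at balanced accuracy 1/3. With the generator's default settings the deep
stager nevertheless reached ≈ 0.5 — without using the signal at all. The
night-starts-awake initial distribution gives the truth a time-of-night
trend, and the bi-LSTM reproduces that same trend from position alone;
truth and prediction correlate through the shared prior. This is a genuine
property of non-stationary sequences, not leakage. The chance-level
experiments therefore draw the stage chain from its stationary distribution
(`stationary_distribution()`), under which any signal-independent predictor
has expected balanced accuracy exactly 1/3; the observed values land inside
the [0.28, 0.40] band the tests assert.

## Numerical choices and problem sizes

Gradients for every layer (convolution, batch norm, LSTM, dense, weighted
cross-entropy) are implemented in the package and verified against central
finite differences to < 1e-4 relative error on a down-scaled network (with
parameters nudged off zero, since ReLU kinks at exactly zero make the
subgradient comparison ill-posed). Viterbi and the HMM run in the log
domain with a 1e-6 emission floor. Ties in argmax resolve to the first
class in declared order; equal-length windows resolve to the earlier start;
correlations of constant axes are 0.

The shipped experiments are sized for a single CPU: learning checks use
20 nights of 120 epochs (1 h) each, 15 for training; pretraining uses
1,200 unlabelled windows for 10 epochs; the window-recovery audit uses 100
one-night recordings at label level; the wear simulation uses 25 subjects
× 7 days with 3 replicates per grid cell. These sizes are the package's
test conditions, stated so results are interpretable — they are small
relative to any real cohort, and the deep model's accuracy on
high-contrast synthetic nights (macro-F1 ≥ 0.9) reflects the separability
of the simulator at those settings, not expected performance on
polysomnography-labelled data.

## Known limitations

The stager is validated on synthetic data only; no claim about agreement
with polysomnography follows from this package alone. The movement model
has no circadian or homeostatic structure, so models cannot be probed for
reliance on time-in-night beyond the chain's own dynamics. Calibration is
screened, not estimated. DST cross-overs and shift work are represented
only as exclusion flags in recording metadata, mirroring how such
recordings are excluded rather than modelled in deployment.
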