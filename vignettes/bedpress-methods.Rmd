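---
title: "Reconstructing blood pressure from bed load-cell ballistocardiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing blood pressure from bed load-cell ballistocardiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedpress)
```

## The problem

Nocturnal blood-pressure (BP) dynamics — the normal ~10–20% sleep-time
"dip", its absence, or exaggerated dipping — carry cardiovascular risk
information that a daytime cuff measurement cannot capture, and a cuff
inflating during sleep defeats the purpose of measuring sleep. Load cells
placed under the four legs of a bed sense the tiny recoil forces of each
cardiac ejection (the ballistocardiogram, BCG) without touching the
sleeper. `bedpress` implements a pipeline that regresses the continuous
arterial BP waveform from these four force channels and then reads
systolic (SBP) and diastolic (DBP) pressure off the reconstructed
waveform.

The pipeline has five stages, each usable on its own:

1. **Conditioning** (`preprocessRecording`): zero-phase band-pass of the
   load-cell channels and decimation of all channels to 100 Hz.
2. **Windowing** (`buildWindows`, `partitionParticipants`): the sliding
   4 × N matrix dataset and participant-disjoint splits.
3. **Regression** (`buildModel`, `trainModel`, `reconstructBP`): a stacked
   LSTM maps each 0.5-s window to the concurrent BP sample.
4. **Extraction** (`detectEvents`, `windowEstimates`,
   `recordingEstimate`): derivative zero-crossing extrema with amplitude
   gates and refractory separation, aggregated over 5-s windows.
5. **Agreement** (`waveformMetrics`, `blandAltman`, `evaluateCohort`):
   reconstruction error and Bland–Altman limits of agreement at the
   window and recording level.

A synthetic cohort simulator (`simulateCohort`) stands in for the
original bed recordings so the full pipeline can be trained, tested and
reproduced offline.

## The regression model

Let $LC_j(i)$ be the $j$-th load-cell channel resampled at 100 Hz. For
every target sample $t$ the model receives the strictly causal window of
the $N = 50$ preceding samples of all four channels (a 4 × 50 matrix,
i.e. 0.5 s of force data) and predicts the scalar $BP(t)$. Sliding the
window by one sample reconstructs the entire waveform except its first
$N$ samples.

The regressor is a sequence of three 30-unit LSTM layers — the first two
return their full output sequences, the third only its last step —
followed by a single linear dense unit. With 4 input features this
architecture has exactly

$$\underbrace{4\,(30\,(4+30)+30)}_{4200}
  + 2 \times \underbrace{4\,(30\,(30+30)+30)}_{7320}
  + \underbrace{30 + 1}_{31} = 18{,}871$$

trainable parameters; the package treats this count as an architectural
identity and verifies it in its tests (it pins the feature dimension, the
layer widths, the stacking depth and the single-output head all at once).

```{r params}
nTrainableParams(buildModel(modelConfig(), seed = 1))
```

Training minimizes the mean squared error with Adam (learning rate
10^-3^, otherwise conventional moments) over minibatches of 256 windows
for 300 epochs by default, from Glorot-normal initial weights with the
customary forget-gate bias of one. After every epoch the validation MSE
is computed and the weights of the epoch with the lowest validation error
are the ones returned — ties resolve to the earliest epoch, and the
returned model's validation error therefore never exceeds the final
epoch's.

Two numerical conventions matter:

* **Target normalization is on by default**: the loss is computed on
  targets min-max scaled to [0, 1] using the *training* split only; the
  fitted affine map travels with the model and all reported mmHg
  quantities are produced through its exact inverse. Reported waveform
  errors are therefore available on both scales (a mean absolute error
  that looks implausibly small in mmHg is usually a normalized-scale
  number; the package reports both rather than guessing).
* **Load-cell inputs are used in raw filtered units** by default. A
  `zscore_inputs` switch exists for data whose per-channel gains vary
  more than the training distribution covers.

The LSTM forward pass, backpropagation through time and the Adam loop are
implemented in compiled code (single precision, as is standard for neural
network training) with the window tensor gathered on the fly from each
recording's channel matrix — the 50-fold-overlapping window set is never
materialized. The elementwise gate updates use a polynomial
approximation of `exp` with relative error ~4 × 10^-6^, far below
single-precision training noise; correctness of the gradients is checked
in the test suite against finite differences and the forward pass
against an independent double-precision reference implementation.
Bit-exact reproducibility across platforms is not promised (floating
point, BLAS), but all randomness is seeded and reruns on one platform are
identical.

## Signal conditioning

Load-cell channels are band-passed 0.05–35 Hz. The band edges keep the
respiratory and cardiac content and remove the static load and
mains-range noise; the realization — a cascade of 4th-order high- and
low-pass Butterworth sections run forward–backward — is a package choice:
zero phase matters because extrema timing downstream must not shift. The
signal mean is removed first and ends are odd-reflection padded, which
keeps the 0.05 Hz edge numerically clean (a constant maps to zero rather
than to a multi-second edge transient). The BP channel is decimated but
**not** band-passed: it is a calibrated pressure signal whose absolute
level is the quantity of interest.

Decimation from 1000 Hz to 100 Hz applies an 8th-order zero-phase
Butterworth anti-alias low-pass at 40 Hz and keeps every 10th sample;
100 Hz input passes through unchanged. The 100 Hz analysis rate is
justified by the spectral content of both signals, which falls by orders
of magnitude towards 50 Hz.

## SBP/DBP extraction

On a waveform sampled at 100 Hz the detector computes the first
difference and proposes a local maximum at every negative-going zero
crossing (rise then non-rise; plateaus resolve to their first sample) and
a local minimum at every positive-going one. Proposals survive only
inside their amplitude gate — [100, 150] mmHg for systolic, [60, 100] for
diastolic — and surviving same-kind events closer than 50 samples
(0.5 s, i.e. faster than a 120 bpm rhythm) are thinned greedily by
amplitude priority: the larger maximum (smaller minimum) wins, ties going
to the earlier sample. The refractory rule only states the required
separation, so the keep-the-more-extreme policy is a package decision,
chosen because the retained event then best represents the beat's SBP or
DBP.

Events are aggregated over consecutive half-open 5-s windows (the final
partial window is included; its weight in the recording mean is the same
as any other window, which matters little and is stated here for
completeness). A window's SBP is the *mean* of its systolic event
amplitudes — the within-window reducer is not dictated by the extraction
rules; the mean was chosen for symmetry with the recording-level mean —
and windows without events carry `NA`, never zero. The recording-level
estimate is the unweighted mean over windows with values. Reference
SBP/DBP go through exactly the same code path applied to the reference
waveform, so method-vs-reference agreement never mixes two different
detectors.

Detection runs globally over the waveform and events are then assigned
to windows; running the detector per window would split refractory
enforcement at window edges and differ only for boundary events.

## Agreement analysis

For paired estimates the package reports the bias (mean of estimated
minus reference), the sample standard deviation of the differences
(n − 1), and limits of agreement at bias ± 1.96 SD. Window-level
agreement pools index-aligned window pairs across all test recordings,
using only windows where both members have a value; recording-level
agreement pairs one estimate per recording. Averaging across a
recording's windows cancels much of the window-level scatter, so
recording-level limits are expected to be tighter whenever window errors
are imperfectly correlated — the test suite asserts this on the seeded
end-to-end run.

## The synthetic cohort

The simulator generates, per participant, a beat-by-beat pressure
waveform and four load-cell channels with the statistical structure the
method assumes:

* **Beat onsets**: inter-beat intervals 60/HR with Gaussian per-beat
  jitter; HR ~ N(65, 8) truncated above 40 beats/min across the cohort,
  clamped instantaneously to [30, 105].
* **Pressure template**: each beat rises from the diastolic to the
  systolic level along a 0.15 s raised-cosine upstroke, relaxes back
  exponentially over 0.35 s and rests on a diastolic plateau until the
  next onset. The template has *fixed duration*, which makes the
  waveform a true convolution of the beat impulse train — the
  load-cell-to-BP relation is then one linear-time-invariant system
  shared by all participants rather than a heart-rate-dependent warp.
  Onsets are snapped to the sample grid so the force encoding and the
  pressure target share one clock. Levels: SBP ~ U(108, 142),
  DBP ~ U(68, 92) mmHg, inside the extraction gates by construction.
  Respiration adds a ±2 mmHg sinusoid (10–18 breaths/min), and both
  levels drift together along a slow vasomotor-like 90-s sinusoid
  (±4 mmHg by default) — nocturnal pressure is not constant over
  minutes, and the within-recording level variation is also what lets a
  model learn the level readout from few participants.
* **Load cells**: the beat impulse train is convolved with three
  superposed biphasic wavelets shared by all participants — the
  normalized derivative of the pressure template with a 4.5 Hz damped
  ring (amplitude proportional to the beat's pulse pressure: an ejection
  force), an 8 Hz damped ring whose amplitude encodes the diastolic
  level (a stiffness-like association), and a 12 Hz damped ring of
  fixed amplitude (a mass-driven recoil component that does not depend
  on pressure). Each channel is scaled by its own gain (U(0.9, 1.1)),
  delayed 10 ms per channel index, and receives a breath-locked
  respiratory component, white noise (SD 0.05 signal units by default)
  and a small baseline drift. The level wavelet's amplitude tracks the
  *instantaneous* (drifting) diastolic level beat by beat. The ~0.7 s
  wavelet support keeps every 0.5-s window informative about the most
  recent beat; the spectral separation of the wavelets makes pulse
  pressure and diastolic level separately decodable, and ratios against
  the fixed-amplitude component cancel the unknown channel gain, so
  absolute pressure levels are identifiable across participants.

Everything is a pure function of the configuration and a seed:
per-participant seeds derive from the master seed by two rounds of
integer mixing (exact in doubles, platform-stable).

**What the simulator does and does not emulate.** It reproduces the
ingredients the regression relies on: beat-locked force wavelets with
participant-varying gains, amplitude coding of pulse pressure,
respiration, drift, sensor noise, and BP levels spanning the detection
gates. It deliberately omits body movement artifacts, bed exits,
arrhythmias, circadian BP variation and any claim about the true
physical transduction from pressure to leg force — the encoding is an
artifact convention chosen to be learnable, not a biomechanical model.
Passing tests on this cohort therefore demonstrate that the
implementation learns and evaluates correctly, not that the method
achieves any particular accuracy on real beds.

**A note on the learnability floor.** The package asserts, as a sanity
floor far below the LSTM, that a ridge regressor on flattened windows
reaches R² > 0.5 pooled over held-out participants. Pooled evaluation is
the honest choice here: a *linear* reader provably cannot recover the
constant diastolic term of a single recording from zero-mean pulse-locked
wavelets (averaged over beat phases their windowed projections cancel),
so per-participant linear R² degrades for extreme diastolic levels, while
the nonlinear network reads the 8 Hz wavelet's energy envelope —
phase-invariantly — and does not share this limit.

## Problem sizes used in the checks

The desk-scale identities (parameter count, split sizes, closed-form
agreement arithmetic, detector-vs-brute-force equivalence) run in
seconds. The end-to-end check trains on a seeded cohort of 12
participants (8 train / 2 validation / 2 test), 120 s each at 100 Hz —
95,600 training windows — for 30 epochs, and asserts held-out
reconstruction R² ≥ 0.5, recording-level |bias| ≤ 5 mmHg for SBP and
DBP, the recording-vs-window limits-of-agreement ordering, the 50-sample
refractory invariant on its outputs, and checkpoint dominance. These
sizes are the package's chosen compromise between statistical
resolution and a test suite that runs on one ordinary CPU core; the
full-scale configuration (38 participants, 8-minute recordings, 300
epochs) is exposed by `experimentConfig()` defaults.

## Known limitations

* The architecture is pinned to the published design; no hyperparameter
  search, extrema-weighted losses, or per-person transfer-learning
  personalization is included.
* Reconstruction error concentrates at extrema (the conditional mean
  under residual uncertainty shrinks peaks), so window-level SBP/DBP
  limits of agreement are wide relative to the waveform error — the same
  asymmetry the method exhibits on real data.
* Two mechanisms make the extracted pressures sit systematically below
  the reference when training cohorts are small. First, detecting
  minima on a reconstruction that carries ripple selects the ripple's
  local extremes, so detected DBP runs low by roughly the ripple's
  standard deviation; the reference waveform, being smooth, is immune.
  Second, a network trained on few participants compresses absolute
  pressure levels toward the training range, so test participants whose
  systolic or diastolic level falls at or beyond the range edge are
  pulled inward — the proportional-bias pattern visible in Bland–Altman
  plots of this method family. Both effects shrink with more training
  participants and longer training; at the small cohort sizes used in
  the test suite they leave a recording-level negative bias of several
  mmHg that should be read as a property of the scaled-down setting,
  not of the extraction arithmetic.
* Recordings with movement artifacts or detached reference waveforms are
  out of scope; the detector reports, but does not repair, recordings
  with no in-gate events.
* HDF5 interchange is not provided; recordings travel as CSV
  (`t,lc0,lc1,lc2,lc3,bp`).
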