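# bedpress

Blood-pressure waveform reconstruction from the load cells under the legs
of a bed.

## What it does, and for whom

Four force sensors (load cells) under a bed's legs pick up the recoil of
the body from each cardiac ejection — the ballistocardiogram (BCG).
`bedpress` is for researchers in unobtrusive cardiovascular monitoring
who want to estimate **continuous arterial blood pressure during sleep
without a cuff**: it reconstructs the BP waveform from the four load-cell
channels with a recurrent neural regressor, extracts systolic (SBP) and
diastolic (DBP) pressure from the reconstruction, and quantifies
agreement with a reference waveform by Bland–Altman analysis.

The core regression: for every time step $t$ (at 100 Hz), a strictly
causal window of the previous $N = 50$ samples of all four conditioned
load-cell channels — a $4 \times 50$ matrix, 0.5 s of force data — is
mapped to the scalar $BP(t)$ by a stack of three 30-unit LSTM layers and
a single linear output (18,871 trainable parameters). Sliding the window
one sample at a time reconstructs the whole waveform except its first
half second. SBP/DBP are then read off the waveform as the
negative-going (positive-going) zero crossings of its first difference,
gated to [100, 150] mmHg ([60, 100] mmHg) and separated by at least 50
samples, averaged over 5-second windows and over the recording. Agreement
is reported as bias ± 1.96 SD limits of agreement.

A synthetic cohort simulator generates paired load-cell + BP recordings
with the statistical structure the method assumes (beat-locked biphasic
force wavelets, amplitude coding of pulse pressure, respiration, drift,
sensor noise, participant-varying gains), so the whole pipeline can be
trained and evaluated offline. See the methods vignette
(`vignettes/bedpress-methods.Rmd`) for the model, the simulator and every
numerical convention.

## Worked example

```r
library(bedpress)

# simulate a small cohort and condition it
cohort <- simulateCohort(6, duration = 60, masterSeed = 20)
cohort <- lapply(cohort, preprocessRecording)

# participant-disjoint split: 4 train / 1 validation / 1 test
trainDs <- buildWindowsCohort(cohort[1:4])
valDs   <- buildWindowsCohort(cohort[5])

fit <- trainModel(buildModel(seed = 1), trainDs, valDs,
                  trainConfig(epochs = 15, seed = 1))
fit$history
#> TrainHistory: 15 epochs, best epoch 8 (val MSE 0.01896)

# reconstruct and evaluate the held-out participant
ev <- evaluateCohort(fit$model, cohort[6])
round(ev$waveform[, c("mse", "mae", "r2")], 3)
#>      mse   mae    r2
#> 1 26.081 4.106 0.917
ev$recording_table
#>   participant_id  sbp_est  sbp_ref  dbp_est  dbp_ref
#> 1            P06 125.0311 137.3737 71.57714 75.22219
```

The waveform table gives the reconstruction error against the reference
BP (mean squared error in mmHg², mean absolute error in mmHg, and R² —
the fraction of reference-waveform variance captured). The recording
table pairs the SBP/DBP estimates read from the *reconstructed* waveform
with the same quantities read from the *reference* waveform by the same
detector; their differences across test recordings feed the Bland–Altman
summaries in `ev$recording_sbp`, `ev$window_sbp`, etc.

`runExperiment(experimentConfig(...))` chains all stages (simulate →
preprocess → split → train → evaluate) and writes a JSON report; a thin
command-line wrapper with `simulate` / `preprocess` / `train` /
`reconstruct` / `extract` / `evaluate` / `run`
subcommands is installed at `inst/cli/bedpress.R`.

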