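# saipai

Instantaneous sympathetic (SAI) and parasympathetic (PAI) activity
indices from heartbeat dynamics, and their voxelwise mapping onto
resting-state fMRI — the analysis chain for charting central autonomic
networks from pulse recordings acquired during scanning.

## What it computes

Heartbeats are modelled as an inhomogeneous point process: the waiting
time to the next beat is inverse-Gaussian with shape ξ₀ and a
history-dependent mean

  μ_HP(t) = g₀(t) + Σⱼ g₁(j,t) lⱼ(t),

where lⱼ(t) are outputs of orthonormal discrete Laguerre filters
(α = 0.2, orders 0–9) applied to the past heart periods.  The
parameter vector ξ(t) = {g₀, g₁, ξ₀} maximizes a local likelihood over
a sliding 70-s window and is revised every 5 ms (damped Newton–Raphson,
warm-started, right-censoring for the open interval).  SAI and PAI are
linear disentangling combinations ψ of the sympathetic (orders 0–2)
and parasympathetic (orders 3–9) coefficient blocks, divided by μ_HP²
and floored at zero.  For the imaging arm, the index series is
resampled at each fMRI volume (TR 0.72 s, 1200 volumes), convolved
with a double-gamma hemodynamic response, and taken through a
three-level GLM — run-level OLS with signed contrasts, within-subject
inverse-variance combination across two runs, and a group mixed-effects
analysis — followed by cluster correction (Z > 2.3, α = 0.05) against a
sign-flip permutation null of maximal cluster extent.

The package also ships first-class synthetic generators (an
integral-pulse-frequency-modulation heartbeat simulator with separable
LF/HF modulation, a pulse-waveform synthesizer, and BOLD volumes with
planted autonomic coupling), so the whole chain is verifiable without
any real recordings.

## Worked example

```r
library(saipai)
set.seed(42)

# a 900-s synthetic subject with doubled LF drive during 300-600 s
sc  <- scenario("sympathetic_activation", seed = 42, duration = 900)
ev  <- correct_artifacts(detect_beats(sc$ppg, fs = 400))
ev
#> Heartbeat event series: 1000 events over 899.0 s
#>   mean HP 0.900 s (66.7 bpm), range [0.691, 1.253] s

fit <- pphrv(ev, step = 0.25)   # 5-ms default grid; coarser here for speed
fit
#> Inverse-Gaussian point-process heart-rate model
#>   1000 events, grid of 3317 states (step 0.25 s, window 70 s)
#>   Laguerre orders 0..9 (alpha = 0.2), sympathetic block 0..2
#>   converged states: 3228 / 3317
#>   mean mu_HP 0.913 s, mean xi0 1337.7

idx <- index_series(fit)        # SAI / PAI / mu_HP on the fit grid
median(idx$sai[idx$time >= 370 & idx$time < 600], na.rm = TRUE)   # 1.75
median(idx$sai[idx$time <  300 | idx$time >= 670], na.rm = TRUE)  # 1.35

ks <- ks_time_rescaling(ev, fit)
#> KS statistic 0.063 (95% band 0.049, 760 intervals)
```

The epoch-median SAI (1.75 a.u.) sits clearly above its baseline
(1.35 a.u.), tracking the simulated sympathetic activation.  The
time-rescaling KS statistic lands above the 95% band — expected
here, since the integrate-and-fire generator lies outside the fitted
model class; on data simulated from the model class itself the
statistic falls inside the band (see the test suite).

Downstream, `resample_at_volumes()` + `convolve_regressor()` turn an
index series into a GLM regressor, and `first_level()`,
`second_level_fixed()`, `group_mixed_effects()` and `cluster_correct()`
map it onto BOLD data; `run_pipeline()` wires the whole chain on a
synthetic cohort.  A thin command-line wrapper lives in `exec/saipai`
(`saipai beats`, `fit`, `indices`, `regressor`, `simulate`,
`pipeline`).

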