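# ipnblink

Analysis of cerebellar interpositus nucleus (IpN) spiking during delay
eyeblink conditioning, for electrophysiologists working with trial-aligned
extracellular recordings paired with high-speed eyelid tracking.

During conditioning, a neutral conditional stimulus (CS, an LED light)
precedes a corneal air puff (US) by a fixed interval (250 or 200 ms in the
two supported protocols; the stimuli co-terminate). Trained animals close
the eyelid in anticipation — the conditioned response (CR) — and IpN
neurons upstream of the eyelid motor pathway facilitate (or, less often,
suppress) their firing during the CS-US interval. This package implements
the full analysis chain for such data, plus a synthetic-data generator
with known ground truth so every stage can be validated end to end:

* **Eyelid processing** — normalization to the full blink range (0% =
  resting open eye, 100% = mean unconditioned-response peak), order-2
  Savitzky-Golay smoothing, trial quality control (iterative Grubbs test
  on baseline SDs; removal of trials with a half-closed eye), CR detection
  (amplitude > 5% of the blink range within the CS-US interval), CR onset
  from the last unbroken positive-velocity run, and session-level behavior
  summaries (a recording "has behavior" when ≥ 20% of trials carry a CR).
* **Spike processing** — spike density functions (1 ms bins convolved with
  a 5 ms-SD Gaussian kernel), baseline statistics over the 500 ms pre-CS
  window (mean rate, SD of the trial-averaged SDF, ISI CV), and
  baseline-standardized (z-scored) traces.
* **Modulation classification** — CS-US facilitation/suppression
  (criterion: mean change of at least 5 Hz over the last 200 ms of the
  interval after correcting for same-signed baseline excursions; duration
  as ms-bins beyond 3 baseline SDs; onset from the first ≥ 10 ms
  supra-threshold run), transient CS responses (4.5 SD pause/peak between
  50 and 125 ms post-CS with a 2 SD rebound), US responses in the
  1–30 / 16–45 / 31–60 ms post-US windows with their dual
  baseline/interval-end criteria and turnaround rules, and per-trial
  response amplitudes in 30 ms windows.
* **Correlation analysis** — trial-by-trial spike-behavior correlations
  (Pearson for ≥ 30 normally distributed points after Grubbs outlier
  removal, Spearman otherwise), 100 × 100 correlation matrices (20 ms bins
  over the 2 s trial), sign-nullified matrix averaging, temporal
  cross-correlation lag estimation (positive lag = spikes lead), bootstrap
  tests for the population count of significant cells (500 permutation
  datasets), two-stage pooled slopes (per-cell least squares +
  random-effects pooling), and exact power analysis for correlation tests.
* **IpN model** — per-millisecond-bin ISI statistics of Purkinje-cell
  simple spikes across trials, surrogate trial expansion by iterative
  sampling from the local ISI distribution (30 inputs × 30 trials = 900
  surrogate trains at the defaults), and a conductance-based inhibitory
  integrate-and-fire nuclear neuron driven by 30 convergent inputs.
* **Pipeline** — `pipeline_config()` / `run_pipeline()` tie the stages
  together with CSV/JSON interchange formats, a run manifest, and every
  numerical criterion as a named, logged configuration key.

## Worked example

```r
library(ipnblink)

timing <- timing_dataset1()          # 260 ms CS, 10 ms US, 250 ms interval
sess   <- generate_session(sim_config(n_trials = 100), timing, seed = 42)
rec    <- sess$recording

stats   <- baseline_stats(rec$spikes, timing)
avg     <- average_sdf(rec$spikes, timing$trial_window)
profile <- classify_csus(avg, stats, timing)

flt  <- filter_trials(rec$eyelid$pos, rec$eyelid$time, timing)
crs  <- lapply(flt$kept, function(i)
  detect_cr(rec$eyelid$pos[, i], rec$eyelid$time, timing))
summ <- behavior_summary(crs)

x  <- sapply(rec$spikes[flt$kept], function(sp)
  sum(sp > timing$us_onset - 200 & sp <= timing$us_onset) / 0.2)
y  <- sapply(crs, `[[`, "amplitude_at_us")
tc <- trial_correlation(x, y)
xc <- temporal_cross_correlation(avg, rec$eyelid$time,
                                 rowMeans(rec$eyelid$pos[, flt$kept]),
                                 timing)
```

Output (printed by the objects above):

```
baseline: 66.3 Hz (SDF SD 2.83 Hz), ISI CV 0.41, 100 trials / 3315 spikes
CS-US modulation: facilitation (16.7 Hz, duration 115 ms, onset 135.5 ms, peak 249.5 ms)
CRs in 79% of trials, mean amplitude 30.6%, with_behavior: TRUE
trial-by-trial r = 0.75 (p = 1.4e-19, spearman, n = 100)
spikes lead the eyelid by 26 ms (peak r = 0.97)
```

Reading this: the synthetic cell fires at 66 Hz at rest with moderately
regular ISIs, carries 16.7 Hz of CS-US facilitation starting ~135 ms after
the CS and peaking just before the US, and the animal produces CRs in 79%
of trials averaging ~31% closure. Spike rate in the last 200 ms of the
interval correlates with CR amplitude across trials (the pooled r exceeds
the injected within-CR-trial coupling of 0.5 because CR-absent trials,
which carry neither modulation nor closure, widen the joint spread), and
the facilitation leads the eyelid by ~26 ms — close to the 30 ms lead the
generator injected.

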