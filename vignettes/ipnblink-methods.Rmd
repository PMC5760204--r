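---
title: "Methods: models, criteria and numerical choices in ipnblink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, criteria and numerical choices in ipnblink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipnblink)
```

# Scope

`ipnblink` analyzes trial-aligned extracellular recordings of cerebellar
interpositus nucleus (IpN) neurons during delay eyeblink conditioning:
eyelid preprocessing and conditioned-response (CR) detection, spike
density estimation, classification of CS-US modulation and of transient
CS/US responses, trial-by-trial spike-behavior correlation machinery, and
a convergent-inhibition integrate-and-fire model of nuclear neurons driven
by Purkinje-cell simple spikes. Because no public recording set
accompanies this analysis style, the package ships a first-class synthetic
generator with known ground truth; the test suite validates every stage by
parameter recovery against that ground truth.

# Trial structure and behavioral processing

A trial is a 2 s window with the CS at +500 ms, leaving a 500 ms pre-CS
baseline. Two co-terminating protocols are built in: a 260 ms CS with a
10 ms US (250 ms CS-US interval, `timing_dataset1()`) and a 220 ms CS with
a 20 ms US (200 ms interval, `timing_dataset2()`).

Eyelid traces (250 samples/s) are normalized to the full blink range —
0% at the resting open-eye level, 100% at the mean unconditioned-response
peak — and smoothed with an order-2 Savitzky-Golay filter. The nominal
10 ms span is 2.5 samples at this rate; the implementation uses the
nearest odd window of 3 samples. An order-2 polynomial through 3 points
interpolates them exactly, so at the default the smoother is the identity;
the window length is exposed for data acquired at higher rates, where the
filter is genuinely active. Quality control removes trials whose baseline
SD is an outlier under an iterative two-sided Grubbs test (alpha = 0.05,
one removal per iteration, critical value from the t quantile at
alpha/(2n)) and trials whose baseline mean is at or beyond 50% closure
("eye not at least halfway open"; the boundary keeps strictly-below-50%
trials).

A CR is an eyelid rise exceeding 5% of the blink range (strict `>`) within
the open CS-US interval, measured against the trial-baseline mean on the
smoothed trace (whether to use the raw trace is not settled in this
analysis style; smoothed is the default and the choice is configurable by
smoothing with a wider window or not at all). CR onset is the start of the
last unbroken run of positive velocity (central differences) that carries
the trace to 5% of the baseline-to-peak amplitude. A session "has
behavior" when at least 20% of retained trials carry a CR (inclusive
boundary). Degenerate inputs — an all-excluded session, a blink range with
`closed_level <= open_level` — raise explicit errors rather than returning
silently empty results.

# Spike density functions and baselines

Spike times are binned at 1 ms and convolved with a Gaussian kernel
(SD 5 ms by default, truncated at ±4 SD and renormalized to unit mass, so
one spike integrates to one). Outside the trial the train is treated as
empty; rate estimates within ~4 kernel SDs of the window edges are biased
low, and the baseline SD therefore skips bins within 20 ms of the window
edges. Baseline statistics over the 500 ms pre-CS window are: mean rate
(count over time), SD across 1 ms bins of the *trial-averaged* SDF (the
natural scale for criteria applied to average traces; a pooled
single-trial variant would mix in within-trial variance), and the ISI
coefficient of variation pooled over trials. A zero baseline SD makes
z-scoring impossible and is signalled as an error.

# Modulation classification

Facilitation is scored as the mean rate change over the last 200 ms of the
CS-US interval relative to the baseline mean, minus the mean
*above*-baseline activity within the baseline itself (so a cell whose
baseline wanders upward does not get credit for that wander in the
window); suppression mirrors this with below-baseline excursions. The
label requires a score of at least 5 Hz (inclusive — "at least" — and the
test suite pins 5.00 vs 4.99 Hz). If both scores pass, the larger
magnitude wins and exact ties go to facilitation, the dominant class in
this preparation. Modulation duration counts window bins beyond 3 baseline
SDs; onset is the first bin of the first supra-threshold run of at least
10 ms anywhere in the interval, and is reported as undefined when the mean
criterion passes without such a run. The peak-rate velocity is the maximum
central-difference derivative of the 5 ms-kernel average SDF within the
interval, in the direction of the labeled modulation.

Transient CS responses are evaluated on the baseline-standardized average
SDF between 50 and 125 ms post-CS (a 50–130 ms variant circulates in this
literature; the bound is an argument). A pause requires a drop beyond
−4.5 SD followed by a rebound above +2 SD *relative to baseline* (the
alternative reading — relative to the pause minimum — is obtainable via
the `rebound_sd` argument); the rebound is searched for 100 ms after the
extremum, a window the criteria themselves do not specify. CS peaks
mirror the pause. US responses use windows of 1–30, 16–45 and 31–60 ms
post-US, each against dual criteria referencing both the baseline (z = 0)
and the mean over the last 50 ms of the CS-US interval; pauses and second
peaks additionally require a turnaround regressing at least 2 SD back
toward baseline. Per-trial response amplitudes take the extremum of the
absolute rate in a 30 ms window centered on the cell-average response
time, flagging windows clipped at trace edges.

# Correlation machinery

Trial-by-trial correlations follow one rule everywhere: iterative Grubbs
outlier removal on each variable (a pair is dropped if either member is
flagged), then Pearson's r when at least 30 pairs remain and both
variables pass Shapiro-Wilk at alpha = 0.05 (the normality test is not
prescribed by the criteria; Shapiro-Wilk is the conventional choice),
otherwise Spearman's rho.

Correlation matrices divide the 2 s trial into 20 ms bins (100 × 100;
non-overlapping bins are the canonical form, and entry `[i, j]` is the
across-trial correlation of spike bin `i` with eyelid bin `j`).
Zero-variance bins give `NA` entries, which sign-nullified averaging
excludes from the mean after zeroing entries of the unwanted sign.
Temporal cross-correlation resamples the 4 ms eyelid grid to 1 ms by
linear interpolation and correlates eyelid(t) with spikes(t − lag) over
the CS-onset-to-US-onset window (the analysis window is not prescribed;
the CS-US interval is where the behavior lives, and the window is
configurable), so positive lags mean spikes lead.

The bootstrap population test breaks the spike-behavior pairing by
permuting the behavior vector within each cell — preserving both
marginals and per-cell trial counts, which is the concrete reading of
"random datasets with similar amounts of cells and trials" — and counts
direction-consistent significant cells per repetition (500 by default,
giving p a resolution of 1/500, reported as "< 0.002" when no repetition
reaches the observed count). For speed, repetitions reuse each cell's
outlier-cleaned data and chosen method with t-approximate p-values; the
observed count uses the full rule. The pooled slope is a two-stage
approximation to a mixed model with random intercepts and slopes: per-cell
least-squares slopes combined by a DerSimonian-Laird random-effects
meta-analysis (inverse-variance weights plus between-cell variance).
Likelihood-based mixed-effects fitting with likelihood-ratio model
selection is deliberately out of scope; with balanced per-cell information
the two-stage estimate is close, and it degrades gracefully to a flagged
single-cell slope.

Power analysis for the correlation test uses the exact sampling
distribution of the sample correlation coefficient under a bivariate
normal (Hotelling's density with a Gauss hypergeometric factor, evaluated
by direct series and integrated numerically at `rel.tol = 1e-10`), with
the Fisher-z normal approximation reported alongside; the minimal n
search runs upward from n = 4. At 80% power and two-sided alpha = 0.05
the exact method and the approximation differ by at most one trial across
the r range of interest.

# The synthetic generator

The generator emulates a conditioned animal: tonic baseline firing of
67 Hz with gamma-renewal ISIs (shape `1/CV^2`, default CV 0.4), a logistic
facilitation ramp (default plateau 50 Hz, onset 100 ms post-CS, 60 ms
20–80% rise) sustained to the US and decaying after it — yielding a
measured window amplitude around 20 Hz and a 3 SD-crossing onset near
120–135 ms, the regime reported for facilitation cells — optional CS
pauses (default latency 88 ms) and US transients, CR incidence 0.8 (a
well-trained animal), CR amplitudes of 30 ± 10% closure, and spikes
leading the eyelid by 30 ms (the eyelid waveform is the spike ramp delayed
by the lead and scaled to reach the latent amplitude at US onset).

Spiking uses time rescaling: unit-mean gamma intervals mapped through the
inverse integrated rate. The first interval is drawn from the equilibrium
forward-recurrence distribution (a length-biased interval times a
uniform), so rates are unbiased from the window edge onward. A 1 ms
refractory floor is enforced by deleting violating spikes; at the default
CV this is negligible, but for Poisson-like trains (CV = 1) at 67 Hz it
removes ~6% of spikes and biases rates low — rate-conservation guarantees
hold for CV ≤ 0.5. Negative rate profiles are clipped at zero with a
warning. The CS-pause depth is specified in SD units of the trial-averaged
baseline SDF and converted to Hz with the exact stationary variance of the
kernel-smoothed gamma-renewal process (spectral density integrated against
the squared kernel transform) — not the Poisson-limit shortcut, which
underestimates the SD at sub-Poisson regularity.

Trial-by-trial coupling draws the latent CR amplitude and the latent
modulation gain from a shared standard normal. Spike-count noise over the
200 ms metric window attenuates any latent correlation by
`sd_signal / sqrt(sd_signal^2 + rate * CV^2 / 0.2)`; the generator divides
the target `coupling_r` by this (and the analogous, near-unity eyelid
factor) so that the *measured* correlation targets `coupling_r` on CR
trials. Unreachable targets (attenuation too strong for the requested r)
raise an error rather than silently under-delivering. Non-CR trials carry
neither closure nor modulation, so pooled correlations across all trials
exceed the within-CR-trial coupling — visible in the README example.

What the generator does not emulate: slow drifts in excitability or
behavior across a session, complex-spike-driven cross-trial dependencies,
eyelid measurement artifacts other than white noise, and learning curves
within a session. Passing recovery tests therefore demonstrates that the
estimators are calibrated for stationary sessions with known structure,
not that they are robust to every nonstationarity of real recordings.

# The IpN model

Per-bin ISI statistics take, for each 1 ms bin and trial, the interval
containing the bin center. Such intervals are length-biased (an interval
covers a fixed time point with probability proportional to its length), so
the recorded moments are weighted by 1/length, recovering the ordinary
local ISI distribution — for a 67 Hz Poisson train the per-bin mean is
~14.9 ms with skewness ~2, not the doubled length-biased mean. An
unweighted "interval starting in this bin" variant is available. Bins with
fewer than 2 samples are undefined (the expander falls back to the nearest
defined bin); bins with fewer than 8 are flagged, as third and fourth
moments are unreliable there.

Surrogate expansion advances through the window by repeatedly sampling an
ISI from the local distribution. The default sampler resamples the pooled
per-bin empirical ISIs with the same 1/length weights — the most direct
reading of sampling "from the local ISI distribution" — and a gamma
distribution matched to the de-biased mean and SD is available as a
parametric alternative (`sampler = "moment"`); a four-moment Pearson-system
family was considered and set aside, since Type IV sampling is
disproportionate to what the expansion needs and the empirical sampler
preserves the distribution by construction. Surrogate trains converge to
the *source cell's empirical* rate profile, so profile noise is bounded by
the source trial count, not the surrogate count — relevant when sizing
simulations. Thirty inputs per modeled trial (the reported 20–50:1
Purkinje-to-nuclear convergence) and 30 modeled trials give the canonical
900 surrogate trains, all drawn from one reference cell (a heterogeneous
mix is possible by expanding several cells and interleaving).

The nuclear neuron is a conductance-based leaky integrate-and-fire unit:
each input spike increments an inhibitory conductance (decay 5 ms,
reversal −85 mV, increment 0.04 leak units), a constant drive (40 mV)
sets the baseline, and the membrane (tau 10 ms, threshold −50 mV, reset
−70 mV, refractory 1.5 ms) integrates by forward Euler at 0.1 ms — the
constructor rejects steps larger than a fifth of the fastest time
constant. The original parameter table for this model class is not
available in text form; the defaults are standard conductance-LIF values
tuned so that 30 tonic 70 Hz inputs produce baseline output within the
recorded 40–94 Hz nuclear range, and every one is exposed in
`ipn_params()`. With zero inhibition and zero noise the simulator matches
the closed-form LIF rate (the test suite requires 2% agreement), and
synchronized input silence produces disinhibition bursts.

# Calibration methodology and problem sizes

The acceptance-style tests size their simulations as follows, chosen once
as realistic desk-scale conditions: amplitude recovery and detector
sensitivity at 100-trial sessions; false-positive rates on 1000 null cells
of 20 trials (the small-session case is the noisier, conservative one);
coupling and lead recovery at 200 trials; oracle-equivalence on 100 random
small sessions; bootstrap calibration over 200 experiments of 20 cells ×
30 trials; the model sweep at three suppression depths (20/45/70 Hz
rapid-onset sustained troughs) with 200 source and 200 modeled trials per
depth, enough for the max-velocity extremum statistic to resolve the
between-depth differences.

Two methodological points deserve note. First, "2× threshold" injections
for the CS pause double both of its criteria (9 SD drop *and* 4 SD
rebound): doubling only the drop would leave the rebound check sitting at
its own noise floor by construction. Second, the bootstrap p-value is
heavily discrete — under the null the significant-cell count is usually
0–3 — so the naive ECDF-against-diagonal Kolmogorov-Smirnov comparison is
dominated by the atoms and their Monte-Carlo jitter even for a perfectly
calibrated test. Uniformity is therefore checked on the randomized PIT:
the rank of the observed count among the permutation counts with uniform
tie-breaking, which is exactly U(0, 1) when observed and permutation
counts are exchangeable. That is the calibration property the test
actually guarantees.

# Known limitations

* The two-stage pooled slope approximates, and does not reproduce, a
  likelihood-ratio-selected mixed model; with few cells or very unbalanced
  trial counts the estimates can differ.
* Rate conservation of the spike generator degrades at CV near 1 because
  of the refractory deletion rule.
* The Savitzky-Golay default is an identity at 250 samples/s; smoothing
  only becomes active at higher sampling rates or wider windows.
* The IpN model is a single-compartment caricature without rebound
  (T-type/H-current) biophysics; it captures disinhibition timing and
  gain, not post-inhibitory rebound bursting.
* Population-level percentages from the original recordings (proportions
  of facilitation/suppression cells, and similar) require data that are
  not publicly deposited and are out of scope; the synthetic defaults only
  emulate the printed single-cell regimes.
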