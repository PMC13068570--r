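---
title: "Detecting beta bursts and their coupling to self-paced behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting beta bursts and their coupling to self-paced behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betabursts)
```

## The model

Beta-band (13–30 Hz) activity in sensorimotor cortex is not a sustained
oscillation but a train of brief, high-power *bursts* lasting on the
order of 100–300 ms. This package treats the beta band of a continuous
EEG channel as a binary point-process-like signal — at every sample the
channel is either inside a burst or not — and asks how that binary
process relates to a concurrent stream of self-paced behavioral events
(touchscreen touches in the motivating application).

A burst is defined operationally, per channel and per frequency:

1. decompose the channel into instantaneous power with complex Morlet
   wavelets on a 1-Hz grid spanning 13–30 Hz;
2. threshold each frequency's power trace at **6× its median** over the
   whole valid recording (strict inequality);
3. delete suprathreshold runs shorter than **2 cycles** at that
   frequency (a run at *f* Hz must last at least 2/*f* seconds);
4. collapse the surviving binary time–frequency mask across frequencies
   (logical OR) into the binary burst time series.

The median-multiple threshold makes detection invariant to channel
gain: multiplying a channel by any positive constant leaves its burst
mask unchanged, because the threshold is a quantile of the same power
trace. The 2-cycle rule discards fluctuations too brief to constitute
an oscillatory event at their own frequency. Both rules are applied per
frequency *before* the collapse; no duration rule is re-applied to the
collapsed series, so a collapsed burst can be longer than any
single-frequency run that contributes to it.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `f_lo`, `f_hi` | 13, 30 | Hz | analysis band (beta) |
| `f_step` | 1 | Hz | frequency grid (18 bins) |
| `threshold_factor` | 6 | — | power threshold as a multiple of the per-frequency median |
| `min_cycles` | 2 | cycles | minimum burst duration at each frequency |
| `wavelet_cycles` | 7 | cycles | Morlet width; envelope SD is `cycles/(2*pi*f)` s |

Seven wavelet cycles is the conventional width in the burst-detection
literature; it trades temporal smoothing (≈56 ms envelope SD at 20 Hz)
against frequency resolution (≈2.9 Hz SD at 20 Hz). The width matters
more than usual here because both detection rules act on the *smoothed*
power trace; see "Detectability" below.

## From bursts to behavior

Given the binary series and an event train on the same clock, the
package computes:

- **Burst occupancy (BO)** — the fraction of valid recording time each
  channel spends inside bursts (equivalently the mean of the binary
  series). "Valid" means after edge-trimming and after the optional
  inactivity mask; occupancy must be a proportion of time that was
  actually searched for bursts.
- **Burst probability index (BPI)** — epoch the series from −3 to +3 s
  around each event (inclusive endpoints: 6001 samples at 1 kHz),
  average across trials, and subtract the per-channel *median of the
  trial average across the full epoch time course*. The median-across-
  time baseline follows the definition of the index; it is not a
  pre-stimulus baseline.
- **BPI extrema** — minimum and maximum of the BPI in a −1 to +1 s
  search window, with the time of *first* occurrence as the latency
  (tie-break fixed so results are deterministic). A negative-latency
  minimum and positive-latency maximum are the burst-level analogue of
  movement-related beta desynchronization and rebound.
- **Touch–burst latencies** — per event, the time to the next burst
  onset and since the previous burst offset. Events inside an ongoing
  burst skip that burst in both directions: the within-burst
  co-occurrence is counted once, by the BTR, rather than zero-inflating
  both latency distributions.
- **Intra-burst touch rate (BTR)** — events landing on an ON sample of
  the series (floor to the containing sample; half-open burst
  intervals, so an event on the offset sample is outside) divided by
  total burst time, in events/second.
- **Burst–behavior timing index (BBTI)** — split consecutive
  inter-event intervals by whether any series sample in the *open*
  interval between the two events is ON, and report
  `log10(median WITH) − log10(median WITHOUT)`. The open interval
  prevents the same within-burst touch from driving BTR and BBTI
  simultaneously. Note the intrinsic sampling bias: even for bursts
  generated independently of behavior, longer intervals are more likely
  to contain a burst, so the expected BBTI is positive; the package's
  validation asserts this property rather than pretending the index is
  unbiased. Interpretation of an observed BBTI should therefore be
  against an independence baseline at matched occupancy, not against
  zero.

### Preprocessing: the inactivity mask

Stretches of recording farther than 30 s from every event on *both*
sides are behaviorally inactive and are removed before detection
(`inactive_segment_mask()`). Edges are treated as eventless (infinite
distance), so leading and trailing dead time is removable. The kept
segments are concatenated and an index map translates event and burst
times between clocks. Concatenation seams are recorded; epochs,
inter-event intervals, and latency spans that would cross a seam are
dropped rather than measured across fabricated adjacency, and segments
clipped by a seam or by the wavelet edge are excluded from duration
medians (but still counted).

Conventions used throughout: times in seconds at API boundaries,
0-based sample indices in the masks' bookkeeping, half-open `[onset,
offset)` intervals, inclusive epoch windows.

## Group-level inference

Scalar channel maps (BO, extrema values/latencies, BTR, BBTI — raw and
z-normalized across electrodes with the sample SD) are pooled across
participants and tested against zero with one-sample t-tests and
Bonferroni correction. Channel × time BPI maps use a spatio-temporal
cluster-based bootstrap: candidate cells at raw p < 0.05 are grouped by
adjacency (neighboring channels at the same time point, adjacent time
points at the same channel), each cluster scored by its mass (sum of
|t|; sensitive to both extent and strength), and compared to the
1 − α quantile of the maximal cluster mass over bootstrap resamples of
participants after centering each participant's map at the group mean.
Channel adjacency comes from electrode positions with a distance
threshold chosen so the median neighbor count is 4–8, or is supplied
explicitly; the bootstrap seed is a required argument so every
stochastic result is reproducible.

A calibration property worth knowing: with participant-level
resampling, every cell of a bootstrap map shares the same resampling
weights, so the *empirical* cross-cell covariances of the centered data
(random, of order 1/√n even for truly independent cells) are baked into
the null field. At n = 20 participants this inflates the co-exceedance
of adjacent cells in the null relative to genuinely independent
observed maps (we measure ≈0.0034 vs 0.0025) and therefore inflates
the null's maximal cluster masses. The consequence is a conservative
test: on simulated null groups of 20 participants × 16 channels × 200
samples the family-wise error rate is below 1% at nominal α = 0.05,
while the degenerate single-cell case calibrates near 3.5%. The same
mechanism affects sign-flipping schemes; it is a property of
max-statistic resampling at moderate n, strongest when the true maps
have little spatial correlation. Power for realistic effects remains
good — a 1-SD mean shift over a 4-channel × 16-sample block is
recovered essentially always in our tests — but borderline effects
will be missed more often than the nominal α suggests.

## The synthetic generator

`synth_config()` + `simulate_session()` produce ground-truth-annotated
sessions:

- **Background**: independent per-channel 1/f^α Gaussian noise
  (spectral shaping of white noise; α = 1 by default), RMS-normalized.
- **Bursts**: Hann-windowed sinusoidal atoms — bounded support makes
  ground-truth onset/offset/duration exact — with Poisson timing,
  frequencies uniform in 13–30 Hz, lognormal durations (median 0.2 s,
  sdlog 0.3 by default), and a default rate of 0.5 Hz giving occupancy
  near 0.10, matching the 0.10–0.15 range typical of continuous EEG.
- **Touches**: a lognormal renewal process with median 0.871 s and
  sdlog 0.977; the sdlog is solved so the interquartile range is
  1.236 s, reproducing both summary statistics reported for
  naturalistic smartphone interaction.
- **Coupling**, by two separable mechanisms so that detection-side and
  behavior-side recovery can be tested independently: (a) the atom
  *rate* is multiplied by a suppression gain (default 0.3) when an atom
  center falls within [−0.8, 0] s before a touch and by a rebound gain
  (default 1.5) within [0.2, 1] s after one; (b) optionally, candidate
  touches landing inside a burst of a reference channel are kept only
  with probability `g_touch` (in-burst touch suppression).
- **Amplitude calibration**: `snr` is defined as the atom's realized
  peak wavelet power at its frequency divided by the channel's
  background median wavelet power at that frequency. The amplitude is
  set per atom by compensating the Hann × Morlet smearing factor, so
  the target holds in the noiseless limit regardless of atom duration.
  No empirical amplitude distribution is claimed; `snr` is an explicit
  simulation knob.

All randomness flows from one mandatory seed per session;
`gen_dataset()` derives per-participant seeds from a master seed and
adds lognormal participant jitter to rates and coupling gains.

What the generator does *not* emulate: volume conduction and realistic
scalp topography (channels are independent), non-stationary background
spectra, artifacts (blinks, muscle), burst waveform asymmetries, and
serial dependence in behavior beyond the renewal process. Passing
recovery tests on this generator therefore validates the *estimators*,
not the physiological interpretation of real recordings.

## Detectability: what the threshold and duration rules imply

The two detection rules interact with the wavelet width in a way that
sets a hard floor on the contrast a burst needs to be detected. A
Hann-enveloped atom whose measured time-frequency peak is *s*× the
median exceeds the 6×-median threshold only where its smoothed power
profile is above 6/s of its peak. At s = 8 that is the central ~35% of
the atom — about 70–100 ms for a 0.2-s atom — which is *shorter* than
2 cycles at most beta frequencies, so the duration rule removes the
event. Solving for the contrast at which the suprathreshold stretch
reaches 2 cycles gives a floor of roughly 10–12× the median at 7
wavelet cycles (8.3–8.7 at 10 cycles). Conversely, noise-driven
suprathreshold runs survive the 2-cycle rule with a probability
governed by the ratio of the required duration to the smoothing
timescale, `(2/f) / (cycles/(2*pi*f)) = 4*pi/cycles` — independent of
frequency — so wider wavelets also admit more false bursts. At
moderate contrast there is consequently no wavelet width that yields
both high recall and high precision against ground-truth atoms: in our
simulations at snr 8 the detector reaches recall ≈0.65 at precision
≈0.6 (7 cycles), while at snr ≥ 16–24 recall and precision both exceed
0.9. Real cortical bursts detected with this rule family are exactly
the events whose contrast clears the floor; occupancy measured this
way should be read as "time spent in *detectable* bursts", and
detected occupancy on simulated data runs below true atom occupancy at
moderate contrast (e.g. ≈0.065 detected vs 0.10 true at snr 8). This
is a property of the detection rule family, not an implementation
artifact.

## Numerical choices

- Wavelet support is truncated at ±3 envelope SDs; samples within half
  a wavelet length of either recording end are flagged invalid per
  frequency and excluded from the median, from detection, and from the
  valid duration. The collapsed series' valid range uses the widest
  (lowest-frequency) wavelet.
- Convolution is FFT-based with one padded length per recording
  (`nextn`), one signal FFT per channel, and precomputed wavelet
  spectra shared across channels; detection streams one channel at a
  time so memory stays flat in channel count.
- Ties: threshold exceedance is strict (`>`); a run of exactly
  `min_cycles/f` seconds survives (the rule excludes runs *shorter*
  than 2 cycles); extremum latency ties take the earliest time.
- Degenerate inputs: constant power traces produce zero bursts (not an
  error); zero-variance cells in group maps get `t = NA`, `p = 1`;
  constant channel maps z-normalize to all zeros with a warning; a
  channel with zero burst time reports `NA` BTR and is flagged.
- Event-to-sample mapping floors to the containing sample; epoch
  windows are inclusive at both ends.

## Validation scale

The packaged tests validate the pipeline at desk scale: detector
equivalence against a literal per-sample reference on random
time–frequency matrices; recovery, null-calibration, and directionality
properties on simulated sessions of 5–10 minutes at 1 kHz with 8
channels; and family-wise error calibration on 200 simulated null
groups of 20 participants (16 channels × 200 samples, 500 resamples).
These sizes were chosen so the full suite runs on a laptop-class
machine in minutes; all of the statistical properties asserted are
size-stable in the directions that matter (larger simulations only
tighten the Monte-Carlo error).

## Known limitations

- No ICA-based artifact rejection, bad-channel interpolation, or
  re-referencing: the package expects cleaned continuous data.
- BrainVision files are not read; use the native matrix+JSON dialect
  or 16-bit continuous EDF.
- The BPI operates on the collapsed binary series only; no
  per-frequency event-locked analysis.
- The cluster bootstrap is conservative at moderate participant counts
  (see above); Bonferroni on scalar maps is conservative by
  construction.
- BBTI is positively biased under independence by interval-length
  sampling; compare against a matched-occupancy independence baseline.
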