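# betabursts

Beta-band (13–30 Hz) activity in continuous EEG is transient: brief
(~100–300 ms) bursts of elevated oscillatory power rather than a
sustained rhythm. `betabursts` is an R package for researchers who
record continuous EEG during naturalistic, self-paced behavior (the
motivating case is smartphone touchscreen interaction) and want to ask
*when* the brain bursts relative to *what the person does*.

## What it computes

**Burst detection.** Per channel, complex Morlet wavelet power on a
1-Hz grid over 13–30 Hz is thresholded at 6× its per-frequency median
over the whole recording; suprathreshold runs shorter than 2 cycles at
their frequency are discarded; the surviving binary time–frequency mask
is collapsed across frequencies into a binary burst time series
(`β(t) ∈ {0,1}`). Detection is invariant to channel gain because the
threshold is a quantile of each channel's own power.

**Burst–behavior statistics**, for an event train `t₁ < t₂ < …`:

- burst occupancy `BO = Σ burst durations / valid recording time`,
  with across-electrode z-scores for topography;
- burst probability index `BPI(τ) = mean over trials of β(tᵢ + τ) −
  median over τ` for τ ∈ [−3, 3] s, with its minimum/maximum and their
  latencies in [−1, 1] s (burst suppression before and rebound after
  the event);
- intra-burst touch rate `BTR = #events with β(tᵢ)=1 / Σ burst
  durations` (events/s);
- burst–behavior timing index
  `BBTI = log₁₀ median{Δᵢ: burst in (tᵢ, tᵢ₊₁)} − log₁₀ median{Δᵢ: no burst}`
  on inter-event intervals `Δᵢ = tᵢ₊₁ − tᵢ`;
- touch→burst-onset and burst-offset→touch latencies;
- group-level one-sample t-maps with Bonferroni correction (scalar
  maps) or spatio-temporal cluster-based bootstrap correction
  (channel × time BPI maps).

A ground-truth synthetic generator (1/f background + Hann-windowed
burst atoms + lognormal touch trains with controllable burst–behavior
coupling) makes every stage testable end-to-end. Inputs are plain
matrices + JSON headers (native dialect), 16-bit continuous EDF, and
CSV event tables with a `time_s` column. Preprocessing is limited to a
behavior-based inactivity filter (stretches > 30 s from every event are
removed) plus optional zero-phase Butterworth filters; artifact
rejection is expected upstream.

## Worked example

```r
library(betabursts)

cfg <- synth_config(n_channels = 4, duration_s = 180, snr = 16, seed = 42)
ses <- simulate_session(cfg)          # recording + touches + ground truth
fit <- beta_bursts(ses$recording, ses$events)
fit
#> Beta-burst fit: 4 channels, 179.5 s valid, 351 bursts
#>   occupancy 0.070-0.098, median burst duration 164 ms
#>   131 events, 127 trials in BPI raster

round(coef(fit)[, c("bo", "bo_z", "median_duration_s", "btr", "bbti")], 3)
#>        bo   bo_z median_duration_s   btr bbti
#> ch1 0.083 -0.175             0.158 0.799 0.43
#> ch2 0.098  1.087             0.165 0.798 0.46
#> ch3 0.070 -1.284             0.164 0.555 0.39
#> ch4 0.089  0.372             0.167 0.739 0.40

fit$extrema
#>   channel min_value min_latency_s max_value max_latency_s
#> 1     ch1    -0.063         -0.26     0.039          0.30
#> 2     ch2    -0.071         -0.11     0.063          0.40
#> 3     ch3    -0.047         -0.32     0.055          0.95
#> 4     ch4    -0.071         -0.53     0.087          0.87
```

Reading the output: each channel spends 7–10% of the session inside
bursts, with median burst durations near 165 ms. The generator's
default coupling suppresses the burst rate before each touch and
elevates it afterwards, and the fitted BPI extrema recover exactly that
signature — every channel's minimum falls *before* the touch (negative
latency) and its maximum *after* it. A `BBTI` of 0.43 means intervals
containing a burst are about 10^0.43 ≈ 2.7× longer in the median than
burst-free intervals (note this index is positively biased even under
independence — see the vignette).

For group inference over several fitted participants:

```r
fits <- lapply(gen_dataset(cfg, n_participants = 12, jitter_sd = 0.1,
                           signal = TRUE),
               function(s) beta_bursts(s$recording, s$events))
run_group(fits, what = "bo_z")                       # Bonferroni t-map
adj <- adjacency_from_positions(positions)           # or supply explicitly
run_group(fits, what = "bpi", adjacency = adj,
          n_boot = 1000, seed = 1)                   # cluster bootstrap
```

The methods vignette (`vignettes/beta-burst-analysis.Rmd`) documents
the model, every tunable parameter, the synthetic generator's scope,
and the numerical conventions (tie-breaks, edge handling, seam rules),
plus two properties worth reading before interpreting results: the
detectability floor implied by the 6×-median + 2-cycle rules, and the
conservative calibration of max-statistic cluster bootstraps at
moderate participant counts.

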