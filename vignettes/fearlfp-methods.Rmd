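---
title: "Methods: dual-region LFP analysis for auditory fear conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-region LFP analysis for auditory fear conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`fearlfp` analyses paired local field potential (LFP) recordings from the
dorsomedial prefrontal cortex (dmPFC) and basolateral amygdala (BLA) taken
during auditory fear conditioning and extinction. The behavioural paradigm
presents 30-s conditioned-stimulus (CS) tones built from 30 pips of 100 ms at
1 Hz, with inter-trial intervals drawn uniformly from 80–160 s; recordings
are sampled at 1 kHz and band-passed 1–500 Hz. Four measures are extracted
per animal at three timepoints (before conditioning, fear recall, extinction
recall):

1. **Auditory evoked potential (AEP) amplitude** — pip-aligned averages
   scored as the difference between the first peak and the first trough of
   the response, normalized per animal to the before-conditioning value.
2. **Evoked theta power** — a complex Morlet wavelet decomposition of the
   averaged evoked response, z-scored per frequency and baseline-subtracted,
   averaged over 0–250 ms and 2–12 Hz.
3. **Theta coherence** — Welch magnitude-squared coherence between the two
   channels over the CS windows, summarized over 2–12 Hz.
4. **Lead/lag** — the lag of the peak of the normalized cross-correlation
   between the two channels' theta amplitude envelopes, tested against a
   chance distribution built from random circular time shifts.

Because raw in-vivo recordings for this paradigm are not publicly available,
every stage is validated by parameter recovery on a synthetic generator
whose ground truth is known exactly.

# The synthetic generator

`simulate_session()` builds a two-channel session from four components:

* **Ongoing theta.** A shared band-limited (4–10 Hz) Gaussian source `s(t)`
  with unit variance. The dmPFC channel carries `s(t)`; the BLA channel
  carries `sqrt(c)·s(t − lag) + sqrt(1 − c)·p(t)` with an independent source
  `p`, so the coupling `c` sets the shared variance fraction without
  changing BLA theta variance, and `lag` (positive = dmPFC leads) sets the
  directional delay. The source is band-limited noise rather than a
  sinusoid because a pure tone has a constant envelope, which would make
  envelope cross-correlation degenerate. Both channels scale this component
  by `theta_sd` (default 15 µV).
* **Evoked responses.** At every pip onset two templates are added: a fast
  biphasic deflection (two Gaussian-windowed half-cycles, peak at 15 ms,
  trough at 30 ms) scaled so its scored peak-minus-trough amplitude equals
  the trial's `aep_amplitude` (default 75 µV), and a Gaussian-windowed 6 Hz
  burst over 0–250 ms scaled by the trial's `region_theta_gain` times
  `theta_burst_uv`. The published traces show but never parameterize the
  evoked waveform, so this shape is the package's own construction.
* **Background noise.** `1/f` (pink) noise confined to the 1–500 Hz
  recording band, `noise_sd` (default 10 µV) standard deviation.

Two design points deserve emphasis:

* **The per-trial theta gain scales only the pip-locked burst.** The
  ongoing theta source is stationary across the session. Evoked theta power
  is computed from the *pip-averaged* response, so non-phase-locked theta
  averages away (by a factor `1/sqrt(n_pips)`) and acts as noise; only a
  phase-locked component can carry a recoverable per-trial gain. Modulating
  the ongoing source as well would change the z-scoring reference along
  with the signal and make the normalized measure insensitive to the gain.
* **The default burst amplitude (8 µV at gain 1) is deliberately of the
  same order as the averaging residual** (`theta_sd / sqrt(60) ≈ 2 µV plus
  pink-noise residual). A z-scored, baseline-subtracted power is a
  *relative* measure: once the evoked component dwarfs the residual
  background, the z value saturates at a shape-determined ceiling and stops
  tracking the underlying amplitude. Published group effects are of order
  1.5–2.5×, i.e. within the informative regime. Monotonicity tests
  therefore sweep the gain on a log grid from sub-threshold to saturation.

Freezing behaviour is generated as interval sets (the frame-level video
scoring that produces such intervals is out of scope): deterministic mode
produces one bout per tone with exactly the requested fraction, stochastic
mode draws independent per-second freezing so the fraction is recovered in
expectation.

All randomness derives from one seed per session; `run_experiment()` spawns
per-animal child seeds as `master_seed * 1000 + animal_index` and records
them in the manifest.

# Analysis choices

## AEP scoring

Epochs span −200 to +400 ms around each pip, each baseline-corrected by its
own mean over [−100, 0) ms. All timestamps use half-open `[start, end)`
windows so boundary samples are never double-counted. The amplitude scorer
takes the *first* local maximum after onset whose topographic prominence
exceeds a floor, then the first local minimum after it. The floor is
`max(2 × SD(pre-onset waveform), 0.1 × range(search window))`: the first
term adapts to residual averaging noise, the second prevents a noise ripple
on the rising flank — which can have prominence above a few noise SDs —
from being taken as the response peak. The trough uses only the noise term,
because genuinely shallow troughs are legitimate (an asymmetric response
with a 5 µV trough after a 70 µV peak must still score). The search window
is 0–250 ms, matching the evoked theta window; the published methods never
state an upper latency bound. `NoDeflection` (a monotone segment) is an
error distinct from amplitude zero.

## Time-frequency decomposition

Complex Morlet wavelets in the bandwidth/centre-frequency convention
(`fb = 2`, `fc = 1` Hz), frequency grid 2–100 Hz in 0.1 Hz steps. A wavelet
analysing `f` Hz uses scale `a = fc / f`; in the frequency domain the scaled
kernel is `exp(-pi^2 · fb · (a·ξ − fc)^2)`. Kernels are **L1-normalized**
(`psi(t/a)/a`): with L2 normalization the ridge of a pure tone is biased low
by about 1.3% (the `sqrt(a)` factor tilts the scale profile), which already
exceeds the 0.1 Hz grid at 8 Hz. Conventions differ across libraries, so
this mapping is stated explicitly.

The transform runs on the pip-averaged evoked response, not on single
trials. Edges are handled by reflection, one wavelet support (three envelope
SDs at the lowest frequency) per side; the cone of influence is not masked.
Power is `10·log10(|W|^2)` with a floor of `1e-12` before the logarithm.
Each frequency row is z-scored across the full epoch (−200 to +400 ms) —
"across the time series" is ambiguous in the source description, and the
full epoch is the least arbitrary span — then the mean over the [−200, 0) ms
baseline is subtracted. Evoked theta power is the plain mean over
[0, 250) ms × 2–12 Hz. Note one practical consequence of wavelet support:
at 8 Hz the envelope SD is 125 ms, so ridge statements are only meaningful
for interior points at least ~375 ms from an epoch edge.

Normalizing theta power to the before-conditioning timepoint divides two
z-scores; when the baseline value is not positive the ratio is meaningless,
so the pipeline reports the raw difference instead and flags the row
(`theta_pct_flag_*` column).

## Coherence

Welch magnitude-squared coherence with 500 ms Hamming windows, 1024-point
FFT and 50% overlap (the overlap is unstated in the source description; 50%
is the Welch default). The theta summary is the mean over 2–12 Hz. The
finite-sample no-coherence floor depends on the number of averaged windows,
so tests compare uncoupled channels against a Monte-Carlo oracle at the same
window count rather than against zero.

## Envelope lead/lag

Channels are band-passed 2–12 Hz with a zero-phase (forward–backward)
4th-order Butterworth — zero-phase so the filter itself cannot introduce a
between-channel delay — then the analytic-signal modulus gives the
instantaneous amplitude, demeaned. Envelopes are computed **once on the
continuous channels and sliced into the 30 s CS windows afterwards**:
filter and Hilbert transients sit at the recording edges, and if each
segment were filtered separately the transients would occupy the same
samples in both channels and mimic zero-lag coupling (measurably inflating
the false-positive rate of the surrogate test).

Cross-correlation is normalized (Pearson) at every integer-sample lag in
±0.1 s, computed on the overlapping samples only; positive lag means the
dmPFC leads. The surrogate null shifts the BLA envelope by 2–5 s (sign
randomized) 100 times and records each peak. The default shift is *linear*
(the displaced alignment is cross-correlated over its overlapping samples);
a circular shift, which preserves length, is available but fires too often
on independent channels: random shifts drawn from a 2–5 s range give
surrogate windows that overlap on the underlying correlation curve, so the
surrogate peaks are mutually dependent and the "beat 95% of the peaks" rule
becomes anti-conservative (measured 0.062 at 30 s versus the nominal
0.0495), whereas the linear policy's slightly shorter surrogate overlap
compensates almost exactly (measured 0.0485 over 2000 uncoupled runs). A
segment is significant when its peak exceeds more than 95% of its own
surrogate peaks.
With the two-trial analysis the overall flag requires the majority of
segments (i.e. both) to pass — pooling surrogates across segments would
tighten the null faster than the actual statistic and inflates false
positives when pip-locked evoked activity (common to both channels, and
periodic at the 1 Hz pip rate, so only partially destroyed by shifts)
contributes to the envelopes. The summary lead/lag is the centre of the
maximal 5 ms bin of the per-segment peak-lag histogram (the source
description's "time bin" is unspecified; 5 ms at 1 kHz is 5 samples), ties
broken towards the bin with the larger total peak correlation. Both the
per-segment actual peak lags (used for the summary) and the surrogate peak
values (used for significance) are retained in the result object.

## Group statistics

Outlier screening flags values more than two sample SDs from the mean,
single pass, per measure and group. One-way repeated-measures ANOVAs use
the within-subject error term (`F = MS_level / MS_level×subject`), fitted
through `aov` with an `Error(subject)` stratum; mixed designs (group ×
level) test the group against subjects-within-group and the within/
interaction terms against level×subjects-within-group. Sphericity
corrections are *not* applied — the published degrees of freedom (e.g.
F(3,42)) are uncorrected — and the result objects say so. Post hoc tests
follow the published pairing: Tukey (studentized range on the within-subject
error) across repeated levels after one-way fits; Holm–Šídák-adjusted
group comparisons per level after mixed fits. The lead/lag-versus-chance
test is a pooled-variance two-sample t by default, mirroring the source
description verbatim; a one-sample alternative against zero is provided but
off by default, since testing per-animal lags against chance-derived lags
with an unpaired test is statistically unusual.

# Scenario cohorts

`run_experiment()` simulates a control and a CIS (chronic immobilization
stress) cohort. Ground-truth settings per timepoint:

| | control | CIS |
|---|---|---|
| theta gain (dmPFC / BLA) | 1/1 → 2.5/2.5 → 1/1 | 1/1 → 2.5/2.5 → 1/2.5 |
| AEP µV (dmPFC / BLA) | 75/75 → 120/120 → 80/80 | 75/75 → 75/115 → 75/115 |
| coupling, lag | 0.3 → 0.9 → 0.9, +20 ms | 0 throughout |
| freezing fraction | 0.05 → 0.7 → 0.3 | 0.05 → 0.7 → 0.3 |

The 2.5× theta gain matches the magnitude of published group elevations
(which roughly double); per-animal log-normal multipliers (SD 0.08) add
biological variability. Recall sessions are simulated with the two analysed
trials (the full protocol presents 15 tones but the evoked analyses use the
first two); tone habituation keeps its five tones since the analysis takes
the last two. Sessions at full length would change no analysed sample.

# Numerical notes and limitations

* Sessions are generated with FFT-shaped noise at the next power-of-2
  length and truncated, so generation cost does not depend on the session
  length's prime factorization. The shared source and its delayed copy are
  built before truncation, keeping the delay exact for any real-valued lag.
* The envelope cross-correlation and its surrogate loop are O(n·lags) per
  evaluation and implemented in compiled code; tests verify them against a
  direct R implementation of the Pearson formula at every lag (1e-10).
* The session container is a directory of plain-text CSVs plus a JSON
  manifest; signal samples are written with 17 significant digits so
  doubles round-trip bit-exactly.
* The generator emulates the statistical structure the analyses assume —
  stationary band-limited theta, phase-locked evoked components, pink
  background — not the full physiology: no spiking, no volume conduction,
  no cross-frequency coupling, no non-stationary state changes within a
  session, one composite channel per region (how multi-wire bundles were
  reduced to one LFP per region is unstated in the source description).
  Passing recovery tests therefore demonstrates correctness of the
  estimators under these assumptions, not robustness to every property of
  real tissue.
* The number of CS–US pairings during conditioning is garbled in the
  source description; it is a required argument with no default, and none
  of the analyses depend on it.
* Problem sizes used by the validation suite (20 sessions per lag level,
  1000 calibration runs at 12 s per pair, cohorts of 8 per group, 2-tone
  recall sessions) are the package's choices for desk-scale verification;
  all are arguments and can be raised.
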