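---
title: "Estimating cognitive workload from physiological and performance recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cognitive workload from physiological and performance recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogload)
```

## The problem

When the same operators perform several task conditions of increasing
difficulty — here the motivating design is a flight-simulator study
with a baseline flying task, an added altitude-holding constraint, and
an added secondary touch-screen task — their cognitive workload rises,
and that rise leaves traces in three independent measurement families:
pupil and gaze behaviour, EEG band power, and the way they work the
control inceptor. cogload computes one battery of metrics per
recording, compares the conditions with nonparametric repeated-measures
statistics, and asks whether the independent families agree (the
*conformance* analysis). Everything is verified end to end against a
synthetic study generator with known ground truth.

## Metric models and assumptions

### Pupil metrics

The pupil-diameter series of each eye is treated as
baseline + slow luminance-driven drift (below about 0.2 Hz) +
task-evoked dynamics concentrated in 1–5 Hz + tracker noise.

* **L1NS** sums the single-sided FFT amplitude spectrum of the
  mean-subtracted series over 1–5 Hz inclusive. Amplitudes are scaled
  `2|Y_j|/N` so a sinusoid of amplitude `a` on a bin contributes `a`.
  The epoch must be uniformly sampled (resampling lives in the I/O
  layer) and at least 2 s long (two cycles at the 1 Hz band edge).
* **STDP** is the sample standard deviation of the diameter.
* **LPF** is the mean absolute value of the zero-phase low-pass
  filtered (4th-order Butterworth, 4 Hz cutoff), mean-subtracted
  diameter. Both the filter family and the scalar reduction are
  choices the underlying definition leaves open; they are arguments
  with those defaults.

Blink handling (`preprocess_pupil`): epochs under 50 % valid samples
are rejected; invalid runs up to 500 ms (ordinary blinks) are linearly
interpolated; longer dropouts split the epoch.

**Why L1NS uses a Hann taper.** The obvious implementation — mean
subtraction and a rectangular epoch-length FFT — fails its own
robustness requirement: a slow drift component that is not an integer
number of periods long leaks through the rectangular window's 1/f
sidelobes into *every* 1–5 Hz bin, and because L1NS sums ~40 bin
amplitudes, the accumulated leakage can exceed the band signal (we
measured up to 160 % shifts from a 0.3 mm drift under a 0.2 mm band
signal). Two standard remedies also fail here: an IIR high-pass
detrend at 0.5 Hz has edge transients comparable to the signal on
10–60 s epochs, and subtracting a fitted polynomial trend injects its
own broadband leakage into the band sum. The Hann taper solves the
problem exactly because of a happy identity: applied *without*
coherent-gain renormalisation, a bin-aligned sinusoid of amplitude `a`
contributes `a/2` at its bin and `a/4` at each neighbour — the band
**sum** is still exactly `a` — while the taper's fast-decaying
sidelobes attenuate sub-0.2 Hz drift leakage to below 0.3 %. The raw
rectangular transform remains available via `window = "none"`.

### Gaze metrics

`ivt_classify` implements the I-VT velocity filter: per-sample angular
velocity by central difference over valid neighbours, saccade at
≥ 30°/s (the conventional default), consecutive fixation samples
merged, fixations shorter than 60 ms discarded. The per-sample classes
partition the valid samples exactly, which the tests assert.

`nni` is the Clark–Evans-style nearest-neighbour index over fixation
centroids: the mean nearest-neighbour distance divided by
`0.5 * sqrt(area / N)`, its expectation under complete spatial
randomness on the bounding rectangle of the points. No edge-effect
correction is applied, so uniform scatter calibrates slightly above 1
(≈ 1.02 at N = 1000); the acceptance checks allow for this. The
printed source formula for the mean nearest-neighbour distance
contains a typographical minus sign between the squared coordinate
differences and an ambiguous placement of 1/N; the standard Euclidean
form is implemented.

`detect_si` finds saccadic intrusions: small *horizontal* out-and-back
movements leaving a local baseline by more than 0.1° and returning to
within 0.1° (configurable, at most the 0.4° definition bound) after
60–870 ms; the event velocity is the out-and-back mean
`2 × amplitude / duration`. Three design decisions, each forced by a
failure mode observed on realistic scanpaths rather than isolated
traces:

1. an excursion may only *open* while the trailing 100 ms baseline
   window is settled (range ≤ 2 × the minimum amplitude) — otherwise a
   saccade in flight seeds a phantom event against a stale baseline;
2. excursions above 2° are refixations, not intrusions
   (`max_amplitude`);
3. when a vertical channel is available, excursions accompanied by
   more than 0.4° of vertical displacement are rejected: an intrusion
   is horizontal by definition, and a refixation that happens to land
   near the old horizontal position would otherwise masquerade as one.

With these rules the detector recovers ≥ 95 % of planted intrusions in
full scanpath simulations with ~5 % median-velocity error.

### EEG metrics

`psd_welch` is a standard Welch estimator: 2 s Hann segments, 50 %
overlap, per-segment mean removal, one-sided density scaling (checked
against Parseval). The 0.5 Hz resolution resolves the 4 Hz theta edge.
`band_power` integrates the density over theta 4–8, alpha 8–13, low
beta 13–21, high beta 21–30 Hz; gamma (31–100 Hz) is clipped at
Nyquist when undersampled and excluded from default summaries, since
low-cost headsets cannot cover it and it carries no demand signal in
this design. `band_power_summary` epochs each channel (10 s default),
computes band powers per channel × epoch, and takes one pooled median
per band — matching a single median-per-band-per-condition report.
Pooling first and taking one median (rather than median-of-medians)
is a choice; the per-cell table is returned alongside so alternatives
are a one-liner.

### Performance metrics

`duty_cycle`: an inter-sample interval is *active* when the absolute
deflection rate reaches the noise threshold (0.5 mm/s default) or the
stick is pinned at full scale. The printed definition sums
dimensionless indicators over elapsed time; the default here
time-weights them (`100 · Σ x_i Δt_i / (t_n − t_1)`) so the result is
a true, bounded percentage for any sampling; `method = "per_sample"`
retains the raw expression. The rate comparison uses the absolute
value — a signed rate would make leftward motion unconditionally
"active". `aggressiveness` is the mean squared deflection rate, and
`rmse_percent` normalises the RMS tracking error by the task
reference (altitude-band midpoint; 120 kt trim airspeed), both
configurable since the normalisation is not part of the original
definition.

### Statistics

The harness follows the analysis route of the motivating study:
outer fencing (quartiles by linear interpolation, type 7; the 3×IQR
*outer* fence) applied per metric within condition; an
Anderson–Darling composite-normality gate (case 3, the usual
piecewise-exponential p approximation) at α = 0.05; Friedman's
tie-corrected chi-square plus all pairwise Wilcoxon signed-rank tests
on the nonparametric branch, one-way repeated-measures ANOVA with
partial η² on the parametric branch. The Wilcoxon p-value is exact
(own dynamic-programming enumeration of the 2^n sign assignments) for
n ≤ 25 without ties, otherwise a tie- and continuity-corrected normal
approximation; both `W` and `Z` are reported because published
summaries quote either. Spearman's ρ uses the classical
`1 − 6Σd²/(n³−n)` without ties and the rank-Pearson form with ties.
All of these are cross-checked in the test suite against independent
implementations (`stats::friedman.test`, `wilcox.test`, `cor.test`,
`aov`, `nortest::ad.test`) to 1e-9 on random tables. Two boundary
choices: a table whose rows are all fully tied carries no rank
information and reports χ² = 0 (the reference implementation returns
NaN there), and no multiple-testing correction is applied by default,
mirroring the source analysis (`p.adjust` on the pairwise table is a
one-liner for users who want it).

Note one property that is sometimes assumed but false: the signed-rank
test is *not* invariant under arbitrary monotone transforms of the
data (the ranks of |a−b| are not preserved); it is invariant under
positive affine maps, and the tests assert exactly that.

## The synthetic study generator

`gen_study()` emulates a 12-participant × 3-condition repeated-measures
design (default workloads 0.3 / 0.45 / 0.9 for C1 / C2 / C3: the
baseline and the altitude-constraint conditions sit close together,
the secondary-task condition far above, which is the structure the
motivating design induces). Signal models are deliberately minimal —
sinusoid banks, bout processes, AR(1) errors — so that each metric's
driving property is independently tunable via the effect map
(`default_gains()`): 1–5 Hz pupil amplitude, fixation-cluster spread
and switching probability, per-band EEG amplitudes, inceptor active
fraction, tracking-error SD, and saccadic-intrusion rate, each scaled
by `(1 + gain × workload)`. Per-participant log-normal trait
multipliers (SD 0.12) are constant across conditions, giving the
between-subject variance a repeated-measures design exists to remove.
Seeds fully determine every output (Mersenne–Twister with fixed normal
and sample kinds, per-recording sub-seeds derived from the master
seed), and the generator writes the same CSV dialect the readers
parse, so synthetic and real studies share one code path.

Two generator subtleties worth recording. First, gaze transitions are
instantaneous sample-to-sample jumps with a 1.2° minimum target
separation: with finite-velocity ramps, the number of samples I-VT
charges to a saccade grows with its amplitude, which couples the
fixation-time share to workload even when the dwell distribution is
fixed — violating the requirement that zero-gain metrics stay flat
across conditions. Second, planted saccadic intrusions are square-wave
excursions (step out, hold, step back), the classical intrusion
morphology, which also makes the planted velocity `2a/duration` exact.

What the generator does *not* emulate: pupil light-reflex dynamics,
EEG nonstationarity and artefacts (ocular or muscular), flight-dynamic
coupling between inceptor input and flight state, and saccade
main-sequence kinematics. Consequently a green test suite shows the
*pipeline* is correct — every metric measures what it claims, the
statistics are calibrated, effects propagate and null metrics stay
null — not that these metrics will separate conditions in any
particular real cockpit dataset.

## Problem sizes and numerical choices

The shipped analyses use 60 s recordings (gaze and pupil at 100 Hz,
EEG at 128 Hz, inceptor and flight state at 20 Hz) for the
12 × 3 monotone-workload study, and 12 s recordings at reduced rates
(50 / 64 / 10 Hz) for the 200-replicate null-calibration suite; both
sizes keep every stage well-conditioned (≥ 2 s epochs for the 1 Hz
band edge, ≥ 2 s Welch windows, ≥ 870 ms for the intrusion window)
while the calibration stays a few minutes of CPU. Epoch boundaries are
closed intervals; timestamps are seconds as doubles; all tests at
α = 0.05 unless a table states otherwise; flags in comparison tables
mark p < 0.1 / 0.05 / 0.01 as `.` / `*` / `**`.

## Known limitations

* The conformance analysis pools participant × condition recordings,
  so its correlations mix between- and within-participant variance;
  a per-participant partial correlation is not implemented.
* The NNI carries no edge-effect correction (deliberately, matching
  the uncorrected index it reproduces); its null calibration sits
  ~2 % above 1.
* Saccadic-intrusion detection assumes a reasonably stable fixation
  baseline; nystagmus-like drift would defeat the settled-baseline
  rule.
* Gamma-band EEG power is reported only when the sampling rate
  supports it and is excluded from default summaries.
* Two-way repeated-measures designs (condition × lighting, sphericity
  corrections, multivariate tests) are out of scope; the harness is
  one-way repeated measures only.
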