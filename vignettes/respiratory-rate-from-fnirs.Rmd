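---
title: "Estimating respiratory rate from fNIRS baseline wander"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating respiratory rate from fNIRS baseline wander}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsrr)
```

## The idea

Respiration modulates cerebral blood volume, and that modulation is visible
in functional near-infrared spectroscopy (fNIRS) as a slow wander underneath
the cardiac pulsations of the oxygenated-hemoglobin (O2Hb) signal. Rather
than treating this interference as a nuisance, `fnirsrr` reads the
respiratory rate (RR) off it:

1. **Channel selection.** Every channel's optical-density (OD) pair is
   converted to O2Hb/HHb concentration changes with the modified
   Beer-Lambert law (MBLL), detrended, band-passed to the cardiac band
   (0.4-3 Hz, 208th-order zero-phase FIR), and scored 1-5 on consecutive
   10 s windows; the channel with the best aggregate score wins.
2. **Band-pass.** The selected O2Hb series is filtered to 0.05-2 Hz with a
   zero-phase FIR, removing slow drift and high-frequency noise while
   keeping both the respiratory wander and the cardiac pulse.
3. **Trough detection.** After min-max normalization to $[-1, 1]$, strict
   local minima below $\mathrm{Th}_1 = A\,\overline{x}$ are candidate
   troughs ($A = 1$ by default). The candidate trough values $z$ are then
   screened for motion-artifact outliers: troughs deeper than
   $\overline{z} - B\,\mathrm{sd}(z)$ are discarded ($B = 3$).
4. **Baseline synthesis.** The retained troughs, an irregularly sampled
   series, are interpolated by a cubic spline evaluated at every sample,
   giving a regularly sampled baseline wander $m(n)$.
5. **Detrending and spectral readout.** A zero-phase moving average
   ($L = 3$ s) estimates the very-low-frequency trend $S(n)$; the residual
   $G(n) = m(n) - S(n)$ is mean-removed, zero-padded, Fourier transformed,
   and the dominant frequency in 0.05-2 Hz times 60 is the RR in breaths
   per minute (BPM).

The estimate is evaluated per 50 s constant-rate trial against a reference
respiration trace, using absolute error (AE), Bland-Altman limits of
agreement (mean $\pm 2$ sd, multiplier exactly 2), per-subject paired
t-tests, and — for the trough/artifact detectors — the critical success
index $\mathrm{CSI} = TP/(TP+FN+FP)$ under greedy one-to-one event matching
with a $\pm 100$ ms tolerance.

## Resolving the trough-rejection rule

The dual-threshold detector is usually transcribed as "discard trough
values lower than $\overline{z} + B\,\mathrm{sd}(z)$" with the keep-rule
"$z > \mathrm{Th}_2$". Taken literally this is self-defeating: trough
values sit *below* the signal mean, so $\overline{z} + 3\,\mathrm{sd}(z)$
lies above nearly all of them and the literal rule would discard almost
every trough — the opposite of its stated purpose, which is to reject the
*abnormally deep* troughs carved by motion artifacts while keeping the
ordinary ones. `detect_troughs()` therefore retains
$z \ge \overline{z} - B\,\mathrm{sd}(z)$, which realizes the intended
behaviour; the literal transcription remains available as
`th2_convention = "literal"` for comparison. With fewer than two candidates
the dispersion is undefined and everything is retained, and the comparison
is non-strict so a zero-variance candidate set (e.g. a pure sinusoid) is
kept in full. The sample standard deviation ($n-1$ denominator) is used
throughout.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `A` | 1 | — | Scales $\mathrm{Th}_1$; keeps dicrotic-notch minima out of the candidate set |
| `B` | 3 | — | Scales $\mathrm{Th}_2$; rejects abnormally deep (artifact) troughs |
| `L_seconds` | 3 | s | Moving-average kernel; separates trend from wander |
| `filter$low`, `filter$high` | 0.05, 2 | Hz | Analysis band of the selected O2Hb channel |
| `filter$order_factor` | 33 | — | Main-stage FIR order = factor × fs |
| `spectrum$pad_factor` | 8 | — | FFT zero-padding; ~0.09 BPM grid at 50 s |
| `match$tolerance_s` | 0.1 | s | Event-matching tolerance for CSI |
| `window_s` | 50 | s | Trial window length |

`run_sweep()` reproduces the tuning procedure that selected $A$, $B$ and
$L$: one parameter sweeps its grid ($A$: 0.25-1.5 by 0.25; $B$: 1-6 by 1;
$L$: 2-5 s by 0.5) while the others hold their defaults, scoring mean
trough CSI (for $A$, $B$) or mean AE (for $L$) over all trials. On
simulated cohorts the CSI-vs-$B$ curve rises steeply from $B=1$
(over-rejection of genuine troughs) and is shallow from $B=2$ upward, so
the argbest can move between 2 and 6 from seed to seed; the defaults
$A=1, B=3, L=3$ s are kept as the published operating point, and the
synthetic sweeps serve to confirm they are plausible, not to re-derive
them.

## Numerical choices

**FIR order.** A Hamming-windowed band-pass of order $4 f_s$ (a 4 s
filter) has a transition width of roughly 0.8 Hz: its nominal 0.05 Hz
lower edge then attenuates a 0.1 Hz (6 BPM) respiratory component by more
than half per pass, and because the moving-average *subtraction* passes
harmonics more readily than the 0.1 Hz fundamental, 6 BPM trials get
mis-read at twice their rate. The default order is therefore
$33 f_s$ (transition half-width ≈ 0.05 Hz), which leaves everything at or
above 0.1 Hz essentially untouched. The price is that the signal must be
longer than three filter lengths (~100 s): **sessions are filtered whole
and trial windows are cut afterwards**, which is also how paced-breathing
recordings are processed in practice. `fir_bandpass()` additionally
de-means the taps, pinning an exact spectral null at DC (a windowed design
cannot hold a 60 dB stop at DC with so low an edge); the perturbation to
the passband is of order $10^{-3}$.

**Zero-phase filtering.** All filtering (both FIR stages and the moving
average) is applied forward and backward over a reflection-padded signal,
for exactly zero phase: trough positions and spectral peaks never shift.
For large signal × kernel products the forward-backward pass is evaluated
as a single linear convolution with the tap autocorrelation via FFT —
bit-equivalent to the direct path (asserted in the test suite) and
necessary to keep an order-1650 filter over an 1180 s session cheap.

**Spline.** `stats::splinefun(method = "fmm")`, whose end conditions fit a
cubic through the outermost points, so evaluation beyond the first/last
trough extrapolates with the end polynomials; with fewer than four knots
the exact lower-order interpolant is used (two knots degenerate to a
straight line). The spline passes through every knot to machine precision.

**Spectral grid.** $G$ is zero-padded to the next power of two of
$8n$, a ~0.0015 Hz (0.09 BPM) argmax grid for a 50 s window. The search
band defaults to the analysis band (0.05-2 Hz) and always excludes the DC
bin; zero-padding refines peak localisation but cannot remove the few-mHz
bias contributed by harmonic distortion of the trough-sampled baseline, so
recovered rates on noiseless trials are accurate to ~0.1-0.2 BPM, not to
one grid step.

**Indexing.** All sample indices the package exposes (troughs, segments,
artifact centers) are 1-based with inclusive segment ends, the R
convention; timestamps are seconds with $t = (i-1)/f_s$.

**Degenerate inputs.** Constant windows fail normalization ("degenerate
amplitude"); windows with fewer than two retained troughs fail baseline
synthesis ("insufficient troughs"); an all-zero detrended baseline fails
the spectral stage ("no spectral content"). `run_pipeline()` converts
per-trial failures into flagged rows rather than aborting a session, and
the command-line tool maps validation and degenerate-input errors to exit
codes 2 and 3.

## What the simulator emulates — and what it does not

`synthesize_o2hb()` builds an O2Hb series as the exact sum of recorded
component tracks:

* a **cardiac pulse train** (two wrapped Gaussians per cycle: systolic
  peak plus a delayed dicrotic bump at 0.3 of the peak), mean-removed,
  amplitude 1 concentration unit; the dicrotic notch produces the shallow
  local minima that $\mathrm{Th}_1$ must ignore;
* a **respiratory wander**: a sinusoid at the commanded rate with
  continuous phase across segments, amplitude 0.15 — the geometry is
  chosen once so notch minima sit above the signal mean while true troughs
  sit well below it;
* a **Mayer wave** (0.1 Hz, amplitude 0.05) and a **slow drift** (0.01 Hz,
  amplitude 0.10);
* **white Gaussian noise** (sd 0.02 by default);
* optional **motion artifacts**: sparse (≥ 2 s apart) Gaussian excursions
  of 0.3-1 s, 20× the respiratory amplitude, negative by default — deep
  enough after band-passing that they remain "abnormally deep", which is
  the condition the $\mathrm{Th}_2$ rule exists for.

Ground truth records every component track, the per-cycle deepest local
minimum of the cardiac + respiratory assembly (the true troughs), artifact
event positions, and the per-segment commanded rate.
`synthesize_protocol()` arranges the paced-breathing session used for
evaluation: 60 s rest, five 50 s steps at 6/12/24/12/6 BPM, 30 s rest,
five steps at 9/18/24/18/9 BPM, and the same four blocks repeated —
1180 s and 20 constant-rate trials per subject, with rest-period breathing
drawn uniformly from 12-18 BPM and the subject's heart rate from
1.0-1.3 Hz. The simulated reference respiration trace is stored at the
fNIRS sampling rate (a chest band's kilohertz rate adds nothing to a
pure-tone spectral reference).

Deliberately **not** modelled: hemodynamic responses to neuronal
activation, heart-rate variability and respiratory sinus arrhythmia,
amplitude modulation of the pulse by respiration, photon-transport and
optode-coupling physics, IMU channels, and short-separation channels.
Passing tests on this generator therefore demonstrate the algorithm's
internal correctness and its contracts (threshold behaviour, artifact
robustness, spectral readout) — not performance on recorded human data,
whose artifacts and physiology are richer.

Because all channels of a simulated recording share the same systemic
physiology and differ only in measurement-noise level (growing with
channel index), channel selection has an unambiguous right answer, which
the quality-score tests exploit.

## The surrogate quality score

The published channel-selection stage scores 10 s windows 1-5 with a
feature set defined in external work that this package does not reproduce.
`sqi_score()` keeps the stage's architecture (MBLL → least-squares detrend
→ 208th-order 0.4-3 Hz zero-phase FIR → windowed features) with a
documented surrogate: amplitude-range sanity bounds (flat or saturated
→ 1), the spectral concentration of the cardiac peak (power within
±0.15 Hz of the dominant 0.6-2.5 Hz peak over total 0.4-3 Hz power;
below 0.50 → 2, below 0.65 → 3), and the O2Hb-HHb correlation sign
(strong peak → 4, or 5 when the two are clearly anti-correlated, the
physiological signature of genuine pulsation). The ratio thresholds were
fixed from the measured separation between filtered white noise (≤ 0.45)
and clean simulated cardiac windows (≥ 0.82). Window scores aggregate by
mean (configurable: median, min); ties between channels resolve to the
lowest index. A trailing window shorter than 10 s is ignored.

## Problem sizes used by the tests and acceptance script

The test suite and `scripts/acceptance.R` run entirely on simulated data:
ten noiseless 160 s recordings for rate recovery (five rates × two
sampling rates, the central 50 s analyzed), one 8-subject × 20-trial
cohort at SNR 10 dB relative to the respiratory component for the
error ceiling, 100 seeded 50 s artifact pairs for the
$\mathrm{Th}_2$ contract, 1000 random short signals for brute-force
oracle equivalence of the trough detector, and single paced sessions for
the sweep and protocol-structure checks. Standalone 50 s signals are
band-passed with a 16 $f_s$-order filter (the session-length default
cannot run on 50 s of data); all session-level processing uses the
defaults.

## Known limitations

* The RR readout assumes a quasi-constant rate within the analysis window;
  within-window rate changes produce a smeared spectral peak and are not
  tracked.
* Trough-based baseline synthesis needs a detectable cardiac pulse; on
  signals without pulsatile structure the pipeline (correctly) fails with
  "insufficient troughs" rather than guessing.
* At 24 BPM and a 1 Hz heart rate the wander is sampled barely above its
  Nyquist rate by the trough series; spline reconstruction then leaks a
  small alias, one reason accuracy is bounded by ~0.2 BPM rather than the
  spectral grid.
* The surrogate quality score ranks simulated channels correctly but is
  not the published feature set; absolute scores on real data will differ.
* The moving-average subtraction used for detrending has a gentle,
  frequency-dependent passband (it attenuates 6 BPM wander about 4× more
  than 15 BPM wander), which is inherent to the published procedure.
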