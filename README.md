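# fnirsrr

Respiratory-rate estimation from the baseline wander of fNIRS
oxygenated-hemoglobin signals.

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cerebral
oxygenated- and deoxygenated-hemoglobin concentration changes (O2Hb, HHb)
optically. Respiration modulates cerebral blood volume, leaving a slow
wander underneath the cardiac pulsations of the O2Hb signal — usually
treated as interference. `fnirsrr` turns that interference into a
measurement: it estimates the respiratory rate (RR) directly from the
O2Hb baseline wander, so wearable fNIRS devices can report RR without a
dedicated respiration sensor. The package is aimed at physiological
signal-processing work: it provides the full pipeline, a synthetic
generator with known ground truth for validating every stage, evaluation
metrics, and a small command-line tool.

## The method

For a band-passed (0.05–2 Hz), min–max-normalized O2Hb window *x(n)*:

1. **Trough detection.** Candidate troughs are strict local minima with
   `x(i) < Th1 = A·mean(x)` (default `A = 1`), which excludes the shallow
   minima caused by the dicrotic notch. Their values `z` are screened for
   motion artifacts: troughs deeper than `mean(z) − B·sd(z)` (default
   `B = 3`) are rejected as abnormally deep.
2. **Baseline synthesis.** A cubic spline through the retained troughs,
   evaluated at every sample, gives the regularly sampled baseline wander
   `m(n)`.
3. **Detrend + FFT.** A zero-phase moving average (`L = 3 s`) yields the
   trend `S(n)`; the residual `G = m − S` is mean-removed, zero-padded and
   Fourier-transformed, and

   `RR [BPM] = 60 × argmax |FFT(G)|` over 0.05–2 Hz.

Upstream, recordings are converted from optical densities with the
modified Beer–Lambert law, channels are scored 1–5 on 10 s windows
(cardiac spectral concentration, amplitude sanity, O2Hb–HHb
anti-correlation) and the best channel is selected before filtering.
Evaluation uses absolute error against a reference respiration trace,
Bland–Altman limits of agreement (`mean ± 2·sd`), per-subject paired
t-tests, and the critical success index `CSI = TP/(TP+FN+FP)` for event
detection. See the methods vignette
(`vignettes/respiratory-rate-from-fnirs.Rmd`) for the design decisions and
numerical choices.

## Worked example

Simulate a paced 18 BPM recording, band-pass it, and estimate RR on a
50 s trial cut from the filtered session:

```r
library(fnirsrr)

sim <- synthesize_o2hb(sim_config(sampling_rate = 50, duration = 160,
                                  resp_rate = 18 / 60, seed = 42))
x <- fir_bandpass(sim$o2hb, 50, 0.05, 2)
res <- estimate_rr_pipeline(x[(55 * 50 + 1):(105 * 50)], 50)
print(res)
#> <rr_result> RR = 18.04 BPM (dominant 0.3006 Hz, grid 0.092 BPM)
#>   troughs: 55 retained / 55 candidates
```

The commanded 18 BPM is recovered to 0.04 BPM; all 55 cardiac troughs were
used as spline knots (none rejected — there are no artifacts here).
Cohort-level evaluation runs the full pipeline (channel selection,
filtering, per-trial estimation, reference comparison) over simulated
paced-breathing sessions:

```r
rep2 <- evaluate_cohort(n_subjects = 2, base_seed = 1, noise_sd = 0.0335)
print(rep2)
#> <eval_report> 40 trials (40 estimated), mean AE 0.05 BPM
#>   Bland-Altman: mean diff 0.037, LOA [-0.112, 0.185], 100.0% within
```

and the sweep harness re-examines the trough-rejection threshold on an
artifact-laden cohort (mean ± sd of trough-detection CSI per grid value):

```r
sw <- run_sweep(sweep_trials(synthesize_protocol(55, artifact_rate = 2)), "B")
print(sw)
#> <sweep_result> parameter B, objective csi, best = 3
#>  value      mean         sd
#>      1 0.9193162 0.06934565
#>      2 0.9589129 0.03803304
#>      3 0.9599440 0.03638382
#>      4 0.9548501 0.04618534
#>      5 0.9526898 0.04845786
#>      6 0.9512892 0.05017813
```

`B = 1` over-rejects genuine troughs; from `B = 2` up the curve is
shallow, with the operating point `B = 3` best here.

A thin CLI wraps the same functions
(`system.file("cli", "fnirsrr", package = "fnirsrr")`):

```sh
fnirsrr simulate --protocol --seed 9 --out proto
fnirsrr evaluate --in proto/recording.csv --truth proto/truth.json \
                 --resp proto/resp.csv --out report.json
fnirsrr sweep --param B --seed 5 --out sweepB.csv
```

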