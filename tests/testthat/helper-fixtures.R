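# Shared fixture builders and independent oracles, all generated in code.

# Brute-force trough detector: exhaustive per-sample scan applying both
# thresholds literally, used as the independent oracle for the vectorized
# detector.
oracle_troughs <- function(x, A = 1, B = 3) {
  n <- length(x)
  th1 <- A * mean(x)
  cand <- integer(0)
  for (i in 2:(n - 1))
    if (x[i] < x[i - 1] && x[i] < x[i + 1] && x[i] < th1)
      cand <- c(cand, i)
  z <- x[cand]
  retained <- if (length(z) < 2) cand
              else cand[z >= mean(z) - B * stats::sd(z)]
  list(candidates = cand, retained = retained)
}

# A constant-rate trial cut from the centre of a filtered 160 s recording,
# the way trials are cut from a filtered session.
make_filtered_trial <- function(bpm, fs = 50, seed = 1, noise_sd = 0, ...) {
  sim <- synthesize_o2hb(sim_config(sampling_rate = fs, duration = 160,
                                    resp_rate = bpm / 60, noise_sd = noise_sd,
                                    seed = seed, ...))
  xf <- fir_bandpass(sim$o2hb, fs, 0.05, 2)
  list(x = xf[(55 * fs + 1):(105 * fs)], sim = sim, fs = fs)
}

# Standalone 50 s signals (artifact pairing etc.) use a shorter FIR whose
# three-filter-length precondition a 50 s window satisfies.
short_fir <- function(x, fs) fir_bandpass(x, fs, 0.05, 2, order = 16 * fs)
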