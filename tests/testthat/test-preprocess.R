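test_that("MBLL is linear and rejects malformed input", {
  od <- cbind(c(0, 0.01, -0.02), c(0, 0.02, 0.01))
  h1 <- mbll(od)
  h3 <- mbll(3 * od)
  expect_equal(h3$o2hb, 3 * h1$o2hb)
  expect_equal(h3$hhb, 3 * h1$hhb)
  expect_equal(mbll(od * 0)$o2hb, numeric(3))
  expect_error(mbll(od[, 1, drop = FALSE]), "exactly two wavelengths")
  expect_error(mbll(od, extinction = matrix(1, 2, 2)), "singular")
})

test_that("least-squares detrend removes exactly linear structure", {
  n <- 0:99
  expect_equal(detrend_ls(2 * n + 5), numeric(100))
  expect_equal(detrend_ls(rep(3.7, 50)), numeric(50))
  t <- seq(0, 10, by = 0.01)
  s <- sin(2 * pi * 0.7 * t)
  out <- detrend_ls(s + 0.3 * t - 2)
  # any added line is removed exactly: same output as detrending the sine
  expect_equal(out, detrend_ls(s), tolerance = 1e-10)
  # the sine survives up to its own small projection onto {1, ramp}
  # (a non-integer cycle count leaves a line component of ~0.1 amplitude)
  expect_lt(sqrt(mean((out - s)^2)), 0.1)
  # residual orthogonal to ramp and mean-free
  expect_lt(abs(mean(out)), 1e-12)
  expect_lt(abs(cov(out, seq_along(out))), 1e-9)
  expect_error(detrend_ls(1), "at least 2")
})

test_that("band-pass rejects DC by at least 60 dB and is zero-phase", {
  fs <- 50
  x <- rep(1, 3000)
  out <- fir_bandpass(x, fs, 0.05, 2, order = 800)
  expect_lt(max(abs(out)), 1e-3)
  # symmetric pulse stays symmetric about its centre
  n <- 4001; c0 <- 2001
  pulse <- exp(-0.5 * ((seq_len(n) - c0) / 40)^2)
  pf <- fir_bandpass(pulse, fs, 0.05, 2, order = 800)
  expect_equal(which.max(pf), c0)
  j <- 1:1500
  expect_equal(pf[c0 + j], pf[c0 - j], tolerance = 1e-9)
})

test_that("band-pass preserves in-band tones and attenuates out-of-band tones", {
  fs <- 50
  t <- (0:7999) / fs
  tone <- sin(2 * pi * 1 * t)
  out <- fir_bandpass(tone, fs, 0.05, 2, order = 800)
  core <- 2000:6000
  expect_equal(max(abs(out[core])), 1, tolerance = 0.05)
  # zero phase: the filtered tone tracks the input pointwise (no lag)
  expect_lt(max(abs(out[core] - tone[core])), 0.06)
  hi <- sin(2 * pi * 5 * t)
  outhi <- fir_bandpass(hi, fs, 0.4, 3, order = 208)
  expect_lt(max(abs(outhi[core])), 0.1)
  expect_error(fir_bandpass(tone, fs, 0.05, 30), "band edges")
  expect_error(fir_bandpass(tone, fs, 0.05, 2, order = 7), "even")
})

test_that("FFT and direct convolution zero-phase paths agree exactly", {
  set.seed(31)
  x <- cumsum(rnorm(3000))
  b <- as.numeric(signal::fir1(120, c(0.4, 3) / 25, type = "pass"))
  direct <- fnirsrr:::zero_phase_fir(x, b)        # below FFT threshold
  n <- length(x); k <- length(b); pad <- k
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  nfft <- 2^ceiling(log2(length(xp) + 2 * k - 1))
  G <- stats::fft(c(b, numeric(nfft - k)))
  y <- Re(stats::fft(stats::fft(c(xp, numeric(nfft - length(xp)))) * (G * Conj(G)),
                     inverse = TRUE)) / nfft
  expect_equal(y[pad + seq_len(n)], direct, tolerance = 1e-12)
})

test_that("quality scores order clean cardiac above noise above flat", {
  fs <- 50
  w <- 1:(10 * fs)
  sim <- synthesize_o2hb(sim_config(duration = 30, seed = 4))
  o2f <- fir_bandpass(detrend_ls(sim$o2hb), fs, 0.4, 3, order = 208)
  hhf <- fir_bandpass(detrend_ls(sim$hhb), fs, 0.4, 3, order = 208)
  clean_score <- sqi_score(o2f[w], hhf[w], fs)
  expect_gte(clean_score, 4L)
  set.seed(12)
  noise_scores <- replicate(5, {
    nz <- fir_bandpass(detrend_ls(rnorm(1500)), fs, 0.4, 3, order = 208)
    nz2 <- fir_bandpass(detrend_ls(rnorm(1500)), fs, 0.4, 3, order = 208)
    sqi_score(nz[w], nz2[w], fs)
  })
  expect_true(all(noise_scores <= 2L))
  flat_score <- sqi_score(numeric(500), numeric(500), fs)
  expect_equal(flat_score, 1L)
  expect_true(clean_score > max(noise_scores) && max(noise_scores) >= flat_score)
  expect_error(sqi_score(numeric(400), numeric(400), fs), "exactly 10 s")
})

test_that("channel selection takes the highest aggregate score with stable ties", {
  expect_equal(select_best_channel(c(ch1 = 3.0, ch2 = 4.2)), "ch2")
  expect_equal(select_best_channel(c(ch1 = 4.0, ch2 = 4.0)), "ch1")
  expect_equal(select_best_channel(c(only = 2.5)), "only")
  expect_error(select_best_channel(numeric(0)), "empty")
})

test_that("quality report scores channels and a NaN channel hits the floor", {
  sr <- simulate_recording(sim_config(duration = 30, n_channels = 2, seed = 6))
  rec <- sr$recording
  rep1 <- sqi_report(rec)
  expect_true(all(rep1$window_scores %in% 1:5))
  expect_equal(nrow(rep1$window_scores), 3L)  # 30 s -> three 10 s windows
  expect_equal(rep1$selected_channel, "ch1")  # lowest-noise channel
  rec$od[5, 1] <- NaN
  rep2 <- sqi_report(rec)
  expect_equal(unname(rep2$channel_scores[["ch1"]]), 1)
  expect_equal(rep2$selected_channel, "ch2")
})
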