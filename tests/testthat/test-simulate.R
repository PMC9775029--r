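test_that("identical configuration gives bitwise-identical output", {
  cfg <- sim_config(duration = 20, artifact_rate = 2, seed = 7)
  a <- synthesize_o2hb(cfg)
  b <- synthesize_o2hb(cfg)
  expect_identical(a$o2hb, b$o2hb)
  expect_identical(a$hhb, b$hhb)
  expect_identical(a$truth, b$truth)
})

test_that("component tracks sum exactly to the signal", {
  sim <- synthesize_o2hb(sim_config(duration = 30, artifact_count = 2, seed = 3))
  expect_identical(sim$o2hb, Reduce(`+`, sim$truth$components))
})

test_that("respiratory track places its spectral peak at the commanded rate", {
  fs <- 50
  sim <- synthesize_o2hb(sim_config(sampling_rate = fs, duration = 50,
                                    resp_rate = 0.2, seed = 5))
  resp <- sim$truth$components$respiratory
  mag <- Mod(stats::fft(resp - mean(resp)))
  half <- seq_len(length(resp) %/% 2)
  freq <- (half - 1) * fs / length(resp)
  bin <- fs / length(resp)
  expect_lt(abs(freq[which.max(mag[half])] - 0.2), bin + 1e-12)
})

test_that("zero respiratory amplitude leaves no energy at the commanded rate", {
  fs <- 50
  sim <- synthesize_o2hb(sim_config(sampling_rate = fs, duration = 50,
                                    resp_rate = 0.25, resp_amplitude = 0,
                                    noise_sd = 0, seed = 5))
  expect_identical(sim$truth$components$respiratory, rep(0, length(sim$o2hb)))
  mag <- Mod(stats::fft(sim$o2hb - mean(sim$o2hb)))
  half <- seq_len(length(sim$o2hb) %/% 2)
  freq <- (half - 1) * fs / length(sim$o2hb)
  at_rr <- mag[half][which.min(abs(freq - 0.25))]
  # nothing above the window-leakage floor of the other components (~1-2%)
  expect_lt(at_rr, 0.02 * max(mag[half]))
})

test_that("every true trough is a local minimum of the cardiac+respiratory assembly", {
  for (seed in 1:5) {
    sim <- synthesize_o2hb(sim_config(duration = 30, seed = seed,
                                      resp_rate = 0.1 + 0.05 * seed))
    assembly <- sim$truth$components$cardiac + sim$truth$components$respiratory
    k <- sim$truth$trough_indices
    expect_true(all(k > 1 & k < length(assembly)))
    expect_true(all(assembly[k] < assembly[k - 1] & assembly[k] < assembly[k + 1]))
    expect_false(is.unsorted(k, strictly = TRUE))
    # about one trough per cardiac cycle
    expect_equal(length(k), 30 * sim$heart_rate, tolerance = 0.1)
  }
})

test_that("artifact events are sparse and counted as configured", {
  sim <- synthesize_o2hb(sim_config(duration = 50, artifact_count = 3, seed = 11))
  art <- sim$truth$artifacts
  expect_equal(nrow(art), 3L)
  expect_true(all(diff(art$index) >= 2 * 50))  # >= 2 s apart
  expect_true(all(art$sign == -1))             # default sign: negative
  expect_true(all(art$duration_s >= 0.3 & art$duration_s <= 1.0))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(sampling_rate = 2, heart_rate = 1.1), "Nyquist")
  expect_error(sim_config(duration = -5), "positive")
  expect_error(sim_config(resp_rate = 1.5, heart_rate = 1.1), "below the heart rate")
  expect_error(sim_config(cardiac_amplitude = -1), ">= 0")
})

test_that("protocol session matches the published block structure", {
  sched <- protocol_schedule()
  expect_equal(sum(sched$duration_s), 1180)  # 2 x (60 + 250 + 30 + 250)
  expect_equal(sum(sched$is_trial), 20L)
  expect_equal(sched$rr_bpm[sched$is_trial],
               rep(c(6, 12, 24, 12, 6, 9, 18, 24, 18, 9), 2))
  sim <- synthesize_protocol(42, sampling_rate = 50)
  seg <- sim$truth$segments
  expect_equal(length(sim$o2hb), 1180 * 50)
  # segments partition the sample range
  expect_equal(seg$start, c(1L, head(seg$end, -1) + 1L))
  expect_equal(seg$end[nrow(seg)], length(sim$o2hb))
  trials <- seg[seg$is_trial, ]
  expect_equal(nrow(trials), 20L)
  expect_true(all(trials$end - trials$start + 1L == 50 * 50))
  # rest-period spontaneous rates inside the documented range
  rests <- seg[!seg$is_trial, ]
  expect_true(all(rests$rr_bpm >= 12 & rests$rr_bpm <= 18))
  # 8 subjects x 20 trials = 160 trials
  expect_equal(8 * nrow(trials), 160L)
})

test_that("hemoglobin-to-OD conversion is linear and inverts the MBLL", {
  o2 <- c(0, 1, -2, 0.5)
  hh <- c(0, -0.3, 1, 0.2)
  expect_equal(hemo_to_od(numeric(4), numeric(4)),
               hemo_to_od(numeric(4), numeric(4)) * 0)
  expect_equal(hemo_to_od(2 * o2, 2 * hh), 2 * hemo_to_od(o2, hh))
  set.seed(8)
  o2 <- rnorm(200); hh <- rnorm(200)
  od <- hemo_to_od(o2, hh, distance_mm = 35, dpf = 6)
  rec <- mbll(od, distance_mm = 35, dpf = 6)
  expect_equal(rec$o2hb, o2, tolerance = 1e-9)
  expect_equal(rec$hhb, hh, tolerance = 1e-9)
  expect_error(hemo_to_od(o2, hh, extinction = matrix(1, 2, 2)), "singular")
})

test_that("multichannel recordings share physiology but not noise", {
  sr <- simulate_recording(sim_config(duration = 15, n_channels = 3, seed = 9))
  expect_equal(ncol(sr$recording$od), 6L)
  expect_equal(sr$recording$channel_labels, c("ch1", "ch2", "ch3"))
  h1 <- mbll(sr$recording$od[, 1:2])
  h2 <- mbll(sr$recording$od[, 3:4])
  clean <- sr$sim$o2hb - sr$sim$truth$components$noise
  expect_equal(h1$o2hb, sr$sim$o2hb, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(h2$o2hb, h1$o2hb)))
  expect_gt(cor(h2$o2hb, clean), 0.9)  # same underlying physiology
})
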