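test_that("min-max normalization maps onto [-1, 1] exactly", {
  expect_equal(normalize_minmax(c(0, 5, 10)), c(-1, 0, 1))
  expect_equal(normalize_minmax(c(2, 4, 8)), c(-1, -1/3, 1))
  set.seed(2)
  for (i in 1:5) {
    y <- normalize_minmax(rnorm(50, sd = sample(1:20, 1)))
    expect_equal(range(y), c(-1, 1))
  }
  expect_error(normalize_minmax(rep(2, 10)), "degenerate amplitude")
})

test_that("trough detection finds sine minima and ignores ramps", {
  fs <- 50
  t <- (0:499) / fs
  x <- sin(2 * pi * 0.5 * t)
  ts <- detect_troughs(normalize_minmax(x))
  expect_equal(ts$candidates, c(76L, 176L, 276L, 376L, 476L))
  expect_equal(ts$retained, ts$candidates)   # zero-variance z kept in full
  ramp <- normalize_minmax(seq(0, 1, length.out = 200))
  empty <- detect_troughs(ramp)
  expect_length(empty$candidates, 0)
  expect_length(empty$retained, 0)
  expect_error(detect_troughs(c(-1, 0, 1) * 3), "normalized")
  expect_error(detect_troughs(c(0, 1)), "at least 3")
})

test_that("an injected deep excursion is detected but rejected by Th2", {
  fs <- 50
  t <- (0:2999) / fs
  x <- sin(2 * pi * 0.5 * t) - 3 * exp(-0.5 * ((t - 30.5) / 0.1)^2)
  ts <- detect_troughs(normalize_minmax(x))
  exc <- which.min(x)
  expect_true(exc %in% ts$candidates)
  expect_false(exc %in% ts$retained)
  # all periodic troughs retained
  periodic <- setdiff(ts$candidates, exc)
  expect_true(all(periodic %in% ts$retained))
  # the literal transcription would discard nearly everything
  lit <- detect_troughs(normalize_minmax(x), th2_convention = "literal")
  expect_lt(length(lit$retained), 3)
})

test_that("vectorized detector matches the exhaustive brute-force oracle", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(10:120, 1)
    raw <- switch(1 + i %% 3,
                  cumsum(rnorm(n)),
                  sin(2 * pi * runif(1, 0.5, 3) * seq_len(n) / 50) + rnorm(n, 0, 0.3),
                  rnorm(n))
    if (diff(range(raw)) == 0) next
    x <- normalize_minmax(raw)
    A <- sample(c(0.25, 0.5, 1, 1.5), 1)
    B <- sample(1:6, 1)
    got <- detect_troughs(x, trough_params(A, B))
    want <- oracle_troughs(x, A, B)
    expect_identical(got$candidates, want$candidates)
    expect_identical(got$retained, want$retained)
  }
})

test_that("trough indices are invariant to constant offsets before normalization", {
  set.seed(13)
  x <- sin(2 * pi * 0.5 * (0:999) / 50) + rnorm(1000, 0, 0.1)
  a <- detect_troughs(normalize_minmax(x))
  b <- detect_troughs(normalize_minmax(x + 57.3))
  expect_identical(a$candidates, b$candidates)
  expect_identical(a$retained, b$retained)
})

test_that("spline baseline interpolates knots exactly and lines trivially", {
  x <- numeric(20)
  x[1] <- 0; x[11] <- 1
  m <- synthesize_baseline(c(1L, 11L), x)
  expect_equal(m[6], 0.5)   # two knots degenerate to a straight line
  # knot interpolation on a real trial
  tr <- make_filtered_trial(12, seed = 6)
  res <- estimate_rr_pipeline(tr$x, tr$fs)
  k <- res$troughs$retained
  expect_equal(res$baseline[k], res$x_norm[k], tolerance = 1e-12)
  expect_error(synthesize_baseline(integer(0), x), "insufficient troughs")
  expect_error(synthesize_baseline(5L, x), "insufficient troughs")
})

test_that("spline recovers a smooth wander between sparse knots", {
  fs <- 40
  t <- (0:1200) / fs
  x <- sin(2 * pi * t / 10)
  k <- seq(1L, 1201L, by = 50L)          # knots every 1.25 s
  m <- synthesize_baseline(k, x)
  # between interior knots (the end spans see the one-sided end conditions)
  interior <- k[2]:k[length(k) - 1]
  expect_lt(max(abs(m[interior] - x[interior])), 0.01)
})

test_that("moving-average detrend annihilates constants and interior ramps", {
  fs <- 50
  out <- ma_detrend(rep(4.2, 1000), fs, 3)
  expect_equal(out$G, numeric(1000))
  ramp <- seq(0, 10, length.out = 2000)
  out <- ma_detrend(ramp, fs, 3)
  core <- 400:1600
  expect_lt(max(abs(out$G[core])), 1e-8)
  expect_equal(out$S + out$G, ramp)
  expect_error(ma_detrend(rnorm(100), fs, 3), "three kernel lengths")
  expect_error(ma_detrend(rnorm(100), fs, 0.01), "at least 2 samples")
})

test_that("spectral estimator localizes pure and mixed tones", {
  fs <- 50
  t <- (0:2499) / fs
  r1 <- estimate_rr(sin(2 * pi * 0.2 * t), fs)
  expect_equal(r1$rr, 12, tolerance = 0.1)
  r2 <- estimate_rr(sin(2 * pi * 0.4 * t), fs)
  expect_equal(r2$dominant_frequency, 0.4, tolerance = 0.002)
  expect_equal(r2$rr, 24, tolerance = 0.1)
  mix <- sin(2 * pi * 0.15 * t) + 0.4 * sin(2 * pi * 0.35 * t)
  r3 <- estimate_rr(mix, fs)
  expect_equal(r3$rr, 9, tolerance = 0.1)
  # exact identity, not an approximation
  for (r in list(r1, r2, r3)) expect_identical(r$rr, 60 * r$dominant_frequency)
  expect_error(estimate_rr(numeric(1000), fs), "no spectral content")
})

test_that("pipeline recovers a commanded 18 BPM trial within one grid step", {
  tr <- make_filtered_trial(18, seed = 2)
  res <- estimate_rr_pipeline(tr$x, tr$fs)
  expect_lt(abs(res$rr - 18), res$grid_step_bpm)
  expect_identical(res$rr, 60 * res$dominant_frequency)
  # intermediates exposed for inspection
  expect_length(res$baseline, length(tr$x))
  expect_s3_class(res$troughs, "trough_set")
})

test_that("motion artifacts leave the estimate unchanged via Th2", {
  fs <- 50
  sim <- synthesize_o2hb(sim_config(duration = 50, artifact_count = 2, seed = 1005))
  with_art <- short_fir(sim$o2hb, fs)
  without <- short_fir(sim$o2hb - sim$truth$components$artifact, fs)
  r1 <- estimate_rr_pipeline(with_art, fs)
  r0 <- estimate_rr_pipeline(without, fs)
  expect_lte(abs(r1$rr - r0$rr), r1$grid_step_bpm)
  expect_gte(length(r1$troughs$rejected), 2)
})

test_that("degenerate windows propagate stage errors", {
  expect_error(estimate_rr_pipeline(rep(1, 1500), 50), "degenerate amplitude")
  ramp <- seq(0, 1, length.out = 1500)
  expect_error(estimate_rr_pipeline(ramp, 50), "insufficient troughs")
  expect_warning(
    tryCatch(estimate_rr_pipeline(rep(c(0, 1), 100), 50), error = function(e) NULL),
    "shorter than")
})
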