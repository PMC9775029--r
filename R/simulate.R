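#' Simulation configuration for synthetic fNIRS signals
#'
#' Bundles every knob of the synthetic O2Hb generator: the deterministic
#' physiological components (cardiac pulse train with a dicrotic notch,
#' sinusoidal respiratory baseline wander, ~0.1 Hz Mayer wave, slow drift),
#' white measurement noise, and sparse motion-artifact excursions.
#' Amplitudes are in arbitrary concentration units (micromolar-equivalent).
#'
#' @param sampling_rate Sampling rate in Hz. Must exceed twice the heart rate.
#' @param duration Recording length in seconds.
#' @param heart_rate Cardiac fundamental in Hz. `NA` draws one value per call
#'   uniformly from `heart_rate_range` (used by the protocol generator to vary
#'   simulated subjects).
#' @param heart_rate_range Range (Hz) for a drawn heart rate.
#' @param resp_rate Respiratory rate in Hz for a constant-rate recording.
#'   Ignored when `resp_schedule` is supplied. Must lie in (0, heart_rate).
#' @param resp_schedule Optional data frame with columns `duration_s`,
#'   `rr_bpm`, `is_trial` describing a paced-breathing session; `rr_bpm = NA`
#'   marks a rest segment whose spontaneous rate is drawn uniformly from
#'   `rest_rr_range`.
#' @param rest_rr_range Spontaneous respiratory-rate range (BPM) for rest
#'   segments.
#' @param cardiac_amplitude,resp_amplitude,mayer_amplitude,drift_amplitude
#'   Component amplitudes (concentration units, all >= 0).
#' @param dicrotic_depth Dicrotic bump height as a fraction of the systolic
#'   peak, in (0, 1).
#' @param mayer_rate,drift_rate Frequencies (Hz) of the Mayer and drift
#'   sinusoids.
#' @param noise_sd Standard deviation of white Gaussian measurement noise.
#' @param artifact_rate Expected motion-artifact events per minute (Poisson).
#' @param artifact_count Optional exact number of artifact events, overriding
#'   the Poisson draw.
#' @param artifact_amplitude Artifact excursion amplitude in multiples of
#'   `resp_amplitude`. The default (20) keeps excursions far deeper than the
#'   respiratory wander even after the 0.05-2 Hz analysis band-pass
#'   attenuates the briefest (0.3 s) events by roughly half.
#' @param artifact_sign `"negative"`, `"positive"`, or `"both"`. Negative
#'   excursions create the abnormally deep troughs the Th2 rule must reject.
#' @param hhb_ratio Scale of the (anti-correlated) HHb signal relative to the
#'   clean O2Hb assembly.
#' @param n_channels Number of channels for recordings built from this
#'   configuration; channels share the physiological components and differ in
#'   measurement noise.
#' @param seed Integer seed; identical configurations give bitwise-identical
#'   output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [synthesize_o2hb()], [synthesize_protocol()], [simulate_recording()]
#' @export
sim_config <- function(sampling_rate = 50,
                       duration = 50,
                       heart_rate = 1.1,
                       heart_rate_range = c(1.0, 1.3),
                       resp_rate = 0.25,
                       resp_schedule = NULL,
                       rest_rr_range = c(12, 18),
                       cardiac_amplitude = 1.0,
                       resp_amplitude = 0.15,
                       mayer_amplitude = 0.05,
                       drift_amplitude = 0.10,
                       dicrotic_depth = 0.3,
                       mayer_rate = 0.1,
                       drift_rate = 0.01,
                       noise_sd = 0.02,
                       artifact_rate = 0,
                       artifact_count = NULL,
                       artifact_amplitude = 20,
                       artifact_sign = c("negative", "positive", "both"),
                       hhb_ratio = 1 / 3,
                       n_channels = 1L,
                       seed = 1L) {
  artifact_sign <- match.arg(artifact_sign)
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar_num(duration, "duration", positive = TRUE)
  if (!is.na(heart_rate)) {
    assert_scalar_num(heart_rate, "heart_rate", positive = TRUE)
    if (sampling_rate <= 2 * heart_rate)
      stop_validation("sampling_rate must exceed twice the heart rate (Nyquist)")
  } else if (sampling_rate <= 2 * max(heart_rate_range)) {
    stop_validation("sampling_rate must exceed twice the heart rate (Nyquist)")
  }
  for (nm in c("cardiac_amplitude", "resp_amplitude", "mayer_amplitude",
               "drift_amplitude", "noise_sd", "artifact_rate",
               "artifact_amplitude")) {
    v <- get(nm)
    assert_scalar_num(v, nm)
    if (v < 0) stop_validation(sprintf("`%s` must be >= 0", nm))
  }
  if (dicrotic_depth <= 0 || dicrotic_depth >= 1)
    stop_validation("`dicrotic_depth` must be in (0, 1)")
  if (is.null(resp_schedule)) {
    assert_scalar_num(resp_rate, "resp_rate", positive = TRUE)
    hr_cap <- if (is.na(heart_rate)) min(heart_rate_range) else heart_rate
    if (resp_rate >= hr_cap)
      stop_validation("`resp_rate` must lie below the heart rate")
  } else {
    if (!is.data.frame(resp_schedule) ||
        !all(c("duration_s", "rr_bpm", "is_trial") %in% names(resp_schedule)))
      stop_validation("`resp_schedule` needs columns duration_s, rr_bpm, is_trial")
    if (any(resp_schedule$duration_s <= 0))
      stop_validation("schedule durations must be positive")
  }
  structure(list(
    sampling_rate = sampling_rate, duration = duration,
    heart_rate = heart_rate, heart_rate_range = heart_rate_range,
    resp_rate = resp_rate, resp_schedule = resp_schedule,
    rest_rr_range = rest_rr_range,
    cardiac_amplitude = cardiac_amplitude, resp_amplitude = resp_amplitude,
    mayer_amplitude = mayer_amplitude, drift_amplitude = drift_amplitude,
    dicrotic_depth = dicrotic_depth, mayer_rate = mayer_rate,
    drift_rate = drift_rate, noise_sd = noise_sd,
    artifact_rate = artifact_rate, artifact_count = artifact_count,
    artifact_amplitude = artifact_amplitude, artifact_sign = artifact_sign,
    hhb_ratio = hhb_ratio, n_channels = as.integer(n_channels),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Periodic cardiac pulse waveform on phase u in [0, 1): a systolic Gaussian
# peak plus a smaller, delayed dicrotic bump. Wrapped over adjacent cycles so
# the waveform is smooth and strictly analytic everywhere (no flat plateaus,
# so local minima of the assembly are well defined). The geometry keeps the
# dicrotic-notch local minimum well above the cycle mean while the true
# trough sits well below it, which is what the Th1 mean-threshold exploits.
#' @noRd
pulse_shape <- function(u, dicrotic_depth) {
  g <- function(x, c, w) exp(-0.5 * ((x - c) / w)^2)
  v <- 0
  for (off in -1:1)
    v <- v + g(u + off, 0.30, 0.10) + dicrotic_depth * g(u + off, 0.52, 0.07)
  v
}

# Strict local minima (interior samples only), 1-based.
#' @noRd
local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] < x[i - 1L] & x[i] < x[i + 1L]]
}

# All random draws for one recording; assumes the RNG is already seeded.
#' @noRd
synth_core <- function(config) {
  fs <- config$sampling_rate
  hr <- config$heart_rate
  if (is.na(hr))
    hr <- stats::runif(1, config$heart_rate_range[1], config$heart_rate_range[2])

  # segment table (durations in whole samples)
  if (is.null(config$resp_schedule)) {
    sched <- data.frame(duration_s = config$duration,
                        rr_bpm = config$resp_rate * 60, is_trial = TRUE)
  } else {
    sched <- config$resp_schedule
  }
  n_per <- round(sched$duration_s * fs)
  n <- sum(n_per)
  ends <- cumsum(n_per)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rr <- sched$rr_bpm
  rest <- is.na(rr)
  if (any(rest))
    rr[rest] <- stats::runif(sum(rest), config$rest_rr_range[1],
                             config$rest_rr_range[2])
  segments <- data.frame(start = starts, end = ends, rr_bpm = rr,
                         is_trial = sched$is_trial)

  t <- (seq_len(n) - 1) / fs
  phi <- stats::runif(4, 0, 2 * pi)  # cardiac, resp, mayer, drift phases

  # cardiac: mean-removed pulse train
  phase_c <- hr * t + phi[1] / (2 * pi)
  shape_mean <- mean(pulse_shape(seq(0, 1, length.out = 4096L)[-4096L],
                                 config$dicrotic_depth))
  cardiac <- config$cardiac_amplitude *
    (pulse_shape(phase_c %% 1, config$dicrotic_depth) - shape_mean)

  # respiratory wander with continuous phase across segments
  f_inst <- rep(segments$rr_bpm / 60, times = n_per)
  phase_r <- 2 * pi * cumsum(f_inst) / fs + phi[2]
  respiratory <- config$resp_amplitude * sin(phase_r)

  mayer <- config$mayer_amplitude * sin(2 * pi * config$mayer_rate * t + phi[3])
  drift <- config$drift_amplitude * sin(2 * pi * config$drift_rate * t + phi[4])
  noise <- stats::rnorm(n, 0, config$noise_sd)

  # motion artifacts: brief (0.3-1 s) Gaussian-shaped excursions
  n_events <- if (!is.null(config$artifact_count)) config$artifact_count
              else stats::rpois(1, config$artifact_rate * config$duration / 60)
  artifact <- numeric(n)
  artifacts <- data.frame(index = integer(0), sign = numeric(0),
                          duration_s = numeric(0))
  if (n_events > 0) {
    # sparse events: centers at least 2 s apart so each excursion carves its
    # own trough rather than merging with a neighbour
    centers <- sort(stats::runif(n_events, 2, config$duration - 2))
    for (try in seq_len(200)) {
      if (n_events < 2L || all(diff(centers) >= 2)) break
      centers <- sort(stats::runif(n_events, 2, config$duration - 2))
    }
    durs <- stats::runif(n_events, 0.3, 1.0)
    signs <- switch(config$artifact_sign,
                    negative = rep(-1, n_events),
                    positive = rep(1, n_events),
                    both = sample(c(-1, 1), n_events, replace = TRUE))
    amp <- config$artifact_amplitude * config$resp_amplitude
    for (e in seq_len(n_events))
      artifact <- artifact +
        signs[e] * amp * exp(-0.5 * ((t - centers[e]) / (durs[e] / 4))^2)
    artifacts <- data.frame(index = round(centers * fs) + 1L, sign = signs,
                            duration_s = durs)
  }

  components <- list(cardiac = cardiac, respiratory = respiratory,
                     mayer = mayer, drift = drift, artifact = artifact,
                     noise = noise)
  o2hb <- Reduce(`+`, components)  # same summation order as the truth tracks
  clean <- cardiac + respiratory + mayer + drift
  hhb <- -config$hhb_ratio * clean + stats::rnorm(n, 0, config$noise_sd / 2)

  # ground-truth troughs: deepest strict local minimum of the
  # cardiac + respiratory assembly within each cardiac cycle
  assembly <- cardiac + respiratory
  cand <- local_minima(assembly)
  u_grid <- seq(0, 1, length.out = 4096L)[-4096L]
  u_star <- u_grid[which.min(pulse_shape(u_grid, config$dicrotic_depth))]
  grp <- round(phase_c[cand] - u_star)
  troughs <- vapply(split(cand, grp),
                    function(ix) ix[which.min(assembly[ix])], integer(1))
  troughs <- sort(unname(troughs))

  truth <- list(
    segments = segments,
    trough_indices = troughs,
    artifacts = artifacts,
    heart_rate = hr,
    components = components
  )
  resp_ref <- list(signal = sin(phase_r), sampling_rate = fs)
  structure(list(o2hb = o2hb, hhb = hhb, sampling_rate = fs, truth = truth,
                 resp_ref = resp_ref, heart_rate = hr, config = config),
            class = "fnirs_sim")
}

#' Synthesize a single-channel O2Hb signal with ground truth
#'
#' Builds an O2Hb concentration-change series as the sum of a cardiac pulse
#' train (with dicrotic notch), a sinusoidal respiratory baseline wander, a
#' Mayer wave, slow drift, white noise, and optional motion-artifact
#' excursions. Every component track, the true trough locations (deepest
#' local minimum of the cardiac + respiratory assembly per cardiac cycle),
#' and artifact event positions are returned as ground truth.
#'
#' @param config A [sim_config()].
#' @return An object of class `fnirs_sim`: list with elements `o2hb`, `hhb`,
#'   `sampling_rate`, `resp_ref` (simulated reference respiration trace),
#'   `heart_rate`, `config`, and `truth` (segments, trough indices, artifact
#'   table, per-component tracks). Component tracks sum exactly to `o2hb`.
#' @examples
#' sim <- synthesize_o2hb(sim_config(duration = 30, seed = 7))
#' length(sim$o2hb)
#' @export
synthesize_o2hb <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  run_seeded(config$seed, synth_core(config))
}

#' Paced-breathing protocol schedule
#'
#' The session layout used for evaluation: a 60 s rest, five 50 s paced
#' steps at 6/12/24/12/6 BPM, a 30 s rest, five 50 s steps at
#' 9/18/24/18/9 BPM, and the same four blocks repeated, for a 1180 s session
#' containing 20 constant-rate trials. Rest segments have `rr_bpm = NA`
#' (spontaneous breathing, drawn at synthesis time).
#'
#' @return Data frame with columns `duration_s`, `rr_bpm`, `is_trial`.
#' @export
protocol_schedule <- function() {
  block <- function(rates) data.frame(duration_s = rep(50, 5), rr_bpm = rates,
                                      is_trial = TRUE)
  rest <- function(s) data.frame(duration_s = s, rr_bpm = NA_real_,
                                 is_trial = FALSE)
  half <- rbind(rest(60), block(c(6, 12, 24, 12, 6)),
                rest(30), block(c(9, 18, 24, 18, 9)))
  rbind(half, half)
}

#' Simulate a full paced-breathing session for one subject
#'
#' Runs [synthesize_o2hb()] over the [protocol_schedule()]: 20 constant-rate
#' 50 s trials embedded in a 1180 s session, with the subject's heart rate
#' drawn once from `heart_rate_range` and rest-period breathing drawn from
#' `rest_rr_range`.
#'
#' @param subject_seed Integer seed identifying the simulated subject.
#' @param sampling_rate Sampling rate in Hz (50 and 100 mirror the two
#'   device classes the method targets).
#' @param ... Further overrides passed to [sim_config()] (amplitudes,
#'   noise_sd, artifact settings, n_channels, ...).
#' @return An `fnirs_sim` object; `truth$segments[truth$segments$is_trial, ]`
#'   holds the 20 trials.
#' @export
synthesize_protocol <- function(subject_seed, sampling_rate = 50, ...) {
  sched <- protocol_schedule()
  config <- sim_config(sampling_rate = sampling_rate,
                       duration = sum(sched$duration_s),
                       heart_rate = NA, resp_schedule = sched,
                       seed = subject_seed, ...)
  synthesize_o2hb(config)
}

#' Convert hemoglobin concentration changes to optical densities
#'
#' The inverse of the modified Beer-Lambert conversion: maps O2Hb/HHb
#' concentration changes (micromolar) to optical-density changes at two
#' wavelengths through the extinction-coefficient matrix, source-detector
#' distance, and differential pathlength factor. [mbll()] applied to the
#' output recovers the input concentrations (round-trip contract).
#'
#' @param o2hb,hhb Concentration-change series (equal length, micromolar).
#' @param wavelengths Wavelength pair in nm (rows of the extinction table).
#' @param distance_mm Source-detector separation in mm.
#' @param dpf Differential pathlength factor (dimensionless).
#' @param extinction 2x2 extinction matrix (rows: wavelengths; columns:
#'   HbO2, HHb; units 1/(mM cm)); defaults to [extinction_coefficients()].
#' @return n x 2 matrix of OD changes, one column per wavelength.
#' @export
hemo_to_od <- function(o2hb, hhb, wavelengths = c(760, 850),
                       distance_mm = 35, dpf = 6,
                       extinction = extinction_coefficients(wavelengths)) {
  if (length(o2hb) != length(hhb))
    stop_validation("o2hb and hhb must have the same length")
  assert_scalar_num(distance_mm, "distance_mm", positive = TRUE)
  assert_scalar_num(dpf, "dpf", positive = TRUE)
  if (abs(det(extinction)) < 1e-12)
    stop_validation("extinction matrix is singular")
  od <- cbind(o2hb, hhb) %*% t(extinction) * (distance_mm * dpf * 1e-4)
  colnames(od) <- paste0("od_", wavelengths)
  od
}

#' Simulate a multichannel fNIRS recording
#'
#' Generates one subject-level physiological signal via [synthesize_o2hb()]
#' and derives `n_channels` optical-density channel pairs from it: all
#' channels share the systemic components (cardiac, respiratory, Mayer,
#' drift, artifacts) but carry independent measurement noise whose standard
#' deviation grows with channel index, so lower-numbered channels are
#' genuinely higher quality.
#'
#' @inheritParams hemo_to_od
#' @param config A [sim_config()]; `config$n_channels` sets the channel count.
#' @return List with `recording` (class `fnirs_recording`) and `sim` (the
#'   underlying `fnirs_sim`, whose truth refers to the shared clean signal).
#' @export
simulate_recording <- function(config = sim_config(), distance_mm = 35,
                               dpf = 6, wavelengths = c(760, 850)) {
  stopifnot(inherits(config, "sim_config"))
  run_seeded(config$seed, {
    sim <- synth_core(config)
    n <- length(sim$o2hb)
    k <- config$n_channels
    clean <- sim$o2hb - sim$truth$components$noise
    hhb_clean <- sim$hhb  # channel 1 keeps its own noise draw
    od <- matrix(NA_real_, n, 2L * k)
    labels <- paste0("ch", seq_len(k))
    cols <- character(2L * k)
    for (ch in seq_len(k)) {
      if (ch == 1L) {
        o2 <- sim$o2hb
        hh <- hhb_clean
      } else {
        sd_ch <- config$noise_sd * (1 + 0.6 * (ch - 1))
        o2 <- clean + stats::rnorm(n, 0, sd_ch)
        hh <- -config$hhb_ratio * (clean - sim$truth$components$artifact) +
          stats::rnorm(n, 0, sd_ch / 2)
      }
      od[, (2 * ch - 1):(2 * ch)] <-
        hemo_to_od(o2, hh, wavelengths, distance_mm, dpf)
      cols[(2 * ch - 1):(2 * ch)] <- paste0(labels[ch], "_", wavelengths)
    }
    colnames(od) <- cols
    rec <- structure(list(od = od, sampling_rate = config$sampling_rate,
                          wavelengths = wavelengths, channel_labels = labels,
                          distance_mm = distance_mm),
                     class = "fnirs_recording")
    list(recording = rec, sim = sim)
  })
}

#' @export
print.fnirs_sim <- function(x, ...) {
  n <- length(x$o2hb)
  cat(sprintf("<fnirs_sim> %d samples @ %g Hz (%.1f s), HR %.2f Hz\n",
              n, x$sampling_rate, n / x$sampling_rate, x$heart_rate))
  cat(sprintf("  segments: %d (%d trials), troughs: %d, artifacts: %d\n",
              nrow(x$truth$segments), sum(x$truth$segments$is_trial),
              length(x$truth$trough_indices), nrow(x$truth$artifacts)))
  invisible(x)
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf("<fnirs_recording> %d samples @ %g Hz, %d channels x %d wavelengths (%s nm)\n",
              nrow(x$od), x$sampling_rate, length(x$channel_labels),
              length(x$wavelengths), paste(x$wavelengths, collapse = "/")))
  invisible(x)
}
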