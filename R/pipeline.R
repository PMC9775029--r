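# End-to-end orchestration: channel selection -> band-pass -> per-trial RR
# estimation -> evaluation, plus the parameter-sweep harness used to pick
# the trough thresholds and MA length.

#' @noRd
even_order <- function(factor, fs) 2L * round(factor * fs / 2)

#' Run the full RR-estimation pipeline on a recording
#'
#' Scores every channel with [sqi_report()], selects the best one, converts
#' it to O2Hb, band-passes it to the 0.05-2 Hz analysis band, splits the
#' session into trial windows, and estimates RR per window with
#' [estimate_rr_pipeline()]. When ground-truth segments are supplied their
#' trial windows are used (otherwise fixed-length windows tile the
#' recording, trailing remainder discarded); when a reference respiration
#' trace is supplied the reference RR and absolute error are computed per
#' trial. A window whose estimation fails (e.g. too few troughs) is flagged
#' in the trial table rather than aborting the run.
#'
#' @param recording An `fnirs_recording`.
#' @param config Configuration list, see [default_config()].
#' @param truth Optional simulation truth (uses its `segments` trial
#'   windows and records the commanded rate).
#' @param resp_ref Optional [respiration_ref()] aligned with the recording.
#' @param keep_results Keep the full `rr_result` objects (with
#'   intermediates) for every trial.
#' @param verbose Log stage decisions (selected channel, trough counts).
#' @return Object of class `rr_pipeline`: list with `trials` (data frame:
#'   start, end, commanded_bpm, reference_bpm, estimated_bpm, ae_bpm,
#'   candidates, retained, rejected, error), `quality`, `selected_channel`,
#'   `results` (if kept), `config`.
#' @export
run_pipeline <- function(recording, config = default_config(), truth = NULL,
                         resp_ref = NULL, keep_results = FALSE,
                         verbose = FALSE) {
  stopifnot(inherits(recording, "fnirs_recording"))
  fs <- recording$sampling_rate
  quality <- sqi_report(recording, dpf = config$mbll$dpf,
                        aggregate = config$sqi$aggregate,
                        sqi_order = config$sqi$order)
  best <- quality$selected_channel
  if (verbose)
    message(sprintf("selected channel %s (score %.2f)", best,
                    quality$channel_scores[[best]]))
  hemo <- quality$hemo[[best]]
  xf <- fir_bandpass(hemo$o2hb, fs, config$filter$low, config$filter$high,
                     order = even_order(config$filter$order_factor, fs))

  if (!is.null(truth)) {
    seg <- truth$segments[truth$segments$is_trial, , drop = FALSE]
    windows <- data.frame(start = seg$start, end = seg$end,
                          commanded_bpm = seg$rr_bpm)
  } else {
    w <- round(config$window_s * fs)
    n_win <- length(xf) %/% w
    if (n_win < 1L) stop_validation("recording shorter than one trial window")
    windows <- data.frame(start = (seq_len(n_win) - 1L) * w + 1L,
                          end = seq_len(n_win) * w,
                          commanded_bpm = NA_real_)
  }

  params <- trough_params(config$trough$A, config$trough$B)
  results <- vector("list", nrow(windows))
  out <- windows
  out$reference_bpm <- NA_real_
  out$estimated_bpm <- NA_real_
  out$ae_bpm <- NA_real_
  out$candidates <- NA_integer_
  out$retained <- NA_integer_
  out$rejected <- NA_integer_
  out$error <- NA_character_
  for (i in seq_len(nrow(windows))) {
    ix <- windows$start[i]:windows$end[i]
    res <- tryCatch(
      estimate_rr_pipeline(xf[ix], fs, params = params,
                           L_seconds = config$ma$L_seconds,
                           band = config$spectrum$band,
                           th2_convention = config$trough$th2_convention,
                           pad_factor = config$spectrum$pad_factor),
      error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
      if (verbose) message(sprintf("trial %d failed: %s", i, out$error[i]))
      next
    }
    out$estimated_bpm[i] <- res$rr
    out$candidates[i] <- length(res$troughs$candidates)
    out$retained[i] <- length(res$troughs$retained)
    out$rejected[i] <- length(res$troughs$rejected)
    if (keep_results) results[[i]] <- res
    if (!is.null(resp_ref))
      out$reference_bpm[i] <- reference_rr(resp_ref,
                                           window = c(windows$start[i],
                                                      windows$end[i]),
                                           band = config$spectrum$band,
                                           pad_factor = config$spectrum$pad_factor)
  }
  ok <- !is.na(out$estimated_bpm) & !is.na(out$reference_bpm)
  out$ae_bpm[ok] <- absolute_error(out$reference_bpm[ok], out$estimated_bpm[ok])
  structure(list(trials = out, quality = quality, selected_channel = best,
                 results = if (keep_results) results else NULL,
                 config = config),
            class = "rr_pipeline")
}

#' @export
print.rr_pipeline <- function(x, ...) {
  ok <- !is.na(x$trials$estimated_bpm)
  cat(sprintf("<rr_pipeline> channel %s, %d/%d trials estimated",
              x$selected_channel, sum(ok), nrow(x$trials)))
  if (any(!is.na(x$trials$ae_bpm)))
    cat(sprintf(", mean AE %.2f BPM", mean(x$trials$ae_bpm, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' Simulate and evaluate a paced-breathing cohort
#'
#' Generates one protocol session per simulated subject (20 constant-rate
#' 50 s trials each), runs the full pipeline on the multichannel recording,
#' derives the reference RR per trial from the simulated respiration trace,
#' and aggregates: per-trial absolute error, per-subject mean AE and paired
#' t-test, overall mean AE, and a Bland-Altman summary.
#'
#' @param n_subjects Number of simulated subjects (8 gives 160 trials).
#' @param base_seed Integer; subject k uses seed `base_seed + k`.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_channels Channels per simulated recording.
#' @param config Pipeline configuration, see [default_config()].
#' @param ... Simulator overrides passed to [sim_config()] (noise_sd,
#'   artifact settings, amplitudes, ...).
#' @return Object of class `eval_report`: list with `trials` (data frame
#'   incl. `subject`), `per_subject` (mean AE, t statistic, dof, p),
#'   `mean_ae`, `bland_altman`, `n_trials`.
#' @export
evaluate_cohort <- function(n_subjects = 8, base_seed = 1, sampling_rate = 50,
                            n_channels = 3, config = default_config(), ...) {
  all_trials <- vector("list", n_subjects)
  for (k in seq_len(n_subjects)) {
    sched <- protocol_schedule()
    sc <- sim_config(sampling_rate = sampling_rate,
                     duration = sum(sched$duration_s), heart_rate = NA,
                     resp_schedule = sched, seed = base_seed + k,
                     n_channels = n_channels, ...)
    simrec <- simulate_recording(sc)
    pl <- run_pipeline(simrec$recording, config, truth = simrec$sim$truth,
                       resp_ref = respiration_ref(simrec$sim$resp_ref$signal,
                                                  sampling_rate))
    tr <- pl$trials
    tr$subject <- k
    all_trials[[k]] <- tr
  }
  trials <- do.call(rbind, all_trials)
  ok <- !is.na(trials$ae_bpm)
  per_subject <- do.call(rbind, lapply(split(trials[ok, ], trials$subject[ok]),
    function(d) {
      tt <- paired_t_test(d$reference_bpm, d$estimated_bpm)
      data.frame(subject = d$subject[1L], n = nrow(d),
                 mean_ae = mean(d$ae_bpm), t = tt$statistic, dof = tt$dof,
                 p_value = tt$p_value)
    }))
  rownames(per_subject) <- NULL
  ba <- bland_altman(trials$reference_bpm[ok], trials$estimated_bpm[ok])
  structure(list(trials = trials, per_subject = per_subject,
                 mean_ae = mean(trials$ae_bpm[ok]), bland_altman = ba,
                 n_trials = nrow(trials), n_estimated = sum(ok)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d trials (%d estimated), mean AE %.2f BPM\n",
              x$n_trials, x$n_estimated, x$mean_ae))
  cat(sprintf("  Bland-Altman: mean diff %.3f, LOA [%.3f, %.3f], %.1f%% within\n",
              x$bland_altman$mean_diff, x$bland_altman$loa_low,
              x$bland_altman$loa_high, x$bland_altman$pct_within))
  invisible(x)
}

#' Extract per-trial sweep inputs from a simulated session
#'
#' Band-passes the clean-channel O2Hb of a simulated session once and
#' slices out the constant-rate trials, each carrying the filtered window,
#' the ground-truth trough indices shifted into window coordinates, and the
#' reference RR from the simulated respiration trace.
#'
#' @param sim An `fnirs_sim` from [synthesize_protocol()] or
#'   [synthesize_o2hb()].
#' @param config Pipeline configuration (filter band/order, spectrum).
#' @details The ground-truth trough indices are refined into the analysis
#'   domain before matching: band-limiting to 0.05-2 Hz reshapes the
#'   cardiac pulse (its harmonics are cut), which systematically shifts
#'   each cycle's minimum by tens of milliseconds relative to the raw
#'   assembly. Each raw truth trough is therefore replaced by the minimum
#'   of the identically filtered clean cardiac + respiratory assembly
#'   within +/-0.3 s, so detector and annotation live in the same domain
#'   and the matching tolerance only has to absorb genuine jitter.
#' @return List of trial objects (`x`, `fs`, `truth_troughs`,
#'   `reference_bpm`, `commanded_bpm`).
#' @export
sweep_trials <- function(sim, config = default_config()) {
  stopifnot(inherits(sim, "fnirs_sim"))
  fs <- sim$sampling_rate
  ord <- even_order(config$filter$order_factor, fs)
  xf <- fir_bandpass(sim$o2hb, fs, config$filter$low, config$filter$high,
                     order = ord)
  assembly_f <- fir_bandpass(sim$truth$components$cardiac +
                               sim$truth$components$respiratory,
                             fs, config$filter$low, config$filter$high,
                             order = ord)
  half <- round(0.3 * fs)
  n <- length(assembly_f)
  refined <- vapply(sim$truth$trough_indices, function(k) {
    lo <- max(1L, k - half)
    hi <- min(n, k + half)
    (lo:hi)[which.min(assembly_f[lo:hi])]
  }, integer(1))
  refined <- sort(unique(refined))
  seg <- sim$truth$segments[sim$truth$segments$is_trial, , drop = FALSE]
  resp <- respiration_ref(sim$resp_ref$signal, fs)
  lapply(seq_len(nrow(seg)), function(i) {
    ix <- seg$start[i]:seg$end[i]
    tr <- refined[refined >= seg$start[i] & refined <= seg$end[i]] -
      seg$start[i] + 1L
    list(x = xf[ix], fs = fs, truth_troughs = tr,
         reference_bpm = reference_rr(resp, window = c(seg$start[i], seg$end[i]),
                                      band = config$spectrum$band,
                                      pad_factor = config$spectrum$pad_factor),
         commanded_bpm = seg$rr_bpm[i])
  })
}

#' Parameter-sweep harness
#'
#' Reproduces the threshold-regulation procedure: sweep one parameter over
#' a grid while the others stay at their defaults, and report the
#' objective's mean and standard deviation over all trials per grid value.
#' For the trough thresholds `A` and `B` the objective is the mean critical
#' success index of trough detection against ground truth; for the
#' moving-average length `L` it is the mean absolute error of the RR
#' estimate against the reference.
#'
#' @param trials List of trial objects from [sweep_trials()].
#' @param parameter One of `"A"`, `"B"`, `"L"`.
#' @param grid Grid values; defaults: A 0.25-1.5 by 0.25, B 1-6 by 1,
#'   L 2-5 s by 0.5.
#' @param config Pipeline configuration supplying the held-fixed defaults.
#' @return Object of class `sweep_result`: data frame with columns `value`,
#'   `mean`, `sd`; attributes `objective` (`"csi"` or `"ae"`) and `argbest`
#'   (grid value with the best mean objective).
#' @export
run_sweep <- function(trials, parameter = c("A", "B", "L"), grid = NULL,
                      config = default_config()) {
  parameter <- match.arg(parameter)
  if (!length(trials)) stop_validation("empty cohort")
  if (is.null(grid))
    grid <- switch(parameter,
                   A = seq(0.25, 1.5, by = 0.25),
                   B = seq(1, 6, by = 1),
                   L = seq(2, 5, by = 0.5))
  if (!length(grid)) stop_validation("empty sweep grid")
  objective <- if (parameter == "L") "ae" else "csi"
  tol <- NULL
  rows <- lapply(grid, function(g) {
    vals <- vapply(trials, function(tr) {
      if (parameter == "L") {
        res <- tryCatch(
          estimate_rr_pipeline(tr$x, tr$fs,
                               params = trough_params(config$trough$A,
                                                      config$trough$B),
                               L_seconds = g, band = config$spectrum$band,
                               th2_convention = config$trough$th2_convention,
                               pad_factor = config$spectrum$pad_factor),
          error = function(e) NULL)
        if (is.null(res)) return(NA_real_)
        absolute_error(tr$reference_bpm, res$rr)
      } else {
        params <- if (parameter == "A")
          trough_params(g, config$trough$B)
        else trough_params(config$trough$A, g)
        ts <- detect_troughs(normalize_minmax(tr$x), params,
                             config$trough$th2_convention)
        counts <- match_events(tr$truth_troughs, ts$retained,
                               round(config$match$tolerance_s * tr$fs))
        csi(counts)
      }
    }, numeric(1))
    data.frame(value = g, mean = mean(vals, na.rm = TRUE),
               sd = stats::sd(vals[!is.na(vals)]))
  })
  out <- do.call(rbind, rows)
  best_mean <- if (objective == "ae") min(out$mean) else max(out$mean)
  best <- min(out$value[abs(out$mean - best_mean) < 1e-12])  # ties: smallest value
  structure(out, objective = objective, argbest = best,
            parameter = parameter, class = c("sweep_result", "data.frame"))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> parameter %s, objective %s, best = %g\n",
              attr(x, "parameter"), attr(x, "objective"), attr(x, "argbest")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Evaluate motion-artifact trough rejection on a simulated trial
#'
#' Runs the trough detector on the band-passed simulated O2Hb and matches
#' the rejected troughs against the centers of the trough-inducing
#' (negative-sign) artifact events, within a time tolerance. The returned
#' counts feed [csi()]: a rejected trough near an artifact center is a TP,
#' an artifact with no nearby rejection an FN, and a rejection far from any
#' artifact an FP.
#'
#' @param sim An `fnirs_sim` containing injected artifacts.
#' @param config Pipeline configuration.
#' @param tolerance_s Matching tolerance in seconds (artifact excursions
#'   last 0.3-1 s, so the default 0.6 s covers the trough's offset from the
#'   event center).
#' @param filter_order Band-pass FIR order; the default follows the
#'   configuration, which requires the signal to exceed three filter
#'   lengths. For standalone 50 s trials pass a shorter order (e.g.
#'   `16 * fs`).
#' @return A `match_counts` object.
#' @export
evaluate_artifact_rejection <- function(sim, config = default_config(),
                                        tolerance_s = 0.6,
                                        filter_order = NULL) {
  stopifnot(inherits(sim, "fnirs_sim"))
  fs <- sim$sampling_rate
  if (is.null(filter_order))
    filter_order <- even_order(config$filter$order_factor, fs)
  xf <- fir_bandpass(sim$o2hb, fs, config$filter$low, config$filter$high,
                     order = filter_order)
  ts <- detect_troughs(normalize_minmax(xf),
                       trough_params(config$trough$A, config$trough$B),
                       config$trough$th2_convention)
  art <- sim$truth$artifacts
  centers <- sort(art$index[art$sign < 0])
  match_events(centers, ts$rejected, round(tolerance_s * fs))
}
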