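#' Extinction coefficients for oxy- and deoxyhemoglobin
#'
#' A fixed published pair of molar extinction coefficients for the nominal
#' 760/850 nm wavelengths of continuous-wave fNIRS devices, in 1/(mM cm).
#' Any user-supplied 2x2 matrix with the same layout (rows: wavelengths,
#' columns: HbO2, HHb) can be used instead.
#'
#' @param wavelengths Wavelength pair in nm; only 760 and 850 are tabulated.
#' @return 2x2 numeric matrix, rows named by wavelength.
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  table <- rbind(`760` = c(HbO2 = 0.586, HHb = 1.548),
                 `850` = c(HbO2 = 1.058, HHb = 0.691))
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(table)))
    stop_validation("extinction coefficients tabulated only for 760 and 850 nm; supply a matrix for other wavelengths")
  table[key, , drop = FALSE]
}

#' Modified Beer-Lambert conversion of optical density to hemoglobin
#'
#' Solves the 2x2 linear system relating optical-density changes at two
#' wavelengths to O2Hb/HHb concentration changes, using the extinction
#' matrix, source-detector distance (mm), and differential pathlength
#' factor. Linear in the OD input; exact inverse of [hemo_to_od()].
#'
#' @param od n x 2 matrix (or list of two vectors) of OD changes, one column
#'   per wavelength.
#' @param wavelengths Wavelength pair in nm.
#' @param distance_mm Source-detector separation in mm.
#' @param dpf Differential pathlength factor.
#' @param extinction 2x2 extinction matrix, see [extinction_coefficients()].
#' @param channel_label Optional label carried into the result.
#' @return Object of class `hemo_signal`: list with `o2hb`, `hhb` (micromolar
#'   change), `sampling_rate` (if known, else `NA`), `channel_label`.
#' @export
mbll <- function(od, wavelengths = c(760, 850), distance_mm = 35, dpf = 6,
                 extinction = extinction_coefficients(wavelengths),
                 channel_label = NA_character_) {
  if (is.list(od) && !is.data.frame(od)) od <- do.call(cbind, od)
  od <- as.matrix(od)
  if (ncol(od) != 2L)
    stop_validation("exactly two wavelengths required")
  assert_scalar_num(distance_mm, "distance_mm", positive = TRUE)
  assert_scalar_num(dpf, "dpf", positive = TRUE)
  if (abs(det(extinction)) < 1e-12)
    stop_validation("extinction matrix is singular")
  conc <- t(solve(extinction, t(od) / (distance_mm * dpf * 1e-4)))
  structure(list(o2hb = conc[, 1L], hhb = conc[, 2L],
                 sampling_rate = NA_real_, channel_label = channel_label),
            class = "hemo_signal")
}

#' Least-squares linear detrend
#'
#' Subtracts the least-squares straight-line fit from a series. The result
#' has zero mean and zero covariance with the sample-index ramp.
#'
#' @param x Numeric vector, length >= 2.
#' @return Detrended vector of the same length.
#' @export
detrend_ls <- function(x) {
  n <- length(x)
  if (n < 2L) stop_validation("detrend_ls needs at least 2 samples")
  i <- seq_len(n) - (n + 1) / 2          # centred ramp
  slope <- sum(i * x) / sum(i * i)
  x - mean(x) - slope * i
}

#' Zero-phase FIR band-pass filter
#'
#' Designs a Hamming-windowed linear-phase FIR band-pass (via
#' [signal::fir1()]) and applies it forward and backward, giving exactly
#' zero phase distortion. The taps are de-meaned so the filter has an exact
#' spectral null at DC, which a windowed design alone cannot guarantee for a
#' lower edge as low as 0.05 Hz.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param order Even FIR order (number of taps minus one). The default,
#'   `33 * fs` rounded to even, keeps the Hamming transition half-width at
#'   about 0.05 Hz so that a 0.1 Hz respiratory component passes the
#'   0.05 Hz lower edge essentially unattenuated; the signal must
#'   accordingly be longer than three filter lengths (about 100 s), which a
#'   session recording always is. Shorter analysis windows are cut from the
#'   session after filtering, never filtered individually.
#' @param dc_null Force an exact null at DC by de-meaning the taps.
#' @return Filtered signal, same length as `x`.
#' @export
fir_bandpass <- function(x, fs, low, high, order = NULL, dc_null = TRUE) {
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (is.null(order)) order <- 2L * round(33 * fs / 2)
  order <- as.integer(order)
  if (order %% 2L != 0L) stop_validation("FIR order must be even")
  if (!(low > 0 && low < high && high < fs / 2))
    stop_validation("band edges must satisfy 0 < low < high < fs/2")
  if (length(x) <= 3L * order)
    stop_validation("signal too short for stable zero-phase filtering")
  b <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  b <- as.numeric(b)
  if (dc_null) b <- b - mean(b)
  zero_phase_fir(x, b)
}

# Spectral concentration of the cardiac band in a 10 s window:
# power within +/-0.15 Hz of the dominant 0.6-2.5 Hz peak, relative to the
# total 0.4-3 Hz power.
#' @noRd
cardiac_peak_ratio <- function(x, fs) {
  sp <- spectral_peak(x, fs, band = c(0.6, 2.5), pad_factor = 4)
  f <- sp$frequencies
  p2 <- sp$magnitudes^2
  total <- sum(p2[f >= 0.4 & f <= 3])
  if (total <= 0) return(0)
  peak <- sum(p2[f >= sp$dominant_frequency - 0.15 &
                   f <= sp$dominant_frequency + 0.15])
  peak / total
}

#' Signal quality score for one 10 s window
#'
#' Scores a 10 s window of detrended, 0.4-3 Hz band-passed signals on the
#' conventional 1 (very low) to 5 (very high) quality scale. The feature set
#' is a documented surrogate: amplitude-range sanity bounds, the spectral
#' concentration of the cardiac peak, and the sign of the O2Hb-HHb
#' correlation. Flat, saturated or non-finite windows score 1; windows with
#' no discernible cardiac peak score 2; a detectable but weak peak scores 3;
#' a strong peak scores 4, or 5 when O2Hb and HHb are clearly
#' anti-correlated (the physiological signature of genuine pulsation).
#'
#' @param o2hb,hhb Window of O2Hb and HHb (detrended, cardiac-band filtered),
#'   exactly `10 * fs` samples.
#' @param fs Sampling rate in Hz.
#' @param saturation_limit Amplitude range above which the window is treated
#'   as saturated/railed (concentration units).
#' @return Integer score in 1..5.
#' @export
sqi_score <- function(o2hb, hhb, fs, saturation_limit = 100) {
  if (length(o2hb) != round(10 * fs) || length(hhb) != length(o2hb))
    stop_validation("SQI window must be exactly 10 s of paired O2Hb/HHb samples")
  if (!all(is.finite(o2hb)) || !all(is.finite(hhb))) return(1L)
  rng <- diff(range(o2hb))
  if (rng < 1e-10 || rng > saturation_limit) return(1L)
  ratio <- cardiac_peak_ratio(o2hb, fs)
  if (ratio < 0.50) return(2L)
  if (ratio < 0.65) return(3L)
  cc <- suppressWarnings(stats::cor(o2hb, hhb))
  if (is.finite(cc) && cc <= -0.5) 5L else 4L
}

#' Windowed signal-quality report for a recording
#'
#' For each channel: converts the OD pair to O2Hb/HHb via [mbll()],
#' detrends (least-squares line), applies the 208th-order zero-phase
#' 0.4-3 Hz FIR band-pass, scores consecutive non-overlapping 10 s windows
#' with [sqi_score()] (a trailing remainder shorter than 10 s is ignored),
#' and aggregates window scores per channel.
#'
#' @param recording An `fnirs_recording` (see [simulate_recording()],
#'   [read_recording()]).
#' @param dpf Differential pathlength factor for the MBLL conversion.
#' @param aggregate How window scores combine into the channel score:
#'   `"mean"` (default), `"median"`, or `"min"`.
#' @param sqi_order FIR order of the quality-stage band-pass (208).
#' @return Object of class `quality_report`: list with `window_scores`
#'   (windows x channels integer matrix), `channel_scores` (named numeric),
#'   `selected_channel`, and `hemo` (list of per-channel `hemo_signal`s for
#'   reuse downstream).
#' @export
sqi_report <- function(recording, dpf = 6, aggregate = c("mean", "median", "min"),
                       sqi_order = 208L) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(recording, "fnirs_recording"))
  fs <- recording$sampling_rate
  n <- nrow(recording$od)
  win <- round(10 * fs)
  n_win <- n %/% win
  if (n_win < 1L)
    stop_validation("recording shorter than one 10 s quality window")
  labels <- recording$channel_labels
  scores <- matrix(NA_integer_, n_win, length(labels),
                   dimnames = list(NULL, labels))
  hemo <- vector("list", length(labels))
  names(hemo) <- labels
  for (ch in seq_along(labels)) {
    od <- recording$od[, (2 * ch - 1):(2 * ch), drop = FALSE]
    hs <- mbll(od, recording$wavelengths, recording$distance_mm, dpf,
               channel_label = labels[ch])
    hs$sampling_rate <- fs
    hemo[[ch]] <- hs
    bad <- !all(is.finite(hs$o2hb)) || !all(is.finite(hs$hhb))
    if (bad) {
      scores[, ch] <- 1L
      next
    }
    o2f <- fir_bandpass(detrend_ls(hs$o2hb), fs, 0.4, 3, order = sqi_order)
    hhf <- fir_bandpass(detrend_ls(hs$hhb), fs, 0.4, 3, order = sqi_order)
    for (w in seq_len(n_win)) {
      ix <- ((w - 1L) * win + 1L):(w * win)
      scores[w, ch] <- sqi_score(o2f[ix], hhf[ix], fs)
    }
  }
  agg_fun <- switch(aggregate, mean = mean, median = stats::median, min = min)
  channel_scores <- apply(scores, 2L, agg_fun)
  structure(list(window_scores = scores, channel_scores = channel_scores,
                 selected_channel = select_best_channel_scores(channel_scores),
                 aggregate = aggregate, hemo = hemo),
            class = "quality_report")
}

#' @noRd
select_best_channel_scores <- function(channel_scores) {
  names(channel_scores)[which.max(channel_scores)]  # ties -> lowest index
}

#' Select the best channel from a quality report
#'
#' Returns the label of the channel with the highest aggregate window score;
#' ties are broken in favour of the lowest channel index.
#'
#' @param report A `quality_report` from [sqi_report()], or a named numeric
#'   vector of channel scores.
#' @return Channel label (character scalar).
#' @export
select_best_channel <- function(report) {
  scores <- if (inherits(report, "quality_report")) report$channel_scores
            else report
  if (!length(scores)) stop_validation("empty quality report")
  if (is.null(names(scores)))
    names(scores) <- paste0("ch", seq_along(scores))
  select_best_channel_scores(scores)
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n  channel scores:",
      paste(sprintf("%s=%.2f", names(x$channel_scores), x$channel_scores),
            collapse = ", "),
      sprintf("\n  selected: %s (%d windows, aggregate=%s)\n",
              x$selected_channel, nrow(x$window_scores), x$aggregate))
  invisible(x)
}
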