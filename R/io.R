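#' Write a recording to CSV
#'
#' One file per recording: commented metadata header lines (sampling rate,
#' wavelengths, source-detector distance), then a comma-separated table with
#' a `time_s` column followed by one OD column per wavelength per channel
#' (named `<channel>_<wavelength>`). UTF-8, `.` decimal separator.
#'
#' @param recording An `fnirs_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "fnirs_recording"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "# fnirs recording",
    sprintf("# sampling_rate_hz: %.10g", recording$sampling_rate),
    sprintf("# wavelengths_nm: %s", paste(recording$wavelengths, collapse = ",")),
    sprintf("# source_detector_mm: %.10g", recording$distance_mm)
  ), con)
  n <- nrow(recording$od)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$sampling_rate,
                   recording$od, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Parses the dialect written by [write_recording()]: commented metadata
#' lines, then `time_s` plus OD columns named `<channel>_<wavelength>`.
#' Validates that the time column is monotone and consistent with the
#' declared sampling rate, that exactly two distinct wavelengths are
#' present (each channel carrying both), and that the recording spans at
#' least one 10 s quality window. The time axis is reconstructed from the
#' sampling rate; samples are 1-based.
#'
#' @param path CSV file path.
#' @param format Only `"csv"` is supported.
#' @return An `fnirs_recording`.
#' @export
read_recording <- function(path, format = c("csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  header <- readLines(path, n = 10L)
  meta <- function(key) {
    line <- grep(sprintf("^# %s:", key), header, value = TRUE)
    if (!length(line)) stop_validation(sprintf("malformed header: missing `%s`", key))
    trimws(sub(sprintf("^# %s:", key), "", line[1L]))
  }
  fs <- as.numeric(meta("sampling_rate_hz"))
  wavelengths <- as.numeric(strsplit(meta("wavelengths_nm"), ",")[[1L]])
  distance_mm <- as.numeric(meta("source_detector_mm"))
  if (!is.finite(fs) || fs <= 0) stop_validation("malformed header: bad sampling rate")
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (names(df)[1L] != "time_s") stop_validation("malformed header: first column must be time_s")
  tm <- df$time_s
  if (is.unsorted(tm, strictly = TRUE)) stop_validation("non-monotone time column")
  od_names <- names(df)[-1L]
  parts <- regmatches(od_names, regexec("^(.*)_([0-9]+)$", od_names))
  if (any(lengths(parts) != 3L)) stop_validation("malformed header: OD columns must be <channel>_<wavelength>")
  chans <- vapply(parts, `[`, "", 2L)
  wls <- as.numeric(vapply(parts, `[`, "", 3L))
  if (length(unique(wls)) != 2L) stop_validation("exactly two wavelengths required")
  if (!setequal(unique(wls), wavelengths)) stop_validation("wavelength columns disagree with header")
  labels <- unique(chans)
  for (lb in labels)
    if (!setequal(wls[chans == lb], wavelengths))
      stop_validation(sprintf("channel %s lacks both wavelengths", lb))
  # column order: per channel, wavelengths in header order
  ord <- unlist(lapply(labels, function(lb)
    vapply(wavelengths, function(w) which(chans == lb & wls == w), 1L)))
  od <- as.matrix(df[, -1L, drop = FALSE])[, ord, drop = FALSE]
  if (nrow(od) < 10 * fs)
    stop_validation("recording shorter than one 10 s quality window")
  structure(list(od = od, sampling_rate = fs, wavelengths = wavelengths,
                 channel_labels = labels, distance_mm = distance_mm),
            class = "fnirs_recording")
}

#' Write / read the simulation ground truth as a JSON sidecar
#'
#' Serializes the segment table, true trough indices, and artifact table
#' (component tracks are omitted; they are reproducible from the seed).
#'
#' @param truth The `truth` element of an `fnirs_sim`.
#' @param path JSON file path.
#' @return `path` invisibly (write); truth list (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(segments = truth$segments,
                            trough_indices = truth$trough_indices,
                            artifacts = truth$artifacts,
                            heart_rate = truth$heart_rate),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$segments <- as.data.frame(x$segments)
  x$artifacts <- as.data.frame(x$artifacts)
  x
}

#' Reference respiration trace
#'
#' Container for a concurrently recorded (or simulated) respiration signal
#' used to derive the reference respiratory rate per trial.
#'
#' @param signal Numeric respiration trace (arbitrary units).
#' @param sampling_rate Sampling rate in Hz.
#' @return Object of class `respiration_ref`.
#' @export
respiration_ref <- function(signal, sampling_rate) {
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  structure(list(signal = as.numeric(signal), sampling_rate = sampling_rate),
            class = "respiration_ref")
}

#' Reference respiratory rate from a respiration trace
#'
#' Dominant FFT frequency of the mean-removed (windowed) respiration signal
#' times 60 — deliberately the same spectral estimator as the final stage
#' of the O2Hb pipeline, so reference and estimate share one definition of
#' "rate". The window must span at least two breathing cycles at the
#' slowest expected rate.
#'
#' @param resp A [respiration_ref()].
#' @param window Optional 1-based inclusive sample range `c(from, to)`;
#'   default is the whole trace.
#' @param slowest_bpm Slowest expected rate (BPM) defining the minimum
#'   window length.
#' @param band Spectral search band in Hz.
#' @param pad_factor Zero-padding factor.
#' @return Reference RR in BPM.
#' @export
reference_rr <- function(resp, window = NULL, slowest_bpm = 6,
                         band = c(0.05, 2), pad_factor = 8) {
  stopifnot(inherits(resp, "respiration_ref"))
  x <- resp$signal
  if (!is.null(window)) {
    if (length(window) != 2L || window[1] < 1 || window[2] > length(x) ||
        window[1] >= window[2])
      stop_validation("window must be c(from, to) within the trace")
    x <- x[window[1]:window[2]]
  }
  min_len <- 2 * (60 / slowest_bpm) * resp$sampling_rate
  if (length(x) < min_len)
    stop_validation(sprintf(
      "window shorter than two breathing cycles at %g BPM (need >= %g samples)",
      slowest_bpm, ceiling(min_len)))
  sp <- spectral_peak(x, resp$sampling_rate, band = band,
                      pad_factor = pad_factor)
  60 * sp$dominant_frequency
}

#' Default pipeline configuration
#'
#' The resolved defaults of every tunable stage, as a nested list that can
#' be written to / read from YAML and overridden per run: MBLL constants,
#' SQI aggregation, filter band and order factor, trough thresholds, MA
#' length, spectral search band and padding, event-matching tolerance, and
#' trial window length.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    mbll = list(dpf = 6, wavelengths = c(760, 850)),
    sqi = list(aggregate = "mean", order = 208L),
    filter = list(low = 0.05, high = 2, order_factor = 33),
    trough = list(A = 1, B = 3, th2_convention = "corrected"),
    ma = list(L_seconds = 3),
    spectrum = list(band = c(0.05, 2), pad_factor = 8),
    match = list(tolerance_s = 0.1),
    window_s = 50
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' Values present in the file override the defaults from
#' [default_config()]; everything else keeps its default, so partial
#' configuration files are valid.
#'
#' @param path YAML file path.
#' @param config Configuration list (for writing).
#' @return Resolved configuration list (read); `path` invisibly (write).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  user <- yaml::read_yaml(path)
  config <- default_config()
  for (section in names(user)) {
    if (is.list(user[[section]]) && is.list(config[[section]])) {
      for (key in names(user[[section]]))
        config[[section]][[key]] <- user[[section]][[key]]
    } else {
      config[[section]] <- user[[section]]
    }
  }
  config
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
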