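# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_validation <- function(msg) {
  stop(structure(class = c("fnirsrr_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @noRd
stop_degenerate <- function(msg) {
  stop(structure(class = c("fnirsrr_degenerate_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
#' @noRd
run_seeded <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Zero-phase FIR filtering: reflect-pad, filter forward and backward with the
# same taps, strip the padding. Net frequency response is |B(f)|^2 with no
# phase distortion; constants and (in the interior) straight lines are
# preserved exactly by a moving-average kernel. For large signal x kernel
# products the forward-backward pass is evaluated as one linear convolution
# with the tap autocorrelation via FFT (identical result to rounding).
#' @noRd
zero_phase_fir <- function(x, b) {
  n <- length(x)
  k <- length(b)
  if (n <= k + 1L)
    stop_validation("signal too short for stable zero-phase filtering")
  pad <- k
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  np <- length(xp)
  if (as.double(n) * k > 4e6) {
    # autocorrelation kernel g = conv(b, rev(b)); out[i] = (xp * g)[i + k - 1]
    nc <- 2L * k - 1L
    nfft <- 2^ceiling(log2(np + nc))
    G <- stats::fft(c(b, numeric(nfft - k)))
    Y <- stats::fft(c(xp, numeric(nfft - np))) * (G * Conj(G))
    y <- Re(stats::fft(Y, inverse = TRUE)) / nfft
    # |B|^2 is the zero-lag autocorrelation kernel: no group-delay shift
    out <- y[pad + seq_len(n)]
  } else {
    fwd <- stats::filter(xp, b, method = "convolution", sides = 1L)
    bwd <- rev(stats::filter(rev(fwd), b, method = "convolution", sides = 1L))
    out <- as.numeric(bwd[pad + seq_len(n)])
  }
  if (anyNA(out)) stop_validation("zero-phase filtering produced NA output")
  out
}

# Magnitude spectrum of the mean-removed, zero-padded signal and its dominant
# frequency within a search band. Shared by the RR estimator and the
# reference-respiration extractor so both use the identical estimator.
#' @noRd
spectral_peak <- function(x, fs, band = c(0.05, 2), pad_factor = 8) {
  x <- x - mean(x)
  if (all(x == 0)) stop_degenerate("no spectral content")
  n <- length(x)
  nfft <- 2^ceiling(log2(pad_factor * n))
  half <- nfft %/% 2L + 1L
  mag <- Mod(stats::fft(c(x, numeric(nfft - n))))[seq_len(half)]
  freq <- (seq_len(half) - 1) * fs / nfft
  if (!is.null(band)) {
    sel <- which(freq > 0 & freq >= band[1] & freq <= band[2])
  } else {
    sel <- which(freq > 0)
  }
  if (!length(sel)) stop_validation("empty frequency search band")
  peak <- sel[which.max(mag[sel])]
  list(frequencies = freq, magnitudes = mag,
       dominant_frequency = freq[peak],
       grid_step_hz = fs / nfft)
}

#' @noRd
assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop_validation(sprintf("`%s` must be positive", name))
  invisible(x)
}
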