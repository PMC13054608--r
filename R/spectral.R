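# Amplitude spectra of 20-s EEG blocks and the neighbour-bin SNR spectrum.

#' Construct an EEG block
#'
#' Container for one triggered 20-s core segment of a familiarization block:
#' a channels-by-samples matrix sampled at 1000 Hz (20000 samples) plus
#' session metadata.
#'
#' @param data Numeric matrix, channels x samples, finite values.
#' @param fs Sampling rate in Hz.
#' @param subject,timepoint,block Metadata (timepoint one of `"T1"`,
#'   `"T2"`, `"T3"`).
#' @param looking_s Seconds of looking within the 20-s core, in `[0, 20]`.
#' @return An `eeg_block`.
#' @export
eeg_block <- function(data, fs = 1000, subject = NA_character_,
                      timepoint = NA_character_, block = NA_integer_,
                      looking_s = NA_real_) {
  if (!is.matrix(data) || !is.numeric(data)) stopf("`data` must be a numeric matrix")
  if (!all(is.finite(data))) stopf("`data` must be finite")
  check_scalar_number(fs, "fs", lower = 1)
  if (!is.na(looking_s)) check_scalar_number(looking_s, "looking_s", 0, 20)
  structure(
    list(data = data, fs = fs, subject = subject, timepoint = timepoint,
         block = block, looking_s = looking_s),
    class = "eeg_block"
  )
}

#' One-sided amplitude spectrum of a 20-s block
#'
#' Removes each channel's mean, applies a rectangular-window FFT and returns
#' the one-sided amplitude spectrum `2 |X_k| / N` (DC and Nyquist unhalved,
#' i.e. `|X_k| / N`). With 20000 samples at 1000 Hz the bin spacing is
#' exactly 0.05 Hz, so every tagged frequency (multiples of 3 Hz) falls on a
#' bin centre and a pure sinusoid shows zero leakage.
#'
#' @param x An `eeg_block`, or a channels-by-samples numeric matrix.
#' @param fs Sampling rate, used when `x` is a plain matrix.
#' @return An `amplitude_spectrum`: list with `freqs` (Hz), `amp`
#'   (channels x bins, >= 0), `fs`, `n`.
#' @export
amplitude_spectrum <- function(x, fs = 1000) {
  if (inherits(x, "eeg_block")) {
    data <- x$data
    fs <- x$fs
  } else if (is.matrix(x) && is.numeric(x)) {
    data <- x
  } else {
    stopf("`x` must be an eeg_block or a numeric channels-by-samples matrix")
  }
  n <- ncol(data)
  if (fs != 1000 || n != 20000L) {
    stopf("expected a 20-s block at fs = 1000 Hz (20000 samples); got fs = %s, %d samples (no padding or truncation is applied)",
          fs, n)
  }
  xc <- data - rowMeans(data)
  X <- stats::mvfft(t(xc))
  nb <- n %/% 2L + 1L
  amp <- 2 * Mod(X[seq_len(nb), , drop = FALSE]) / n
  amp[1L, ] <- amp[1L, ] / 2
  amp[nb, ] <- amp[nb, ] / 2
  structure(
    list(freqs = (seq_len(nb) - 1) * fs / n, amp = t(amp), fs = fs, n = n),
    class = "amplitude_spectrum"
  )
}

#' Neighbour-bin SNR spectrum
#'
#' The SNR at bin `k` is the amplitude at `k` divided by the mean amplitude
#' of the 10 surrounding bins: 5 on each side, excluding the two bins
#' immediately adjacent to `k` (offsets +/-2 .. +/-6). Bins whose
#' neighbourhood exits the spectrum (the first and last 6 bins) are masked
#' `NA`, as are bins whose neighbourhood mean is exactly zero.
#'
#' @param spec An `amplitude_spectrum`.
#' @return An `snr_spectrum`: list with `freqs`, `snr` (channels x bins,
#'   `NA` where undefined) and `valid` (logical per bin: neighbourhood
#'   inside the spectrum).
#' @export
snr_spectrum <- function(spec) {
  if (!inherits(spec, "amplitude_spectrum")) stopf("expected an `amplitude_spectrum`")
  amp <- spec$amp
  nb <- ncol(amp)
  if (nb < 13L) stopf("spectrum too short for a +/-6 bin neighbourhood")
  offs <- c(-6:-2, 2:6)
  inner <- 7:(nb - 6)
  acc <- matrix(0, nrow(amp), length(inner))
  for (o in offs) acc <- acc + amp[, inner + o, drop = FALSE]
  noise <- acc / length(offs)
  snr <- matrix(NA_real_, nrow(amp), nb)
  snr[, inner] <- amp[, inner, drop = FALSE] / noise
  snr[, inner][noise == 0] <- NA_real_
  valid <- rep(FALSE, nb)
  valid[inner] <- TRUE
  structure(
    list(freqs = spec$freqs, snr = snr, valid = valid),
    class = "snr_spectrum"
  )
}

#' Bin index of a tagged frequency
#'
#' @param freqs Bin-centre frequencies (Hz) or an object with a `freqs`
#'   field.
#' @param f Target frequency in Hz; must coincide with a bin centre.
#' @return Integer bin index (1-based).
#' @keywords internal
freq_bin <- function(freqs, f) {
  if (is.list(freqs)) freqs <- freqs$freqs
  idx <- which(abs(freqs - f) < 1e-9)
  if (length(idx) != 1L) {
    stopf("frequency %s Hz does not fall on a bin centre", f)
  }
  as.integer(idx)
}

# Restrict an SNR spectrum to a set of bin-centre frequencies (used to keep
# per-block storage small when streaming many blocks).
reduce_snr_spectrum <- function(snr, freqs) {
  bins <- vapply(freqs, function(f) freq_bin(snr$freqs, f), 1L)
  structure(
    list(freqs = snr$freqs[bins], snr = snr$snr[, bins, drop = FALSE],
         valid = snr$valid[bins]),
    class = "snr_spectrum"
  )
}

#' Export a spectrum in long format
#'
#' @param spec An `amplitude_spectrum` or `snr_spectrum`.
#' @param channels Optional subset of channel indices.
#' @return Data frame with columns `channel`, `freq_hz`, and `amp` or `snr`.
#' @export
spectrum_table <- function(spec, channels = NULL) {
  mat <- if (inherits(spec, "amplitude_spectrum")) spec$amp else
    if (inherits(spec, "snr_spectrum")) spec$snr else
      stopf("expected an amplitude_spectrum or snr_spectrum")
  value_name <- if (inherits(spec, "amplitude_spectrum")) "amp" else "snr"
  channels <- channels %||% seq_len(nrow(mat))
  out <- data.frame(
    channel = rep(channels, times = length(spec$freqs)),
    freq_hz = rep(spec$freqs, each = length(channels)),
    value = as.vector(mat[channels, , drop = FALSE])
  )
  names(out)[3] <- value_name
  out
}
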