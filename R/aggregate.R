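# ROI/harmonic aggregation of SNR and the learning index.

#' Combine SNR across ROI electrodes and harmonics
#'
#' Averages the SNR over the ROI electrodes at each harmonic bin, then takes
#' the unweighted mean across harmonics. Electrode-then-harmonic and
#' harmonic-then-electrode orderings coincide for equal-weight means.
#'
#' @param snr An `snr_spectrum`.
#' @param roi Integer vector of electrode numbers (1-based channel labels).
#' @param harmonics Numeric vector of harmonic frequencies in Hz; every
#'   harmonic must fall on a defined (unmasked) bin.
#' @return A single positive number.
#' @export
combined_snr <- function(snr, roi, harmonics) {
  if (!inherits(snr, "snr_spectrum")) stopf("expected an `snr_spectrum`")
  if (length(roi) == 0L || length(harmonics) == 0L) {
    stopf("ROI and harmonic set must be non-empty")
  }
  bins <- vapply(harmonics, function(f) freq_bin(snr$freqs, f), 1L)
  vals <- snr$snr[roi, bins, drop = FALSE]
  if (anyNA(vals)) stopf("SNR undefined (masked bin) for a requested harmonic")
  mean(colMeans(vals))
}

#' Learning index: log doublet SNR minus log base SNR
#'
#' The natural-log ratio of doublet-frequency to base-frequency SNR. Zero
#' means equal entrainment at the two rates; positive values mean the
#' pair-structure response dominates the stimulus-driven response. Being a
#' log ratio it is invariant to any common rescaling of the two inputs.
#'
#' @param base_snr,doublet_snr Positive numerics (vectorised).
#' @return `log(doublet_snr) - log(base_snr)`.
#' @export
learning_index <- function(base_snr, doublet_snr) {
  if (!is.numeric(base_snr) || !is.numeric(doublet_snr) ||
      any(!is.finite(base_snr)) || any(!is.finite(doublet_snr)) ||
      any(base_snr <= 0) || any(doublet_snr <= 0)) {
    stopf("SNR inputs must be finite and strictly positive")
  }
  log(doublet_snr) - log(base_snr)
}
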