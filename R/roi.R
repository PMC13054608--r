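# Permutation maximum-statistics thresholding of SNR topographies and ROI
# derivation.

#' Maximum-statistics permutation threshold for SNR topographies
#'
#' Tests, per electrode, whether the group-averaged SNR exceeds 1, with
#' family-wise control over electrodes via the maximum statistic. For each
#' permutation every subject's whole-scalp topography is independently
#' replaced with a unit topography (SNR 1 everywhere) with probability 0.5;
#' the group mean per electrode is computed and its maximum over electrodes
#' recorded. The significance threshold is the `1 - alpha` empirical
#' quantile (linear interpolation between order statistics) of the
#' permutation maxima, and electrodes whose observed group mean strictly
#' exceeds it are declared significant.
#'
#' Note that the unit-replacement scheme yields a data-adaptive threshold
#' that tracks roughly half of the observed peak elevation; it is a
#' signal-localisation device rather than a test with guaranteed nominal
#' family-wise error under a global null (see the methods vignette).
#'
#' @param topos Numeric matrix, subjects x electrodes, of subject-mean SNR
#'   at one frequency and timepoint; values must be positive.
#' @param n_perm Number of permutations (default 10000).
#' @param alpha Significance level in (0, 1).
#' @param seed Optional integer seed for the permutation draws.
#' @return A `max_stat` result: list with `null_max` (the permutation
#'   maxima), `threshold`, `significant` (electrode numbers),
#'   `observed` (group-mean topography), `alpha`, `n_perm`.
#' @export
max_stat_threshold <- function(topos, n_perm = 10000L, alpha = 0.05,
                               seed = NULL) {
  if (!is.matrix(topos) || !is.numeric(topos) || nrow(topos) < 2L) {
    stopf("`topos` must be a numeric subjects x electrodes matrix with >= 2 subjects")
  }
  if (any(!is.finite(topos)) || any(topos <= 0)) {
    stopf("topography values must be finite and positive")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stopf("`alpha` must lie strictly between 0 and 1")
  }
  if (n_perm < 1L) stopf("`n_perm` must be a positive integer")
  if (n_perm < 100L) warnf("n_perm = %d is small; the threshold quantile will be unstable", n_perm)
  n <- nrow(topos)
  maxima <- with_seed(seed, {
    keep <- matrix(stats::runif(n * n_perm) >= 0.5, n, n_perm)
    n_replaced <- n - colSums(keep)
    gm <- (crossprod(keep, topos) + n_replaced) / n
    do.call(pmax, as.data.frame(gm))
  })
  threshold <- unname(stats::quantile(maxima, 1 - alpha, type = 7))
  observed <- colMeans(topos)
  labels <- colnames(topos) %||% seq_len(ncol(topos))
  sig <- which(observed > threshold)
  structure(
    list(
      null_max = maxima,
      threshold = threshold,
      significant = if (is.character(labels)) labels[sig] else as.integer(sig),
      observed = observed,
      alpha = alpha,
      n_perm = as.integer(n_perm)
    ),
    class = "max_stat"
  )
}

#' Derive the analysis ROI from per-condition significance maps
#'
#' Default rule: an electrode enters the ROI when it is significant at BOTH
#' the doublet frequency (3 Hz) and the base frequency (6 Hz) in at least
#' `min_timepoints` of the timepoints.
#'
#' @param significance Named list, one element per timepoint; each element a
#'   named list mapping frequency labels (e.g. `"3"`, `"6"`) to vectors of
#'   significant electrode numbers.
#' @param freqs The two frequency labels that must both be significant
#'   (default `c("3", "6")`).
#' @param min_timepoints Minimum number of timepoints at which the
#'   conjunction must hold (default 2).
#' @return Sorted integer vector of ROI electrode numbers.
#' @export
derive_roi <- function(significance, freqs = c("3", "6"), min_timepoints = 2L) {
  if (!is.list(significance) || length(significance) < min_timepoints) {
    stopf("need significance maps for at least %d timepoints", min_timepoints)
  }
  both <- lapply(significance, function(tp) {
    sets <- lapply(freqs, function(f) {
      if (is.null(tp[[f]])) stopf("significance map missing frequency '%s'", f)
      as.integer(tp[[f]])
    })
    Reduce(intersect, sets)
  })
  tally <- table(unlist(both))
  roi <- sort(as.integer(names(tally)[tally >= min_timepoints]))
  if (length(roi) == 0L) {
    stopf("empty ROI: no electrode is significant at both frequencies in >= %d timepoints",
          min_timepoints)
  }
  roi
}

#' Subject-level SNR topographies at one frequency
#'
#' Builds the subjects x electrodes matrix fed to [max_stat_threshold()]:
#' per subject, the amplitude spectra of all their valid blocks are
#' averaged and the SNR spectrum of the averaged spectrum is read at the
#' target frequency for every electrode. Averaging before taking the ratio
#' keeps the per-electrode SNR statistic nearly unbiased under pure noise.
#'
#' @param spectra_by_subject Named list; per subject, a list of
#'   `amplitude_spectrum` objects.
#' @param freq Target frequency in Hz.
#' @return Numeric matrix, subjects x electrodes.
#' @export
subject_snr_topography <- function(spectra_by_subject, freq) {
  if (length(spectra_by_subject) == 0L) stopf("no subjects given")
  out <- t(vapply(spectra_by_subject, function(specs) {
    amp <- Reduce(`+`, lapply(specs, function(s) s$amp)) / length(specs)
    avg <- structure(
      list(freqs = specs[[1]]$freqs, amp = amp, fs = specs[[1]]$fs,
           n = specs[[1]]$n),
      class = "amplitude_spectrum"
    )
    snr <- snr_spectrum(avg)
    snr$snr[, freq_bin(snr$freqs, freq)]
  }, numeric(nrow(spectra_by_subject[[1]][[1]]$amp))))
  rownames(out) <- names(spectra_by_subject)
  out
}
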