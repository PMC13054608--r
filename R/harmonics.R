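# Wilcoxon-based selection of base and doublet harmonics.

#' Select significant harmonics by one-sample Wilcoxon tests
#'
#' For each candidate frequency (multiples of 3 Hz within 3--24 Hz) a
#' one-sided Wilcoxon signed-rank test checks whether per-subject mean SNR
#' exceeds 1 across subjects. Retained frequencies are partitioned into the
#' base set (multiples of 6 Hz) and the doublet set (multiples of 3 Hz that
#' are not multiples of 6): doublet harmonics overlapping base harmonics are
#' never attributed to the pair structure. When a list of matrices is given
#' (one per timepoint), a frequency is retained only if significant at every
#' timepoint.
#'
#' The exact signed-rank null is used for n <= `exact_max_n` subjects
#' (falling back to the normal approximation when zeros or ties make the
#' exact null unavailable); above that, the normal approximation with
#' continuity correction is used. A frequency whose differences from 1 are
#' all zero is a degenerate test and is never retained.
#'
#' @param snr_means Numeric matrix, subjects x candidate frequencies, with
#'   candidate frequencies (Hz) as column names -- or a named list of such
#'   matrices, one per timepoint.
#' @param alpha Significance level (default 0.05).
#' @param exact_max_n Largest n for the exact null (default 25).
#' @return A `harmonic_selection`: list with `candidate` frequencies,
#'   `base_set`, `doublet_set`, `p_values` (frequencies x timepoints),
#'   `alpha`, and `degenerate` (frequencies with all-zero differences).
#' @export
select_harmonics <- function(snr_means, alpha = 0.05, exact_max_n = 25L) {
  check_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  mats <- if (is.list(snr_means)) snr_means else list(all = snr_means)
  if (is.null(names(mats))) names(mats) <- paste0("group", seq_along(mats))
  freqs <- NULL
  for (m in mats) {
    if (!is.matrix(m) || is.null(colnames(m))) {
      stopf("each SNR matrix needs candidate frequencies as column names")
    }
    f <- as.numeric(colnames(m))
    if (any(is.na(f)) || any(f %% 3 != 0) || any(f < 3 | f > 24)) {
      stopf("candidate frequencies must be multiples of 3 Hz in [3, 24]")
    }
    if (nrow(m) < 6L) stopf("need at least 6 subjects per group for the signed-rank test")
    if (is.null(freqs)) freqs <- f else if (!identical(freqs, f)) {
      stopf("all groups must share the same candidate frequencies")
    }
  }
  pmat <- matrix(NA_real_, length(freqs), length(mats),
                 dimnames = list(as.character(freqs), names(mats)))
  degenerate <- logical(length(freqs))
  for (j in seq_along(mats)) {
    m <- mats[[j]]
    for (i in seq_along(freqs)) {
      d <- m[, i] - 1
      if (all(d == 0)) {
        degenerate[i] <- TRUE
        pmat[i, j] <- 1
        next
      }
      use_exact <- nrow(m) <= exact_max_n && !any(d == 0) && !anyDuplicated(abs(d))
      p <- suppressWarnings(stats::wilcox.test(
        d, alternative = "greater", exact = use_exact, correct = TRUE
      )$p.value)
      pmat[i, j] <- p
    }
  }
  retained <- apply(pmat < alpha, 1, all) & !degenerate
  sel <- freqs[retained]
  structure(
    list(
      candidate = freqs,
      base_set = sel[sel %% 6 == 0],
      doublet_set = sel[sel %% 3 == 0 & sel %% 6 != 0],
      p_values = pmat,
      alpha = alpha,
      degenerate = freqs[degenerate]
    ),
    class = "harmonic_selection"
  )
}

#' @export
print.harmonic_selection <- function(x, ...) {
  cat("Harmonic selection (alpha =", x$alpha, ")\n")
  cat("  base set (multiples of 6 Hz):   ", paste(x$base_set, collapse = ", "), "\n")
  cat("  doublet set (odd multiples of 3):", paste(x$doublet_set, collapse = ", "), "\n")
  invisible(x)
}

#' Per-subject mean SNR at candidate frequencies
#'
#' Aggregation used upstream of harmonic selection: for each subject the
#' amplitude spectra of all their valid blocks are averaged, the average
#' spectrum is additionally averaged over the given channels, an SNR
#' spectrum is computed from that averaged spectrum, and the SNR is read at
#' the candidate frequencies. Computing the ratio on averaged spectra keeps
#' the SNR statistic essentially unbiased under pure noise (the inverse
#' noise-floor estimate's small-sample bias vanishes with averaging), so the
#' selection test holds its nominal level.
#'
#' @param spectra_by_subject Named list; per subject, a list of
#'   `amplitude_spectrum` objects (that subject's valid blocks).
#' @param channels Channel set to average over (default the a-priori
#'   occipital channels).
#' @param candidate_freqs Candidate frequencies in Hz.
#' @return Matrix subjects x frequencies, column names the frequencies.
#' @export
subject_mean_snr <- function(spectra_by_subject,
                             channels = occipital_channels(),
                             candidate_freqs = seq(3, 24, by = 3)) {
  if (length(spectra_by_subject) == 0L) stopf("no subjects given")
  out <- t(vapply(spectra_by_subject, function(specs) {
    amp <- Reduce(`+`, lapply(specs, function(s) s$amp)) / length(specs)
    chan_mean <- colMeans(amp[channels, , drop = FALSE])
    avg_spec <- structure(
      list(freqs = specs[[1]]$freqs, amp = matrix(chan_mean, nrow = 1),
           fs = specs[[1]]$fs, n = specs[[1]]$n),
      class = "amplitude_spectrum"
    )
    snr <- snr_spectrum(avg_spec)
    bins <- vapply(candidate_freqs, function(f) freq_bin(snr$freqs, f), 1L)
    snr$snr[1, bins]
  }, numeric(length(candidate_freqs))))
  colnames(out) <- as.character(candidate_freqs)
  out
}
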