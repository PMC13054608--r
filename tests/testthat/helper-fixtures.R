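# Shared fixtures: hand-built spectra and draws from the null sampling
# distribution of the SNR statistic (Rayleigh amplitude over the mean of
# 10 neighbouring Rayleigh amplitudes).

# Rayleigh draws with unit scale (modulus of a circular complex Gaussian).
ray <- function(n) sqrt(stats::rexp(n))

# Amplitude spectrum object from a channels x bins matrix (0.05 Hz bins).
make_amp_spectrum <- function(amp, fs = 1000) {
  structure(
    list(freqs = (seq_len(ncol(amp)) - 1) * 0.05, amp = amp, fs = fs,
         n = (ncol(amp) - 1) * 2),
    class = "amplitude_spectrum"
  )
}

# SNR spectrum with constant or supplied values over a small grid.
make_snr_spectrum <- function(snr) {
  nb <- ncol(snr)
  valid <- rep(FALSE, nb)
  valid[7:(nb - 6)] <- TRUE
  snr[, !valid] <- NA_real_
  structure(
    list(freqs = (seq_len(nb) - 1) * 0.05, snr = snr, valid = valid),
    class = "snr_spectrum"
  )
}

# Null per-subject SNR values as produced by the averaged-spectrum
# aggregation: ratio of the mean of `n_num` tagged-bin amplitudes to the
# mean of `10 * n_num` neighbour amplitudes, per subject.
null_subject_snr <- function(n_subjects, n_num) {
  num <- rowMeans(matrix(ray(n_subjects * n_num), ncol = n_num))
  den <- rowMeans(matrix(ray(n_subjects * n_num * 10), ncol = n_num * 10))
  num / den
}

# Null subjects x electrodes topography matrix under the same construction.
null_topography <- function(n_subjects, n_electrodes, n_blocks) {
  num <- rowMeans(matrix(ray(n_subjects * n_electrodes * n_blocks), ncol = n_blocks))
  den <- rowMeans(matrix(ray(n_subjects * n_electrodes * n_blocks * 10),
                         ncol = n_blocks * 10))
  matrix(num / den, n_subjects, n_electrodes)
}

# Block-feature table generated from known fixed effects with near-zero
# noise, for exact-recovery model tests.
exact_lmm_data <- function(beta, n_subjects = 20, n_blocks = 8,
                           residual_sd = 1e-8, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    tp <- rep(c("T1", "T2", "T3"), length.out = n_subjects)
    df <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                      valid_order = seq_len(n_blocks),
                      stringsAsFactors = FALSE)
    df$timepoint <- tp[match(df$subject, sprintf("S%02d", seq_len(n_subjects)))]
    df$block_order_c <- df$valid_order - mean(df$valid_order)
    df$looking_c <- round(stats::runif(nrow(df), -5, 5), 3)
    df$looking_c <- df$looking_c - mean(df$looking_c)
    t2 <- as.integer(df$timepoint == "T2")
    t3 <- as.integer(df$timepoint == "T3")
    X <- cbind(1, t2, t3, df$block_order_c, df$looking_c,
               t2 * df$block_order_c, t3 * df$block_order_c)
    df$log_base_snr <- drop(X %*% beta) + stats::rnorm(nrow(df), 0, residual_sd)
    df
  })
}
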