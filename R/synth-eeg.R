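# Waveform-level synthesis: Rice-mean amplitude calibration, 1/f noise and
# frequency-tagged EEG blocks.

#' Mean of the Rice distribution
#'
#' Expected modulus of `nu * exp(i phi) + Z` where `Z` is a circular complex
#' Gaussian with per-component standard deviation `sigma`. Evaluated via
#' the closed form with exponentially scaled Bessel functions, so it is
#' stable for large non-centrality.
#'
#' @param nu Non-centrality (deterministic amplitude), >= 0, vectorised.
#' @param sigma Noise component standard deviation, >= 0.
#' @return Expected modulus.
#' @export
rice_mean <- function(nu, sigma) {
  if (any(nu < 0) || any(sigma < 0)) stopf("`nu` and `sigma` must be non-negative")
  if (length(sigma) == 1L) sigma <- rep(sigma, length(nu))
  out <- numeric(length(nu))
  zero_sd <- sigma == 0
  out[zero_sd] <- nu[zero_sd]
  if (any(!zero_sd)) {
    n <- nu[!zero_sd]
    s <- sigma[!zero_sd]
    x <- n^2 / (2 * s^2)
    # sqrt(pi/2) * sigma * exp(-x/2) * ((1+x) I0(x/2) + x I1(x/2))
    b0 <- besselI(x / 2, 0, expon.scaled = TRUE)
    b1 <- besselI(x / 2, 1, expon.scaled = TRUE)
    out[!zero_sd] <- sqrt(pi / 2) * s * ((1 + x) * b0 + x * b1)
  }
  out
}

#' Calibrate a sinusoid amplitude for a target spectral SNR
#'
#' Returns the deterministic sinusoid amplitude `a` such that the expected
#' amplitude at the tagged bin -- the mean of the Rice-distributed modulus
#' of signal plus complex spectral noise -- equals
#' `target_snr * noise_floor_amp`. Solved by monotone numerical inversion to
#' a relative tolerance of 1e-6. A target of 1 returns 0: noise alone
#' attains its own floor.
#'
#' @param target_snr Target SNR, >= 1.
#' @param noise_floor_amp Expected noise amplitude at the bin (the local
#'   noise floor), > 0.
#' @param noise_sd Per-component standard deviation of the complex spectral
#'   noise at the bin. Defaults to the value consistent with the floor
#'   (`noise_floor_amp * sqrt(2 / pi)`, the Rayleigh relation).
#' @return The calibrated amplitude (same units as `noise_floor_amp`),
#'   vectorised over `target_snr`.
#' @export
calibrate_amplitude <- function(target_snr, noise_floor_amp,
                                noise_sd = noise_floor_amp * sqrt(2 / pi)) {
  if (any(!is.finite(target_snr)) || any(target_snr < 1)) {
    stopf("`target_snr` must be >= 1 (the noise floor itself has SNR 1)")
  }
  check_scalar_number(noise_floor_amp, "noise_floor_amp", lower = 1e-300)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  vapply(target_snr, function(s) {
    target <- s * noise_floor_amp
    if (rice_mean(0, noise_sd) >= target) return(0)
    upper <- target + 6 * noise_sd
    stats::uniroot(
      function(a) rice_mean(a, noise_sd) - target,
      lower = 0, upper = upper,
      tol = 1e-6 * max(target, 1e-12)
    )$root
  }, numeric(1))
}

# Amplitude noise floor profile: scale / f^exponent + floor (0 at DC).
noise_amp_profile <- function(freqs, noise) {
  mu <- ifelse(freqs > 0, noise$scale / freqs^noise$exponent + noise$floor, 0)
  mu
}

# Relative inverse-mean bias of the 10-neighbour-bin noise-floor estimate:
# E[mu / mean(10 Rayleigh)] from a third-order delta expansion. The
# measured SNR of a calibrated bin exceeds the numerator target by this
# factor, so block synthesis divides targets by it.
snr_floor_bias <- function(n_neighbours = 10L) {
  relvar <- (4 / pi - 1) / n_neighbours       # relative variance of the mean
  skewness <- 2 * sqrt(pi) * (pi - 3) / (4 - pi)^1.5
  relmu3 <- skewness * (4 / pi - 1)^1.5 / n_neighbours^2
  1 + relvar - relmu3
}

#' Simulate one frequency-tagged EEG block
#'
#' Synthesises a 128-channel, 20-s block at 1000 Hz: calibrated sinusoids at
#' the base harmonics (6, 12, 18, 24 Hz) and doublet harmonics (3, 9, 15,
#' 21 Hz) scaled by the occipital channel gain map, plus 1/f-profiled
#' complex Gaussian noise with a white floor. Per-channel harmonic
#' amplitudes are calibrated (via the Rice mean, including the small
#' inverse-mean bias of the neighbour-bin floor estimate) so that the
#' expected measured log SNR -- ROI-averaged, harmonic-averaged -- matches
#' the requested targets at full-gain channels.
#'
#' @param params A `generative_params` object.
#' @param subject,timepoint,block Metadata stored in the block.
#' @param looking_s Looking time stored in the block.
#' @param target_log_base_snr,target_log_doublet_snr Natural-log SNR targets
#'   for the harmonic-averaged base and doublet responses at full-gain
#'   channels. `-Inf` or `log(1) = 0` yields no injected signal.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   blocks.
#' @return An [eeg_block()].
#' @export
simulate_block_eeg <- function(params, subject = "S01", timepoint = "T1",
                               block = 1L, looking_s = 20,
                               target_log_base_snr = 0,
                               target_log_doublet_snr = 0,
                               seed = NULL) {
  if (!inherits(params, "generative_params")) stopf("expected `generative_params`")
  fs <- params$fs
  n <- 20L * fs
  nchan <- params$n_channels
  gain <- params$gain / max(params$gain)
  base_f <- as.numeric(names(params$harmonic_weights$base))
  dbl_f <- as.numeric(names(params$harmonic_weights$doublet))
  bias <- snr_floor_bias()

  with_seed(seed, {
    ## --- noise: complex spectral coefficients with 1/f amplitude profile
    nb <- n %/% 2L
    fgrid <- (1:(nb - 1)) * fs / n
    mu <- noise_amp_profile(fgrid, params$noise)
    # one-sided amplitude 2|Z|/n has mean mu  =>  component sd of Z
    comp_sd <- n * mu / (2 * sqrt(pi / 2))
    Z <- matrix(complex(
      real = stats::rnorm((nb - 1) * nchan),
      imaginary = stats::rnorm((nb - 1) * nchan)
    ), nb - 1L, nchan) * comp_sd
    X <- matrix(0 + 0i, n, nchan)
    X[2:nb, ] <- Z
    X[(n:(nb + 2)), ] <- Conj(Z)
    noise_t <- Re(stats::mvfft(X, inverse = TRUE)) / n

    ## --- signal: calibrated sinusoids per harmonic and channel
    tvec <- (0:(n - 1)) / fs
    data <- t(noise_t)
    add_harmonics <- function(data, freqs, weights, target_log) {
      s_total <- exp(target_log)
      if (!is.finite(s_total) || s_total <= 1) return(data)
      w <- weights / mean(weights)
      for (k in seq_along(freqs)) {
        f <- freqs[k]
        # per-channel SNR target, bias-corrected for the floor estimate
        s_chan <- 1 + gain * w[k] * (s_total - 1)
        s_chan <- pmax(1, s_chan / bias)
        floor_amp <- noise_amp_profile(f, params$noise)
        uniq <- unique(round(s_chan, 12))
        amp_u <- calibrate_amplitude(uniq, floor_amp)
        amps <- amp_u[match(round(s_chan, 12), uniq)]
        phi <- stats::runif(1, 0, 2 * pi)
        wave <- cos(2 * pi * f * tvec + phi)
        data <- data + outer(amps, wave)
      }
      data
    }
    data <- add_harmonics(data, base_f, params$harmonic_weights$base,
                          target_log_base_snr)
    data <- add_harmonics(data, dbl_f, params$harmonic_weights$doublet,
                          target_log_doublet_snr)
    eeg_block(data, fs = fs, subject = subject, timepoint = timepoint,
              block = block, looking_s = looking_s)
  })
}
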