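# Generative parameters of the synthetic longitudinal cohort.

#' Occipital channel gain map
#'
#' Per-channel gain of the frequency-tagged signal, concentrated on the
#' medial occipital electrodes: the seven-electrode ROI cluster carries the
#' full response (gain 1), the remaining a-priori occipital electrodes a
#' tapered response (gain 0.5), and all other channels none. The map is
#' normalised to its maximum wherever it is used, so rescaling all gains by
#' a common factor leaves every simulated SNR unchanged.
#'
#' @param n_channels Number of channels (default 128).
#' @param plateau,taper Gains of the cluster and of the surrounding
#'   occipital ring.
#' @return Numeric vector of length `n_channels`.
#' @export
occipital_gain_map <- function(n_channels = 128L, plateau = 1, taper = 0.5) {
  g <- numeric(n_channels)
  ring <- setdiff(occipital_channels(), roi_cluster_channels())
  g[roi_cluster_channels()] <- plateau
  g[ring] <- taper
  g
}

# Fixed-effect vectors share this layout: intercept, T2 and T3 offsets from
# T1, centred block-order slope, centred looking-time slope (s^-1), and the
# two timepoint-by-order interactions. Units: natural-log SNR.
fixef_names <- c("intercept", "t2", "t3", "block", "looking", "t2_block", "t3_block")

#' Generative parameters for synthetic cohorts
#'
#' Bundles every constant of the simulator. The defaults reproduce the
#' fitted longitudinal models of the base-frequency response, the
#' doublet-frequency response and the learning index, the cohort structure
#' (30/27/23 infants across three timepoints, ~8 familiarization blocks per
#' session), the long-run valid-block rate (76.42%), and a per-timepoint
#' linear link from the learning index to the behavioural novelty-preference
#' score.
#'
#' The learning index is never drawn directly: it is the difference of the
#' log doublet and log base outcomes. Its variance components are induced by
#' correlating the two outcomes' random intercepts and residuals, with
#' covariances chosen so that the difference has exactly the requested
#' `li_vc` components: `cov = (var_base + var_doublet - var_li) / 2`.
#'
#' @param base_fixed,doublet_fixed Named numeric vectors of the seven fixed
#'   effects on log SNR (see Details for the layout).
#' @param base_vc,doublet_vc,li_vc Variance components
#'   `c(intercept = ..., residual = ...)` of the three outcomes.
#' @param behaviour List with per-timepoint `intercepts` and `slopes` of the
#'   preference-score-on-learning-index link (seconds and seconds per log
#'   unit), `residual_sd` of the preference score, `trial_base_s` (mean
#'   per-trial looking) and `trial_sd_s`.
#' @param cohort List with `n_t` (subjects per timepoint, monotone
#'   attrition), `invalid_p` (per-block probability of failing the
#'   valid-block filter), `behav_fail_share` (share of invalid blocks that
#'   fail the looking criterion rather than the electrophysiological one),
#'   `looking_shape` (Beta shape parameters of core looking on [7, 20] s for
#'   attended blocks), `min_blocks`, `max_blocks`, `criterion_s`.
#' @param noise List with 1/f `exponent`, `scale` and white `floor`
#'   (amplitude units).
#' @param harmonic_weights List with relative per-harmonic response weights
#'   for the `base` set (6/12/18/24 Hz) and `doublet` set (3/9/15/21 Hz);
#'   normalised to mean 1 internally so the harmonic-averaged SNR matches
#'   the per-block target.
#' @param gain Channel gain map (see [occipital_gain_map()]).
#' @param fs Sampling rate in Hz.
#' @param n_channels Channel count.
#' @param looking_coef_alt Alternative (text-reported) looking-time
#'   coefficient, exposed for sensitivity analyses; the tabled value in
#'   `base_fixed["looking"]` is the default generative one.
#' @return A validated `generative_params` list.
#' @export
generative_params <- function(
    base_fixed = c(intercept = 0.302, t2 = 0.100, t3 = 0.002,
                   block = -0.024, looking = 0.029,
                   t2_block = 0.001, t3_block = 0.025),
    doublet_fixed = c(intercept = 0.152, t2 = 0.060, t3 = 0.083,
                      block = -0.013, looking = 0.018,
                      t2_block = -0.006, t3_block = 0.027),
    base_vc = c(intercept = 0.013, residual = 0.043),
    doublet_vc = c(intercept = 0.010, residual = 0.042),
    li_vc = c(intercept = 0.006, residual = 0.066),
    behaviour = list(
      intercepts = c(t1 = -0.070, t2 = 0.692, t3 = 0.484),
      slopes = c(t1 = -0.969, t2 = 1.672, t3 = 4.421),
      residual_sd = 0.75,
      trial_base_s = 3.5,
      trial_sd_s = 1.0
    ),
    cohort = list(
      n_t = c(30L, 27L, 23L),
      invalid_p = 0.2358,
      behav_fail_share = 0.5,
      looking_shape = c(2.6, 0.8),
      min_blocks = 8L,
      max_blocks = 15L,
      criterion_s = 120
    ),
    noise = list(exponent = 1, scale = 0.6, floor = 0.02),
    harmonic_weights = list(
      base = c(`6` = 2.6, `12` = 0.6, `18` = 0.5, `24` = 0.3),
      doublet = c(`3` = 1.2, `9` = 1.8, `15` = 0.6, `21` = 0.4)
    ),
    gain = occipital_gain_map(),
    fs = 1000,
    n_channels = 128L,
    looking_coef_alt = 0.485) {
  for (v in list(base_fixed, doublet_fixed)) {
    if (!identical(names(v), fixef_names)) {
      stopf("fixed-effect vectors must be named %s", paste(fixef_names, collapse = ", "))
    }
  }
  for (vc in list(base_vc, doublet_vc, li_vc)) {
    if (any(vc < 0)) stopf("variance components must be non-negative")
  }
  if (cohort$invalid_p < 0 || cohort$invalid_p > 1 ||
      cohort$behav_fail_share < 0 || cohort$behav_fail_share > 1) {
    stopf("probabilities must lie in [0, 1]")
  }
  if (any(diff(cohort$n_t) > 0)) stopf("cohort sizes must be non-increasing (monotone attrition)")
  if (any(cohort$looking_shape <= 0)) stopf("looking Beta shapes must be positive")
  p <- list(
    base_fixed = base_fixed, doublet_fixed = doublet_fixed,
    base_vc = base_vc, doublet_vc = doublet_vc, li_vc = li_vc,
    behaviour = behaviour, cohort = cohort, noise = noise,
    harmonic_weights = harmonic_weights, gain = gain,
    fs = fs, n_channels = as.integer(n_channels),
    looking_coef_alt = looking_coef_alt
  )
  cv <- li_covariances(p)
  if (cv$rho_u > 1 || cv$rho_e > 1 || cv$rho_u < -1 || cv$rho_e < -1) {
    stopf("requested variance components imply an invalid correlation between outcomes")
  }
  class(p) <- "generative_params"
  p
}

#' Covariances linking the base and doublet outcomes
#'
#' Covariances of the random intercepts and residuals of the two log-SNR
#' outcomes implied by the requested learning-index variance components
#' (`var(d - b) = var_d + var_b - 2 cov`).
#'
#' @param params A `generative_params` object.
#' @return List with `cov_u`, `cov_e` and the corresponding correlations
#'   `rho_u`, `rho_e`.
#' @export
li_covariances <- function(params) {
  cov_u <- (params$base_vc[["intercept"]] + params$doublet_vc[["intercept"]] -
              params$li_vc[["intercept"]]) / 2
  cov_e <- (params$base_vc[["residual"]] + params$doublet_vc[["residual"]] -
              params$li_vc[["residual"]]) / 2
  list(
    cov_u = cov_u,
    cov_e = cov_e,
    rho_u = cov_u / sqrt(params$base_vc[["intercept"]] * params$doublet_vc[["intercept"]]),
    rho_e = cov_e / sqrt(params$base_vc[["residual"]] * params$doublet_vc[["residual"]])
  )
}

# Implied fixed effects of the learning index (difference of the two
# outcome models); used by tests and documentation.
implied_li_fixed <- function(params) {
  params$doublet_fixed - params$base_fixed
}
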