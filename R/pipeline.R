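# End-to-end orchestration: simulate -> spectra -> validate -> harmonics ->
# ROI -> aggregate -> models -> behaviour, seeded and logged.

#' Configuration of a pipeline run
#'
#' Collects every analysis constant with the protocol's standard values as
#' defaults; each is overridable. `n_perm = 0` (or other out-of-range
#' constants) fail validation before any simulation starts.
#'
#' @param seed Master seed of the run.
#' @param mode `"fast"` (generative features) or `"full"` (waveform
#'   synthesis + spectral chain).
#' @param params [generative_params()] for the simulated cohort.
#' @param snr_threshold Electrophysiological valid-block threshold at 6 Hz.
#' @param looking_min_s Behavioural valid-block threshold (s).
#' @param alpha Significance level shared by harmonic selection and
#'   max-statistics.
#' @param n_perm Permutations for the maximum-statistics threshold.
#' @param candidate_freqs Candidate harmonics (Hz) for selection.
#' @param roi Electrode set used for aggregation in fast mode (full mode
#'   derives it from the data).
#' @param roi_min_timepoints Conjunction rule for ROI derivation.
#' @param max_order Valid-block order truncation.
#' @param min_valid Minimum valid blocks per participant-timepoint.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A validated `ft_run_config`.
#' @export
run_config <- function(seed = 1L, mode = c("fast", "full"),
                       params = generative_params(),
                       snr_threshold = 2, looking_min_s = 7, alpha = 0.05,
                       n_perm = 10000L, candidate_freqs = seq(3, 24, by = 3),
                       roi = roi_cluster_channels(), roi_min_timepoints = 2L,
                       max_order = 8L, min_valid = 2L, out_dir = NULL) {
  mode <- match.arg(mode)
  check_scalar_number(seed, "seed")
  check_scalar_number(snr_threshold, "snr_threshold", lower = 0)
  check_scalar_number(looking_min_s, "looking_min_s", 0, 20)
  check_scalar_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  check_scalar_number(n_perm, "n_perm", lower = 1)
  if (length(candidate_freqs) == 0L) stopf("empty candidate frequency set")
  if (length(roi) == 0L) stopf("empty ROI")
  structure(
    list(seed = as.integer(seed), mode = mode, params = params,
         snr_threshold = snr_threshold, looking_min_s = looking_min_s,
         alpha = alpha, n_perm = as.integer(n_perm),
         candidate_freqs = candidate_freqs, roi = roi,
         roi_min_timepoints = roi_min_timepoints,
         max_order = max_order, min_valid = min_valid, out_dir = out_dir),
    class = "ft_run_config"
  )
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Deterministic given the master seed. In fast mode the generative block
#' features feed the models directly and the configured harmonic sets and
#' ROI are used; in full mode the EEG waveforms pass through the spectral
#' chain, valid-block filter, harmonic selection and maximum-statistics ROI
#' derivation before aggregation. Fits the base, doublet and learning-index
#' models, the behavioural preference model, and the brain-behaviour link
#' with its simple slopes; writes CSV/JSON artifacts when `out_dir` is set.
#'
#' @param config A [run_config()].
#' @return List with `cohort`, `block_table`, `harmonics`, `roi`, `fits`,
#'   `behaviour`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "ft_run_config")) stopf("expected a `ft_run_config`")
  cohort <- simulate_cohort(config$params, seed = config$seed,
                            mode = config$mode)
  harmonic_sets <- list(base = c(6, 12, 18, 24), doublet = c(3, 9, 15, 21))
  roi <- config$roi
  harm_sel <- NULL
  if (config$mode == "full") {
    ## Stream the waveforms: each block is transformed once, reduced to the
    ## bins the analysis needs, and its waveform released, so memory stays
    ## bounded by one full spectrum plus per-subject running averages.
    raw <- cohort$raw
    freqs_needed <- sort(unique(c(config$candidate_freqs, 3, 6)))
    blocks <- vector("list", nrow(raw))
    amp_sum <- list() # per subject x timepoint, over valid blocks
    amp_n <- list()
    proto <- NULL
    for (i in seq_len(nrow(raw))) {
      spec <- amplitude_spectrum(cohort$eeg[[i]])
      cohort$eeg[i] <- list(NULL)
      snr <- reduce_snr_spectrum(snr_spectrum(spec), freqs_needed)
      blocks[[i]] <- list(snr = snr, subject = raw$subject[i],
                          timepoint = raw$timepoint[i],
                          raw_block = raw$raw_block[i],
                          looking_s = raw$looking_s[i])
      v <- validate_block(snr, raw$looking_s[i],
                          snr_threshold = config$snr_threshold,
                          looking_min_s = config$looking_min_s)
      if (v$valid) {
        key <- paste(raw$subject[i], raw$timepoint[i], sep = "|")
        if (is.null(amp_sum[[key]])) {
          amp_sum[[key]] <- spec$amp
          amp_n[[key]] <- 1L
        } else {
          amp_sum[[key]] <- amp_sum[[key]] + spec$amp
          amp_n[[key]] <- amp_n[[key]] + 1L
        }
        if (is.null(proto)) proto <- spec[c("freqs", "fs", "n")]
      }
    }
    cohort$eeg <- NULL
    avg_spec <- function(key) {
      structure(
        list(freqs = proto$freqs, amp = amp_sum[[key]] / amp_n[[key]],
             fs = proto$fs, n = proto$n),
        class = "amplitude_spectrum"
      )
    }
    keys <- names(amp_sum)
    key_subject <- sub("\\|.*$", "", keys)
    key_tp <- sub("^.*\\|", "", keys)

    ## harmonic selection on per-subject averaged spectra
    harm_sel <- tryCatch({
      by_subject <- lapply(split(keys, key_subject), function(ks) {
        lapply(ks, avg_spec)
      })
      sm <- subject_mean_snr(by_subject, candidate_freqs = config$candidate_freqs)
      select_harmonics(sm, alpha = config$alpha)
    }, error = function(e) {
      warnf("harmonic selection skipped (%s); using the configured sets",
            conditionMessage(e))
      NULL
    })
    ## data-driven ROI: max-statistics at 3 and 6 Hz per timepoint,
    ## conjunction rule across timepoints; configured ROI as fallback
    roi <- tryCatch({
      sig <- list()
      for (tp in unique(key_tp)) {
        bys <- lapply(split(keys[key_tp == tp], key_subject[key_tp == tp]),
                      function(ks) lapply(ks, avg_spec))
        sig[[tp]] <- lapply(c(`3` = 3, `6` = 6), function(f) {
          topos <- subject_snr_topography(bys, f)
          max_stat_threshold(topos, n_perm = config$n_perm,
                             alpha = config$alpha)$significant
        })
      }
      derive_roi(sig, min_timepoints = min(config$roi_min_timepoints, length(sig)))
    }, error = function(e) {
      warnf("ROI derivation failed (%s); using the configured ROI", conditionMessage(e))
      config$roi
    })
    if (!is.null(harm_sel) &&
        length(harm_sel$base_set) && length(harm_sel$doublet_set)) {
      harmonic_sets <- list(base = harm_sel$base_set,
                            doublet = harm_sel$doublet_set)
    }
    block_table <- build_block_table(
      blocks, roi = roi,
      base_harmonics = harmonic_sets$base,
      doublet_harmonics = harmonic_sets$doublet,
      snr_threshold = config$snr_threshold,
      looking_min_s = config$looking_min_s,
      max_order = config$max_order, min_valid = config$min_valid
    )
  } else {
    block_table <- cohort$blocks
  }

  fits <- list(
    base = fit_base_model(block_table),
    doublet = fit_doublet_model(block_table),
    learning_index = fit_li_model(block_table)
  )

  behaviour <- NULL
  if (!is.null(cohort$trials)) {
    scores <- cohort_preference_scores(cohort)
    tests <- timepoint_tests(scores$preference, scores$timepoint)
    bb <- fit_brain_behaviour_model(scores)
    behaviour <- list(
      scores = scores,
      tests = tests,
      preference_fit = fit_preference_model(scores),
      brain_behaviour_fit = bb,
      simple_slopes = simple_slopes(bb)
    )
  }

  manifest <- list(
    seed = config$seed,
    mode = config$mode,
    n_sessions = nrow(cohort$sessions),
    n_blocks_recorded = nrow(cohort$raw),
    n_blocks_valid = sum(cohort$raw$valid),
    n_blocks_retained = nrow(block_table),
    valid_pct = valid_block_rate(sum(cohort$raw$valid), nrow(cohort$raw)),
    harmonics = harmonic_sets,
    roi = roi,
    grand_means = as.list(attr(block_table, "grand_means")),
    constants = list(
      snr_threshold = config$snr_threshold,
      looking_min_s = config$looking_min_s,
      alpha = config$alpha, n_perm = config$n_perm,
      max_order = config$max_order, min_valid = config$min_valid
    )
  )

  result <- list(cohort = cohort, block_table = block_table,
                 harmonics = harm_sel, roi = roi, fits = fits,
                 behaviour = behaviour, manifest = manifest)
  if (!is.null(config$out_dir)) write_run_artifacts(result, config$out_dir)
  result
}

# CSV/JSON export of a pipeline run.
write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$block_table,
                   file.path(out_dir, "block_table.csv"), row.names = FALSE)
  if (!is.null(result$behaviour)) {
    utils::write.csv(result$behaviour$scores,
                     file.path(out_dir, "preference_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(result$behaviour$tests,
                     file.path(out_dir, "timepoint_tests.csv"),
                     row.names = FALSE)
  }
  model_report <- lapply(result$fits, function(f) {
    list(formula = paste(deparse(f$formula), collapse = ""),
         coefficients = f$coefficients,
         varcomp = as.list(f$varcomp), icc = f$icc, aic = f$aic,
         degenerate = f$degenerate)
  })
  jsonlite::write_json(model_report, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(attr(result$block_table, "filter_report"),
                       file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
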