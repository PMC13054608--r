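# Valid-block filtering and construction of the block-level analysis table.

#' A-priori medial occipital channels (EGI-128 labels)
#'
#' The ten occipital electrodes used for the electrophysiological
#' valid-block criterion.
#' @return Integer vector of channel numbers.
#' @export
occipital_channels <- function() c(69L, 70L, 73L, 74L, 75L, 81L, 82L, 83L, 88L, 89L)

#' Default medial occipital ROI cluster (EGI-128 labels)
#'
#' The seven-electrode cluster showing significant SNR at both 3 and 6 Hz
#' across timepoints, used for ROI-averaged SNR.
#' @return Integer vector of channel numbers.
#' @export
roi_cluster_channels <- function() c(70L, 71L, 74L, 75L, 76L, 82L, 83L)

#' Two-criterion valid-block check
#'
#' A familiarization block is valid when (i) the 6-Hz SNR exceeds 2 in at
#' least one of the a-priori occipital channels (electrophysiological
#' criterion) and (ii) the infant looked for at least 7 s of the 20-s core
#' (behavioural criterion).
#'
#' @param snr An `snr_spectrum` for the block.
#' @param looking_s Looking time within the core, seconds.
#' @param channels Channel set for the electrophysiological criterion.
#' @param snr_threshold SNR threshold at the base frequency (default 2).
#' @param looking_min_s Minimum looking time (default 7 s).
#' @param base_freq Base stimulation frequency in Hz (default 6).
#' @return List with `electrophys_pass`, `looking_pass`, `valid`.
#' @export
validate_block <- function(snr, looking_s, channels = occipital_channels(),
                           snr_threshold = 2, looking_min_s = 7,
                           base_freq = 6) {
  if (!inherits(snr, "snr_spectrum")) stopf("expected an `snr_spectrum`")
  check_scalar_number(looking_s, "looking_s", 0, 20)
  bin <- freq_bin(snr$freqs, base_freq)
  vals <- snr$snr[channels, bin]
  if (anyNA(vals)) stopf("SNR undefined at the %s-Hz bin", base_freq)
  ep <- any(vals > snr_threshold)
  lp <- looking_s >= looking_min_s
  list(electrophys_pass = ep, looking_pass = lp, valid = ep && lp)
}

#' Build the block-level analysis table from SNR spectra
#'
#' Applies the two-criterion valid-block filter, drops participants with
#' fewer than two valid blocks at a timepoint, renumbers valid blocks 1..n
#' in raw presentation order, truncates at order 8, computes ROI/harmonic
#' combined SNR on base and doublet harmonics, log-transforms, derives the
#' learning index, and mean-centres block order and looking time at the
#' grand mean over retained rows.
#'
#' @param blocks List of per-block records, each a list with elements `snr`
#'   (an `snr_spectrum`), `subject`, `timepoint`, `raw_block`, `looking_s`.
#' @param roi Electrode set for SNR aggregation.
#' @param base_harmonics,doublet_harmonics Harmonic sets in Hz.
#' @param snr_threshold,looking_min_s Valid-block criteria.
#' @param max_order Truncation of valid-block order (default 8).
#' @param min_valid Minimum valid blocks per participant-timepoint
#'   (default 2).
#' @param center `"grand"` (one dataset-wide mean, the default) or
#'   `"timepoint"`.
#' @return A `block_table` data frame; see [finalize_block_table()] for the
#'   columns and attributes.
#' @export
build_block_table <- function(blocks, roi = roi_cluster_channels(),
                              base_harmonics = c(6, 12, 18, 24),
                              doublet_harmonics = c(3, 9, 15, 21),
                              snr_threshold = 2, looking_min_s = 7,
                              max_order = 8L, min_valid = 2L,
                              center = c("grand", "timepoint")) {
  if (length(roi) == 0L || length(base_harmonics) == 0L ||
      length(doublet_harmonics) == 0L) {
    stopf("ROI and harmonic sets must be non-empty")
  }
  rows <- lapply(blocks, function(b) {
    v <- validate_block(b$snr, b$looking_s, snr_threshold = snr_threshold,
                        looking_min_s = looking_min_s)
    base <- combined_snr(b$snr, roi, base_harmonics)
    dbl <- combined_snr(b$snr, roi, doublet_harmonics)
    data.frame(
      subject = b$subject, timepoint = b$timepoint,
      raw_block = b$raw_block, looking_s = b$looking_s,
      electrophys_pass = v$electrophys_pass, looking_pass = v$looking_pass,
      valid = v$valid,
      log_base_snr = log(base), log_doublet_snr = log(dbl),
      stringsAsFactors = FALSE
    )
  })
  finalize_block_table(do.call(rbind, rows), max_order = max_order,
                       min_valid = min_valid, center = match.arg(center))
}

#' Finalize a block-feature table
#'
#' Shared tail of the analysis-table construction, also used on fast-mode
#' synthetic features: filter valid blocks, enforce the participant minimum,
#' renumber, truncate, and centre. The input must have columns `subject`,
#' `timepoint`, `raw_block`, `looking_s`, `valid`, `log_base_snr`,
#' `log_doublet_snr` (and optionally the per-criterion pass flags).
#'
#' @param df Data frame of per-block features, one row per recorded block.
#' @param max_order,min_valid,center See [build_block_table()].
#' @return A `block_table`: retained rows with added columns `valid_order`
#'   (1-based position among valid blocks), `block_order_c` (centred order,
#'   the model's Block Order), `looking_c` (centred looking time) and
#'   `learning_index`. Attributes: `grand_means`, `filter_report`.
#' @export
finalize_block_table <- function(df, max_order = 8L, min_valid = 2L,
                                 center = c("grand", "timepoint")) {
  center <- match.arg(center)
  needed <- c("subject", "timepoint", "raw_block", "looking_s", "valid",
              "log_base_snr", "log_doublet_snr")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) stopf("missing columns: %s", paste(missing_cols, collapse = ", "))
  df <- df[order(df$subject, df$timepoint, df$raw_block), , drop = FALSE]

  report <- filter_counts(df)

  kept <- df[df$valid, , drop = FALSE]
  if (nrow(kept) > 0L) {
    grp <- interaction(kept$subject, kept$timepoint, drop = TRUE)
    kept$valid_order <- stats::ave(seq_len(nrow(kept)), grp, FUN = seq_along)
    n_valid <- stats::ave(rep(1L, nrow(kept)), grp, FUN = sum)
    kept <- kept[n_valid >= min_valid, , drop = FALSE]
    kept <- kept[kept$valid_order <= max_order, , drop = FALSE]
  }
  if (nrow(kept) == 0L) {
    warnf("no blocks retained after filtering")
    out <- kept
    attr(out, "grand_means") <- c(block_order = NA_real_, looking_s = NA_real_)
    attr(out, "filter_report") <- report
    class(out) <- c("block_table", "data.frame")
    return(out)
  }
  if (center == "grand") {
    mo <- mean(kept$valid_order)
    ml <- mean(kept$looking_s)
    kept$block_order_c <- kept$valid_order - mo
    kept$looking_c <- kept$looking_s - ml
  } else {
    mo <- tapply(kept$valid_order, kept$timepoint, mean)
    ml <- tapply(kept$looking_s, kept$timepoint, mean)
    kept$block_order_c <- kept$valid_order - mo[as.character(kept$timepoint)]
    kept$looking_c <- kept$looking_s - ml[as.character(kept$timepoint)]
    mo <- mean(mo)
    ml <- mean(ml)
  }
  kept$learning_index <- kept$log_doublet_snr - kept$log_base_snr
  rownames(kept) <- NULL
  report$n_retained <- nrow(kept)
  attr(kept, "grand_means") <- c(block_order = unname(mo[1]), looking_s = unname(ml[1]))
  attr(kept, "filter_report") <- report
  class(kept) <- c("block_table", "data.frame")
  kept
}

filter_counts <- function(df) {
  tps <- sort(unique(as.character(df$timepoint)))
  per_tp <- lapply(tps, function(tp) {
    d <- df[df$timepoint == tp, , drop = FALSE]
    list(
      n_recorded = nrow(d),
      n_valid = sum(d$valid),
      n_electrophys_fail = if ("electrophys_pass" %in% names(d)) sum(!d$electrophys_pass) else NA_integer_,
      n_looking_fail = if ("looking_pass" %in% names(d)) sum(!d$looking_pass) else NA_integer_
    )
  })
  names(per_tp) <- tps
  list(
    n_recorded = nrow(df),
    n_valid = sum(df$valid),
    valid_pct = valid_block_rate(sum(df$valid), nrow(df)),
    per_timepoint = per_tp
  )
}

#' Worked-count summaries of a familiarization dataset
#'
#' Small report arithmetic on block and cohort counts.
#'
#' @param n_valid,n_recorded Valid and recorded block counts.
#' @return `valid_block_rate()`: percentage of recorded blocks that are
#'   valid.
#' @export
valid_block_rate <- function(n_valid, n_recorded) {
  if (n_recorded <= 0) return(NA_real_)
  100 * n_valid / n_recorded
}

#' @rdname valid_block_rate
#' @param n_sessions Number of testing sessions contributing blocks.
#' @return `mean_valid_blocks()`: average valid blocks per session.
#' @export
mean_valid_blocks <- function(n_valid, n_sessions) n_valid / n_sessions

#' @rdname valid_block_rate
#' @param n_initial,n_final Cohort sizes at the first and last timepoint.
#' @return `dropout_rate()`: cumulative percentage dropout.
#' @export
dropout_rate <- function(n_initial, n_final) 100 * (1 - n_final / n_initial)
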