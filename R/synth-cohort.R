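# Cohort-level simulation: longitudinal subjects, blocks, looking behaviour,
# attrition and test-phase trials.

#' Simulate a longitudinal frequency-tagging cohort
#'
#' Draws a full longitudinal dataset under the generative model: subjects
#' with persistent (correlated) random intercepts for the base and doublet
#' log-SNR outcomes, monotone attrition across the three timepoints,
#' per-session block counts driven by the looking-time stopping rule,
#' invalid blocks at the configured rate, block-level outcomes from the
#' linear mixed models (fixed effects + random intercept + correlated
#' residuals), the learning index as their difference, and test-phase trial
#' looking times linked to the subject's mean learning index.
#'
#' In `"fast"` mode block features are emitted directly from the generative
#' models; in `"full"` mode an EEG waveform is synthesised for every shown
#' block (see [simulate_block_eeg()]), with the 6-Hz response suppressed in
#' electrophysiologically invalid blocks.
#'
#' @param params A [generative_params()] object.
#' @param seed Integer master seed.
#' @param mode `"fast"` (features only) or `"full"` (waveforms too).
#' @return A `ft_cohort`: list with `blocks` (the retained analysis
#'   `block_table`), `raw` (all recorded blocks with validity flags),
#'   `sessions` (one row per testing session), `trials` (test-phase trial
#'   looking times), `eeg` (full mode: list of `eeg_block`s), `params`,
#'   `seed`, `mode`.
#' @export
simulate_cohort <- function(params = generative_params(), seed = 1L,
                            mode = c("fast", "full")) {
  mode <- match.arg(mode)
  if (!inherits(params, "generative_params")) stopf("expected `generative_params`")
  co <- params$cohort
  with_seed(seed, {
    ## subjects and monotone attrition
    ids <- sprintf("S%02d", seq_len(co$n_t[1]))
    present <- list(
      T1 = ids,
      T2 = sort(sample(ids, co$n_t[2])),
      T3 = NULL
    )
    present$T3 <- sort(sample(present$T2, co$n_t[3]))

    ## persistent correlated random intercepts (base, doublet)
    cv <- li_covariances(params)
    Sigma_u <- matrix(c(params$base_vc[["intercept"]], cv$cov_u,
                        cv$cov_u, params$doublet_vc[["intercept"]]), 2, 2)
    U <- matrix(stats::rnorm(2 * length(ids)), ncol = 2) %*% chol(Sigma_u)
    rownames(U) <- ids

    ## sessions and raw blocks
    raw <- list()
    sessions <- list()
    for (tp in c("T1", "T2", "T3")) {
      for (sj in present[[tp]]) {
        nmax <- co$max_blocks
        invalid <- stats::runif(nmax) < co$invalid_p
        behav_fail <- invalid & (stats::runif(nmax) < co$behav_fail_share)
        core <- 7 + 13 * stats::rbeta(nmax, co$looking_shape[1], co$looking_shape[2])
        core[behav_fail] <- stats::runif(sum(behav_fail), 0, 7)
        extended <- pmin(24, core * 1.2)
        plan <- apply_stopping_rule(extended, co$min_blocks, co$max_blocks,
                                    co$criterion_s)
        shown <- seq_len(plan$n_blocks_shown)
        raw[[length(raw) + 1L]] <- data.frame(
          subject = sj, timepoint = tp, raw_block = shown,
          looking_s = core[shown],
          electrophys_pass = !(invalid[shown] & !behav_fail[shown]),
          looking_pass = !behav_fail[shown],
          valid = !invalid[shown],
          stringsAsFactors = FALSE
        )
        sessions[[length(sessions) + 1L]] <- data.frame(
          subject = sj, timepoint = tp,
          n_blocks_shown = plan$n_blocks_shown,
          cumulative_looking = plan$cumulative_looking,
          reached_test = plan$reached_test,
          stringsAsFactors = FALSE
        )
      }
    }
    raw <- do.call(rbind, raw)
    sessions <- do.call(rbind, sessions)

    ## retained analysis rows and centred covariates
    raw$log_base_snr <- 0
    raw$log_doublet_snr <- 0
    bt <- finalize_block_table(raw)

    ## block-level outcomes from the generative LMMs
    tp2 <- as.integer(bt$timepoint == "T2")
    tp3 <- as.integer(bt$timepoint == "T3")
    X <- cbind(1, tp2, tp3, bt$block_order_c, bt$looking_c,
               tp2 * bt$block_order_c, tp3 * bt$block_order_c)
    Sigma_e <- matrix(c(params$base_vc[["residual"]], cv$cov_e,
                        cv$cov_e, params$doublet_vc[["residual"]]), 2, 2)
    E <- matrix(stats::rnorm(2 * nrow(bt)), ncol = 2) %*% chol(Sigma_e)
    bt$log_base_snr <- drop(X %*% params$base_fixed) + U[bt$subject, 1] + E[, 1]
    bt$log_doublet_snr <- drop(X %*% params$doublet_fixed) + U[bt$subject, 2] + E[, 2]
    bt$learning_index <- bt$log_doublet_snr - bt$log_base_snr
    bt$timepoint <- factor(bt$timepoint, levels = c("T1", "T2", "T3"))

    ## raw table mirrors the retained outcomes where applicable
    key_raw <- paste(raw$subject, raw$timepoint, raw$raw_block)
    key_bt <- paste(bt$subject, bt$timepoint, bt$raw_block)
    idx <- match(key_raw, key_bt)
    raw$log_base_snr <- ifelse(is.na(idx), NA_real_, bt$log_base_snr[idx])
    raw$log_doublet_snr <- ifelse(is.na(idx), NA_real_, bt$log_doublet_snr[idx])

    ## full-mode waveforms
    eeg <- NULL
    if (mode == "full") {
      gm <- attr(bt, "grand_means")
      eeg <- vector("list", nrow(raw))
      for (i in seq_len(nrow(raw))) {
        if (!is.na(idx[i])) {
          tb <- raw$log_base_snr[i]
          td <- raw$log_doublet_snr[i]
        } else {
          lc <- raw$looking_s[i] - gm[["looking_s"]]
          t2i <- as.integer(raw$timepoint[i] == "T2")
          t3i <- as.integer(raw$timepoint[i] == "T3")
          xb <- c(1, t2i, t3i, 0, lc, 0, 0)
          tb <- sum(xb * params$base_fixed) + U[raw$subject[i], 1] +
            stats::rnorm(1, 0, sqrt(params$base_vc[["residual"]]))
          td <- sum(xb * params$doublet_fixed) + U[raw$subject[i], 2] +
            stats::rnorm(1, 0, sqrt(params$doublet_vc[["residual"]]))
        }
        if (!raw$electrophys_pass[i]) {
          tb <- 0
          td <- 0
        }
        eeg[[i]] <- simulate_block_eeg(
          params, subject = raw$subject[i], timepoint = raw$timepoint[i],
          block = raw$raw_block[i], looking_s = raw$looking_s[i],
          target_log_base_snr = max(0, tb), target_log_doublet_snr = max(0, td)
        )
      }
    }

    ## test-phase behaviour for sessions that reached the test
    trials <- list()
    for (k in seq_len(nrow(sessions))) {
      if (!sessions$reached_test[k]) next
      sj <- sessions$subject[k]
      tp <- sessions$timepoint[k]
      li_rows <- bt$learning_index[bt$subject == sj & bt$timepoint == tp]
      if (length(li_rows) == 0L) next
      tr <- simulate_test_behaviour(params, mean(li_rows), tp)
      tr$subject <- sj
      tr$timepoint <- tp
      trials[[length(trials) + 1L]] <- tr
    }
    trials <- if (length(trials)) do.call(rbind, trials) else NULL

    structure(
      list(blocks = bt, raw = raw, sessions = sessions, trials = trials,
           eeg = eeg, params = params, seed = seed, mode = mode),
      class = "ft_cohort"
    )
  })
}

#' Simulate test-phase trial looking times
#'
#' Draws the eight test-trial looking times (alternating familiar/novel,
#' familiar first) such that the expected preference score -- novel mean
#' minus familiar mean -- equals the configured per-timepoint linear link
#' `intercept + slope * learning_index`, up to the [0, 7] s truncation of
#' individual trials.
#'
#' @param params A [generative_params()] object.
#' @param learning_index The subject's mean learning index at this
#'   timepoint.
#' @param timepoint `"T1"`, `"T2"` or `"T3"`.
#' @param seed Optional integer seed.
#' @return Data frame with columns `trial`, `type`, `looking_s`.
#' @export
simulate_test_behaviour <- function(params, learning_index, timepoint,
                                    seed = NULL) {
  if (!inherits(params, "generative_params")) stopf("expected `generative_params`")
  tp <- tolower(as.character(timepoint))
  b <- params$behaviour
  if (!tp %in% names(b$intercepts)) stopf("unknown timepoint '%s'", timepoint)
  with_seed(seed, {
    pref <- b$intercepts[[tp]] + b$slopes[[tp]] * learning_index +
      stats::rnorm(1, 0, b$residual_sd)
    type <- rep(c("familiar", "novel"), 4)
    mu <- ifelse(type == "novel", b$trial_base_s + pref / 2,
                 b$trial_base_s - pref / 2)
    looking <- pmin(7, pmax(0, stats::rnorm(8, mu, b$trial_sd_s)))
    data.frame(trial = 1:8, type = type, looking_s = looking,
               stringsAsFactors = FALSE)
  })
}

#' Preference scores of a simulated cohort
#'
#' @param cohort A `ft_cohort`.
#' @return Data frame with one row per tested session: `subject`,
#'   `timepoint`, `preference`, `mean_novel`, `mean_familiar`, and the
#'   session's mean `learning_index`.
#' @export
cohort_preference_scores <- function(cohort) {
  if (!inherits(cohort, "ft_cohort")) stopf("expected a `ft_cohort`")
  if (is.null(cohort$trials)) stopf("cohort has no test-phase trials")
  sp <- split(cohort$trials, paste(cohort$trials$subject, cohort$trials$timepoint))
  bt <- cohort$blocks
  rows <- lapply(sp, function(d) {
    ps <- preference_score(d$looking_s, d$type)
    li <- mean(bt$learning_index[bt$subject == d$subject[1] &
                                   bt$timepoint == d$timepoint[1]])
    data.frame(subject = d$subject[1], timepoint = d$timepoint[1],
               preference = ps$score, mean_novel = ps$mean_novel,
               mean_familiar = ps$mean_familiar, learning_index = li,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$timepoint, out$subject), ]
  rownames(out) <- NULL
  out$timepoint <- factor(out$timepoint, levels = c("T1", "T2", "T3"))
  out
}
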