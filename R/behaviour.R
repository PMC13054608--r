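# Test-phase looking-time quantification and preference-score inference.

#' Looking time of one test trial from a 100-ms coded timeline
#'
#' @param samples Logical (or 0/1) vector, one entry per 100-ms coding
#'   frame (at most 70 for a 7-s trial): `TRUE` = looking at the screen.
#' @return Looking time in seconds (`0.1 * number of looking frames`).
#' @export
trial_looking_time <- function(samples) {
  if (length(samples) > 70L) stopf("a 7-s trial has at most 70 coding frames")
  if (is.numeric(samples)) {
    if (any(!samples %in% c(0, 1))) stopf("`samples` must be logical or 0/1")
    samples <- as.logical(samples)
  }
  if (length(samples) && !is.logical(samples)) stopf("`samples` must be logical or 0/1")
  0.1 * sum(samples)
}

#' Novelty preference score
#'
#' Mean looking time on novel test trials minus mean looking time on
#' familiar test trials. Positive scores indicate a novelty preference,
#' negative a familiarity preference.
#'
#' @param looking_s Numeric vector of per-trial looking times in seconds.
#' @param trial_type Character vector (`"familiar"`/`"novel"`) aligned with
#'   `looking_s`; at least one trial of each type is required.
#' @return List with `score`, `mean_novel`, `mean_familiar`.
#' @export
preference_score <- function(looking_s, trial_type) {
  if (length(looking_s) != length(trial_type)) {
    stopf("`looking_s` and `trial_type` must be aligned")
  }
  if (!all(trial_type %in% c("familiar", "novel"))) {
    stopf("trial types must be 'familiar' or 'novel'")
  }
  nov <- looking_s[trial_type == "novel"]
  fam <- looking_s[trial_type == "familiar"]
  if (length(nov) == 0L || length(fam) == 0L) {
    stopf("need at least one trial of each type")
  }
  list(score = mean(nov) - mean(fam), mean_novel = mean(nov),
       mean_familiar = mean(fam))
}

#' Per-timepoint one-sample tests of preference scores
#'
#' Two-sided one-sample t-tests of the preference scores against zero at
#' each timepoint, with Holm step-down adjustment across the timepoint
#' family. Timepoints with fewer than two scores are skipped with a
#' warning.
#'
#' @param scores Numeric vector of preference scores.
#' @param timepoint Factor/character vector aligned with `scores`.
#' @return Data frame with one row per tested timepoint: `timepoint`, `n`,
#'   `mean`, `se`, `t`, `df`, `ci_lo`, `ci_hi`, `p`, `p_holm` (capped at 1).
#' @export
timepoint_tests <- function(scores, timepoint) {
  if (length(scores) != length(timepoint)) stopf("inputs must be aligned")
  tps <- unique(as.character(timepoint))
  rows <- list()
  for (tp in tps) {
    x <- scores[timepoint == tp]
    if (length(x) < 2L) {
      warnf("timepoint %s skipped: fewer than 2 scores", tp)
      next
    }
    tt <- stats::t.test(x, mu = 0)
    rows[[tp]] <- data.frame(
      timepoint = tp, n = length(x), mean = mean(x),
      se = stats::sd(x) / sqrt(length(x)),
      t = unname(tt$statistic), df = unname(tt$parameter),
      ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
      p = tt$p.value, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) stopf("no timepoint had enough scores to test")
  out <- do.call(rbind, rows)
  out$p_holm <- pmin(stats::p.adjust(out$p, method = "holm"), 1)
  rownames(out) <- NULL
  out
}
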