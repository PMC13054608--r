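# Stimulus protocol: doublet assignment, pseudo-random familiarization
# streams, test schedules, session stopping rule, and transitional
# probabilities.

#' Randomly pair eight shapes into four ordered doublets
#'
#' Assigns each of eight distinct shape identifiers to exactly one ordered
#' (leading, trailing) pair. The assignment is randomised once per
#' participant and reused across all blocks of that participant's session.
#'
#' @param shape_ids Character or atomic vector of exactly 8 distinct shape
#'   identifiers.
#' @param seed Optional integer seed; the same ids and seed always give the
#'   same pairing.
#' @param set_label Optional label for the shape set in use (one of three
#'   sets across longitudinal timepoints).
#' @return A `doublet_set`: data frame with columns `doublet` (1..4),
#'   `leading`, `trailing`.
#' @examples
#' assign_doublets(LETTERS[1:8], seed = 1)
#' @export
assign_doublets <- function(shape_ids, seed = NULL, set_label = NA_character_) {
  if (!is.atomic(shape_ids) || length(shape_ids) != 8L ||
      anyNA(shape_ids) || anyDuplicated(shape_ids)) {
    stopf("`shape_ids` must be 8 distinct non-missing identifiers")
  }
  shape_ids <- as.character(shape_ids)
  perm <- with_seed(seed, sample(shape_ids))
  out <- data.frame(
    doublet = 1:4,
    leading = perm[c(1, 3, 5, 7)],
    trailing = perm[c(2, 4, 6, 8)],
    stringsAsFactors = FALSE
  )
  attr(out, "set_label") <- set_label
  class(out) <- c("doublet_set", "data.frame")
  out
}

assert_doublet_set <- function(doublets) {
  if (!inherits(doublets, "doublet_set")) {
    stopf("expected a `doublet_set` (see assign_doublets())")
  }
  ids <- c(doublets$leading, doublets$trailing)
  if (length(ids) != 8L || anyDuplicated(ids)) {
    stopf("corrupt doublet set: shapes must each appear in exactly one position")
  }
  invisible(doublets)
}

#' Generate one pseudo-random familiarization block
#'
#' Concatenates 72 doublets (144 shapes at 6 Hz, i.e. a 24-s extended block)
#' with no doublet immediately repeated: each slot is drawn uniformly from
#' the three doublets different from the previous one, which yields an
#' inter-doublet transitional probability of 1/3. The first and last 12
#' shapes (2 s each) are fade-in/fade-out; the triggered 20-s core is items
#' 13--132 (120 shapes).
#'
#' @param doublets A `doublet_set`.
#' @param seed Optional integer seed.
#' @return A `shape_sequence`: list with `items` (length 144),
#'   `doublet_slots` (length 72), `core_start`, `core_end`, `rate_hz`,
#'   `fade_s`.
#' @export
generate_familiarization_block <- function(doublets, seed = NULL) {
  assert_doublet_set(doublets)
  slots <- with_seed(seed, {
    s <- integer(72)
    s[1] <- sample.int(4, 1)
    for (j in 2:72) {
      s[j] <- sample(setdiff(1:4, s[j - 1]), 1)
    }
    s
  })
  items <- as.vector(rbind(doublets$leading[slots], doublets$trailing[slots]))
  structure(
    list(
      items = items,
      doublet_slots = slots,
      core_start = 13L,
      core_end = 132L,
      rate_hz = 6,
      fade_s = 2,
      type = "familiarization"
    ),
    class = "shape_sequence"
  )
}

#' Parse a familiarization stream back into doublet slots
#'
#' Inverse of [generate_familiarization_block()]: checks that the item
#' stream is a concatenation of doublets from `doublets` and returns the
#' slot labels.
#'
#' @keywords internal
parse_doublet_slots <- function(seq, doublets) {
  assert_doublet_set(doublets)
  items <- if (inherits(seq, "shape_sequence")) seq$items else as.character(seq)
  if (length(items) %% 2L != 0L) stopf("stream length must be even")
  lead <- items[seq(1, length(items), by = 2)]
  trail <- items[seq(2, length(items), by = 2)]
  slot <- match(lead, doublets$leading)
  if (anyNA(slot) || any(doublets$trailing[slot] != trail)) {
    stopf("stream is not a concatenation of doublets from this set")
  }
  slot
}

#' Empirical transition matrix of a shape stream
#'
#' Counts first-order transitions and normalises each row by the number of
#' times the row shape was observed as a predecessor. When a list of
#' sequences is given, transitions are counted within each sequence only
#' (never across block boundaries). Shapes never observed as predecessors
#' get an `NA` row and are flagged in `attr(, "absent")` rather than being
#' zero-filled.
#'
#' @param x A `shape_sequence`, a character vector of items, or a list of
#'   either.
#' @return Square numeric matrix `tp` with `tp[a, b]` the estimated
#'   probability that `b` follows `a`; attributes `counts` (raw transition
#'   counts) and `absent` (shapes with no observed successor).
#' @export
empirical_transition_matrix <- function(x) {
  seqs <- if (inherits(x, "shape_sequence")) {
    list(x$items)
  } else if (is.list(x)) {
    lapply(x, function(s) if (inherits(s, "shape_sequence")) s$items else as.character(s))
  } else {
    list(as.character(x))
  }
  seqs <- seqs[vapply(seqs, length, 1L) >= 2L]
  if (length(seqs) == 0L) stopf("no transitions observed: sequences too short or empty")
  shapes <- sort(unique(unlist(seqs)))
  counts <- matrix(0L, length(shapes), length(shapes), dimnames = list(shapes, shapes))
  for (s in seqs) {
    from <- s[-length(s)]
    to <- s[-1]
    t2 <- table(factor(from, levels = shapes), factor(to, levels = shapes))
    counts <- counts + unclass(t2)
  }
  n_from <- rowSums(counts)
  tp <- counts / ifelse(n_from == 0, NA_real_, n_from)
  attr(tp, "counts") <- counts
  attr(tp, "absent") <- shapes[n_from == 0]
  tp
}

#' Mean inter-doublet transitional probability
#'
#' Averages `tp[trailing of d, leading of d']` over all ordered pairs of
#' distinct doublets `d != d'`: the empirical probability of one particular
#' next doublet given the end of the current doublet. Under the no-repeat
#' pseudo-random ordering this converges to 1/3.
#'
#' @param tp Matrix from [empirical_transition_matrix()].
#' @param doublets The generating `doublet_set`.
#' @return Mean transition probability over the 12 inter-doublet cells.
#' @export
inter_doublet_tp <- function(tp, doublets) {
  assert_doublet_set(doublets)
  cells <- numeric(0)
  for (d in 1:4) {
    for (d2 in setdiff(1:4, d)) {
      cells <- c(cells, tp[doublets$trailing[d], doublets$leading[d2]])
    }
  }
  mean(cells, na.rm = TRUE)
}

#' Generate the 8-trial test schedule
#'
#' Four familiar trials (doublets from familiarization, within-doublet TP 1)
#' and four novel trials (pairings never shown, TP 0) in strict alternation,
#' starting with a familiar trial. Novel pairs recombine a leading shape
#' with the trailing shape of a different doublet (a random derangement), so
#' each shape keeps its within-pair position, every shape is used at most
#' once, and no novel pair ever occurred as an adjacent ordered pair during
#' familiarization. Each trial repeats its pair for 21 cycles: 42 shapes at
#' 6 Hz, i.e. 7 s including 1-s fades.
#'
#' @param doublets A `doublet_set`.
#' @param seed Optional integer seed.
#' @return A `test_schedule`: data frame with columns `trial`, `type`
#'   (`"familiar"`/`"novel"`), `leading`, `trailing`; attributes `n_cycles`
#'   (21), `items_per_trial` (42), `rate_hz`, `fade_s`, `duration_s`.
#' @export
generate_test_schedule <- function(doublets, seed = NULL) {
  assert_doublet_set(doublets)
  sched <- with_seed(seed, {
    fam_order <- sample.int(4)
    repeat {
      der <- sample.int(4)
      if (all(der != 1:4)) break
    }
    nov_order <- sample.int(4)
    list(fam = fam_order, der = der, nov = nov_order)
  })
  fam <- data.frame(
    type = "familiar",
    leading = doublets$leading[sched$fam],
    trailing = doublets$trailing[sched$fam],
    stringsAsFactors = FALSE
  )
  nov_idx <- sched$nov
  nov <- data.frame(
    type = "novel",
    leading = doublets$leading[nov_idx],
    trailing = doublets$trailing[sched$der[nov_idx]],
    stringsAsFactors = FALSE
  )
  trials <- vector("list", 8)
  trials[c(1, 3, 5, 7)] <- split(fam, 1:4)
  trials[c(2, 4, 6, 8)] <- split(nov, 1:4)
  out <- do.call(rbind, trials)
  out <- cbind(trial = 1:8, out)
  rownames(out) <- NULL
  attr(out, "n_cycles") <- 21L
  attr(out, "items_per_trial") <- 42L
  attr(out, "rate_hz") <- 6
  attr(out, "fade_s") <- 1
  attr(out, "duration_s") <- 7
  class(out) <- c("test_schedule", "data.frame")
  out
}

#' Item stream of one test trial
#'
#' @param schedule A `test_schedule`.
#' @param trial Trial number (1..8).
#' @return Character vector of 42 shape ids (21 repetitions of the pair).
#' @export
test_trial_sequence <- function(schedule, trial) {
  if (!inherits(schedule, "test_schedule")) stopf("expected a `test_schedule`")
  check_scalar_number(trial, "trial", 1, nrow(schedule))
  row <- schedule[trial, ]
  rep(c(row$leading, row$trailing), attr(schedule, "n_cycles"))
}

#' Apply the familiarization stopping rule
#'
#' Blocks are shown sequentially; after a minimum of 8 blocks the session
#' moves to test as soon as cumulative looking reaches 120 s, with a hard
#' cap of 15 blocks. If the criterion is not reached within 15 blocks the
#' infant does not proceed to test.
#'
#' @param per_block_looking Numeric vector of per-extended-block looking
#'   times in seconds, each in `[0, 24]`, in presentation order.
#' @param min_blocks,max_blocks Session bounds (defaults 8 and 15).
#' @param criterion_s Cumulative looking criterion (default 120 s).
#' @return A `session_plan`: list with `n_blocks_shown`,
#'   `cumulative_looking` (seconds at stop) and `reached_test`.
#' @examples
#' apply_stopping_rule(rep(15, 15)) # stops at 8 blocks (8 x 15 = 120 s)
#' @export
apply_stopping_rule <- function(per_block_looking, min_blocks = 8L,
                                max_blocks = 15L, criterion_s = 120) {
  x <- per_block_looking
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stopf("`per_block_looking` must be a non-empty numeric vector")
  }
  if (any(x < 0 | x > 24)) {
    stopf("per-block looking must lie in [0, 24] seconds")
  }
  cum <- cumsum(x)
  hit <- which(cum >= criterion_s)
  first_hit <- if (length(hit)) hit[1] else Inf
  n_shown <- min(max(min_blocks, first_hit), max_blocks, length(x))
  structure(
    list(
      n_blocks_shown = as.integer(n_shown),
      cumulative_looking = cum[n_shown],
      reached_test = cum[n_shown] >= criterion_s
    ),
    class = "session_plan"
  )
}

#' Event table for a stimulus sequence
#'
#' Long-format export of one sequence: one row per shape with onset time,
#' shape id, doublet id (for familiarization streams) and phase
#' (`fade_in`/`core`/`fade_out`).
#'
#' @param seq A `shape_sequence`.
#' @param doublets Optional `doublet_set` used to label doublet ids.
#' @param block_index Block number recorded in the table.
#' @return Data frame with columns `time_s`, `shape_id`, `doublet_id`,
#'   `phase`, `block_index`.
#' @export
sequence_events <- function(seq, doublets = NULL, block_index = 1L) {
  if (!inherits(seq, "shape_sequence")) stopf("expected a `shape_sequence`")
  n <- length(seq$items)
  idx <- seq_len(n)
  phase <- rep("core", n)
  phase[idx < seq$core_start] <- "fade_in"
  phase[idx > seq$core_end] <- "fade_out"
  doublet_id <- if (!is.null(doublets)) {
    slots <- parse_doublet_slots(seq, doublets)
    rep(slots, each = 2)
  } else {
    rep(NA_integer_, n)
  }
  data.frame(
    time_s = (idx - 1) / seq$rate_hz,
    shape_id = seq$items,
    doublet_id = doublet_id,
    phase = phase,
    block_index = as.integer(block_index),
    stringsAsFactors = FALSE
  )
}
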