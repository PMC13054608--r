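# Stimulus protocol: doublet assignment, stream generation, transitional
# probabilities, test schedule, stopping rule.

test_that("doublet assignment covers all shapes, is deterministic, never pairs a shape with itself", {
  d <- assign_doublets(LETTERS[1:8], seed = 11)
  expect_setequal(c(d$leading, d$trailing), LETTERS[1:8])
  expect_identical(d, assign_doublets(LETTERS[1:8], seed = 11))

  # brute force over seeds: no (x, x) pair, full coverage every time
  for (s in 1:1000) {
    d <- assign_doublets(LETTERS[1:8], seed = s)
    expect_false(any(d$leading == d$trailing))
    expect_equal(anyDuplicated(c(d$leading, d$trailing)), 0L)
  }

  expect_error(assign_doublets(LETTERS[1:7]), "8 distinct")
  expect_error(assign_doublets(c(LETTERS[1:7], "A")), "8 distinct")
})

test_that("familiarization blocks have 144 items, a 120-item core, and no repeated doublet", {
  d <- assign_doublets(letters[1:8], seed = 5)
  for (s in 1:50) {
    b <- generate_familiarization_block(d, seed = s)
    expect_length(b$items, 144L)
    expect_equal(b$core_end - b$core_start + 1L, 120L)
    expect_false(any(diff(b$doublet_slots) == 0))
    # parses back into exactly 72 doublets from the generating set
    expect_identical(parse_doublet_slots(b, d), b$doublet_slots)
    expect_length(b$doublet_slots, 72L)
  }
})

test_that("the no-repeat sampler occupies each doublet slot with frequency 1/4", {
  d <- assign_doublets(letters[1:8], seed = 1)
  set.seed(42)
  slots <- unlist(replicate(3000, generate_familiarization_block(d)$doublet_slots,
                            simplify = FALSE))
  freqs <- as.vector(table(slots)) / length(slots)
  expect_length(freqs, 4L)
  expect_true(all(abs(freqs - 0.25) < 0.02))
})

test_that("empirical transition probabilities are 1 within doublets and 1/3 between doublets", {
  d <- assign_doublets(LETTERS[1:8], seed = 2)
  set.seed(7)
  blocks <- replicate(1000, generate_familiarization_block(d), simplify = FALSE)
  expect_gt(1000 * 143, 1e5) # enough transitions for the tolerance below
  tm <- empirical_transition_matrix(blocks)
  for (i in 1:4) {
    expect_equal(tm[d$leading[i], d$trailing[i]], 1)
  }
  expect_equal(inter_doublet_tp(tm, d), 1 / 3, tolerance = 0.01 / (1 / 3))
  # a trailing shape is never followed by the same doublet's leading shape
  for (i in 1:4) expect_equal(unname(tm[d$trailing[i], d$leading[i]]), 0)
})

test_that("transition matrix handles short sequences and flags absent predecessors", {
  tm <- empirical_transition_matrix(c("A", "B", "A", "B"))
  expect_equal(unname(tm["A", "B"]), 1)
  expect_equal(unname(tm["B", "A"]), 1)

  tm2 <- empirical_transition_matrix(c("A", "B", "C"))
  expect_identical(attr(tm2, "absent"), "C")
  expect_true(all(is.na(tm2["C", ])))

  expect_error(empirical_transition_matrix(character(0)), "no transitions")
  expect_error(empirical_transition_matrix(list("A")), "no transitions")
})

test_that("test schedules alternate familiar/novel, start familiar, and use only unseen novel pairs", {
  d <- assign_doublets(LETTERS[1:8], seed = 9)
  fam_pairs <- paste(d$leading, d$trailing)
  # all adjacent ordered pairs that can occur during familiarization
  seen <- c(fam_pairs, as.vector(outer(d$trailing, d$leading, paste)))
  for (s in 1:200) {
    ts <- generate_test_schedule(d, seed = s)
    expect_identical(ts$type, rep(c("familiar", "novel"), 4))
    fam <- ts[ts$type == "familiar", ]
    nov <- ts[ts$type == "novel", ]
    expect_setequal(paste(fam$leading, fam$trailing), fam_pairs)
    nov_pairs <- paste(nov$leading, nov$trailing)
    expect_equal(anyDuplicated(nov_pairs), 0L)
    expect_length(intersect(nov_pairs, seen), 0L)
    # position-preserving recombination: each shape used at most once
    expect_equal(anyDuplicated(c(nov$leading, nov$trailing)), 0L)
  }
  expect_length(test_trial_sequence(generate_test_schedule(d, seed = 1), 3), 42L)
})

test_that("the stopping rule respects the 8-block minimum, 120-s criterion and 15-block cap", {
  p <- apply_stopping_rule(rep(15, 15))
  expect_identical(p$n_blocks_shown, 8L)
  expect_true(p$reached_test)

  p <- apply_stopping_rule(rep(10, 15))
  expect_identical(p$n_blocks_shown, 12L)
  expect_true(p$reached_test)

  p <- apply_stopping_rule(rep(7, 15))
  expect_identical(p$n_blocks_shown, 15L)
  expect_false(p$reached_test)

  expect_error(apply_stopping_rule(c(10, -1)), "\\[0, 24\\]")
  expect_error(apply_stopping_rule(c(10, 25)), "\\[0, 24\\]")

  # monotonicity: more looking never means more blocks
  set.seed(1)
  for (i in 1:200) {
    x <- runif(15, 0, 24)
    y <- pmin(24, x + runif(15, 0, 5))
    expect_lte(apply_stopping_rule(y)$n_blocks_shown,
               apply_stopping_rule(x)$n_blocks_shown)
  }
})

test_that("sequence event tables label fades, core and doublet identity", {
  d <- assign_doublets(LETTERS[1:8], seed = 3)
  b <- generate_familiarization_block(d, seed = 4)
  ev <- sequence_events(b, d, block_index = 2)
  expect_equal(nrow(ev), 144L)
  expect_identical(ev$phase[1:12], rep("fade_in", 12))
  expect_identical(ev$phase[133:144], rep("fade_out", 12))
  expect_true(all(ev$phase[13:132] == "core"))
  expect_equal(ev$time_s[2] - ev$time_s[1], 1 / 6)
  expect_true(all(ev$block_index == 2L))
})
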