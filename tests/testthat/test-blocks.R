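# Valid-block filtering, renumbering, truncation, centering.

snr_with <- function(value6 = 1, channel = 75, looking_channels = 128) {
  snr <- matrix(1, looking_channels, 201)
  snr[channel, 121] <- value6 # 6 Hz at 0.05-Hz spacing
  make_snr_spectrum(snr)
}

test_that("valid blocks need both the 6-Hz occipital SNR and the looking criterion", {
  v <- validate_block(snr_with(2.5, channel = 75), looking_s = 8)
  expect_true(v$valid)

  v <- validate_block(snr_with(1.9, channel = 75), looking_s = 20)
  expect_false(v$electrophys_pass)
  expect_false(v$valid)

  v <- validate_block(snr_with(3.0, channel = 70), looking_s = 6.9)
  expect_true(v$electrophys_pass)
  expect_false(v$looking_pass)
  expect_false(v$valid)

  # an SNR of 2.5 outside the a-priori occipital set does not count
  v <- validate_block(snr_with(2.5, channel = 10), looking_s = 10)
  expect_false(v$valid)
})

test_that("valid blocks are renumbered in raw order and truncated at 8, with centred covariates", {
  mk <- function(subject, raw, valid, looking = 10) {
    data.frame(subject = subject, timepoint = "T1", raw_block = raw,
               looking_s = looking, valid = valid,
               log_base_snr = 0.3, log_doublet_snr = 0.1,
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    mk("A", 1:10, c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)),
    mk("B", 1:12, TRUE)
  )
  bt <- finalize_block_table(df)
  a <- bt[bt$subject == "A", ]
  expect_identical(a$raw_block, c(2L, 3L, 5L, 9L))
  expect_identical(a$valid_order, c(1L, 2L, 3L, 4L))
  b <- bt[bt$subject == "B", ]
  expect_identical(b$valid_order, 1:8) # truncated from 12 valid blocks
  expect_lt(abs(mean(bt$block_order_c)), 1e-12)
  expect_lt(abs(mean(bt$looking_c)), 1e-12)
  expect_equal(bt$learning_index, bt$log_doublet_snr - bt$log_base_snr)
})

test_that("participants with fewer than two valid blocks contribute no rows", {
  df <- data.frame(
    subject = c("A", "A", "B", "B", "B"), timepoint = "T1",
    raw_block = c(1:2, 1:3), looking_s = 10,
    valid = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    log_base_snr = 0.2, log_doublet_snr = 0.1, stringsAsFactors = FALSE
  )
  bt <- finalize_block_table(df)
  expect_false("A" %in% bt$subject)
  expect_equal(sum(bt$subject == "B"), 3L)

  df$valid <- FALSE
  expect_warning(bt0 <- finalize_block_table(df), "no blocks retained")
  expect_equal(nrow(bt0), 0L)
})

test_that("filtering is idempotent and no retained row violates the criteria", {
  co <- simulate_cohort(seed = 3)
  bt <- co$blocks
  expect_true(all(bt$looking_s >= 7))
  expect_true(all(bt$valid))
  expect_true(all(bt$valid_order <= 8))

  again <- finalize_block_table(as.data.frame(bt))
  expect_equal(again$valid_order, bt$valid_order)
  expect_equal(again$block_order_c, bt$block_order_c)
})

test_that("block tables built from spectra aggregate SNR over the ROI and harmonics", {
  # two tiny synthetic 'blocks' with known SNR values
  mk_snr <- function(v) {
    snr <- matrix(1, 128, 501)
    snr[, seq(61, 481, by = 60)] <- v # 3,6,...,24 Hz bins
    snr[75, 121] <- 3                 # pass the 6-Hz criterion
    make_snr_spectrum(snr)
  }
  blocks <- list(
    list(snr = mk_snr(2), subject = "A", timepoint = "T1", raw_block = 1, looking_s = 10),
    list(snr = mk_snr(2), subject = "A", timepoint = "T1", raw_block = 2, looking_s = 12)
  )
  bt <- build_block_table(blocks)
  expect_equal(nrow(bt), 2L)
  # ROI rows other than electrode 75 have SNR 2 at every harmonic
  expect_true(all(abs(bt$log_doublet_snr - log(2)) < 1e-12))
  report <- attr(bt, "filter_report")
  expect_equal(report$n_valid, 2L)
})

test_that("worked count summaries reproduce the protocol arithmetic", {
  expect_equal(round(valid_block_rate(512, 670), 2), 76.42)
  expect_equal(mean_valid_blocks(512, 80), 6.4)
  expect_equal(round(dropout_rate(30, 23), 2), 23.33)
})
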