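# Mixed-model fitting, comparison, contrasts, simple slopes, ICC.

beta_true <- c(0.302, 0.100, 0.002, -0.024, 0.029, 0.001, 0.025)

test_that("noise-free data recover the generating coefficients essentially exactly", {
  df <- exact_lmm_data(beta_true, residual_sd = 1e-8, seed = 2)
  fit <- suppressWarnings(suppressMessages(
    fit_lmm(log_base_snr ~ timepoint * block_order_c + looking_c + (1 | subject), df)
  ))
  est <- fit$coefficients$estimate
  expect_lt(max(abs(est - beta_true)), 1e-6)
})

test_that("Wald intervals are estimate +/- 1.96 SE and ICC matches the printed worked example", {
  co <- simulate_cohort(seed = 12)
  fit <- fit_base_model(co$blocks)
  cf <- fit$coefficients
  expect_lt(max(abs((cf$ci_hi - cf$ci_lo) / 2 - 1.96 * cf$se)), 1e-9)
  expect_true(fit$icc >= 0 && fit$icc <= 1)

  expect_equal(round(icc_from_components(0.013, 0.043), 2), 0.23)
  expect_equal(icc_from_components(0.013, 0.043), 0.232, tolerance = 1e-3)
  expect_equal(icc_from_components(0, 0.4), 0)
})

test_that("coefficients are invariant to shifting and re-centring the block-order variable", {
  co <- simulate_cohort(seed = 13)
  d1 <- co$blocks
  d2 <- d1
  d2$block_order_c <- (d1$block_order_c + 3) - mean(d1$block_order_c + 3)
  f1 <- fit_base_model(d1)
  f2 <- fit_base_model(d2)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("rank-deficient designs fail with the aliased term named", {
  co <- simulate_cohort(seed = 14)
  d <- co$blocks
  d$dup <- d$block_order_c
  expect_error(
    fit_lmm(log_base_snr ~ block_order_c + dup + (1 | subject), d),
    "aliased.*dup"
  )
})

test_that("model comparison rejects non-nested sequences and scores a duplicate model at zero", {
  co <- simulate_cohort(seed = 15)
  d <- co$blocks
  expect_error(
    compare_models(list(learning_index ~ looking_c + (1 | subject),
                        learning_index ~ block_order_c + (1 | subject)), d),
    "not nested"
  )
  cmp <- compare_models(list(learning_index ~ block_order_c + (1 | subject),
                             learning_index ~ block_order_c + (1 | subject)), d)
  expect_equal(cmp$table$delta_aic[2], 0, tolerance = 1e-8)
  expect_equal(cmp$selected, 1L)
})

test_that("LRT p-values are uniform when the added covariate is pure noise", {
  set.seed(31)
  ps <- replicate(100, {
    n <- 120
    d <- data.frame(y = rnorm(n), x = rnorm(n), junk = rnorm(n))
    cmp <- compare_models(list(y ~ x, y ~ x + junk), d)
    cmp$table$p[2]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the generating timepoint-by-order interaction is detected well above chance", {
  # Analytic oracle: the LRT for the two interaction terms has
  # non-centrality ~ (b/se)^2 ~ (0.027/0.012)^2 + (-0.006/0.010)^2 ~ 5.4,
  # i.e. power ~ 0.5 at alpha = .05 for a 2-df test - far above the 5%
  # null rate, so the selection rate must clear a 25% floor.
  ncp <- (0.027 / 0.012)^2 + (0.006 / 0.010)^2
  power <- stats::pchisq(stats::qchisq(0.95, 2), 2, ncp = ncp, lower.tail = FALSE)
  expect_gt(power, 0.4)

  hits <- vapply(1:30, function(s) {
    d <- simulate_cohort(seed = 400 + s)$blocks
    cmp <- compare_models(
      list(log_doublet_snr ~ timepoint + block_order_c + looking_c + (1 | subject),
           log_doublet_snr ~ timepoint * block_order_c + looking_c + (1 | subject)),
      d
    )
    cmp$selected == 2L
  }, TRUE)
  expect_gt(mean(hits), 0.25)
})

test_that("marginal contrasts vanish when timepoint carries no effect", {
  # residual pattern replicated identically across timepoints, so every
  # timepoint contrast is exactly zero while the residual variance is not
  set.seed(16)
  e <- rnorm(8)
  d <- expand.grid(slot = 1:4, block_order_c = c(-1, 1),
                   timepoint = c("T1", "T2", "T3"), stringsAsFactors = FALSE)
  d$subject <- paste0(d$timepoint, "_", d$slot)
  d$y <- 2 + 0.5 * d$block_order_c +
    e[d$slot + 4 * (d$block_order_c == 1)]
  fit <- fit_lmm(y ~ timepoint * block_order_c, d)
  mc <- marginal_contrasts(fit, adjust = "holm")
  expect_lt(max(abs(mc$contrasts$estimate)), 1e-10)
  expect_true(all(mc$contrasts$p.value > 0.999))
})

test_that("the doublet model's interaction steepens the T3-T1 contrast at late blocks", {
  diffs <- vapply(1:12, function(s) {
    d <- simulate_cohort(seed = 600 + s)$blocks
    mc <- marginal_contrasts(fit_doublet_model(d), adjust = "holm")
    ct <- mc$contrasts
    lowhigh <- ct[ct$contrast == "T1 - T3", ]
    # (T1 - T3) at -1 SD minus at +1 SD: positive when T3 gains with order
    lowhigh$estimate[1] - lowhigh$estimate[3]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.6)
})

test_that("the +/-1 SD and +/-2 SD grids agree qualitatively", {
  d <- simulate_cohort(seed = 17)$blocks
  fit <- fit_base_model(d)
  mc1 <- marginal_contrasts(fit, grid_sd = c(-1, 0, 1), adjust = "holm")
  mc2 <- suppressWarnings(marginal_contrasts(fit, grid_sd = c(-2, 0, 2), adjust = "holm"))
  mid1 <- mc1$contrasts[mc1$contrasts$block_order_c == 0, ]
  mid2 <- mc2$contrasts[mc2$contrasts$block_order_c == 0, ]
  expect_equal(mid1$estimate, mid2$estimate, tolerance = 1e-8)
  # contrasts that are significant on the +/-1 SD grid keep their direction
  # (and significance pattern at the shared mean grid point) on the wider grid
  sig <- which(mc1$contrasts$p.value < 0.05)
  expect_identical(sign(mc1$contrasts$estimate[sig]),
                   sign(mc2$contrasts$estimate[sig]))
  expect_identical(mid1$p.value < 0.05, mid2$p.value < 0.05)
})

test_that("simple slopes reproduce the coefficient arithmetic of the brain-behaviour model", {
  b <- c("(Intercept)" = -0.070, "learning_index" = -0.969,
         "timepointT2" = 0.762, "timepointT3" = 0.554,
         "learning_index:timepointT2" = 2.641,
         "learning_index:timepointT3" = 5.390)
  sl <- simple_slopes(b)
  expect_equal(sl$slope[sl$timepoint == "T1"], -0.969)
  expect_equal(sl$slope[sl$timepoint == "T2"], 1.672)
  expect_equal(sl$slope[sl$timepoint == "T3"], 4.421)

  b0 <- b
  b0["learning_index:timepointT2"] <- 0
  b0["learning_index:timepointT3"] <- 0
  sl0 <- simple_slopes(b0)
  expect_true(all(sl0$slope == -0.969))
})

test_that("simple slopes from a fitted model match emtrends", {
  co <- simulate_cohort(seed = 18)
  sc <- cohort_preference_scores(co)
  fit <- fit_brain_behaviour_model(sc)
  sl <- simple_slopes(fit)
  emt <- as.data.frame(emmeans::emtrends(fit$fit, ~ timepoint, var = "learning_index"))
  expect_equal(sl$slope, emt$learning_index.trend, tolerance = 1e-6)
  expect_equal(sl$se, emt$SE, tolerance = 1e-6)
  pw <- attr(sl, "pairwise")
  expect_equal(nrow(pw), 3L)
  expect_true(all(pw$p_tukey >= 0 & pw$p_tukey <= 1))
})

test_that("the brain-behaviour model degenerates to OLS when the intercept variance is zero", {
  co <- simulate_cohort(seed = 20)
  sc <- cohort_preference_scores(co)
  fit <- suppressMessages(fit_brain_behaviour_model(sc))
  # the generative behaviour model has no subject effect, so the random
  # intercept should collapse and the linear model be retained
  expect_true(fit$degenerate)
  expect_s3_class(fit$fit, "lm")
  expect_equal(fit$icc, 0)
})
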