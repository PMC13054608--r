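# Linear mixed-effects modelling of block-level entrainment and behaviour:
# model fits, stepwise comparison, marginal contrasts, simple slopes, ICC.

#' Fit a (mixed) linear model and extract a standard report
#'
#' Fits a random-intercept linear mixed model by REML (via lmerTest, so
#' t-tests use Satterthwaite degrees of freedom) when the formula contains a
#' random term, and an ordinary linear model otherwise. Confidence
#' intervals are Wald: estimate +/- 1.96 SE. The fixed-effect design is
#' checked for rank deficiency up front and aliased terms are named in the
#' error.
#'
#' @param formula Model formula; random intercepts as `(1 | subject)`.
#' @param data Data frame (a `block_table`, preference-score table, ...).
#'   A `timepoint` column is coerced to a factor with reference level T1.
#' @param reml Fit by REML (default) or ML.
#' @param refit_if_singular If `TRUE` and the random-intercept variance
#'   estimates to zero, refit as an ordinary linear model and flag the
#'   result as degenerate (used for the brain-behaviour model).
#' @return A `ft_model_fit`: list with `fit` (the underlying model object),
#'   `coefficients` (term, estimate, se, ci_lo, ci_hi, t, df, p),
#'   `varcomp` (intercept/residual variances and SDs), `icc`, `logLik`,
#'   `aic`, `degenerate`, `formula`.
#' @export
fit_lmm <- function(formula, data, reml = TRUE, refit_if_singular = FALSE) {
  if ("timepoint" %in% names(data)) {
    data$timepoint <- factor(as.character(data$timepoint),
                             levels = c("T1", "T2", "T3"))
    data$timepoint <- droplevels(data$timepoint)
  }
  has_ranef <- length(lme4::findbars(formula)) > 0L
  fixed_formula <- if (has_ranef) lme4::nobars(formula) else formula
  mm <- stats::model.matrix(fixed_formula, data = data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stopf("rank-deficient fixed-effect design; aliased term(s): %s",
          paste(aliased, collapse = ", "))
  }

  degenerate <- FALSE
  if (has_ranef) {
    fit <- lmerTest::lmer(formula, data = data, REML = reml)
    vc <- as.data.frame(lme4::VarCorr(fit))
    int_var <- vc$vcov[vc$grp != "Residual"][1]
    res_var <- vc$vcov[vc$grp == "Residual"]
    if (refit_if_singular && int_var < 1e-10) {
      degenerate <- TRUE
      fit <- stats::lm(fixed_formula, data = data)
      has_ranef <- FALSE
    }
  }
  if (!has_ranef) {
    if (!degenerate) fit <- stats::lm(fixed_formula, data = data)
    int_var <- 0
    res_var <- summary(fit)$sigma^2
  }

  cf <- if (inherits(fit, "lmerModLmerTest")) {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, "Estimate"],
               se = s[, "Std. Error"], t = s[, "t value"],
               df = s[, "df"], p = s[, "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  } else {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, "Estimate"],
               se = s[, "Std. Error"], t = s[, "t value"],
               df = stats::df.residual(fit), p = s[, "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  }
  cf$ci_lo <- cf$estimate - 1.96 * cf$se
  cf$ci_hi <- cf$estimate + 1.96 * cf$se
  cf <- cf[, c("term", "estimate", "se", "ci_lo", "ci_hi", "t", "df", "p")]
  rownames(cf) <- NULL

  structure(
    list(
      fit = fit,
      coefficients = cf,
      varcomp = c(intercept_var = unname(int_var),
                  residual_var = unname(res_var),
                  intercept_sd = sqrt(unname(int_var)),
                  residual_sd = sqrt(unname(res_var))),
      icc = icc_from_components(int_var, res_var),
      logLik = as.numeric(stats::logLik(fit)),
      aic = stats::AIC(fit),
      degenerate = degenerate,
      formula = formula,
      data = data
    ),
    class = "ft_model_fit"
  )
}

#' @export
print.ft_model_fit <- function(x, digits = 3, ...) {
  cat("Model:", deparse(x$formula), "\n")
  if (x$degenerate) cat("  (random intercept variance 0; ordinary linear model retained)\n")
  print(cbind(x$coefficients[1], round(x$coefficients[-1], digits)))
  cat(sprintf("  intercept var %.3f, residual var %.3f, ICC %.2f, AIC %.1f\n",
              x$varcomp[["intercept_var"]], x$varcomp[["residual_var"]],
              x$icc, x$aic))
  invisible(x)
}

#' Intraclass correlation from variance components
#'
#' Share of outcome variance attributable to stable between-subject
#' differences in a random-intercept model.
#'
#' @param intercept_var,residual_var Non-negative variance components.
#' @return `intercept_var / (intercept_var + residual_var)`, in [0, 1]
#'   (0 when both components are 0).
#' @export
icc_from_components <- function(intercept_var, residual_var) {
  if (intercept_var < 0 || residual_var < 0) stopf("variances must be non-negative")
  tot <- intercept_var + residual_var
  if (tot == 0) return(0)
  intercept_var / tot
}

## Canonical model specifications -------------------------------------------

#' Fit the canonical block-level and behavioural models
#'
#' Convenience wrappers around [fit_lmm()] for the four analysis models:
#' base-frequency SNR and doublet-frequency SNR
#' (`outcome ~ timepoint * block_order_c + looking_c + (1 | subject)`),
#' the learning index
#' (`learning_index ~ timepoint + block_order_c + (1 | subject)`),
#' preference scores (`preference ~ timepoint + (1 | subject)`), and the
#' brain-behaviour link
#' (`preference ~ learning_index * timepoint + (1 | subject)`, refit as an
#' ordinary linear model when the intercept variance degenerates to zero).
#'
#' @param data A `block_table` (block-level models) or a preference-score
#'   table from [cohort_preference_scores()] (behavioural models).
#' @return A `ft_model_fit`.
#' @export
fit_base_model <- function(data) {
  fit_lmm(log_base_snr ~ timepoint * block_order_c + looking_c + (1 | subject), data)
}

#' @rdname fit_base_model
#' @export
fit_doublet_model <- function(data) {
  fit_lmm(log_doublet_snr ~ timepoint * block_order_c + looking_c + (1 | subject), data)
}

#' @rdname fit_base_model
#' @export
fit_li_model <- function(data) {
  fit_lmm(learning_index ~ timepoint + block_order_c + (1 | subject), data)
}

#' @rdname fit_base_model
#' @export
fit_preference_model <- function(data) {
  fit_lmm(preference ~ timepoint + (1 | subject), data)
}

#' @rdname fit_base_model
#' @export
fit_brain_behaviour_model <- function(data) {
  fit_lmm(preference ~ learning_index * timepoint + (1 | subject), data,
          refit_if_singular = TRUE)
}

## Stepwise comparison ------------------------------------------------------

#' Stepwise comparison of nested models
#'
#' Refits each model by maximum likelihood and compares consecutive pairs by
#' likelihood-ratio test and change in AIC. Fixed-effect terms of each
#' model must nest within the next; non-nested pairs raise an error. The
#' selected model is the endpoint of the forward walk: each step is accepted
#' while its LRT p-value is below `alpha` or its AIC improves by more than
#' `delta_aic`.
#'
#' @param formulas List of model formulas, simplest first.
#' @param data Shared data frame.
#' @param alpha LRT acceptance level (default 0.05).
#' @param delta_aic AIC acceptance change (default -2: AIC must drop by 2).
#' @return List with `table` (one row per model: parameters, logLik, AIC,
#'   chisq, df, p of the step) and `selected` (index into `formulas`).
#' @export
compare_models <- function(formulas, data, alpha = 0.05, delta_aic = -2) {
  if (length(formulas) < 2L) stopf("need at least two models to compare")
  term_sets <- lapply(formulas, function(f) {
    attr(stats::terms(lme4::nobars(f)), "term.labels")
  })
  for (i in seq_len(length(formulas) - 1L)) {
    if (!all(term_sets[[i]] %in% term_sets[[i + 1L]])) {
      stopf("model %d is not nested in model %d (terms: %s)", i, i + 1L,
            paste(setdiff(term_sets[[i]], term_sets[[i + 1L]]), collapse = ", "))
    }
  }
  fits <- lapply(formulas, function(f) {
    if (length(lme4::findbars(f))) {
      lme4::lmer(f, data = data, REML = FALSE)
    } else {
      stats::lm(f, data = data)
    }
  })
  ll <- vapply(fits, function(m) as.numeric(stats::logLik(m)), 1)
  npar <- vapply(fits, function(m) attr(stats::logLik(m), "df"), 1)
  aic <- vapply(fits, stats::AIC, 1)
  chisq <- c(NA, 2 * diff(ll))
  ddf <- c(NA, diff(npar))
  p <- ifelse(is.na(chisq), NA,
              ifelse(ddf > 0, stats::pchisq(pmax(chisq, 0), ddf, lower.tail = FALSE), NA))
  tab <- data.frame(
    model = vapply(formulas, function(f) paste(deparse(f), collapse = ""), ""),
    npar = npar, logLik = ll, aic = aic,
    chisq = chisq, chi_df = ddf, p = p,
    delta_aic = c(NA, diff(aic)),
    stringsAsFactors = FALSE
  )
  selected <- 1L
  for (i in 2:length(formulas)) {
    ok <- (!is.na(tab$p[i]) && tab$p[i] < alpha) ||
      (!is.na(tab$delta_aic[i]) && tab$delta_aic[i] < delta_aic)
    if (ok) selected <- i else break
  }
  list(table = tab, selected = selected)
}

## Marginal means and contrasts ---------------------------------------------

#' Timepoint contrasts at representative block orders
#'
#' Estimated marginal means of the outcome per timepoint at representative
#' centred block orders (by default -1 SD, mean, +1 SD; a +/-2 SD grid for
#' robustness checks), with all pairwise timepoint differences adjusted
#' within each grid point. Degrees of freedom are Satterthwaite for mixed
#' fits. Other covariates are held at their centred zero.
#'
#' @param fit A `ft_model_fit` whose model contains `timepoint` and
#'   `block_order_c`.
#' @param grid_sd Multiples of the observed SD of `block_order_c` at which
#'   to estimate the means (default `c(-1, 0, 1)`).
#' @param adjust Multiplicity adjustment: `"holm"` or `"tukey"`.
#' @return List with `emmeans` and `contrasts` data frames and the `grid`
#'   of block-order values used.
#' @export
marginal_contrasts <- function(fit, grid_sd = c(-1, 0, 1),
                               adjust = c("holm", "tukey")) {
  adjust <- match.arg(adjust)
  if (!inherits(fit, "ft_model_fit")) stopf("expected a `ft_model_fit`")
  data <- fit$data
  if (!all(c("timepoint", "block_order_c") %in% names(data))) {
    stopf("model data must contain `timepoint` and `block_order_c`")
  }
  sd_bo <- stats::sd(data$block_order_c)
  grid <- grid_sd * sd_bo
  rng <- range(data$block_order_c)
  if (any(grid < rng[1] | grid > rng[2])) {
    warnf("grid value outside the observed block-order range [%.2f, %.2f]",
          rng[1], rng[2])
  }
  at <- list(block_order_c = grid)
  if ("looking_c" %in% names(data)) at$looking_c <- 0
  emm <- emmeans::emmeans(fit$fit, ~ timepoint | block_order_c, at = at,
                          lmer.df = "satterthwaite")
  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = adjust)
  list(
    emmeans = as.data.frame(emm),
    contrasts = as.data.frame(ctr),
    grid = grid
  )
}

## Simple slopes ------------------------------------------------------------

#' Per-timepoint simple slopes of preference on the learning index
#'
#' For a model `preference ~ learning_index * timepoint`, the slope at the
#' reference timepoint is the learning-index coefficient and the slope at
#' each later timepoint adds the corresponding interaction coefficient.
#' Standard errors come from the coefficient covariance matrix; confidence
#' intervals are Wald. Pairwise slope differences are the interaction
#' contrasts, Tukey-adjusted over the three timepoints.
#'
#' @param fit A `ft_model_fit` of the interaction model, or a named
#'   coefficient vector (then `vcov` may supply the covariance matrix).
#' @param vcov Optional coefficient covariance matrix when `fit` is a plain
#'   vector.
#' @param df Residual degrees of freedom for p-values (default `Inf`:
#'   normal reference).
#' @return Data frame with `timepoint`, `slope`, `se`, `ci_lo`, `ci_hi`,
#'   `t`, `p`; pairwise differences in `attr(, "pairwise")`.
#' @export
simple_slopes <- function(fit, vcov = NULL, df = Inf) {
  if (inherits(fit, "ft_model_fit")) {
    b <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
    V <- as.matrix(stats::vcov(fit$fit))
    df <- if (inherits(fit$fit, "lm")) stats::df.residual(fit$fit) else {
      nrow(fit$data) - length(b)
    }
  } else if (is.numeric(fit) && !is.null(names(fit))) {
    b <- fit
    V <- vcov
  } else {
    stopf("`fit` must be a ft_model_fit or a named coefficient vector")
  }
  li_term <- grep("^learning_index$", names(b), value = TRUE)
  if (length(li_term) != 1L) stopf("no `learning_index` main-effect term found")
  int_terms <- grep("^learning_index:timepointT[23]$|^timepointT[23]:learning_index$",
                    names(b), value = TRUE)
  if (length(int_terms) == 0L) {
    stopf("no learning_index x timepoint interaction terms in the model")
  }
  tps <- c("T1", sub(".*timepoint", "", int_terms))
  slopes <- c(b[[li_term]], b[[li_term]] + unname(b[int_terms]))
  se <- rep(NA_real_, length(slopes))
  if (!is.null(V)) {
    se[1] <- sqrt(V[li_term, li_term])
    for (k in seq_along(int_terms)) {
      it <- int_terms[k]
      se[k + 1] <- sqrt(V[li_term, li_term] + V[it, it] + 2 * V[li_term, it])
    }
  }
  tval <- slopes / se
  out <- data.frame(
    timepoint = tps, slope = unname(slopes), se = se,
    ci_lo = unname(slopes) - 1.96 * se, ci_hi = unname(slopes) + 1.96 * se,
    t = unname(tval),
    p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  ## pairwise slope differences, Tukey-adjusted over the timepoint family
  pw <- NULL
  if (!is.null(V)) {
    combs <- utils::combn(seq_along(tps), 2)
    rows <- apply(combs, 2, function(ij) {
      i <- ij[1]; j <- ij[2]
      ci <- contrast_vec(names(b), li_term, int_terms, tps, i, j)
      est <- sum(ci * b)
      sed <- sqrt(drop(t(ci) %*% V %*% ci))
      tv <- est / sed
      data.frame(
        contrast = paste(tps[j], "-", tps[i]), diff = est, se = sed, t = tv,
        p_tukey = stats::ptukey(abs(tv) * sqrt(2), length(tps), df,
                                lower.tail = FALSE),
        stringsAsFactors = FALSE
      )
    })
    pw <- do.call(rbind, rows)
  }
  attr(out, "pairwise") <- pw
  out
}

# Contrast vector for slope(tps[j]) - slope(tps[i]).
contrast_vec <- function(coef_names, li_term, int_terms, tps, i, j) {
  v <- stats::setNames(numeric(length(coef_names)), coef_names)
  if (i > 1L) v[int_terms[i - 1L]] <- v[int_terms[i - 1L]] - 1
  if (j > 1L) v[int_terms[j - 1L]] <- v[int_terms[j - 1L]] + 1
  v
}
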