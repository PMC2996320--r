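## The three conjoint-measurement tests (equivalence, transitivity,
## dominance) plus eccentricity-error and expected-gain accounting.

mapping_table <- function() {
  data.frame(mapping = c("LOW.MED", "MED.HIGH", "HIGH.LOW"),
             from = c("LOW", "MED", "HIGH"),
             to = c("MED", "HIGH", "LOW"),
             stringsAsFactors = FALSE)
}

## ---- equivalence transformations ------------------------------------------

#' Fit a log-linear equivalence transformation to the PSEs of one mapping
#'
#' Under the Quick-Weibull family, the eccentricity at contrast 2 judged
#' equally discriminable to eccentricity \eqn{e_1} at contrast 1 is log-linear
#' in \eqn{e_1}: \eqn{\log e_2 = a + b \log e_1} with slope equal to the
#' ratio of the two steepness parameters (\eqn{b = \beta_1/\beta_2}) and
#' intercept \eqn{a = \log\tau_2 - b\log\tau_1}. This function estimates
#' \eqn{(a, b)} by ordinary least squares of log PSE on log fixed
#' eccentricity over the staircases of one mapping (natural logarithms).
#'
#' @param points list of [estimate_pse()] results (or a data frame with
#'   columns `fixed_ecc` and `pse`), all from staircases of the same
#'   contrast mapping; 4 in the standard protocol (levels 0.6-0.9).
#' @return An object of class `"equivalence_transform"` with fields `from`,
#'   `to`, `intercept` (log-degrees) and `slope` (dimensionless).
#' @export
fit_equivalence_transform <- function(points) {
  if (is.data.frame(points)) {
    fx <- points$fixed_ecc; ps <- points$pse
    from <- points$fixed_contrast[1L] %||% NA_character_
    to <- points$variable_contrast[1L] %||% NA_character_
  } else {
    fx <- vapply(points, `[[`, numeric(1L), "fixed_ecc")
    ps <- vapply(points, `[[`, numeric(1L), "pse")
    from <- unique(vapply(points, `[[`, character(1L), "fixed_contrast"))
    to <- unique(vapply(points, `[[`, character(1L), "variable_contrast"))
    if (length(from) != 1L || length(to) != 1L)
      stop("all points must come from staircases of the same contrast mapping")
  }
  if (length(unique(fx)) < 2L)
    stop("need PSEs at >= 2 distinct fixed eccentricities to fit a transform")
  x <- log(fx); y <- log(ps)
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  structure(list(from = from, to = to, intercept = intercept, slope = slope),
            class = "equivalence_transform")
}

#' @export
print.equivalence_transform <- function(x, ...) {
  cat(sprintf("Equivalence transform %s -> %s: log e2 = %.4f + %.4f log e1\n",
              x$from, x$to, x$intercept, x$slope))
  invisible(x)
}

#' Composite transitivity statistics from the three equivalence transforms
#'
#' Composes the LOW-to-MED, MED-to-HIGH and HIGH-to-LOW log-linear transforms
#' around the contrast cycle. If choices are transitive the composite must be
#' the identity map, so its intercept `a` and slope deviation `b` (composite
#' slope minus 1) are both zero. Composition in log space:
#' composite slope \eqn{B = b_{LM} b_{MH} b_{HL}}, composite intercept
#' \eqn{A = a_{HL} + b_{HL}(a_{MH} + b_{MH} a_{LM})}; the statistics are
#' \eqn{a = A} and \eqn{b = B - 1}.
#'
#' @param t_lm,t_mh,t_hl [fit_equivalence_transform()] results for the
#'   LOW-to-MED, MED-to-HIGH and HIGH-to-LOW mappings (checked when the
#'   transforms carry contrast labels).
#' @return Named numeric vector `c(a = ..., b = ...)`.
#' @export
transitivity_statistics <- function(t_lm, t_mh, t_hl) {
  chk <- function(tr, from, to) {
    if (!is.na(tr$from %||% NA) && !is.na(tr$to %||% NA) &&
        (tr$from != from || tr$to != to))
      stop(sprintf("expected a %s -> %s transform, got %s -> %s (not a contrast cycle)",
                   from, to, tr$from, tr$to))
  }
  chk(t_lm, "LOW", "MED"); chk(t_mh, "MED", "HIGH"); chk(t_hl, "HIGH", "LOW")
  B <- t_lm$slope * t_mh$slope * t_hl$slope
  A <- t_hl$intercept + t_hl$slope * (t_mh$intercept + t_mh$slope * t_lm$intercept)
  c(a = A, b = B - 1)
}

## ---- transitivity test -----------------------------------------------------

# Empirical preference function of one staircase: logistic regression of
# the choice (variable chosen?) on the variable eccentricity. Degenerate
# all-one-choice records get a flat p of 0 or 1.
fit_preference <- function(record) {
  y <- as.integer(record$choices == "VARIABLE")
  if (length(unique(y)) == 1L)
    return(c(if (y[1L] == 1L) 1e3 else -1e3, 0))
  if (stats::var(record$trajectory) < 1e-12)   # single visited eccentricity
    return(c(stats::qlogis(mean(y)), 0))
  f <- suppressWarnings(stats::glm.fit(cbind(1, record$trajectory), y,
                                       family = stats::binomial()))
  cf <- unname(f$coefficients)
  if (any(!is.finite(cf))) c(stats::qlogis(mean(y)), 0) else cf
}

# Model-based staircase bootstrap ("re-walk"): resampled PSE matrix
# (B x n_records). For each staircase, B fresh one-up one-down walks are
# generated from the empirically fitted preference function (same start,
# step, length and clipping as the original), and the reversal-mean PSE is
# re-estimated on each. This reproduces the estimator's sampling
# distribution, including the serial dependence of the walk that a naive
# resampling of reversal values would ignore. Re-walks with too few
# reversals fall back to the tail-half trajectory mean.
bootstrap_pses <- function(records, B, discard = 2L) {
  out <- vapply(records, function(r) {
    cf <- fit_preference(r)
    sp <- r$spec
    n <- sp$n_trials
    e <- rep(sp$start, B)
    traj <- matrix(0, B, n)
    dirs <- matrix(0L, B, n)
    for (t in seq_len(n)) {
      traj[, t] <- e
      p_var <- stats::plogis(cf[1L] + cf[2L] * e)
      d <- ifelse(stats::runif(B) < p_var, 1L, -1L)
      dirs[, t] <- d
      e <- clip_ecc(e + d * sp$step)
    }
    flips <- dirs[, -1L, drop = FALSE] != dirs[, -n, drop = FALSE]
    pse <- numeric(B)
    half <- seq.int(floor(n / 2) + 1L, n)
    for (b in seq_len(B)) {
      re <- traj[b, c(FALSE, flips[b, ])]
      pse[b] <- if (length(re) >= discard + 2L) mean(re[-seq_len(discard)])
                else mean(traj[b, half])
    }
    pse
  }, numeric(B))
  if (B == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(records)))
  out
}

# Vectorised OLS of log PSE on log fixed eccentricity: Y is B x k.
boot_loglinear <- function(fixed_ecc, Y) {
  x <- log(fixed_ecc)
  xc <- x - mean(x)
  slope <- drop(log(Y) %*% xc) / sum(xc^2)
  intercept <- rowMeans(log(Y)) - slope * mean(x)
  list(intercept = intercept, slope = slope)
}

#' Bootstrap test of transitivity from the 12-staircase battery
#'
#' Fits the three per-mapping equivalence transforms to the staircase PSEs,
#' composes them into the statistics `(a, b)` of
#' [transitivity_statistics()], and attaches 95% percentile bootstrap
#' confidence intervals, Bonferroni-corrected for the two statistics (each
#' interval at size `alpha/2`). The bootstrap resamples the staircase data
#' with a model-based re-walk: within each staircase the preference
#' function is fitted by logistic regression of the choices on the variable
#' eccentricity, B fresh staircase runs are regenerated from it, the PSEs
#' re-estimated and the composite statistics recomputed. The observer's
#' choices are judged intransitive if either interval excludes zero.
#'
#' @param records named list of the 12 `staircase_record`s (from
#'   [run_decision_phase()]), or any list covering all three mappings.
#' @param B number of bootstrap resamples (default 10000).
#' @param alpha overall significance level before Bonferroni correction.
#' @param discard reversals discarded by [estimate_pse()].
#' @param seed optional seed for the resampling.
#' @param pse_fallback passed to [estimate_pse()]: tail-mean fallback for
#'   degenerate staircases instead of an error.
#' @return An object of class `"transitivity_test"`: `a`, `b`, `ci_a`,
#'   `ci_b`, `intransitive`, the three fitted `transforms`, and the
#'   bootstrap draws.
#' @export
transitivity_test <- function(records, B = 10000L, alpha = 0.05,
                              discard = 2L, seed = NULL,
                              pse_fallback = FALSE) {
  points <- lapply(records, estimate_pse, discard = discard,
                   fallback = pse_fallback)
  mt <- mapping_table()
  by_map <- lapply(mt$mapping, function(m)
    points[vapply(points, `[[`, character(1L), "mapping") == m])
  names(by_map) <- mt$mapping
  if (any(lengths(by_map) < 2L))
    stop("need >= 2 staircases per contrast mapping for the transitivity test")
  transforms <- lapply(by_map, fit_equivalence_transform)
  ab <- transitivity_statistics(transforms$LOW.MED, transforms$MED.HIGH,
                                transforms$HIGH.LOW)
  with_seed(seed, {
    Y <- bootstrap_pses(records, B, discard)
    fits <- lapply(mt$mapping, function(m) {
      idx <- vapply(points, `[[`, character(1L), "mapping") == m
      boot_loglinear(vapply(points[idx], `[[`, numeric(1L), "fixed_ecc"),
                     Y[, idx, drop = FALSE])
    })
    names(fits) <- mt$mapping
    B_slope <- fits$LOW.MED$slope * fits$MED.HIGH$slope * fits$HIGH.LOW$slope
    A_int <- fits$HIGH.LOW$intercept +
      fits$HIGH.LOW$slope * (fits$MED.HIGH$intercept +
                             fits$MED.HIGH$slope * fits$LOW.MED$intercept)
    a_boot <- A_int
    b_boot <- B_slope - 1
    pr <- c(alpha / 4, 1 - alpha / 4)  # per-test size alpha/2 (2 conditions)
    ci_a <- unname(stats::quantile(a_boot, pr))
    ci_b <- unname(stats::quantile(b_boot, pr))
    structure(list(a = unname(ab["a"]), b = unname(ab["b"]),
                   ci_a = ci_a, ci_b = ci_b,
                   intransitive = (ci_a[1L] > 0 || ci_a[2L] < 0 ||
                                   ci_b[1L] > 0 || ci_b[2L] < 0),
                   transforms = transforms, points = points,
                   B = B, alpha = alpha,
                   boot = data.frame(a = a_boot, b = b_boot)),
              class = "transitivity_test")
  })
}

#' @export
print.transitivity_test <- function(x, ...) {
  cat(sprintf("Transitivity test (B = %d, overall alpha = %g, Bonferroni x2):\n",
              x$B, x$alpha))
  cat(sprintf("  a (composite intercept) = %.4f, CI [%.4f, %.4f]\n",
              x$a, x$ci_a[1L], x$ci_a[2L]))
  cat(sprintf("  b (composite slope - 1) = %.4f, CI [%.4f, %.4f]\n",
              x$b, x$ci_b[1L], x$ci_b[2L]))
  cat(sprintf("  => choices %s\n",
              if (x$intransitive) "INTRANSITIVE" else "consistent with transitivity"))
  invisible(x)
}

## ---- equivalence test ------------------------------------------------------

# Per-contrast binomial counts from calibration trials.
calib_counts <- function(calib) {
  lapply(stats::setNames(contrast_levels(), contrast_levels()), function(lv) {
    sub <- calib[calib$contrast == lv, ]
    qw_aggregate(sub$eccentricity, sub$correct)
  })
}

fit_calibration <- function(calib) {
  lapply(stats::setNames(contrast_levels(), contrast_levels()), function(lv)
    fit_psychometric(calib[calib$contrast == lv, ], contrast = lv))
}

# Signed probability difference of an equivalence point: true probability of
# the lower-contrast member minus that of the higher-contrast member.
signed_dp <- function(curves, mapping, level, fixed_ecc, pse) {
  mt <- mapping_table()
  m <- mt[mt$mapping == mapping, ]
  p_fixed <- predict(curves[[m$from]], fixed_ecc)
  p_var <- predict(curves[[m$to]], clip_ecc(pse))
  if (contrast_rank(m$from) < contrast_rank(m$to)) p_fixed - p_var
  else p_var - p_fixed
}

#' Bootstrap equivalence test of the 12 subjective-indifference pairs
#'
#' For each staircase, compares the *actual* probabilities correct (from the
#' fitted calibration curves) of the fixed target and of the variable target
#' at its PSE. If the observer judges pairs that really are equally
#' discriminable, every signed difference
#' \eqn{\Delta p} (lower-contrast member minus higher-contrast member) is
#' zero. Percentile bootstrap confidence intervals are computed per pair at
#' size `alpha/12` (Bonferroni over the 12 pairs); by default each resample
#' redraws the calibration trials (binomially within every
#' contrast-by-eccentricity cell, with curve refits) and the staircase data
#' (model-based re-walks within staircase, see [transitivity_test()]).
#' A two-tailed one-sample t-test of the 12
#' signed differences tests for a systematic over- or under-estimation of
#' the contrast effect.
#'
#' Also reports eccentricity errors: the PSE minus the *correct* eccentricity
#' (where the variable contrast truly matches the fixed target's probability),
#' and their median absolute value.
#'
#' @param records named list of 12 `staircase_record`s.
#' @param calib calibration trials with `contrast`, `eccentricity`,
#'   `correct` columns; required when `refit = TRUE` or `fits` is missing.
#' @param fits optional named list of per-contrast fitted curves (or
#'   `psychometric_fit`s); fitted from `calib` when omitted.
#' @param B bootstrap resamples (default 10000); a warning is issued below
#'   100.
#' @param alpha overall significance level (default .05; per-pair size
#'   `alpha/12`).
#' @param refit logical: refit the calibration curves in every resample
#'   (default) or hold them fixed at the point estimates.
#' @param discard reversals discarded by [estimate_pse()].
#' @param seed optional seed for the resampling.
#' @param pse_fallback passed to [estimate_pse()]: tail-mean fallback for
#'   degenerate staircases instead of an error.
#' @return An object of class `"equivalence_test"`: a per-pair `table`
#'   (mapping, level, fixed and PSE eccentricities, probabilities, `dp`, CI
#'   bounds, `significant`, `correct_ecc`, `ecc_error`), plus
#'   `mean_signed_dp`, `t_p_value`, `median_abs_ecc_error`, `n_significant`.
#' @export
equivalence_test <- function(records, calib = NULL, fits = NULL,
                             B = 10000L, alpha = 0.05,
                             refit = !is.null(calib), discard = 2L,
                             seed = NULL, pse_fallback = FALSE) {
  if (is.null(fits)) {
    if (is.null(calib)) stop("supply either calibration trials or fitted curves")
    fits <- fit_calibration(calib)
  }
  if (refit && is.null(calib))
    stop("refitting the curves in the bootstrap requires the calibration trials")
  if (B < 100L) warning("B < 100 bootstrap resamples: confidence intervals unstable")
  curves <- as_curve_map(fits)
  points <- lapply(records, estimate_pse, discard = discard,
                   fallback = pse_fallback)
  tab <- data.frame(
    mapping = vapply(points, `[[`, character(1L), "mapping"),
    level = vapply(points, `[[`, numeric(1L), "level"),
    fixed_ecc = vapply(points, `[[`, numeric(1L), "fixed_ecc"),
    pse = vapply(points, `[[`, numeric(1L), "pse"),
    row.names = NULL, stringsAsFactors = FALSE)
  mt <- mapping_table()
  from <- mt$from[match(tab$mapping, mt$mapping)]
  to <- mt$to[match(tab$mapping, mt$mapping)]
  tab$p_fixed <- mapply(function(f, e) predict(curves[[f]], e), from, tab$fixed_ecc)
  tab$p_variable <- mapply(function(t_, e) predict(curves[[t_]], e), to, tab$pse)
  tab$dp <- mapply(signed_dp, tab$mapping, tab$level, tab$fixed_ecc, tab$pse,
                   MoreArgs = list(curves = curves))
  tab$correct_ecc <- mapply(function(t_, p) qw_invert(curves[[t_]], p),
                            to, pmin(tab$p_fixed, 1 - 1e-12))
  tab$ecc_error <- tab$pse - tab$correct_ecc

  counts <- if (refit) calib_counts(calib) else NULL
  n_pair <- nrow(tab)
  with_seed(seed, {
    pse_boot <- bootstrap_pses(records, B, discard)     # B x 12
    dp_boot <- matrix(NA_real_, B, n_pair)
    for (b in seq_len(B)) {
      cb <- if (refit) {
        lapply(stats::setNames(contrast_levels(), contrast_levels()),
               function(lv) {
                 cc <- counts[[lv]]
                 kstar <- stats::rbinom(nrow(cc), cc$n, cc$k / cc$n)
                 ft <- qw_fit_counts(cc$e, cc$n, kstar,
                                     start = c(curves[[lv]]$tau, curves[[lv]]$beta))
                 quick_weibull(ft$tau, ft$beta)
               })
      } else curves
      dp_boot[b, ] <- mapply(signed_dp, tab$mapping, tab$level, tab$fixed_ecc,
                             pse_boot[b, ], MoreArgs = list(curves = cb))
    }
    pr <- c(alpha / 24, 1 - alpha / 24)  # per-pair size alpha/12
    ci <- apply(dp_boot, 2L, stats::quantile, probs = pr)
    tab$ci_lo <- ci[1L, ]; tab$ci_hi <- ci[2L, ]
    tab$significant <- tab$ci_lo > 0 | tab$ci_hi < 0
    sd_dp <- if (n_pair >= 2L) stats::sd(tab$dp) else NA_real_
    t_p <- if (is.na(sd_dp)) {
      NA_real_
    } else if (sd_dp < 1e-14) {
      if (abs(mean(tab$dp)) < 1e-14) 1 else NA_real_
    } else stats::t.test(tab$dp)$p.value
    structure(list(table = tab,
                   mean_signed_dp = mean(tab$dp),
                   t_p_value = t_p,
                   median_abs_ecc_error = stats::median(abs(tab$ecc_error)),
                   n_significant = sum(tab$significant),
                   B = B, alpha = alpha, refit = refit,
                   fits = fits),
              class = "equivalence_test")
  })
}

#' @export
print.equivalence_test <- function(x, ...) {
  cat(sprintf("Equivalence test (B = %d, per-pair size %.4f):\n",
              x$B, x$alpha / 12))
  cat(sprintf("  %d of %d pairs with significant probability difference\n",
              x$n_significant, nrow(x$table)))
  cat(sprintf("  mean signed dp = %+.4f (t-test p = %.4g)\n",
              x$mean_signed_dp, x$t_p_value))
  cat(sprintf("  median |eccentricity error| = %.2f deg\n",
              x$median_abs_ecc_error))
  invisible(x)
}

## ---- dominance test --------------------------------------------------------

#' Dominance test on the equi-contrast and equi-eccentricity trials
#'
#' A dominance error is choosing the larger eccentricity when contrasts are
#' equal (equi-contrast trials) or the lower contrast when eccentricities
#' are equal (equi-eccentricity trials). Error rates come with 95%
#' equal-tailed intervals obtained by treating the true error proportion as
#' beta-distributed with parameters set by the observed error and non-error
#' counts plus one (a uniform prior): `Beta(errors + 1, n - errors + 1)`.
#'
#' @param trials completed dominance trials (stubs from
#'   [generate_dominance_design()] with the `choice` column filled in,
#'   `"FIRST"` = pair a chosen).
#' @param alpha interval level (default 0.05 for 95% intervals).
#' @return A data frame of class `"dominance_test"` with one row per
#'   condition: `condition`, `n`, `errors`, `rate`, `ci_lo`, `ci_hi`.
#' @export
dominance_test <- function(trials, alpha = 0.05) {
  stopifnot(is.data.frame(trials), "choice" %in% names(trials))
  ec <- trials$origin == "EQUI_CONTRAST"
  if (any(ec & (trials$contrast_a != trials$contrast_b |
                trials$ecc_a == trials$ecc_b)))
    stop("equi-contrast trial with unequal contrasts or equal eccentricities")
  ee <- trials$origin == "EQUI_ECCENTRICITY"
  if (any(ee & (trials$ecc_a != trials$ecc_b |
                trials$contrast_a == trials$contrast_b)))
    stop("equi-eccentricity trial with unequal eccentricities or equal contrasts")
  chose_a <- trials$choice == "FIRST"
  err <- ifelse(ec,
                ifelse(chose_a, trials$ecc_a > trials$ecc_b,
                       trials$ecc_b > trials$ecc_a),
                ifelse(chose_a,
                       contrast_rank(trials$contrast_a) < contrast_rank(trials$contrast_b),
                       contrast_rank(trials$contrast_b) < contrast_rank(trials$contrast_a)))
  one <- function(cond) {
    n <- sum(trials$origin == cond)
    k <- sum(err[trials$origin == cond])
    ci <- stats::qbeta(c(alpha / 2, 1 - alpha / 2), k + 1, n - k + 1)
    data.frame(condition = cond, n = n, errors = k, rate = k / n,
               ci_lo = ci[1L], ci_hi = ci[2L])
  }
  out <- rbind(one("EQUI_CONTRAST"), one("EQUI_ECCENTRICITY"))
  class(out) <- c("dominance_test", "data.frame")
  out
}

## ---- expected gain ---------------------------------------------------------

#' Expected-gain loss from suboptimal choices
#'
#' Each decision trial offers two targets; the observer would later attempt
#' the chosen one for a fixed reward per correct classification. Choosing the
#' target with the lower true probability correct forgoes
#' \eqn{(\max(p_A, p_B) - p_{chosen}) \times \mathrm{reward}} in expectation.
#' The loss fraction is total forgone gain over the ideal expected gain
#' \eqn{\sum \max(p_A, p_B) \times \mathrm{reward}}; it is 0 exactly when
#' every choice was truly optimal (up to ties).
#'
#' @param trials data frame of completed decision trials (staircase and/or
#'   dominance) with columns `ecc_a`, `contrast_a`, `ecc_b`, `contrast_b`,
#'   `choice` (`"FIRST"`/`"SECOND"`).
#' @param curves named list of *true* per-contrast curves (fits or
#'   [quick_weibull()] objects).
#' @param reward reward per correct classification (default 5, in the
#'   currency of the protocol).
#' @return An object of class `"gain_report"`: `reward_per_correct`,
#'   `ideal_expected_gain`, `actual_expected_gain`, `loss_fraction`,
#'   `n_trials`.
#' @export
expected_gain_loss <- function(trials, curves, reward = 5) {
  curves <- as_curve_map(curves)
  p_of <- function(contrast, ecc) {
    p <- numeric(length(ecc))
    for (lv in contrast_levels()) {
      i <- contrast == lv
      if (any(i)) p[i] <- predict(curves[[lv]], ecc[i])
    }
    p
  }
  pa <- p_of(trials$contrast_a, trials$ecc_a)
  pb <- p_of(trials$contrast_b, trials$ecc_b)
  p_chosen <- ifelse(trials$choice == "FIRST", pa, pb)
  ideal <- sum(pmax(pa, pb)) * reward
  actual <- sum(p_chosen) * reward
  structure(list(reward_per_correct = reward,
                 ideal_expected_gain = ideal,
                 actual_expected_gain = actual,
                 loss_fraction = (ideal - actual) / ideal,
                 n_trials = nrow(trials)),
            class = "gain_report")
}

#' @export
print.gain_report <- function(x, ...) {
  cat(sprintf("Expected gain over %d trials: ideal %.2f, actual %.2f (loss %.2f%%)\n",
              x$n_trials, x$ideal_expected_gain, x$actual_expected_gain,
              100 * x$loss_fraction))
  invisible(x)
}
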