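test_that("noiseless PSE transforms are log-linear with slope = beta ratio", {
  # (tau1=5, beta1=2) -> (tau2=8, beta2=2): slope 1, intercept ln(8/5)
  c1 <- quick_weibull(5, 2); c2 <- quick_weibull(8, 2)
  fx <- qw_invert(c1, c(0.6, 0.7, 0.8, 0.9))
  pts <- data.frame(fixed_ecc = fx,
                    pse = sapply(fx, function(e) match_point_uniroot(c1, c2, e)),
                    fixed_contrast = "LOW", variable_contrast = "MED")
  tr <- fit_equivalence_transform(pts)
  expect_equal(tr$slope, 1, tolerance = 1e-6)
  expect_equal(tr$intercept, log(8 / 5), tolerance = 1e-6)

  # differing steepness: slope equals the beta ratio
  c3 <- quick_weibull(5, 2); c4 <- quick_weibull(8, 1)
  pts2 <- data.frame(fixed_ecc = fx,
                     pse = sapply(fx, function(e) match_point_uniroot(c3, c4, e)),
                     fixed_contrast = "LOW", variable_contrast = "MED")
  tr2 <- fit_equivalence_transform(pts2)
  expect_equal(tr2$slope, 2, tolerance = 1e-6)

  # identical curves: identity transform
  pts3 <- data.frame(fixed_ecc = fx,
                     pse = sapply(fx, function(e) match_point_uniroot(c1, c1, e)),
                     fixed_contrast = "LOW", variable_contrast = "MED")
  tr3 <- fit_equivalence_transform(pts3)
  expect_equal(tr3$slope, 1, tolerance = 1e-9)
  expect_equal(tr3$intercept, 0, tolerance = 1e-9)

  expect_error(fit_equivalence_transform(pts[c(1, 1), ]), "distinct")
})

test_that("transitivity statistics compose transforms around the cycle", {
  idt <- function(from, to)
    structure(list(from = from, to = to, intercept = 0, slope = 1),
              class = "equivalence_transform")
  expect_equal(transitivity_statistics(idt("LOW", "MED"), idt("MED", "HIGH"),
                                       idt("HIGH", "LOW")),
               c(a = 0, b = 0))
  sl <- function(from, to, s)
    structure(list(from = from, to = to, intercept = 0, slope = s),
              class = "equivalence_transform")
  ab <- transitivity_statistics(sl("LOW", "MED", 1.2), sl("MED", "HIGH", 1.2),
                                sl("HIGH", "LOW", 1.2))
  expect_equal(ab[["b"]], 1.2^3 - 1)
  expect_equal(ab[["a"]], 0)
  expect_error(transitivity_statistics(sl("LOW", "MED", 1), sl("LOW", "MED", 1),
                                       sl("HIGH", "LOW", 1)), "cycle")
})

test_that("any transitive subjective triple composes to the identity", {
  for (s in 1:5) {
    pars <- withr::with_seed(500 + s,
                             cbind(tau = runif(3, 3, 9), beta = runif(3, 1, 4)))
    sub <- list(LOW = quick_weibull(pars[1, 1], pars[1, 2]),
                MED = quick_weibull(pars[2, 1], pars[2, 2]),
                HIGH = quick_weibull(pars[3, 1], pars[3, 2]))
    pts <- exact_points(sub, fixed_map = sub)
    mp <- sapply(pts, `[[`, "mapping")
    tr <- lapply(split(pts, mp), fit_equivalence_transform)
    ab <- transitivity_statistics(tr$LOW.MED, tr$MED.HIGH, tr$HIGH.LOW)
    expect_equal(ab[["a"]], 0, tolerance = 1e-9)
    expect_equal(ab[["b"]], 0, tolerance = 1e-9)
  }
})

test_that("signed probability differences reflect the true-map gap", {
  # a pair whose members truly sit at p = 0.93 and p = 0.61 differs by 0.32
  curves <- map3(c(5, 6, 7.2))
  fe <- qw_invert(curves$LOW, 0.93)
  pse <- qw_invert(curves$MED, 0.61)
  rec <- fake_record(c(pse - 0.6, rep(pse, 6)),
                     c(1L, -1L, 1L, -1L, 1L, -1L, 1L),
                     spec = staircase_spec(fe, "LOW", "MED", level = 0.9))
  suppressWarnings(
    eq <- equivalence_test(list(`LOW.MED@0.9` = rec), fits = curves, B = 50,
                           refit = FALSE, seed = 1))
  expect_equal(abs(eq$table$dp), 0.32, tolerance = 1e-9)
  expect_equal(eq$table$dp, 0.93 - 0.61, tolerance = 1e-9)
})

test_that("a veridical noiseless observer shows no equivalence failure", {
  curves <- map3(c(5, 6, 7.2))
  pts <- exact_points(curves)
  recs <- lapply(pts, function(p) {
    fake_record(rep(p$pse, 8), rep(c(1L, -1L), 4),
                spec = staircase_spec(p$fixed_ecc, p$fixed_contrast,
                                      p$variable_contrast, level = p$level,
                                      start = p$pse))
  })
  names(recs) <- sapply(pts, function(p) sprintf("%s@%g", p$mapping, p$level))
  suppressWarnings(
    eq <- equivalence_test(recs, fits = curves, B = 50, refit = FALSE))
  expect_true(all(abs(eq$table$dp) < 1e-12))
  expect_equal(eq$n_significant, 0L)
  expect_equal(eq$t_p_value, 1)
  expect_lt(eq$median_abs_ecc_error, 1e-9)
})

test_that("uniform contrast-effect underestimation gives same-signed dp", {
  true_map <- map3(c(5, 6, 7.2))
  taus <- sapply(true_map, function(cv) cv$tau)
  sub <- map3((taus + mean(taus)) / 2)   # compressed contrast effect
  pts <- exact_points(sub, fixed_map = true_map)
  dp <- sapply(pts, function(p)
    conjointvision:::signed_dp(true_map, p$mapping, p$level, p$fixed_ecc,
                               p$pse))
  expect_true(all(dp < 0))
})

test_that("dominance rates get beta intervals from the observed counts", {
  stub <- data.frame(origin = rep(c("EQUI_CONTRAST", "EQUI_ECCENTRICITY"),
                                  each = 30),
                     ecc_a = rep(c(4, 5), each = 30),
                     contrast_a = rep(c("LOW", "LOW"), each = 30),
                     ecc_b = rep(c(6, 5), each = 30),
                     contrast_b = rep(c("LOW", "MED"), each = 30))
  # zero errors: always choose the nearer / higher-contrast member
  stub$choice <- rep(c("FIRST", "SECOND"), each = 30)
  d0 <- dominance_test(stub)
  expect_equal(d0$errors, c(0L, 0L), ignore_attr = TRUE)
  expect_equal(d0$rate, c(0, 0))
  expect_equal(d0$ci_lo, rep(qbeta(0.025, 1, 31), 2), tolerance = 1e-12)
  expect_equal(d0$ci_hi, rep(qbeta(0.975, 1, 31), 2), tolerance = 1e-12)
  expect_lt(d0$ci_lo[1], 0.001); expect_gt(d0$ci_hi[1], 0.11)
  expect_lt(d0$ci_hi[1], 0.12)

  # 15 of 30 errors: rate one half, interval straddles it
  stub$choice <- rep(rep(c("FIRST", "SECOND"), 15), 2)
  stub$choice[1:30] <- rep(c("SECOND", "FIRST"), 15)
  d1 <- dominance_test(stub)
  expect_equal(d1$rate, c(0.5, 0.5))
  expect_true(all(d1$ci_lo < 0.5 & d1$ci_hi > 0.5))

  bad <- stub; bad$contrast_b[1] <- "HIGH"
  expect_error(dominance_test(bad), "equi-contrast")
})

test_that("dominance interval stays below chance for small error rates", {
  for (n in c(30L, 90L)) for (k in unique(pmin(n, c(0L, 3L, round(0.2 * n))))) {
    ci_hi <- qbeta(0.975, k + 1, n - k + 1)
    d <- dominance_test(data.frame(
      origin = "EQUI_CONTRAST", ecc_a = 4, contrast_a = "LOW",
      ecc_b = 6, contrast_b = "LOW",
      choice = rep(c("SECOND", "FIRST"), c(k, n - k)))[sample(n), ])
    expect_equal(d$ci_hi[1], ci_hi)
    if (k / n <= 0.2 && n >= 30) expect_lt(d$ci_hi[1], 0.5)
  }
})

test_that("gain accounting matches brute-force enumeration", {
  curves <- map3(c(5, 6, 7.2))
  # single worked trial: p 0.93 chosen over p 0.61 available -> loses $1.60
  tr1 <- data.frame(origin = "EQUI_ECCENTRICITY",
                    ecc_a = qw_invert(curves$LOW, 0.61), contrast_a = "LOW",
                    ecc_b = qw_invert(curves$MED, 0.93), contrast_b = "MED",
                    choice = "FIRST")
  g1 <- expected_gain_loss(tr1, curves, reward = 5)
  expect_equal(g1$ideal_expected_gain - g1$actual_expected_gain, 1.60,
               tolerance = 1e-9)
  expect_equal(g1$loss_fraction, 1.60 / (0.93 * 5), tolerance = 1e-9)

  # optimal chooser loses nothing
  tr2 <- tr1; tr2$choice <- "SECOND"
  expect_equal(expected_gain_loss(tr2, curves)$loss_fraction, 0)

  # random trial list against an independent per-trial summation
  set.seed(77)
  n <- 200
  tr <- data.frame(origin = "X",
                   ecc_a = runif(n, 2, 12.2),
                   contrast_a = sample(contrast_levels(), n, TRUE),
                   ecc_b = runif(n, 2, 12.2),
                   contrast_b = sample(contrast_levels(), n, TRUE),
                   choice = sample(c("FIRST", "SECOND"), n, TRUE))
  g <- expected_gain_loss(tr, curves, reward = 5)
  loss <- 0; ideal <- 0
  for (i in seq_len(n)) {       # brute force, one trial at a time
    pa <- predict(curves[[tr$contrast_a[i]]], tr$ecc_a[i])
    pb <- predict(curves[[tr$contrast_b[i]]], tr$ecc_b[i])
    pc <- if (tr$choice[i] == "FIRST") pa else pb
    loss <- loss + (max(pa, pb) - pc) * 5
    ideal <- ideal + max(pa, pb) * 5
  }
  expect_equal(g$loss_fraction, loss / ideal, tolerance = 1e-12)
})

test_that("transitivity bootstrap flags the corkscrew but not the veridical", {
  run_tt <- function(preset, s) {
    obs <- observer_preset(preset, seed = s)
    specs <- make_staircase_specs(obs$true_map)
    ph <- run_decision_phase(obs, specs, NULL, seed = derive_seed(s, "d"))
    transitivity_test(ph$records, B = 400, seed = derive_seed(s, "b"))
  }
  null_flags <- sapply(1:12, function(s) run_tt("veridical", s)$intransitive)
  expect_lte(mean(null_flags), 0.25)
  tt <- run_tt("corkscrew", 1)
  expect_gt(tt$b, 0)
  expect_lt(tt$a, 0)
  expect_gt(tt$ci_b[1], 0)   # slope deviation detected as positive
})
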