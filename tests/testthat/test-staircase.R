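test_that("spec validation enforces the staircase contract", {
  expect_error(staircase_spec(6, "LOW", "LOW"), "differ")
  expect_error(staircase_spec(6, "LOW", "MED", step = 0), "positive")
  expect_error(staircase_spec(14, "LOW", "MED"), "outside")
  specs <- make_staircase_specs(map3(c(5, 6, 7.2)))
  expect_length(specs, 12L)
  expect_equal(sum(vapply(specs, `[[`, integer(1), "n_trials")), 840L)
})

test_that("the one-up one-down rule moves the variable target correctly", {
  # subjective map rates the variable (MED) target far better everywhere:
  # the observer always chooses it, so it climbs until pinned at the ceiling
  sub <- list(LOW = quick_weibull(1.01, 2), MED = quick_weibull(1e6, 2),
              HIGH = quick_weibull(1e7, 2))
  always_var <- make_observer(map3(c(5, 6, 7.2)), subjective_map = sub,
                              noise = Inf)
  sp <- staircase_spec(6, "LOW", "MED", level = 0.75, n_trials = 30L)
  rec <- run_staircase(always_var, sp, seed = 1)
  expect_true(all(diff(rec$trajectory) >= 0))
  expect_equal(diff(rec$trajectory)[1:10], rep(sp$step, 10))
  expect_equal(rec$trajectory[30], 12.2)          # pinned at the boundary
  expect_length(rec$reversal_index, 0L)
  expect_error(estimate_pse(rec), "never converged")

  # indifferent observer: symmetric +/- step random walk
  rnd <- observer_preset("veridical", noise = 0)
  sp70 <- staircase_spec(6, "LOW", "MED", level = 0.75)
  steps <- unlist(lapply(1:20, function(s) {
    r <- run_staircase(rnd, sp70, seed = s)
    diff(r$trajectory)
  }))
  steps <- steps[abs(abs(steps) - 0.6) < 1e-9]    # drop clipped moves
  expect_lt(abs(mean(steps)), 3 * 0.6 / sqrt(length(steps)))
})

test_that("reversal bookkeeping matches a brute-force scan", {
  obs <- observer_preset("veridical", seed = 3)
  sp <- make_staircase_specs(obs$true_map)[["MED.HIGH@0.8"]]
  for (s in 1:10) {
    rec <- run_staircase(obs, sp, seed = 100 + s)
    d <- rec$directions
    brute <- which(d[-1] != d[-length(d)]) + 1L
    expect_identical(rec$reversal_index, brute)
    expect_identical(rec$reversal_ecc, rec$trajectory[brute])
    expect_true(all(abs(diff(rec$trajectory)) <= sp$step + 1e-12))
  }
})

test_that("PSE estimator is the post-discard reversal mean", {
  traj <- c(3, 4, 5, 6, 7, 8, 7, 6, 5, 6, 7, 6, 5, 6, 7, 6)
  dirs <- sign(c(diff(traj), -1))
  rec <- fake_record(traj, dirs)
  # reversals at trials where direction flips; first two discarded
  re <- rec$reversal_ecc
  expect_equal(estimate_pse(rec)$pse, mean(re[-(1:2)]))

  rec2 <- fake_record(c(2, 3, 4, 8, 6, 6),
                      c(1L, 1L, 1L, -1L, 1L, -1L))
  expect_error(estimate_pse(rec2), "need at least 4")
  expect_warning(p2 <- estimate_pse(rec2, fallback = TRUE), "tail-mean")
  expect_equal(p2$method, "tail")
})

test_that("constructed reversal sequence gives the documented PSE", {
  # reversal eccentricities [4, 8, 6, 6, 6, 6]: discard the first two
  rec <- fake_record(c(5, 4, 8, 6, 6, 6, 6),
                     c(1L, -1L, 1L, -1L, 1L, -1L, 1L))
  expect_equal(rec$reversal_ecc, c(4, 8, 6, 6, 6, 6))
  expect_equal(estimate_pse(rec)$pse, 6)
})

test_that("PSE converges to the subjective match point", {
  obs <- observer_preset("veridical", seed = 1)
  specs <- make_staircase_specs(obs$true_map)
  sp <- specs[["LOW.MED@0.7"]]
  target <- match_point(obs$subjective_map$LOW, obs$subjective_map$MED,
                        sp$fixed_ecc)
  hits <- sapply(1:60, function(s) {
    abs(estimate_pse(run_staircase(obs, sp, seed = s))$pse - target)
  })
  expect_gte(mean(hits <= 2 * sp$step), 0.95)
})

test_that("decision phase interleaves without disturbing staircase order", {
  obs <- observer_preset("veridical", seed = 7)
  specs <- make_staircase_specs(obs$true_map)
  dom <- generate_dominance_design(obs$true_map)
  ph <- run_decision_phase(obs, specs, dom)
  expect_equal(nrow(ph$log), 840L + 180L)
  expect_equal(sum(ph$log$origin == "STAIRCASE"), 840L)
  # within-staircase order is a subsequence of the stream
  for (id in names(specs)) {
    rows <- ph$log[ph$log$staircase_id == id, ]
    expect_equal(rows$trial_within, seq_len(70L))
    expect_true(all(diff(rows$trial) > 0))
    # and the logged variable eccentricities match the record trajectory
    expect_equal(rows$variable_eccentricity, ph$records[[id]]$trajectory)
  }
  expect_error(run_decision_phase(obs, specs[1:5], dom), "12 staircase")
})
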