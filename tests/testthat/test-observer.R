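test_that("calibration design reproduces the protocol exactly", {
  d <- generate_calibration_design(seed = 1)
  expect_equal(nrow(d), 1620L)                       # 3 x 18 x 5 x 6
  g <- sort(unique(d$eccentricity))
  expect_length(g, 18L)
  expect_equal(range(g), c(2, 12.2))
  expect_equal(unique(round(diff(g), 10)), 0.6)      # equal spacing
  # half top / half bottom within every block x contrast x eccentricity cell
  counts <- aggregate(stimulus == "TOP" ~ block + contrast + eccentricity,
                      data = transform(d, stimulus = stimulus), FUN = sum)
  expect_true(all(counts[[4]] == 3L))
  tot <- aggregate(rep(1, nrow(d)) ~ block + contrast + eccentricity,
                   data = d, FUN = sum)
  expect_true(all(tot[[4]] == 6L))
})

test_that("observer construction validates dominance of the true map", {
  expect_s3_class(observer_preset("veridical"), "observer_model")
  # HIGH worse than LOW everywhere: reversed position parameters
  expect_error(make_observer(map3(c(7.5, 6, 4))), "dominance")
  expect_error(make_observer(map3(c(7.5, 6, 4))), "eccentricity")
})

test_that("identical config and seed give identical trial streams", {
  run <- function() {
    obs <- observer_preset("veridical", seed = 9)
    d <- generate_calibration_design(seed = derive_seed(obs$seed, "design"))
    calib <- simulate_calibration(obs, d)
    specs <- make_staircase_specs(obs$true_map)
    dom <- generate_dominance_design(obs$true_map)
    ph <- run_decision_phase(obs, specs, dom)
    list(calib, ph$log, ph$dominance)
  }
  expect_identical(run(), run())
})

test_that("calibration responses follow the true map probabilities", {
  # essentially-perfect observer: huge position parameters, p ~ 1 everywhere
  perfect <- make_observer(map3(c(1e6, 2e6, 3e6)))
  d <- generate_calibration_design(seed = 5)
  expect_true(all(simulate_calibration(perfect, d, seed = 1)$correct))

  # near-chance observer: performance close to 0.5 over most of the grid
  near_chance <- make_observer(map3(c(2, 2.2, 2.4)))
  calib <- simulate_calibration(near_chance, d, seed = 2)
  p_true <- mapply(function(lv, e) predict(near_chance$true_map[[lv]], e),
                   calib$contrast, calib$eccentricity)
  phat <- mean(calib$correct)
  se <- sqrt(0.25 / nrow(calib))
  expect_lt(mean(p_true), 0.55)             # the regime is near chance
  expect_lt(abs(phat - mean(p_true)), 3 * se)

  # Monte-Carlo check of the closed form: tau = 6, beta = 2 at e = 6
  cv <- map3(c(5, 6, 7.2))
  obs <- make_observer(cv)
  dd <- data.frame(block = 1L, contrast = "MED", eccentricity = 6,
                   stimulus = rep(c("TOP", "BOTTOM"), 5000))
  sim <- simulate_calibration(obs, dd, seed = 3)
  expect_lt(abs(mean(sim$correct) - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
})

test_that("per-cell empirical proportions converge to the true map", {
  obs <- observer_preset("veridical", seed = 1)
  e <- rep(ecc_grid(), each = 556L)  # ~1e4 trials per contrast
  d <- data.frame(block = 1L, contrast = "LOW", eccentricity = e,
                  stimulus = "TOP")
  sim <- simulate_calibration(obs, d, seed = 4)
  agg <- aggregate(correct ~ eccentricity, data = sim, FUN = mean)
  p_true <- predict(obs$true_map$LOW, agg$eccentricity)
  se <- sqrt(p_true * (1 - p_true) / 556L)
  expect_true(all(abs(agg$correct - p_true) < 3.9 * se))
})

test_that("choice rules follow their definitions", {
  # deterministic veridical observer always picks the truly better pair
  det <- observer_preset("veridical_deterministic")
  good <- ecc_pair(qw_invert(det$true_map$LOW, 0.93), "LOW")
  bad <- ecc_pair(qw_invert(det$true_map$MED, 0.61), "MED")
  expect_equal(choice_prob(det, good, bad), 1)
  expect_identical(with_seed(1, simulate_choice(det, good, bad)), "FIRST")
  expect_identical(with_seed(1, simulate_choice(det, bad, good)), "SECOND")

  # zero inverse temperature: coin flip
  rnd <- observer_preset("veridical", noise = 0)
  expect_equal(choice_prob(rnd, good, bad), 0.5)

  # lexicographic semiorder: nearer wins beyond the threshold ...
  lex <- make_observer(map3(c(5, 6, 7.2)), rule = "lexicographic",
                       semiorder_threshold = 2)
  a <- ecc_pair(4, "LOW"); b <- ecc_pair(9, "HIGH")
  expect_equal(choice_prob(lex, a, b), 1)
  # ... and higher contrast wins within it
  expect_equal(choice_prob(lex, ecc_pair(4, "LOW"), ecc_pair(5, "HIGH")), 0)
})

test_that("dominance design uses the p = 0.75 points with protocol counts", {
  curves <- map3(c(5, 6, 7.2))
  d <- generate_dominance_design(curves)
  expect_equal(sum(d$origin == "EQUI_CONTRAST"), 90L)
  expect_equal(sum(d$origin == "EQUI_ECCENTRICITY"), 90L)
  expect_equal(nrow(d), 180L)
  eccs <- sort(unique(c(d$ecc_a, d$ecc_b)))
  expect_equal(eccs, sort(sapply(curves, qw_invert, p = 0.75)),
               ignore_attr = TRUE)
  ec <- d[d$origin == "EQUI_CONTRAST", ]
  expect_true(all(ec$contrast_a == ec$contrast_b & ec$ecc_a != ec$ecc_b))
  ee <- d[d$origin == "EQUI_ECCENTRICITY", ]
  expect_true(all(ee$ecc_a == ee$ecc_b & ee$contrast_a != ee$contrast_b))
  # a curve too shallow for the protocol: p75 point beyond the range
  steep <- map3(c(5, 6, 16.5))
  expect_error(generate_dominance_design(steep), "outside")
})
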