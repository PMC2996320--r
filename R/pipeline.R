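## Orchestration: simulate -> calibrate -> decide -> test -> report, for one
## or many synthetic observers, with JSON/CSV serialisation.

#' Configure a full simulated experiment
#'
#' Defaults reproduce the standard protocol exactly: 1620 calibration trials
#' (3 contrasts x 18 eccentricities x 5 blocks x 6 repetitions), 12
#' staircases of 70 trials (840), 90 + 90 dominance trials, and B = 10000
#' bootstrap resamples. `fast = TRUE` lowers B to 500 for quick runs;
#' everything else stays at protocol scale.
#'
#' @param observers a single [make_observer()] object or a list of them.
#' @param n_blocks,n_reps calibration design, see
#'   [generate_calibration_design()].
#' @param staircase_levels fixed-target probability levels.
#' @param step,staircase_trials staircase geometry, see [staircase_spec()].
#' @param dominance_reps repetitions per dominance combination.
#' @param B bootstrap resamples for both tests.
#' @param alpha overall significance level.
#' @param reward reward per correct classification.
#' @param seed master seed; per-observer, per-stage seeds are derived from
#'   it, so the whole experiment is a pure function of the config.
#' @param out_dir optional directory for trial CSVs and the JSON report.
#' @param fast logical; use the scaled-down bootstrap (B = 500).
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(observers,
                              n_blocks = 5L, n_reps = 6L,
                              staircase_levels = c(0.6, 0.7, 0.8, 0.9),
                              step = 0.6, staircase_trials = 70L,
                              dominance_reps = 10L,
                              B = if (fast) 500L else 10000L,
                              alpha = 0.05, reward = 5,
                              seed = 1L, out_dir = NULL, fast = FALSE) {
  if (inherits(observers, "observer_model")) observers <- list(observers)
  stopifnot(length(observers) >= 1L,
            all(vapply(observers, inherits, logical(1L), "observer_model")))
  if (is.null(names(observers)))
    names(observers) <- sprintf("S%d", seq_along(observers))
  structure(list(observers = observers, n_blocks = n_blocks, n_reps = n_reps,
                 staircase_levels = staircase_levels, step = step,
                 staircase_trials = staircase_trials,
                 dominance_reps = dominance_reps, B = as.integer(B),
                 alpha = alpha, reward = reward, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

run_one_observer <- function(obs, id, cfg) {
  stage <- "calibration design"
  res <- tryCatch({
    sd0 <- derive_seed(cfg$seed + obs$seed, id)
    design <- generate_calibration_design(cfg$n_blocks, cfg$n_reps,
                                          seed = derive_seed(sd0, "design"))
    stage <- "calibration simulation"
    calib <- simulate_calibration(obs, design,
                                  seed = derive_seed(sd0, "calibration"))
    stage <- "psychometric fitting"
    fits <- fit_calibration(calib)
    stage <- "decision design"
    specs <- make_staircase_specs(fits, cfg$staircase_levels, cfg$step,
                                  cfg$staircase_trials, boundary = "clip")
    dom <- generate_dominance_design(fits, cfg$dominance_reps,
                                     boundary = "clip")
    stage <- "decision phase"
    phase <- run_decision_phase(obs, specs, dom,
                                seed = derive_seed(sd0, "decision"))
    stage <- "equivalence test"
    eq <- equivalence_test(phase$records, calib, fits = fits, B = cfg$B,
                           alpha = cfg$alpha, pse_fallback = TRUE,
                           seed = derive_seed(sd0, "equivalence"))
    stage <- "transitivity test"
    tr <- transitivity_test(phase$records, B = cfg$B, alpha = cfg$alpha,
                            pse_fallback = TRUE,
                            seed = derive_seed(sd0, "transitivity"))
    stage <- "dominance test"
    dm <- dominance_test(phase$dominance, alpha = cfg$alpha)
    stage <- "gain accounting"
    choice_cols <- c("origin", "ecc_a", "contrast_a", "ecc_b", "contrast_b",
                     "choice")
    gain <- expected_gain_loss(phase$log[, choice_cols], fits,
                               reward = cfg$reward)
    list(id = id, fits = fits, calibration = calib, phase = phase,
         equivalence = eq, transitivity = tr, dominance = dm, gain = gain,
         converged = all(vapply(fits, `[[`, logical(1L), "converged")))
  }, error = function(e) {
    stop(sprintf("observer %s failed during %s: %s", id, stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}

#' Run the full simulated experiment
#'
#' Executes, for every observer in the configuration: calibration design and
#' simulation, per-contrast maximum-likelihood psychometric fits, the
#' interleaved decision phase (12 staircases + dominance trials), the
#' equivalence, transitivity and dominance tests, and expected-gain
#' accounting. All randomness derives from the config seed, so identical
#' configs give identical reports. When `out_dir` is set, trial logs are
#' written as CSV and the report as JSON (partial outputs are retained if a
#' later observer fails).
#'
#' @param config an [experiment_config()].
#' @return An object of class `"experiment_report"`: per-observer results
#'   plus the [summarize_cohort()] median table.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  results <- list()
  for (i in seq_along(config$observers)) {
    id <- names(config$observers)[i]
    res <- run_one_observer(config$observers[[i]], id, config)
    results[[id]] <- res
    if (!is.null(config$out_dir)) write_observer_outputs(res, config$out_dir)
  }
  report <- structure(list(observers = results,
                           cohort = summarize_cohort(results),
                           config = config),
                      class = "experiment_report")
  if (!is.null(config$out_dir))
    write_report(report, file.path(config$out_dir, "report.json"))
  report
}

#' Median summary across a cohort of observers
#'
#' Medians of the headline per-observer statistics: absolute eccentricity
#' error, the transitivity statistics a and b, the two dominance error
#' rates, and the expected-gain loss fraction. Only observers whose three
#' psychometric fits all converged enter the medians.
#'
#' @param results list of per-observer results as produced inside
#'   [run_experiment()] (an `experiment_report$observers` list).
#' @return A one-row data frame of medians plus the observer counts.
#' @export
summarize_cohort <- function(results) {
  if (length(results) == 0L) stop("empty cohort")
  ok <- vapply(results, function(r) isTRUE(r$converged), logical(1L))
  use <- results[ok]
  if (length(use) == 0L) use <- results  # degenerate: report over all
  g <- function(f) vapply(use, f, numeric(1L))
  data.frame(
    n_observers = length(results),
    n_converged = sum(ok),
    median_abs_ecc_error = stats::median(g(function(r) r$equivalence$median_abs_ecc_error)),
    median_a = stats::median(g(function(r) r$transitivity$a)),
    median_b = stats::median(g(function(r) r$transitivity$b)),
    median_equi_contrast_error_rate =
      stats::median(g(function(r) r$dominance$rate[r$dominance$condition == "EQUI_CONTRAST"])),
    median_equi_eccentricity_error_rate =
      stats::median(g(function(r) r$dominance$rate[r$dominance$condition == "EQUI_ECCENTRICITY"])),
    median_loss_fraction = stats::median(g(function(r) r$gain$loss_fraction)),
    n_intransitive = sum(g(function(r) as.numeric(r$transitivity$intransitive))))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment report: %d observer(s)\n", length(x$observers)))
  for (r in x$observers) {
    cat(sprintf("-- %s: %d/12 significant equivalence pairs, %s, loss %.1f%%\n",
                r$id, r$equivalence$n_significant,
                if (r$transitivity$intransitive) "intransitive" else "transitive",
                100 * r$gain$loss_fraction))
  }
  cat("Cohort medians:\n")
  print(x$cohort, row.names = FALSE)
  invisible(x)
}

## ---- serialisation ---------------------------------------------------------

report_to_list <- function(report) {
  obs_block <- lapply(report$observers, function(r) {
    list(
      fits = lapply(r$fits, function(f)
        list(contrast = f$contrast, tau = f$curve$tau, beta = f$curve$beta,
             log_likelihood = f$log_likelihood, n_trials = f$n_trials,
             converged = f$converged)),
      equivalence = list(
        table = r$equivalence$table,
        mean_signed_dp = r$equivalence$mean_signed_dp,
        t_p_value = r$equivalence$t_p_value,
        median_abs_ecc_error = r$equivalence$median_abs_ecc_error,
        n_significant = r$equivalence$n_significant),
      transitivity = list(
        a = r$transitivity$a, b = r$transitivity$b,
        ci_a = r$transitivity$ci_a, ci_b = r$transitivity$ci_b,
        intransitive = r$transitivity$intransitive,
        transforms = lapply(r$transitivity$transforms, function(tr)
          list(from = tr$from, to = tr$to, intercept = tr$intercept,
               slope = tr$slope))),
      dominance = as.data.frame(r$dominance),
      gain = unclass(r$gain))
  })
  list(observers = obs_block, cohort = report$cohort)
}

#' Write an experiment report to JSON
#'
#' @param report an `experiment_report` (or the list form).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  x <- if (inherits(report, "experiment_report")) report_to_list(report) else report
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

write_observer_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(format_ecc(res$calibration),
                   file.path(out_dir, sprintf("%s_calibration.csv", res$id)),
                   row.names = FALSE)
  utils::write.csv(format_ecc(res$phase$log),
                   file.path(out_dir, sprintf("%s_decision.csv", res$id)),
                   row.names = FALSE)
  invisible(out_dir)
}

# Eccentricities serialised with >= 3 decimal places.
format_ecc <- function(df) {
  for (nm in intersect(c("eccentricity", "ecc_a", "ecc_b",
                         "variable_eccentricity"), names(df)))
    df[[nm]] <- ifelse(is.na(df[[nm]]), NA, sprintf("%.4f", df[[nm]]))
  df
}

#' Read or write an observer configuration as JSON
#'
#' The JSON schema mirrors [make_observer()]: per-contrast `tau`/`beta` for
#' `true_map` and `subjective_map`, plus `rule`, `noise`,
#' `semiorder_threshold`, optional `transforms`, `lapse` and `seed`.
#'
#' @param path JSON file path.
#' @return `read_observer_config()`: an [make_observer()] object.
#' @export
read_observer_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_map <- function(m) lapply(stats::setNames(contrast_levels(), contrast_levels()),
                               function(lv) quick_weibull(m[[lv]]$tau, m[[lv]]$beta))
  tm <- as_map(cfg$true_map)
  sm <- if (is.null(cfg$subjective_map)) tm else as_map(cfg$subjective_map)
  noise <- cfg$noise %||% 20
  if (identical(noise, "Inf")) noise <- Inf
  make_observer(tm, sm,
                rule = cfg$rule %||% "subjective_prob",
                noise = noise,
                semiorder_threshold = cfg$semiorder_threshold %||% 2,
                transforms = cfg$transforms,
                lapse = cfg$lapse %||% 0,
                seed = cfg$seed %||% 1L)
}

#' @rdname read_observer_config
#' @param observer an [make_observer()] object.
#' @export
write_observer_config <- function(observer, path) {
  map_out <- function(m) lapply(m, function(cv) list(tau = cv$tau, beta = cv$beta))
  x <- list(true_map = map_out(observer$true_map),
            subjective_map = map_out(observer$subjective_map),
            rule = observer$rule,
            noise = if (is.infinite(observer$noise)) "Inf" else observer$noise,
            semiorder_threshold = observer$semiorder_threshold,
            transforms = observer$transforms,
            lapse = observer$lapse,
            seed = observer$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
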