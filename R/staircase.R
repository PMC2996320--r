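## One-up one-down adaptive staircases over the variable target's
## eccentricity, the interleaved decision-phase scheduler, and PSE
## estimation.

#' Specify one adaptive staircase
#'
#' A staircase pits a *fixed* eccentricity-contrast pair against a *variable*
#' pair of a different contrast whose eccentricity is adapted: every time the
#' observer chooses the variable target it is made harder (moved 1 step
#' outward), and every time the fixed target is chosen the variable target is
#' made easier (moved 1 step inward). This one-up one-down rule converges on
#' the eccentricity at which the observer is indifferent (chooses each target
#' half the time) — the point of subjective equality (PSE).
#'
#' @param fixed_ecc eccentricity of the fixed target, degrees.
#' @param fixed_contrast,variable_contrast contrast labels; must differ.
#' @param level the design probability-correct level of the fixed target
#'   (0.6, 0.7, 0.8 or 0.9 in the standard protocol); metadata used by the
#'   analysis.
#' @param start starting eccentricity of the variable target; defaults to
#'   the fixed target's eccentricity (a symmetric, unbiased start).
#' @param step step size in degrees (default 0.6, one grid spacing).
#' @param n_trials number of trials (default 70).
#' @return An object of class `"staircase_spec"`.
#' @export
staircase_spec <- function(fixed_ecc, fixed_contrast, variable_contrast,
                           level = NA_real_, start = fixed_ecc,
                           step = 0.6, n_trials = 70L) {
  fixed_contrast <- match.arg(fixed_contrast, contrast_levels())
  variable_contrast <- match.arg(variable_contrast, contrast_levels())
  if (fixed_contrast == variable_contrast)
    stop("fixed and variable contrasts must differ")
  if (step <= 0) stop("'step' must be positive")
  r <- ecc_range()
  if (fixed_ecc < r[1L] || fixed_ecc > r[2L])
    stop(sprintf("fixed eccentricity %.2f outside the stimulus range [%g, %g]",
                 fixed_ecc, r[1L], r[2L]))
  structure(list(fixed_ecc = fixed_ecc, fixed_contrast = fixed_contrast,
                 variable_contrast = variable_contrast, level = level,
                 start = clip_ecc(start), step = step,
                 n_trials = as.integer(n_trials)),
            class = "staircase_spec")
}

#' Build the standard 12-staircase battery from fitted calibration curves
#'
#' One staircase per combination of contrast mapping (LOW to MED, MED to
#' HIGH, HIGH to LOW) and fixed-target probability level (0.6, 0.7, 0.8,
#' 0.9). The fixed target of each staircase sits at the eccentricity where
#' the fitted curve of the *from* contrast reaches the level; the variable
#' target carries the *to* contrast.
#'
#' @param curves named list (`LOW`, `MED`, `HIGH`) of fitted curves or
#'   `psychometric_fit` objects.
#' @param levels fixed-target probability levels.
#' @param step,n_trials passed to [staircase_spec()].
#' @param boundary what to do when a fitted probability point falls outside
#'   the presentable stimulus range: `"error"` (default) or `"clip"` to the
#'   range limit with a warning, as an experimenter bound by the display
#'   would.
#' @return Named list of 12 `staircase_spec`s (names like `"LOW.MED@0.7"`).
#' @export
make_staircase_specs <- function(curves, levels = c(0.6, 0.7, 0.8, 0.9),
                                 step = 0.6, n_trials = 70L,
                                 boundary = c("error", "clip")) {
  curves <- as_curve_map(curves)
  boundary <- match.arg(boundary)
  maps <- list(c("LOW", "MED"), c("MED", "HIGH"), c("HIGH", "LOW"))
  specs <- list()
  for (m in maps) for (q in levels) {
    fe <- qw_invert(curves[[m[1L]]], q)
    r <- ecc_range()
    if (fe < r[1L] || fe > r[2L]) {
      if (boundary == "error")
        stop(sprintf(paste0("p = %.2f point of contrast %s (%.2f deg) falls outside ",
                            "the stimulus range: curve too steep or too shallow for the protocol"),
                     q, m[1L], fe))
      warning(sprintf("p = %.2f point of contrast %s (%.2f deg) clipped into the stimulus range",
                      q, m[1L], fe))
      fe <- clip_ecc(fe)
    }
    specs[[sprintf("%s.%s@%g", m[1L], m[2L], q)]] <-
      staircase_spec(fe, m[1L], m[2L], level = q, step = step,
                     n_trials = n_trials)
  }
  specs
}

# One staircase trial: present fixed vs variable (at eccentricity e), draw
# the observer's choice, and move the variable target one step (clipped to
# the stimulus range; a clip never counts as a direction change by itself
# because direction is defined by the choice, not the realised move).
staircase_advance <- function(observer, spec, e) {
  fixed <- list(eccentricity = spec$fixed_ecc, contrast = spec$fixed_contrast)
  varb <- list(eccentricity = e, contrast = spec$variable_contrast)
  choice <- if (stats::runif(1L) < choice_prob(observer, fixed, varb))
    "FIXED" else "VARIABLE"
  dir <- if (choice == "VARIABLE") 1L else -1L
  list(choice = choice, dir = dir, next_e = clip_ecc(e + dir * spec$step))
}

finish_record <- function(spec, trajectory, choices, dirs) {
  n <- length(trajectory)
  rev_idx <- if (n >= 2L) which(dirs[-1L] != dirs[-n]) + 1L else integer()
  structure(list(spec = spec,
                 trajectory = trajectory,
                 choices = choices,
                 directions = dirs,
                 reversal_index = rev_idx,
                 reversal_ecc = trajectory[rev_idx]),
            class = "staircase_record")
}

#' Run a single staircase in isolation
#'
#' @param observer an [make_observer()] object.
#' @param spec a [staircase_spec()].
#' @param seed optional seed (`NULL` = current RNG stream).
#' @return An object of class `"staircase_record"` with the per-trial
#'   `trajectory` (variable eccentricity presented on each trial), `choices`
#'   (`"FIXED"`/`"VARIABLE"`), movement `directions`, and the indices and
#'   eccentricities of the reversals (trials on which the movement direction
#'   flipped).
#' @seealso [estimate_pse()], [run_decision_phase()]
#' @export
run_staircase <- function(observer, spec, seed = NULL) {
  stopifnot(inherits(observer, "observer_model"),
            inherits(spec, "staircase_spec"))
  with_seed(seed, {
    n <- spec$n_trials
    trajectory <- numeric(n); choices <- character(n); dirs <- integer(n)
    e <- spec$start
    for (t in seq_len(n)) {
      trajectory[t] <- e
      st <- staircase_advance(observer, spec, e)
      choices[t] <- st$choice; dirs[t] <- st$dir; e <- st$next_e
    }
    finish_record(spec, trajectory, choices, dirs)
  })
}

#' @export
print.staircase_record <- function(x, ...) {
  cat(sprintf("Staircase %s -> %s (fixed %.2f deg @ p = %g): %d trials, %d reversals\n",
              x$spec$fixed_contrast, x$spec$variable_contrast,
              x$spec$fixed_ecc, x$spec$level, length(x$trajectory),
              length(x$reversal_index)))
  invisible(x)
}

#' Run the full decision phase: interleaved staircases plus dominance trials
#'
#' All staircase trials (12 staircases x 70 trials = 840 by default) and all
#' dominance trials (90 + 90) are mixed into a single randomly ordered
#' stream, as in the experimental protocol. Each staircase's state advances
#' only on its own trials, so the within-staircase trial order is preserved
#' as a subsequence of the stream.
#'
#' @param observer an [make_observer()] object.
#' @param specs list of 12 staircase specs from [make_staircase_specs()].
#' @param dominance dominance trial stubs from [generate_dominance_design()]
#'   (may be `NULL` to run staircases only).
#' @param seed integer seed; defaults to a stream derived from the
#'   observer's seed.
#' @return An object of class `"decision_phase"`: a list with `records`
#'   (named list of `staircase_record`s), `dominance` (the stubs with a
#'   `choice` column, `"FIRST"` = pair a), and `log` (one row per trial of
#'   the full stream, staircase and dominance trials alike).
#' @export
run_decision_phase <- function(observer, specs, dominance = NULL,
                               seed = derive_seed(observer$seed, "decision")) {
  stopifnot(inherits(observer, "observer_model"), is.list(specs))
  if (length(specs) != 12L)
    stop(sprintf("the decision phase takes 12 staircase specs, got %d",
                 length(specs)))
  n_dom <- if (is.null(dominance)) 0L else nrow(dominance)
  with_seed(seed, {
    slot_stair <- rep(seq_along(specs),
                      vapply(specs, function(s) s$n_trials, integer(1L)))
    slots <- sample(c(slot_stair, rep(0L, n_dom)))          # 0 = dominance
    dom_order <- sample.int(max(n_dom, 1L))[seq_len(n_dom)] # which stub next
    n_tot <- length(slots)

    e_now <- vapply(specs, function(s) s$start, numeric(1L))
    traj <- lapply(specs, function(s) numeric(s$n_trials))
    chc <- lapply(specs, function(s) character(s$n_trials))
    dirs <- lapply(specs, function(s) integer(s$n_trials))
    t_within <- integer(length(specs))
    dom_choice <- character(n_dom)
    dom_done <- 0L

    log <- data.frame(trial = seq_len(n_tot), origin = "", staircase_id = "",
                      trial_within = NA_integer_,
                      ecc_a = NA_real_, contrast_a = "",
                      ecc_b = NA_real_, contrast_b = "",
                      variable_eccentricity = NA_real_, choice = "",
                      stringsAsFactors = FALSE)

    for (g in seq_len(n_tot)) {
      k <- slots[g]
      if (k > 0L) {
        sp <- specs[[k]]
        t_within[k] <- t_within[k] + 1L
        tw <- t_within[k]
        e <- e_now[k]
        st <- staircase_advance(observer, sp, e)
        traj[[k]][tw] <- e; chc[[k]][tw] <- st$choice; dirs[[k]][tw] <- st$dir
        e_now[k] <- st$next_e
        log[g, c("origin", "staircase_id")] <- c("STAIRCASE", names(specs)[k])
        log$trial_within[g] <- tw
        log$ecc_a[g] <- sp$fixed_ecc; log$contrast_a[g] <- sp$fixed_contrast
        log$ecc_b[g] <- e; log$contrast_b[g] <- sp$variable_contrast
        log$variable_eccentricity[g] <- e
        log$choice[g] <- if (st$choice == "FIXED") "FIRST" else "SECOND"
      } else {
        dom_done <- dom_done + 1L
        d <- dominance[dom_order[dom_done], ]
        ch <- simulate_choice(observer,
                              list(eccentricity = d$ecc_a, contrast = d$contrast_a),
                              list(eccentricity = d$ecc_b, contrast = d$contrast_b))
        dom_choice[dom_order[dom_done]] <- ch
        log[g, c("origin", "staircase_id")] <- c(d$origin, "")
        log$ecc_a[g] <- d$ecc_a; log$contrast_a[g] <- d$contrast_a
        log$ecc_b[g] <- d$ecc_b; log$contrast_b[g] <- d$contrast_b
        log$choice[g] <- ch
      }
    }
    records <- stats::setNames(
      lapply(seq_along(specs),
             function(k) finish_record(specs[[k]], traj[[k]], chc[[k]], dirs[[k]])),
      names(specs))
    is_rev <- rep(FALSE, n_tot)
    for (k in seq_along(specs)) {
      gi <- which(slots == k)
      is_rev[gi[records[[k]]$reversal_index]] <- TRUE
    }
    log$is_reversal <- is_rev
    if (n_dom > 0L) dominance$choice <- dom_choice
    structure(list(records = records, dominance = dominance, log = log),
              class = "decision_phase")
  })
}

## ---- PSE estimation --------------------------------------------------------

post_discard_reversals <- function(record, discard = 2L) {
  re <- record$reversal_ecc
  if (length(re) < discard + 2L)
    stop(sprintf(paste0("staircase %s -> %s (level %g) never converged: %d ",
                        "reversal(s), need at least %d to estimate a PSE"),
                 record$spec$fixed_contrast, record$spec$variable_contrast,
                 record$spec$level, length(re), discard + 2L))
  re[-seq_len(discard)]
}

#' Estimate the point of subjective equality from a staircase record
#'
#' The default estimator is the mean of the reversal eccentricities after
#' discarding the first `discard` reversals (which reflect the approach from
#' the starting point rather than the converged oscillation). The
#' `"tail"` alternative, offered for sensitivity analysis, averages the
#' variable eccentricities of the last half of the trials instead.
#'
#' @param record a `staircase_record`.
#' @param method `"reversals"` (default) or `"tail"`.
#' @param discard number of initial reversals to drop (default 2).
#' @param fallback logical: if the record has too few reversals (e.g. a
#'   staircase that drifted to a range boundary and pinned there), fall back
#'   to the tail-mean estimator with a warning instead of raising an error.
#'   The pipeline uses this so one degenerate staircase cannot abort a whole
#'   simulated experiment.
#' @return An object of class `"equivalence_point"`: the staircase's fixed
#'   pair, its mapping and level, the PSE (degrees), and the number of
#'   reversals used.
#' @export
estimate_pse <- function(record, method = c("reversals", "tail"), discard = 2L,
                         fallback = FALSE) {
  stopifnot(inherits(record, "staircase_record"))
  method <- match.arg(method)
  if (method == "reversals" && fallback &&
      length(record$reversal_ecc) < discard + 2L) {
    warning(sprintf("staircase %s.%s@%g has %d reversal(s): falling back to the tail-mean PSE",
                    record$spec$fixed_contrast, record$spec$variable_contrast,
                    record$spec$level, length(record$reversal_ecc)))
    method <- "tail"
  }
  if (method == "reversals") {
    used <- post_discard_reversals(record, discard)
    pse <- mean(used)
    n_used <- length(used)
  } else {
    n <- length(record$trajectory)
    keep <- record$trajectory[seq.int(floor(n / 2) + 1L, n)]
    pse <- mean(keep)
    n_used <- length(keep)
  }
  structure(list(fixed_ecc = record$spec$fixed_ecc,
                 fixed_contrast = record$spec$fixed_contrast,
                 variable_contrast = record$spec$variable_contrast,
                 mapping = paste(record$spec$fixed_contrast,
                                 record$spec$variable_contrast, sep = "."),
                 level = record$spec$level,
                 pse = pse,
                 method = method,
                 n_used = n_used,
                 n_reversals = length(record$reversal_index)),
            class = "equivalence_point")
}

#' @export
print.equivalence_point <- function(x, ...) {
  cat(sprintf("PSE %s (level %g): fixed %.2f deg (%s) ~ variable %.2f deg (%s)\n",
              x$mapping, x$level, x$fixed_ecc, x$fixed_contrast, x$pse,
              x$variable_contrast))
  invisible(x)
}
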