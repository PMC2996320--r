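## Synthetic observers: true and subjective sensitivity maps, choice rules,
## and the trial designs of the two experimental phases.

#' Contrast levels and eccentricity grid of the experimental protocol
#'
#' The protocol uses three contrast levels (LOW < MED < HIGH in nominal Weber
#' contrast) and 18 stimulus eccentricities evenly spaced from 2 to 12.2
#' degrees of visual angle to the right of fixation (spacing 0.6 degrees).
#' The nominal Weber contrasts are display metadata only; no computation uses
#' them.
#'
#' @return `contrast_levels()`: character vector `c("LOW", "MED", "HIGH")`
#'   with the nominal contrasts as a `"nominal"` attribute. `ecc_grid()`: the
#'   18 eccentricities. `ecc_range()`: `c(2, 12.2)`.
#' @export
contrast_levels <- function() {
  structure(c("LOW", "MED", "HIGH"),
            nominal = c(LOW = 0.11, MED = 0.20, HIGH = 0.36))
}

#' @rdname contrast_levels
#' @export
ecc_grid <- function() seq(2, 12.2, length.out = 18L)

#' @rdname contrast_levels
#' @export
ecc_range <- function() c(2, 12.2)

clip_ecc <- function(e) pmin(pmax(e, ecc_range()[1L]), ecc_range()[2L])

contrast_rank <- function(contrast) {
  match(contrast, contrast_levels())
}

#' An eccentricity-contrast pair
#'
#' A stimulus in this protocol is fully described by its retinal eccentricity
#' and its contrast level.
#'
#' @param eccentricity degrees of visual angle, within [ecc_range()].
#' @param contrast one of `"LOW"`, `"MED"`, `"HIGH"`.
#' @return A list of class `"ecc_pair"`.
#' @export
ecc_pair <- function(eccentricity, contrast) {
  contrast <- match.arg(contrast, contrast_levels())
  r <- ecc_range()
  if (!is.numeric(eccentricity) || length(eccentricity) != 1L ||
      eccentricity < r[1L] || eccentricity > r[2L])
    stop(sprintf("eccentricity must lie in [%g, %g] degrees", r[1L], r[2L]))
  structure(list(eccentricity = eccentricity, contrast = contrast),
            class = "ecc_pair")
}

# A sensitivity map is a named list of quick_weibull curves, one per contrast.
check_map <- function(map, what) {
  if (!is.list(map) || !all(contrast_levels() %in% names(map)))
    stop(sprintf("'%s' must be a list with components LOW, MED, HIGH", what))
  for (lv in contrast_levels())
    if (!inherits(map[[lv]], "quick_weibull"))
      stop(sprintf("'%s$%s' must be a quick_weibull curve", what, lv))
  map[contrast_levels()]
}

# Dominance of a sensitivity map on the stimulus grid: probability correct
# strictly increases with contrast at fixed eccentricity and strictly
# decreases with eccentricity at fixed contrast.
check_dominance <- function(map, grid = ecc_grid()) {
  p <- sapply(map, function(cv) predict(cv, grid))  # 18 x 3
  bad <- which(!(p[, "LOW"] < p[, "MED"] & p[, "MED"] < p[, "HIGH"]))
  if (length(bad))
    stop(sprintf(paste0("true sensitivity map violates contrast dominance at ",
                        "eccentricity %.1f deg (p must increase LOW < MED < HIGH)"),
                 grid[bad[1L]]))
  dec <- apply(p, 2L, function(col) all(diff(col) < 0))
  if (!all(dec))
    stop(sprintf("true sensitivity map is not strictly decreasing in eccentricity for contrast %s",
                 names(dec)[!dec][1L]))
  invisible(TRUE)
}

#' Create a synthetic observer
#'
#' An observer couples a *true* sensitivity map (one Quick-Weibull curve per
#' contrast; generates calibration responses) with a *subjective* map and a
#' stochastic choice rule (generates decisions between eccentricity-contrast
#' pairs). Distorting the subjective map relative to the true one produces
#' the patterned equivalence failures the analysis is designed to detect;
#' the `"lexicographic"` and `"transform"` rules produce intransitive choice.
#'
#' Choice rules (probability of choosing pair A over pair B):
#' \describe{
#' \item{`subjective_prob`}{logistic in the subjective probability
#'   difference, \eqn{\mathrm{logit}^{-1}(\lambda (\hat p_A - \hat p_B))}
#'   with inverse temperature \eqn{\lambda} = `noise`. `noise = Inf` gives a
#'   deterministic maximiser of subjective probability; `noise = 0` gives
#'   random choice.}
#' \item{`lexicographic`}{a lexicographic semiorder on (eccentricity,
#'   contrast): if the eccentricity difference exceeds
#'   `semiorder_threshold` degrees the nearer target is chosen, otherwise the
#'   higher contrast wins (ties: random). With probability `lapse` the rule
#'   is replaced by a coin flip.}
#' \item{`transform`}{the observer carries explicit log-linear equivalence
#'   transformations between contrasts (`transforms`, see below); pair A is
#'   preferred when pair B lies beyond the eccentricity judged equivalent to
#'   A at B's contrast, softened logistically with gain `noise` on the
#'   log-eccentricity difference. Same-contrast comparisons fall back to the
#'   subjective map. Transform triples whose composition around the contrast
#'   cycle is not the identity generate intransitive preferences.}
#' }
#'
#' @param true_map,subjective_map named lists (`LOW`, `MED`, `HIGH`) of
#'   [quick_weibull()] curves. `subjective_map` defaults to `true_map`
#'   (a veridical observer). The true map must satisfy dominance on the
#'   stimulus grid; the subjective map may be arbitrary.
#' @param rule choice rule, see Details.
#' @param noise inverse temperature (>= 0) of the stochastic choice rule;
#'   `Inf` for deterministic choice.
#' @param semiorder_threshold eccentricity threshold in degrees for the
#'   lexicographic rule.
#' @param transforms for `rule = "transform"`: named list with components
#'   `LOW.MED`, `MED.HIGH`, `HIGH.LOW`, each a list with `intercept`
#'   (log-degrees) and `slope` (> 0), defining
#'   \eqn{\log e_2 = \mathrm{intercept} + \mathrm{slope}\,\log e_1}.
#' @param lapse probability in [0, 1] of a uniformly random choice
#'   (lexicographic rule only).
#' @param seed integer seed; all simulation helpers derive their random
#'   streams from it, so identical configurations with identical seeds give
#'   identical trial logs.
#' @return An object of class `"observer_model"`.
#' @seealso [observer_preset()] for ready-made observers,
#'   [simulate_calibration()], [simulate_choice()], [run_staircase()]
#' @export
make_observer <- function(true_map,
                          subjective_map = true_map,
                          rule = c("subjective_prob", "lexicographic", "transform"),
                          noise = 20,
                          semiorder_threshold = 2,
                          transforms = NULL,
                          lapse = 0,
                          seed = 1L) {
  rule <- match.arg(rule)
  true_map <- check_map(true_map, "true_map")
  subjective_map <- check_map(subjective_map, "subjective_map")
  check_dominance(true_map)
  if (is.na(noise) || noise < 0) stop("'noise' must be >= 0")
  if (lapse < 0 || lapse > 1) stop("'lapse' must be in [0, 1]")
  if (rule == "transform") {
    need <- c("LOW.MED", "MED.HIGH", "HIGH.LOW")
    if (!is.list(transforms) || !all(need %in% names(transforms)))
      stop("'transforms' must list components LOW.MED, MED.HIGH, HIGH.LOW")
    for (nm in need) {
      tr <- transforms[[nm]]
      if (!is.numeric(tr$slope) || tr$slope <= 0)
        stop(sprintf("transform %s must have a positive slope", nm))
    }
  }
  structure(list(true_map = true_map,
                 subjective_map = subjective_map,
                 rule = rule,
                 noise = noise,
                 semiorder_threshold = semiorder_threshold,
                 transforms = transforms,
                 lapse = lapse,
                 seed = as.integer(seed)),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  tm <- sapply(x$true_map, function(cv) cv$tau)
  cat(sprintf("Synthetic observer (rule %s, noise %.3g, seed %d)\n",
              x$rule, x$noise, x$seed))
  cat(sprintf("  true map tau: LOW %.2f, MED %.2f, HIGH %.2f\n",
              tm["LOW"], tm["MED"], tm["HIGH"]))
  if (!identical(x$subjective_map, x$true_map)) {
    sm <- sapply(x$subjective_map, function(cv) cv$tau)
    cat(sprintf("  subjective tau: LOW %.2f, MED %.2f, HIGH %.2f\n",
                sm["LOW"], sm["MED"], sm["HIGH"]))
  } else cat("  subjective map identical to true map (veridical)\n")
  invisible(x)
}

## ---- choice rule -----------------------------------------------------------

soft_step <- function(d, noise) {
  # P(choose A) given decision variable d (positive favours A)
  if (is.infinite(noise)) (d > 0) + 0.5 * (d == 0) else stats::plogis(noise * d)
}

apply_transform <- function(tr, e) exp(tr$intercept + tr$slope * log(e))

invert_transform <- function(tr) {
  list(intercept = -tr$intercept / tr$slope, slope = 1 / tr$slope)
}

pair_transform <- function(observer, from, to) {
  key <- paste(from, to, sep = ".")
  if (!is.null(observer$transforms[[key]])) return(observer$transforms[[key]])
  rev_key <- paste(to, from, sep = ".")
  if (!is.null(observer$transforms[[rev_key]]))
    return(invert_transform(observer$transforms[[rev_key]]))
  stop(sprintf("observer has no equivalence transform between %s and %s", from, to))
}

#' Probability that an observer chooses the first of two pairs
#'
#' Deterministic closed form of the observer's choice rule; the quantity the
#' one-up one-down staircase drives to 0.5. Useful as an oracle: the
#' staircase's point of subjective equality should sit where this probability
#' crosses 0.5 in the variable pair's eccentricity.
#'
#' @param observer an [make_observer()] object.
#' @param a,b [ecc_pair()] objects (or lists with `eccentricity`, `contrast`).
#' @return P(choose `a`), a probability.
#' @export
choice_prob <- function(observer, a, b) {
  stopifnot(inherits(observer, "observer_model"))
  ca <- a$contrast; cb <- b$contrast
  ea <- a$eccentricity; eb <- b$eccentricity
  if (observer$rule == "lexicographic") {
    det <- if (abs(ea - eb) > observer$semiorder_threshold) {
      (ea < eb) + 0.5 * (ea == eb)
    } else {
      ra <- contrast_rank(ca); rb <- contrast_rank(cb)
      if (ra == rb) (ea < eb) + 0.5 * (ea == eb) else as.numeric(ra > rb)
    }
    return((1 - observer$lapse) * det + observer$lapse * 0.5)
  }
  if (observer$rule == "transform" && ca != cb) {
    m <- apply_transform(pair_transform(observer, ca, cb), ea)
    return(soft_step(log(eb) - log(m), observer$noise))
  }
  pa <- predict(observer$subjective_map[[ca]], ea)
  pb <- predict(observer$subjective_map[[cb]], eb)
  soft_step(pa - pb, observer$noise)
}

#' Simulate one binary choice between two eccentricity-contrast pairs
#'
#' Draws from the observer's choice rule using the current RNG stream (seed
#' upstream with [with_seed()] or via the pipeline).
#'
#' @inheritParams choice_prob
#' @return `"FIRST"` if `a` is chosen, else `"SECOND"`.
#' @export
simulate_choice <- function(observer, a, b) {
  if (stats::runif(1L) < choice_prob(observer, a, b)) "FIRST" else "SECOND"
}

## ---- calibration design & simulation --------------------------------------

#' Generate the calibration-phase trial list
#'
#' The calibration phase measures probability correct on a top/bottom 2AFC
#' judgement at every combination of 3 contrasts and 18 eccentricities
#' (2 to 12.2 degrees, 0.6-degree spacing). There are `n_blocks` blocks; in
#' each block every contrast-by-eccentricity cell repeats `n_reps` times,
#' half with the dot on top and half on bottom, randomly mixed within the
#' block. Defaults give 3 x 18 x 5 x 6 = 1620 trials.
#'
#' @param n_blocks number of blocks (default 5).
#' @param n_reps repetitions per cell per block (default 6; must be even so
#'   top and bottom stimuli balance exactly).
#' @param seed optional integer seed for the within-block shuffling; `NULL`
#'   uses the current RNG stream.
#' @return A data frame of trial stubs with columns `block`, `contrast`,
#'   `eccentricity`, `stimulus` (`"TOP"`/`"BOTTOM"`).
#' @export
generate_calibration_design <- function(n_blocks = 5L, n_reps = 6L, seed = NULL) {
  if (n_reps %% 2L != 0L) stop("'n_reps' must be even (half TOP, half BOTTOM)")
  cell <- expand.grid(contrast = contrast_levels(),
                      eccentricity = ecc_grid(),
                      rep = seq_len(n_reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell$stimulus <- ifelse(cell$rep <= n_reps / 2L, "TOP", "BOTTOM")
  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      idx <- sample.int(nrow(cell))
      data.frame(block = b, cell[idx, c("contrast", "eccentricity", "stimulus")],
                 row.names = NULL)
    })
    do.call(rbind, blocks)
  })
}

#' Simulate calibration responses for an observer
#'
#' Each trial is answered correctly with probability given by the observer's
#' *true* sensitivity map at the trial's contrast and eccentricity,
#' independently across trials (the subjective map plays no role here).
#'
#' @param observer an [make_observer()] object.
#' @param design trial stubs from [generate_calibration_design()].
#' @param seed integer seed; defaults to a stream derived from the observer's
#'   seed.
#' @return The design with `response` (`"TOP"`/`"BOTTOM"`) and `correct`
#'   (logical) columns appended.
#' @export
simulate_calibration <- function(observer, design,
                                 seed = derive_seed(observer$seed, "calibration")) {
  stopifnot(inherits(observer, "observer_model"), is.data.frame(design))
  p <- numeric(nrow(design))
  for (lv in contrast_levels()) {
    i <- design$contrast == lv
    p[i] <- predict(observer$true_map[[lv]], design$eccentricity[i])
  }
  with_seed(seed, {
    correct <- stats::runif(nrow(design)) < p
    design$response <- ifelse(correct, design$stimulus,
                              ifelse(design$stimulus == "TOP", "BOTTOM", "TOP"))
    design$correct <- correct
    design
  })
}

## ---- dominance design ------------------------------------------------------

#' Generate the dominance-trial design
#'
#' Dominance trials probe whether the observer prefers lower eccentricity at
#' equal contrast (equi-contrast trials) and higher contrast at equal
#' eccentricity (equi-eccentricity trials). The three test eccentricities are
#' the points where each fitted calibration curve reaches probability correct
#' 0.75. Defaults give 3 contrasts x 3 eccentricity pairs x 10 reps = 90
#' equi-contrast trials and 3 eccentricities x 3 contrast pairs x 10 reps =
#' 90 equi-eccentricity trials.
#'
#' @param curves named list (`LOW`, `MED`, `HIGH`) of fitted
#'   [quick_weibull()] curves (or `psychometric_fit` objects).
#' @param n_reps repetitions per combination (default 10).
#' @param boundary `"error"` (default) if a p = 0.75 point falls outside the
#'   presentable stimulus range, or `"clip"` to truncate it with a warning.
#' @return A data frame of trial stubs with columns `origin`
#'   (`"EQUI_CONTRAST"`/`"EQUI_ECCENTRICITY"`), `ecc_a`, `contrast_a`,
#'   `ecc_b`, `contrast_b`.
#' @export
generate_dominance_design <- function(curves, n_reps = 10L,
                                      boundary = c("error", "clip")) {
  curves <- as_curve_map(curves)
  boundary <- match.arg(boundary)
  e75 <- vapply(curves, qw_invert, numeric(1L), p = 0.75)
  r <- ecc_range()
  if (any(e75 < r[1L] | e75 > r[2L])) {
    if (boundary == "error")
      stop(sprintf(paste0("p = 0.75 point of contrast %s (%.2f deg) falls outside ",
                          "the stimulus range: curve too steep or too shallow for the protocol"),
                   names(e75)[which(e75 < r[1L] | e75 > r[2L])[1L]],
                   e75[which(e75 < r[1L] | e75 > r[2L])[1L]]))
    warning("p = 0.75 point(s) clipped into the stimulus range")
    e75 <- clip_ecc(e75)
    if (anyDuplicated(e75))
      stop("clipped p = 0.75 points coincide: cannot build equi-contrast pairs")
  }
  lv <- contrast_levels()
  combos <- utils::combn(3L, 2L)
  rows <- list()
  for (ci in lv) for (j in seq_len(ncol(combos))) {
    rows[[length(rows) + 1L]] <- data.frame(
      origin = "EQUI_CONTRAST",
      ecc_a = e75[[combos[1L, j]]], contrast_a = ci,
      ecc_b = e75[[combos[2L, j]]], contrast_b = ci)
  }
  for (ei in seq_len(3L)) for (j in seq_len(ncol(combos))) {
    rows[[length(rows) + 1L]] <- data.frame(
      origin = "EQUI_ECCENTRICITY",
      ecc_a = e75[[ei]], contrast_a = lv[combos[1L, j]],
      ecc_b = e75[[ei]], contrast_b = lv[combos[2L, j]])
  }
  out <- do.call(rbind, rows)
  out <- out[rep(seq_len(nrow(out)), each = n_reps), ]
  rownames(out) <- NULL
  out
}

# Accept either quick_weibull curves or psychometric_fit objects.
as_curve_map <- function(curves) {
  if (inherits(curves, "observer_model")) return(curves$true_map)
  out <- lapply(curves, function(x) if (inherits(x, "psychometric_fit")) x$curve else x)
  check_map(out, "curves")
}

## ---- presets ---------------------------------------------------------------

# Default true sensitivity map. Position parameters are chosen so that the
# protocol is feasible for a veridical observer: every fixed target (levels
# 0.6-0.9 of each curve) and every veridical match point of the 12
# staircases lies inside the stimulus range [2, 12.2] with at least ~0.8
# degrees of margin for the staircase to oscillate without pinning against
# a boundary.
default_true_map <- function() {
  list(LOW = quick_weibull(5.0, 2), MED = quick_weibull(6.0, 2),
       HIGH = quick_weibull(7.2, 2))
}

#' Ready-made synthetic observers
#'
#' Preset observers spanning the behaviours the test battery is designed to
#' separate. All share the same true sensitivity map (tau = 4.0, 5.6, 7.5
#' degrees for LOW/MED/HIGH at common steepness beta = 2, so performance
#' spans roughly 0.55-1 over the stimulus range):
#' \describe{
#' \item{`veridical`}{subjective map equals the true map, moderate choice
#'   noise (inverse temperature 20). Passes all three tests in expectation.}
#' \item{`veridical_deterministic`}{as above with `noise = Inf`; the ideal
#'   observer, never errs against its own map.}
#' \item{`contrast_underestimate`}{subjective position parameters compressed
#'   halfway toward their mean: the observer under-rates how much contrast
#'   helps, producing same-signed equivalence failures.}
#' \item{`corkscrew`}{`transform` rule whose per-mapping slopes are each
#'   \eqn{2^{1/3}} (composite slope 2 around the LOW-MED-HIGH-LOW cycle):
#'   each cross-contrast mapping exaggerates eccentricity differences, giving
#'   an intransitive spiral with composite intercept < 0 and slope deviation
#'   > 0.}
#' \item{`lexicographic`}{lexicographic-semiorder rule with a 2-degree
#'   eccentricity threshold.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed stored in the observer.
#' @param noise optional override of the preset's choice noise.
#' @return An [make_observer()] object.
#' @export
observer_preset <- function(name = c("veridical", "veridical_deterministic",
                                     "contrast_underestimate", "corkscrew",
                                     "lexicographic"),
                            seed = 1L, noise = NULL) {
  name <- match.arg(name)
  tm <- default_true_map()
  switch(name,
    veridical = make_observer(tm, noise = noise %||% 20, seed = seed),
    veridical_deterministic = make_observer(tm, noise = noise %||% Inf, seed = seed),
    contrast_underestimate = {
      taus <- vapply(tm, function(cv) cv$tau, numeric(1L))
      sub <- lapply(stats::setNames(contrast_levels(), contrast_levels()),
                    function(lv) quick_weibull((taus[[lv]] + mean(taus)) / 2, 2))
      make_observer(tm, subjective_map = sub, noise = noise %||% 20, seed = seed)
    },
    corkscrew = make_observer(tm, rule = "transform",
                              transforms = corkscrew_transforms(),
                              noise = noise %||% 10, seed = seed),
    lexicographic = make_observer(tm, rule = "lexicographic",
                                  semiorder_threshold = 2, lapse = 0.05,
                                  seed = seed))
}

# Per-mapping log-linear transforms with common slope 2^(1/3) (composite
# slope 2), each anchored at the geometric middle of its staircase operating
# range so trajectories stay inside the stimulus range.
corkscrew_transforms <- function(slope = 2^(1 / 3)) {
  tm <- default_true_map()
  anchor <- function(from, to) {
    # fixed eccentricities span the 0.9 and 0.6 points of the 'from' curve
    fr <- qw_invert(tm[[from]], c(0.9, 0.6))
    x0 <- exp(mean(log(fr)))                       # geometric mid of inputs
    y0 <- x0 * tm[[to]]$tau / tm[[from]]$tau       # veridical match of x0
    list(intercept = log(y0) - slope * log(x0), slope = slope)
  }
  list(LOW.MED = anchor("LOW", "MED"),
       MED.HIGH = anchor("MED", "HIGH"),
       HIGH.LOW = anchor("HIGH", "LOW"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
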