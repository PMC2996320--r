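#' Quick-Weibull psychometric curve
#'
#' Constructs a decreasing Quick-Weibull psychometric function for a 2AFC
#' discrimination task,
#' \deqn{p(e) = 0.5 + 0.5 \cdot 2^{-(e/\tau)^\beta},}
#' giving the probability of a correct response as a function of retinal
#' eccentricity \eqn{e} (degrees of visual angle). Performance is perfect at
#' the fovea (\eqn{p(0) = 1}) and falls to the 2AFC chance level 0.5 as
#' eccentricity grows. \eqn{\tau} is the position parameter: the eccentricity
#' at which \eqn{p = 0.75}. \eqn{\beta} controls steepness.
#'
#' @param tau position parameter in degrees, > 0. `Inf` is accepted and gives
#'   the degenerate always-correct curve (useful as a boundary case in
#'   simulations).
#' @param beta dimensionless steepness parameter, finite and > 0.
#' @return An object of class `"quick_weibull"` with fields `tau`, `beta`,
#'   `chance` (0.5) and `ceiling` (1.0).
#' @seealso [qw_invert()], [fit_psychometric()]
#' @examples
#' curve <- quick_weibull(tau = 6, beta = 2)
#' predict(curve, c(0, 6, 12))
#' @export
quick_weibull <- function(tau, beta) {
  stopifnot(is.numeric(tau), length(tau) == 1L,
            is.numeric(beta), length(beta) == 1L)
  if (is.na(tau) || tau <= 0) stop("'tau' must be a positive number")
  if (is.na(beta) || beta <= 0 || !is.finite(beta))
    stop("'beta' must be a positive finite number")
  structure(list(tau = tau, beta = beta, chance = 0.5, ceiling = 1.0),
            class = "quick_weibull")
}

#' @export
print.quick_weibull <- function(x, ...) {
  cat(sprintf("Quick-Weibull curve: tau = %.4g deg, beta = %.4g (chance %.2g, ceiling %.2g)\n",
              x$tau, x$beta, x$chance, x$ceiling))
  invisible(x)
}

#' Probability correct at given eccentricities
#'
#' Evaluates a Quick-Weibull curve. Values lie in (0.5, 1] for finite
#' eccentricity and approach 0.5 as eccentricity grows.
#'
#' @param object a [quick_weibull()] curve.
#' @param eccentricity numeric vector of eccentricities in degrees, >= 0.
#' @param ... unused.
#' @return Numeric vector of probabilities correct.
#' @export
predict.quick_weibull <- function(object, eccentricity, ...) {
  e <- eccentricity
  if (!is.numeric(e)) stop("'eccentricity' must be numeric")
  if (any(e < 0, na.rm = TRUE)) stop("'eccentricity' must be non-negative")
  x <- (e / object$tau)^object$beta  # 0 at the fovea, also 0 when tau = Inf
  object$chance + (object$ceiling - object$chance) * 2^(-x)
}

#' Eccentricity at which a curve reaches a given probability correct
#'
#' Closed-form inverse of the Quick-Weibull curve:
#' \eqn{e = \tau (-\log_2(2p - 1))^{1/\beta}}. Exact inverse of
#' [predict.quick_weibull()] on (0.5, 1).
#'
#' @param curve a [quick_weibull()] curve.
#' @param p probability correct, strictly between 0.5 and 1.
#' @return Eccentricity in degrees.
#' @examples
#' qw_invert(quick_weibull(6, 2), 0.75)  # 6
#' @export
qw_invert <- function(curve, p) {
  stopifnot(inherits(curve, "quick_weibull"), is.numeric(p))
  if (any(p <= 0.5 | p >= 1))
    stop("'p' must lie strictly between 0.5 (chance) and 1 (ceiling)")
  curve$tau * (-log2(2 * p - 1))^(1 / curve$beta)
}

## ---- maximum-likelihood fitting -------------------------------------------

# Aggregate Bernoulli trials into per-eccentricity binomial counts.
qw_aggregate <- function(eccentricity, correct) {
  e <- round(eccentricity, 10)
  tab <- tapply(as.logical(correct), e, function(z) c(n = length(z), k = sum(z)))
  m <- do.call(rbind, tab)
  data.frame(e = as.numeric(names(tab)), n = m[, "n"], k = m[, "k"],
             row.names = NULL)
}

qw_negloglik <- function(logpar, e, n, k) {
  tau <- exp(logpar[1L]); beta <- exp(logpar[2L])
  p <- 0.5 + 0.5 * 2^(-(e / tau)^beta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

# Bounded ML fit on binomial counts; optionally multi-started. Returns the
# optim() result with parameters on the natural scale.
qw_fit_counts <- function(e, n, k,
                          start = NULL,
                          tau_bounds = c(1, 30),
                          beta_bounds = c(0.5, 10),
                          multistart = TRUE) {
  lower <- log(c(tau_bounds[1L], beta_bounds[1L]))
  upper <- log(c(tau_bounds[2L], beta_bounds[2L]))
  starts <- if (!is.null(start)) {
    list(log(start))
  } else if (multistart) {
    # fixed log-grid of 5 starts spanning the box
    lapply(list(c(2, 1), c(4, 2), c(7, 2), c(12, 3.5), c(22, 1.2)), log)
  } else {
    list(log(c(6, 2)))
  }
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(s, qw_negloglik, e = e, n = n, k = k,
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(factr = 1e-8 / .Machine$double.eps)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) ||
        fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 && fit$par[1L] < best$par[1L])) {
      best <- fit
    }
  }
  if (is.null(best)) stop("psychometric optimisation failed from every start")
  at_bound <- any(abs(best$par - lower) < 1e-6) || any(abs(best$par - upper) < 1e-6)
  list(tau = exp(best$par[1L]), beta = exp(best$par[2L]),
       log_likelihood = -best$value, at_bound = at_bound)
}

#' Maximum-likelihood fit of a Quick-Weibull curve to calibration trials
#'
#' Fits the position and steepness parameters of the psychometric curve by
#' maximising the Bernoulli log-likelihood
#' \eqn{\sum_i [c_i \log p(e_i) + (1 - c_i)\log(1 - p(e_i))]} over trials
#' \eqn{(e_i, c_i)}. Optimisation uses bounded quasi-Newton (L-BFGS-B) on
#' log-parameters with five fixed starting points spanning
#' \eqn{\tau \in [1, 30]}, \eqn{\beta \in [0.5, 10]}; the best start by
#' likelihood wins, ties broken toward smaller \eqn{\tau}.
#'
#' Degenerate data sets (all correct, all incorrect, or perfectly separable,
#' which push a parameter to its bound) are reported with `converged = FALSE`
#' and a warning: the parameters are then not identifiable and the returned
#' curve sits at a box bound.
#'
#' @param trials a data frame of calibration trials for a single contrast,
#'   with columns `eccentricity` (degrees) and `correct` (logical), e.g. one
#'   contrast's subset of [simulate_calibration()] output.
#' @param contrast optional contrast label stored in the result.
#' @param tau_bounds,beta_bounds parameter box for the bounded optimiser.
#' @return An object of class `"psychometric_fit"`: a list with `curve`
#'   (a [quick_weibull()] object), `log_likelihood` (nats, <= 0),
#'   `converged`, `n_trials` and `contrast`.
#' @examples
#' obs <- observer_preset("veridical", seed = 1)
#' calib <- simulate_calibration(obs, generate_calibration_design(seed = 1))
#' fit <- fit_psychometric(subset(calib, contrast == "MED"), contrast = "MED")
#' fit$curve
#' @export
fit_psychometric <- function(trials, contrast = NULL,
                             tau_bounds = c(1, 30), beta_bounds = c(0.5, 10)) {
  stopifnot(is.data.frame(trials),
            all(c("eccentricity", "correct") %in% names(trials)))
  agg <- qw_aggregate(trials$eccentricity, trials$correct)
  if (nrow(agg) < 2L)
    stop("need responses at >= 2 distinct eccentricities to fit a curve")
  n_trials <- sum(agg$n)
  all_correct <- sum(agg$k) == n_trials
  all_wrong <- sum(agg$k) == 0L
  fit <- qw_fit_counts(agg$e, agg$n, agg$k,
                       tau_bounds = tau_bounds, beta_bounds = beta_bounds)
  converged <- !fit$at_bound
  if (all_correct || all_wrong) {
    warning("responses are all ", if (all_correct) "correct" else "incorrect",
            ": parameters not identifiable, tau pinned to its bound")
    converged <- FALSE
  } else if (fit$at_bound) {
    warning("fitted parameter at its bound (data may be perfectly separable)")
  }
  structure(list(curve = quick_weibull(fit$tau, fit$beta),
                 log_likelihood = fit$log_likelihood,
                 converged = converged,
                 n_trials = n_trials,
                 contrast = contrast),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Psychometric fit%s: tau = %.3f, beta = %.3f (logLik %.2f, n = %d%s)\n",
              if (is.null(x$contrast)) "" else paste0(" [", x$contrast, "]"),
              x$curve$tau, x$curve$beta, x$log_likelihood, x$n_trials,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @export
logLik.psychometric_fit <- function(object, ...) {
  structure(object$log_likelihood, df = 2L, nobs = object$n_trials,
            class = "logLik")
}
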