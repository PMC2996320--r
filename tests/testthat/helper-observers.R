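# Shared fixtures: small curve/observer builders used across the suite.

map3 <- function(tau, beta = c(2, 2, 2)) {
  list(LOW = quick_weibull(tau[1], beta[1]),
       MED = quick_weibull(tau[2], beta[2]),
       HIGH = quick_weibull(tau[3], beta[3]))
}

# Analytic equal-discriminability match point: eccentricity at `to` whose
# probability correct equals that of `e` at `from`. Used as a noiseless
# oracle for PSEs and transforms (closed form, independent of the staircase).
match_point <- function(curve_from, curve_to, e) {
  qw_invert(curve_to, predict(curve_from, e))
}

# Numerical match point by bisection on the probability difference: a second,
# implementation-independent oracle.
match_point_uniroot <- function(curve_from, curve_to, e) {
  f <- function(x) predict(curve_to, x) - predict(curve_from, e)
  stats::uniroot(f, c(1e-6, 1e3), tol = 1e-12)$root
}

# A staircase record built directly from a trajectory (no simulation), for
# arithmetic tests of reversal detection and PSE estimation.
fake_record <- function(trajectory, dirs,
                        spec = staircase_spec(6, "LOW", "MED", level = 0.75)) {
  n <- length(trajectory)
  rev_idx <- if (n >= 2L) which(dirs[-1L] != dirs[-n]) + 1L else integer()
  structure(list(spec = spec, trajectory = trajectory,
                 choices = ifelse(dirs == 1L, "VARIABLE", "FIXED"),
                 directions = dirs,
                 reversal_index = rev_idx,
                 reversal_ecc = trajectory[rev_idx]),
            class = "staircase_record")
}

# Noiseless equivalence points for a subjective map: the PSEs an ideal
# staircase would find, computed analytically.
exact_points <- function(subjective_map, fixed_map = subjective_map,
                         levels = c(0.6, 0.7, 0.8, 0.9)) {
  mt <- data.frame(from = c("LOW", "MED", "HIGH"), to = c("MED", "HIGH", "LOW"))
  pts <- list()
  for (i in seq_len(nrow(mt))) for (q in levels) {
    fe <- qw_invert(fixed_map[[mt$from[i]]], q)
    pts[[length(pts) + 1L]] <- structure(
      list(fixed_ecc = fe, fixed_contrast = mt$from[i],
           variable_contrast = mt$to[i],
           mapping = paste(mt$from[i], mt$to[i], sep = "."),
           level = q,
           pse = match_point(subjective_map[[mt$from[i]]],
                             subjective_map[[mt$to[i]]], fe),
           method = "exact", n_used = NA_integer_, n_reversals = NA_integer_),
      class = "equivalence_point")
  }
  pts
}
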