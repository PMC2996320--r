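#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded simulation helpers do not disturb the surrounding random stream.
#' With `seed = NULL` the code runs on the current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministically maps a master seed and a stage label to a new 32-bit
#' seed, so that each simulation stage (calibration, decision phase,
#' bootstrap, ...) consumes an independent but reproducible stream.
#'
#' @param seed master integer seed.
#' @param tag character stage label.
#' @return An integer in [0, 2^31).
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483629
  h <- 17
  for (v in utf8ToInt(tag)) h <- (h * 31 + v) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}
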