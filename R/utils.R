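# Shared numeric and RNG helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; karyotype tables in the
#' cytogenetics literature are printed with conventional half-up rounding
#' (1.425 -> 1.43, 10.476 -> 10.48), so every value reproduced from a
#' published table goes through this function.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2, the table convention).
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Derive an independent stream seed
#'
#' Stochastic operations that loop over replicates derive one seed per
#' replicate from a master seed, so results do not depend on replicate
#' order and individual replicates can be re-run in isolation.
#'
#' @param seed Master seed (integer).
#' @param stream Replicate index (integer >= 0).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream) {
  # splitmix-style mix, kept in double precision below 2^31
  x <- (as.numeric(seed) * 2654435.0 + as.numeric(stream) * 40503.0 + 12345.0)
  as.integer(x %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# stop() with a consistent error class so callers/tests can catch
# validation failures distinctly from programming errors.
abort_validation <- function(msg, class = "karyophy_validation_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
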