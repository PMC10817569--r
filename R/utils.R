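# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller-visible RNG state, seeds the generator, evaluates the
#' expression, then restores the prior state so library code never perturbs
#' the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

#' Derive a per-iteration seed from a base seed
#'
#' Deterministic linear-congruential style hash: `(base * 48271 + i * 16807)
#' mod (2^31 - 1)`, always a positive 32-bit integer, so repeated-split
#' harnesses are reproducible end to end from a single base seed.
#'
#' @param base_seed Integer base seed.
#' @param i Iteration index (>= 1).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, i) {
  m <- 2147483647
  s <- (as.numeric(base_seed) %% m) * 48271 + (as.numeric(i) %% m) * 16807
  as.integer(s %% m + 1)
}

# logit with epsilon clipping so extreme probabilities stay finite
clipped_logit <- function(p, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  stats::qlogis(p)
}

stop2 <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
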