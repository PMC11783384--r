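#' Derive a child seed from a master seed
#'
#' Deterministic seed fan-out so that pipeline stages, subjects and blocks
#' can each get an independent, reproducible stream. Keys are mixed into the
#' master seed with a multiplicative-congruential hash modulo 2^31 - 1, so
#' the result is always a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param ... integer keys (stage index, subject index, block index, ...).
#' @return a single integer seed in [1, 2^31 - 2].
#' @export
splitSeed <- function(master, ...) {
  m <- 2147483647
  h <- (abs(as.numeric(master)) %% m)
  for (k in c(...)) {
    h <- (h * 48271 + abs(as.numeric(k)) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# run expr with a local RNG state seeded at `seed`, restoring state after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
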