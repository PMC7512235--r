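#' Reproducible random streams
#'
#' A stream wraps an independent Mersenne-Twister state so that the agent and
#' the opponent in a simulated session draw from separate sequences: changing
#' one side's strategy never perturbs the other's randomness at equal seeds.
#'
#' @param seed Integer seed for the stream.
#' @return An object of class `rng_stream`.
#' @examples
#' r <- rng_stream(1)
#' rng_unif(r, 3)
#' @export
rng_stream <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  st <- new.env(parent = emptyenv())
  old <- .save_global_seed()
  set.seed(as.integer(seed))
  st$state <- get(".Random.seed", envir = globalenv())
  .restore_global_seed(old)
  class(st) <- "rng_stream"
  st
}

#' Draw uniforms from a stream
#'
#' @param rng An `rng_stream`.
#' @param n Number of draws.
#' @return Numeric vector of `n` uniform(0,1) draws; the stream advances.
#' @export
rng_unif <- function(rng, n = 1L) {
  stopifnot(inherits(rng, "rng_stream"))
  old <- .save_global_seed()
  assign(".Random.seed", rng$state, envir = globalenv())
  u <- stats::runif(n)
  rng$state <- get(".Random.seed", envir = globalenv())
  .restore_global_seed(old)
  u
}

.save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_global_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic sub-seed for stream `k` of master `seed`; stays below 2^31.
.derive_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 48271 + 12345 * k) %% 2147483647)
}
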