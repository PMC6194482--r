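#' Named reproducible random streams
#'
#' A `rng_stream` carries its own `.Random.seed` state so that independent
#' sources of randomness (pool generation, simulee generation, response
#' draws, selection tie-breaks) never interact: advancing one stream leaves
#' every other stream, and the caller's global RNG, untouched.
#'
#' @param seed integer seed (< 2^31) initialising the stream.
#' @return an object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

#' Evaluate a function under a stream's RNG state
#'
#' Swaps the stream's state into the global RNG, evaluates `f()`, stores the
#' advanced state back into the stream, and restores the caller's RNG.
#'
#' @param stream a [rng_stream()].
#' @param f a zero-argument function whose body uses the RNG.
#' @return the value of `f()`.
#' @export
stream_do <- function(stream, f) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  f()
}

#' Derive a per-unit substream seed from a master seed
#'
#' Deterministic map used to give every simulee its own response and
#' selection substreams, so that batch order or parallel scheduling cannot
#' change any individual administration. The result stays below 2^31.
#'
#' @param master integer master seed.
#' @param index positive integer (e.g. simulee index, calibration cycle).
#' @return an integer-valued seed.
#' @export
derive_seed <- function(master, index) {
  # exact in doubles: 2147483646 * 48271 + 2^31 * 16807 < 2^53
  s <- ((as.double(master) %% 2147483647) * 48271 +
          (as.double(index) %% 2147483647) * 16807) %% 2147483629
  as.integer(s)
}
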