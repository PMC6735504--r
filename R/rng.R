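# Named random-number streams.  Each stream keeps its own .Random.seed state
# so that draws for one consumer (e.g. one sonication target) are unaffected
# by how many draws any other consumer makes.

#' Create a set of independent random-number streams
#'
#' Derives `n` reproducible, independent Mersenne-Twister streams from a
#' single master seed.  Used by the synthetic cavitation plant so that each
#' sonication target (and the ambient-noise channel) consumes its own stream:
#' permuting the draws of one target cannot perturb another target's
#' trajectory.
#'
#' @param seed Master integer seed.
#' @param n Number of streams.
#' @param names Optional character names for the streams.
#' @return A named list of stream objects (environments).
#' @export
rng_streams <- function(seed, n, names = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed), n >= 1)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  # substream seeds drawn once from the master stream
  sub <- sample.int(.Machine$integer.max - 1L, n)
  streams <- lapply(sub, function(s) {
    e <- new.env(parent = emptyenv())
    set.seed(s)
    e$state <- get(".Random.seed", envir = globalenv())
    e
  })
  if (!is.null(names)) names(streams) <- names
  streams
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Evaluate a drawing expression under a stream's state, then save it back.
stream_eval <- function(stream, fn) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  assign(".Random.seed", stream$state, envir = globalenv())
  out <- fn()
  stream$state <- get(".Random.seed", envir = globalenv())
  out
}

#' @rdname rng_streams
#' @param stream A stream created by [rng_streams()].
#' @param ... Passed to the underlying draw function.
#' @export
stream_rnorm <- function(stream, ...) stream_eval(stream, function() stats::rnorm(...))

#' @rdname rng_streams
#' @export
stream_runif <- function(stream, ...) stream_eval(stream, function() stats::runif(...))
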