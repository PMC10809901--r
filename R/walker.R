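# A deliberately old-fashioned 1D random-walk simulator that keeps its whole
# state in a module-level environment, the way many stateful scientific codes
# keep theirs in globals. Two instances of this simulator cannot coexist in
# one process -- stepping one scrambles the other -- which is exactly the
# limitation that hosting it as a memory-isolated service removes.

.walker <- new.env(parent = emptyenv())
.walker$initialized <- FALSE

# Per-instance seeded RNG stream: the draw state lives with the simulator (or
# instance), never in the caller's global stream, so a service and an oracle
# replay share an identical, replayable sign stream.
seedRNGState <- function(seed) {
  old <- preserveGlobalSeed()
  on.exit(restoreGlobalSeed(old))
  set.seed(seed)
  get(".Random.seed", envir = globalenv())
}

withRNGState <- function(holder, field, expr) {
  old <- preserveGlobalSeed()
  on.exit(restoreGlobalSeed(old))
  assign(".Random.seed", get(field, envir = holder), envir = globalenv())
  res <- expr
  assign(field, get(".Random.seed", envir = globalenv()), envir = holder)
  res
}

preserveGlobalSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restoreGlobalSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' The bare module-level random-walk simulator
#'
#' A 1D random walker whose position updates by `pos <- pos +/- step_size`,
#' each sign drawn with probability 1/2 from a dedicated stream seeded at
#' initialization, so that a trajectory is fully determined by
#' `(seed, step_size, start)`. All state — position, step size, and the draw
#' stream — lives at module level in the package namespace: only one walker
#' can exist per process. (The exact update rule and defaults — start 0,
#' step size 1, unit fair steps — are this package's canonical reading of the
#' classic 1D random walk.)
#'
#' * `walkerInit(start, step_size, seed)` (re)initializes the simulator.
#' * `walkerStep()` applies one update and invisibly returns the new position;
#'   calling it before `walkerInit()` raises an uninitialized error.
#' * `walkerGetPos()` / `walkerSetPos(pos)` read / overwrite the position.
#' * `walkerReset()` clears all module-level state.
#'
#' @param start Starting position (dimensionless).
#' @param step_size Positive step magnitude.
#' @param seed Integer seed for the sign stream.
#' @param pos New position for `walkerSetPos()`.
#' @return `walkerGetPos()` and `walkerStep()` return the current position.
#' @examples
#' walkerInit(0, 1, seed = 42L)
#' for (i in 1:10) walkerStep()
#' walkerGetPos()
#' walkerReset()
#' @export
walkerInit <- function(start = 0, step_size = 1, seed = 12345L) {
  stopifnot(is.numeric(start), length(start) == 1L,
            is.numeric(step_size), length(step_size) == 1L, step_size > 0)
  .walker$pos <- as.numeric(start)
  .walker$stepSize <- as.numeric(step_size)
  .walker$rng <- seedRNGState(seed)
  .walker$initialized <- TRUE
  invisible(.walker$pos)
}

#' @rdname walkerInit
#' @export
walkerStep <- function() {
  if (!isTRUE(.walker$initialized)) {
    stop(pxCondition("proxysimUninitializedError",
                     "walkerStep() called before walkerInit()"))
  }
  sgn <- withRNGState(.walker, "rng", sample(c(-1, 1), 1L))
  .walker$pos <- .walker$pos + sgn * .walker$stepSize
  invisible(.walker$pos)
}

#' @rdname walkerInit
#' @export
walkerGetPos <- function() {
  if (!isTRUE(.walker$initialized)) {
    stop(pxCondition("proxysimUninitializedError",
                     "walker not initialized"))
  }
  .walker$pos
}

#' @rdname walkerInit
#' @export
walkerSetPos <- function(pos) {
  stopifnot(is.numeric(pos), length(pos) == 1L)
  if (!isTRUE(.walker$initialized)) {
    stop(pxCondition("proxysimUninitializedError",
                     "walker not initialized"))
  }
  .walker$pos <- as.numeric(pos)
  invisible(.walker$pos)
}

#' @rdname walkerInit
#' @export
walkerReset <- function() {
  rm(list = ls(.walker), envir = .walker)
  .walker$initialized <- FALSE
  invisible(NULL)
}
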