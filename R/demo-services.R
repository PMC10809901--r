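# Reference service implementations: the module-level random walker wrapped
# behind the lifecycle interface, and a fine-scale particle relaxation system
# used as the inner simulator of the two-scale coupled demo.

#' Service interface implementation for the module-level walker
#'
#' Wraps the bare simulator of [walkerInit()] behind the uniform lifecycle:
#' `init` seeds and places the walker at the configured start, `step` applies
#' one `+/- step_size` update (and always continues), and `finish` records the
#' final position in the instance state. Beyond the lifecycle it exposes
#' `get_pos()` and `set_pos(pos)`, so a proxy to a walker service has those
#' same two methods. The wrapper takes no special care about module-level
#' state — it uses the simulator exactly as standalone code would — because
#' each service instance gets a whole process to itself.
#'
#' A private member `.jump(distance)` (excluded from the manifest, like all
#' dot-prefixed members) can be exposed at runtime as the service function
#' `"jump"` by calling the public `enable_jump()` method: a minimal example of
#' an instance extending its own proxy interface while it runs.
#'
#' @return A `ServiceImplementation`. Constructor arguments: `start` (default
#'   0), `step_size` (default 1), `seed` (default 12345).
#' @seealso [randomWalkerService()], [walkerInit()]
#' @export
randomWalkerImplementation <- function() {
  serviceImplementation(
    "RandomWalkerService",
    constructor = function(self, start = 0, step_size = 1, seed = 12345L) {
      self$start <- start
      self$stepSize <- step_size
      self$seed <- seed
      self$nSteps <- 0
    },
    run = function(self) NULL,
    init = function(self) walkerInit(self$start, self$stepSize, self$seed),
    start = function(self) NULL,
    step = function(self) {
      walkerStep()
      self$nSteps <- self$nSteps + 1
      TRUE
    },
    finish = function(self) self$finalPos <- walkerGetPos(),
    methods = list(
      get_pos = function(self) walkerGetPos(),
      set_pos = function(self, pos) walkerSetPos(pos),
      enable_jump = function(self) {
        svc <- currentService()
        jump <- svc$impl$methods[[".jump"]]
        registerServiceFunction(svc, function(distance) jump(svc$self, distance),
                                "jump")
        invisible(TRUE)
      },
      .jump = function(self, distance) {
        walkerSetPos(walkerGetPos() + distance)
        walkerGetPos()
      }
    ),
    metrics = function(self) c(steps_taken = as.numeric(self$nSteps))
  )
}

#' Fine-scale particle relaxation implementation
#'
#' The inner simulator of the two-scale coupled demo: `M` particles with
#' positions `y_i` relax toward a target `x` set by the orchestrator, one
#' substep applying
#' `y_i <- y_i + alpha * (x - y_i) + sigma * xi_i`, with `xi_i` standard
#' normal draws from the instance's own seeded stream. With `sigma = 0` the
#' gap contracts geometrically: after `k` substeps,
#' `y_i - x = (1 - alpha)^k * (y_i0 - x)` exactly, which is the closed form
#' the coupled demo's tests lean on.
#'
#' Beyond the lifecycle it exposes methods `set_target(x)`, `get_target()`
#' and `get_positions()`, plus `target` as a readable/writable property (each
#' property access is one remote round trip; values are copies).
#'
#' @return A `ServiceImplementation`. Constructor arguments: `n_particles`
#'   (default 5), `alpha` in (0, 1] (default 0.5), `sigma >= 0` (default 0),
#'   `seed` (default 0), `y0` (initial positions; default spread evenly on
#'   \[-1, 1\]).
#' @seealso [runCoupledDemo()]
#' @export
fineRelaxerImplementation <- function() {
  serviceImplementation(
    "FineRelaxerService",
    constructor = function(self, n_particles = 5L, alpha = 0.5, sigma = 0,
                           seed = 0L, y0 = NULL) {
      stopifnot(n_particles >= 1L, alpha > 0, alpha <= 1, sigma >= 0)
      self$n <- as.integer(n_particles)
      self$alpha <- alpha
      self$sigma <- sigma
      self$seed <- seed
      self$y0 <- if (is.null(y0)) seq(-1, 1, length.out = self$n) else {
        stopifnot(length(y0) == n_particles)
        as.numeric(y0)
      }
    },
    run = function(self) NULL,
    init = function(self) {
      self$y <- self$y0
      self$target <- 0
      self$rng <- seedRNGState(self$seed)
    },
    start = function(self) NULL,
    step = function(self) {
      noise <- if (self$sigma > 0) {
        self$sigma * withRNGState(self, "rng", stats::rnorm(self$n))
      } else 0
      self$y <- self$y + self$alpha * (self$target - self$y) + noise
      TRUE
    },
    finish = function(self) NULL,
    methods = list(
      set_target = function(self, x) {
        stopifnot(is.numeric(x), length(x) == 1L)
        self$target <- as.numeric(x)
        invisible(NULL)
      },
      get_target = function(self) self$target,
      get_positions = function(self) self$y
    ),
    properties = list(
      target = list(
        get = function(self) self$target,
        set = function(self, value) self$target <- as.numeric(value)
      )
    )
  )
}

#' Create a random-walker simulation service
#'
#' The registered factory for the walker: each call launches a fresh,
#' memory-isolated walker service and returns its proxy. Because every
#' instance owns a whole process, any number of walkers — a simulator that is
#' single-instance by construction — can run simultaneously.
#'
#' @param ... Constructor arguments (`start`, `step_size`, `seed`) plus
#'   [createService()]'s `linger`/`timeout`.
#' @return A `SimServiceProxy`.
#' @examples
#' \dontrun{
#' w <- randomWalkerService(seed = 1L)
#' serviceRun(w); serviceInit(w); serviceStart(w)
#' for (i in 1:100) serviceStep(w)
#' w$get_pos()
#' closeService(w)
#' }
#' @export
randomWalkerService <- function(...) createService("RandomWalker", ...)

#' @rdname randomWalkerService
#' @export
fineRelaxerService <- function(...) createService("FineRelaxer", ...)

registerDemoServices <- function() {
  if (!("RandomWalker" %in% registeredServices())) {
    registerService("RandomWalker", randomWalkerImplementation())
  }
  if (!("FineRelaxer" %in% registeredServices())) {
    registerService("FineRelaxer", fineRelaxerImplementation())
  }
  invisible(NULL)
}
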