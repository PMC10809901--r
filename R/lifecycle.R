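#' Service lifecycle statuses
#'
#' Every simulation service, local or remote, moves through the same execution
#' state machine:
#' `CONSTRUCTED -> RUNNING -> INITIALIZED -> STARTED -> FINISHED`, with
#' `FAILED` reachable from any state when a hook raises an error. `FINISHED`
#' and `FAILED` are terminal for lifecycle calls; status queries (and, for
#' `FINISHED`, ordinary interface methods) remain available.
#'
#' @return `serviceStatuses()` returns the character vector of all six
#'   statuses in lifecycle order (with `FAILED` last).
#' @export
serviceStatuses <- function() {
  c("CONSTRUCTED", "RUNNING", "INITIALIZED", "STARTED", "FINISHED", "FAILED")
}

# status required before each lifecycle operation; the operation's success
# status is given by .lifecycleNext.
.lifecyclePre <- c(
  run    = "CONSTRUCTED",
  init   = "RUNNING",
  start  = "INITIALIZED",
  step   = "STARTED",
  finish = "STARTED"
)

.lifecycleNext <- c(
  run    = "RUNNING",
  init   = "INITIALIZED",
  start  = "STARTED",
  step   = "STARTED",
  finish = "FINISHED"
)

#' Names reserved for the uniform service interface
#'
#' These names are provided on every proxy by the lifecycle layer and can
#' never be taken by implementation members or service functions.
#'
#' @return Character vector of reserved member names.
#' @export
lifecycleNames <- function() {
  c("run", "init", "start", "step", "finish", "status", "metrics")
}

#' Lifecycle operations
#'
#' The five lifecycle operations plus the side-effect-free status query. Each
#' operation is legal in exactly one status (see [serviceStatuses()]); calling
#' it in any other status raises a lifecycle-order error
#' (class `proxysimLifecycleError`) and leaves the service unchanged. A hook
#' that raises an error moves the service to `FAILED` (sticky: there is no
#' recovery transition) and the hook's error propagates to the caller.
#'
#' * `serviceRun()` performs simulator startup (resource allocation) and
#'   returns the new status, `"RUNNING"`.
#' * `serviceInit()` initializes simulation data; returns `TRUE` on success.
#' * `serviceStart()` applies initial conditions; returns `TRUE` on success.
#' * `serviceStep()` advances the simulation by one step and returns the step
#'   hook's continue/stop indicator (`TRUE` = may continue). The service stays
#'   `STARTED`, so `serviceStep()` may be called any number of times.
#' * `serviceFinish()` stores final data / releases resources; returns
#'   `"FINISHED"`. Only legal from `STARTED`.
#' * `serviceStatus()` returns the current status in every state, including
#'   `FAILED`, with no side effects.
#' * `serviceMetrics()` returns the implementation's performance metrics as a
#'   named numeric vector, or an empty one if the implementation supplies no
#'   metrics hook. The schema of the names is implementation-defined.
#'
#' @param service A local service (from [localService()]) or a service proxy
#'   (from [createService()] / [buildProxy()]).
#' @param ... Passed to methods.
#' @return See the per-operation descriptions above.
#' @seealso [serviceImplementation()], [createService()]
#' @examples
#' impl <- serviceImplementation(
#'   "Counter",
#'   constructor = function(self) self$n <- 0L,
#'   run = function(self) NULL,
#'   init = function(self) NULL,
#'   start = function(self) NULL,
#'   step = function(self) { self$n <- self$n + 1L; TRUE },
#'   finish = function(self) NULL,
#'   methods = list(count = function(self) self$n)
#' )
#' svc <- localService(impl)
#' serviceRun(svc); serviceInit(svc); serviceStart(svc)
#' serviceStep(svc); serviceStep(svc)
#' callMember(svc, "count")  # 2
#' serviceFinish(svc)
#' serviceStatus(svc)        # "FINISHED"
#' @export
serviceRun <- function(service, ...) UseMethod("serviceRun")

#' @rdname serviceRun
#' @export
serviceInit <- function(service, ...) UseMethod("serviceInit")

#' @rdname serviceRun
#' @export
serviceStart <- function(service, ...) UseMethod("serviceStart")

#' @rdname serviceRun
#' @export
serviceStep <- function(service, ...) UseMethod("serviceStep")

#' @rdname serviceRun
#' @export
serviceFinish <- function(service, ...) UseMethod("serviceFinish")

#' @rdname serviceRun
#' @export
serviceStatus <- function(service, ...) UseMethod("serviceStatus")

#' @rdname serviceRun
#' @export
serviceMetrics <- function(service, ...) UseMethod("serviceMetrics")

# ---- local (in-process) services --------------------------------------------

#' Instantiate a service implementation in the current process
#'
#' Builds a live service instance in the calling process, without any worker
#' or message passing. Local services obey exactly the same lifecycle contract
#' as remote ones and are the reference against which proxy behaviour is
#' defined: a proxy driven by some call history must observe the same results
#' as a local twin receiving the identical history. They are also what runs
#' inside a worker process.
#'
#' Note that a local service gives no memory isolation: two local instances of
#' a simulator with module-level state will collide, which is precisely what
#' worker-hosted services exist to prevent.
#'
#' @param impl A [serviceImplementation()].
#' @param args List of constructor arguments.
#' @return An object of class `SimService`.
#' @export
localService <- function(impl, args = list()) {
  validateImplementation(impl)
  self <- new.env(parent = emptyenv())
  svc <- structure(
    list2env(list(
      impl = impl,
      self = self,
      status = "CONSTRUCTED",
      stepCount = 0L,
      serviceFunctions = new.env(parent = emptyenv())
    ), envir = new.env(parent = emptyenv())),
    class = "SimService"
  )
  withCurrentService(svc, do.call(impl$constructor, c(list(self), args)))
  svc
}

.lifecycleCall <- function(service, op) {
  st <- service$status
  if (!identical(st, .lifecyclePre[[op]])) stopLifecycleOrder(op, st)
  hook <- service$impl$hooks[[op]]
  res <- withCallingHandlers(
    withCurrentService(service, hook(service$self)),
    error = function(e) service$status <- "FAILED"
  )
  service$status <- .lifecycleNext[[op]]
  logTransition(service$impl$className, op, service$status)
  res
}

#' @export
serviceRun.SimService <- function(service, ...) {
  .lifecycleCall(service, "run")
  service$status
}

#' @export
serviceInit.SimService <- function(service, ...) {
  .lifecycleCall(service, "init")
  TRUE
}

#' @export
serviceStart.SimService <- function(service, ...) {
  .lifecycleCall(service, "start")
  TRUE
}

#' @export
serviceStep.SimService <- function(service, ...) {
  res <- .lifecycleCall(service, "step")
  service$stepCount <- service$stepCount + 1L
  isTRUE(res)
}

#' @export
serviceFinish.SimService <- function(service, ...) {
  .lifecycleCall(service, "finish")
  service$status
}

#' @export
serviceStatus.SimService <- function(service, ...) service$status

#' @export
serviceMetrics.SimService <- function(service, ...) {
  hook <- service$impl$metrics
  if (is.null(hook)) return(stats::setNames(numeric(0), character(0)))
  out <- withCurrentService(service, hook(service$self))
  stopifnot(is.numeric(out))
  out
}

#' @export
print.SimService <- function(x, ...) {
  cat(sprintf("<SimService %s> status: %s, steps taken: %d\n",
              x$impl$className, x$status, x$stepCount))
  invisible(x)
}

# dispatch a non-lifecycle member (method, property, or service function) on a
# local service; shared verbatim by the worker's remote dispatch so that local
# twins and proxies resolve names identically: manifest members first, then
# service functions, else unknown-member.
callMemberInternal <- function(service, name, args = list(),
                               kind = c("METHOD", "PROPERTY_GET", "PROPERTY_SET")) {
  kind <- match.arg(kind)
  impl <- service$impl
  if (kind == "METHOD") {
    fn <- impl$methods[[name]]
    if (!is.null(fn)) {
      return(withCurrentService(service, do.call(fn, c(list(service$self), args))))
    }
    sf <- get0(name, envir = service$serviceFunctions, inherits = FALSE)
    if (!is.null(sf)) {
      return(withCurrentService(service, do.call(sf, args)))
    }
    stopUnknownMember(name)
  }
  prop <- impl$properties[[name]]
  if (kind == "PROPERTY_GET") {
    if (is.null(prop) || is.null(prop$get)) stopUnknownMember(name)
    return(withCurrentService(service, prop$get(service$self)))
  }
  if (is.null(prop) || is.null(prop$set)) stopUnknownMember(name)
  withCurrentService(service, prop$set(service$self, args[[1L]]))
  invisible(NULL)
}

#' Call an implementation-specific member on a local service
#'
#' Dispatches `name` against the service's manifest members first and its
#' service-function table second, mirroring exactly how a worker resolves a
#' proxy call.
#'
#' @param service A `SimService` from [localService()].
#' @param name Member name.
#' @param ... Arguments forwarded to the member.
#' @return The member's return value.
#' @export
callMember <- function(service, name, ...) {
  stopifnot(inherits(service, "SimService"))
  callMemberInternal(service, name, list(...), "METHOD")
}

# ---- current-service context -------------------------------------------------
# User code running inside a hook or member (locally or in a worker) can reach
# its own service via currentService(), e.g. to register service functions.

.pxContext <- new.env(parent = emptyenv())
.pxContext$current <- NULL

withCurrentService <- function(service, expr) {
  prev <- .pxContext$current
  .pxContext$current <- service
  on.exit(.pxContext$current <- prev)
  expr
}

#' The service whose hook or member is currently executing
#'
#' Inside a lifecycle hook, method, property accessor or service function,
#' returns the owning service instance; this is how simulation code registers
#' service functions on itself at runtime (see [registerServiceFunction()]).
#'
#' @return The active `SimService`, or an error if no service code is running.
#' @export
currentService <- function() {
  svc <- .pxContext$current
  if (is.null(svc)) {
    stop(pxCondition("proxysimContextError",
                     "currentService() called outside any service hook or member"))
  }
  svc
}

# lifecycle transition logging (stderr), enabled via options(proxysim.verbose=)
logTransition <- function(className, op, status) {
  if (isTRUE(getOption("proxysim.verbose", FALSE))) {
    message(sprintf("[proxysim] %s: %s -> %s", className, op, status))
  }
}
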