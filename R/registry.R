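# The service registry: names interface implementations, creates and destroys
# service instances through factories, and hosts the service-function
# mechanism. One registry exists per process (like the default cluster in
# parallel R); worker processes each have their own, which is what lets a
# service itself create and own nested services.

.registry <- new.env(parent = emptyenv())
.registry$entries <- list()     # service_name -> list(impl, manifest)
.registry$instances <- list()   # token -> list(serviceName, id, proxy)
.registry$nextInstance <- 1L

#' Register an interface implementation under a service name
#'
#' Registration is what makes an implementation launchable as a simulation
#' service: [createService()] looks implementations up by the registered name.
#' The implementation's interface is discovered once, at registration, and
#' becomes the manifest replicated onto every proxy.
#'
#' @param serviceName Unique, nonempty name for the implementation.
#' @param impl A [serviceImplementation()] conforming to the lifecycle
#'   contract (all five hooks present); a non-conforming object raises a
#'   contract error naming the missing hooks.
#' @return Invisibly, the registry entry: a list with `serviceName`, `impl`
#'   and `manifest`.
#' @examples
#' \dontrun{
#' registerService("RandomWalker", randomWalkerImplementation())
#' w <- createService("RandomWalker", seed = 1L)
#' }
#' @export
registerService <- function(serviceName, impl) {
  stopifnot(is.character(serviceName), length(serviceName) == 1L)
  if (!nzchar(serviceName)) stopRegistration("service name must be nonempty")
  if (!is.null(.registry$entries[[serviceName]])) {
    stopRegistration(sprintf("a service named '%s' is already registered", serviceName))
  }
  manifest <- discoverInterface(impl)  # also validates the contract
  entry <- list(serviceName = serviceName, impl = impl, manifest = manifest)
  .registry$entries[[serviceName]] <- entry
  invisible(entry)
}

#' Names of all registered implementations
#' @return Character vector of service names.
#' @export
registeredServices <- function() {
  names(.registry$entries) %||% character(0)
}

#' Create a live simulation service
#'
#' Looks up the named implementation, spawns a memory-isolated worker process,
#' constructs one instance inside it with the forwarded constructor arguments,
#' and returns a live proxy in `CONSTRUCTED` status. Every call creates a
#' fresh, fully independent instance — the point of the architecture is that
#' many instances of a stateful simulator can run simultaneously, each in its
#' own address space.
#'
#' @param serviceName A name previously passed to [registerService()].
#' @param ... Constructor arguments, forwarded to the implementation's
#'   constructor inside the worker. Must be serializable.
#' @param linger,timeout,grace See [spawnWorker()]; `grace` is unused here and
#'   reserved.
#' @return A `SimServiceProxy`.
#' @seealso [closeService()], [activeServices()], [serviceFactory()]
#' @export
createService <- function(serviceName, ..., linger = 5, timeout = NULL) {
  entry <- .registry$entries[[serviceName]]
  if (is.null(entry)) stopLookup(serviceName, registeredServices())
  ep <- spawnWorker(entry$impl, list(...), serviceName = serviceName,
                    linger = linger, timeout = timeout)
  handle <- structure(
    list(version = WIRE_VERSION, serviceName = serviceName, host = ep$host,
         port = ep$port, key = ep$key, pid = ep$pid, timeout = timeout,
         manifest = entry$manifest),
    class = "ProxyHandle"
  )
  px <- newProxy(endpoint = ep, handle = handle)
  id <- .registry$nextInstance
  .registry$nextInstance <- id + 1L
  .registry$instances[[ep$token]] <- list(serviceName = serviceName, id = id,
                                          proxy = px)
  px
}

#' Destroy a simulation service
#'
#' Shuts the worker down per the broker contract (clean `SHUTDOWN`, forcible
#' reap after `grace` seconds), forgets the instance, and leaves the proxy in
#' a state where subsequent calls raise transport errors. Idempotent: closing
#' an already-closed service returns `TRUE` and does nothing.
#'
#' @param proxy A `SimServiceProxy`.
#' @param grace Seconds to wait for a clean worker exit.
#' @return `TRUE` iff the worker exited cleanly (or was already gone).
#' @export
closeService <- function(proxy, grace = 5) {
  stopifnot(inherits(proxy, "SimServiceProxy"))
  ep <- proxy[["endpoint"]]
  forget <- function(token) {
    if (!is.null(token)) .registry$instances[[token]] <- NULL
  }
  if (is.null(ep)) {
    # detached proxy (from a handle): attach just to shut the worker down
    ep <- tryCatch(ensureEndpoint(proxy), error = function(e) NULL)
    if (is.null(ep)) return(TRUE)  # worker already gone
  }
  if (!isTRUE(ep$open)) {
    forget(ep$token)
    return(shutdownWorker(ep, grace = grace))  # verifies the process is gone
  }
  clean <- shutdownWorker(ep, grace = grace)
  forget(ep$token)
  clean
}

#' Snapshot of live service instances
#'
#' Lists the instances created by this registry that are still open, with each
#' one's current lifecycle status queried live from its worker. Instances
#' whose worker has vanished are dropped from the registry.
#'
#' @return A data frame with columns `serviceName`, `instanceId`, `status`.
#' @export
activeServices <- function() {
  out <- data.frame(serviceName = character(0), instanceId = integer(0),
                    status = character(0), stringsAsFactors = FALSE)
  for (token in names(.registry$instances)) {
    inst <- .registry$instances[[token]]
    st <- tryCatch(serviceStatus(inst$proxy),
                   proxysimTransportError = function(e) NULL)
    if (is.null(st)) {
      .registry$instances[[token]] <- NULL
      next
    }
    out[nrow(out) + 1L, ] <- list(inst$serviceName, inst$id, st)
  }
  out[order(out$instanceId), , drop = FALSE]
}

#' Close every live service created by this registry
#'
#' Registry-level teardown: shuts down all instances; afterwards
#' [activeServices()] is empty and no worker outlives the grace period.
#'
#' @param grace Seconds per worker to wait for clean exit.
#' @return Invisibly, the number of instances closed.
#' @export
closeAllServices <- function(grace = 5) {
  tokens <- names(.registry$instances)
  for (token in tokens) {
    inst <- .registry$instances[[token]]
    tryCatch(closeService(inst$proxy, grace = grace), error = function(e) NULL)
    .registry$instances[[token]] <- NULL
  }
  invisible(length(tokens))
}

#' Make a typed factory for a registered implementation
#'
#' Mirrors the idiomatic factory pattern for end-user applications: one line
#' yields a function that forwards its arguments to [createService()] for a
#' fixed service name, returning a fresh service per call.
#'
#' @param serviceName A registered service name.
#' @return `function(...)` returning a new `SimServiceProxy` per call.
#' @examples
#' \dontrun{
#' newWalker <- serviceFactory("RandomWalker")
#' w1 <- newWalker(seed = 1L); w2 <- newWalker(seed = 2L)
#' }
#' @export
serviceFactory <- function(serviceName) {
  force(serviceName)
  function(...) createService(serviceName, ...)
}

# ---- service functions ------------------------------------------------------

#' Attach a callable to a running service at runtime
#'
#' Service functions extend the interface of one *instance* while it runs:
#' once registered, the callable is available as a method (under
#' `exposedName`, default the callable's own name) on every proxy to that
#' worker, immediately and without any manifest refresh. Registration can
#' happen at any time between construction and worker shutdown, and typically
#' happens worker-side from the simulation's own code (hooks or methods) via
#' [currentService()]; registering through a proxy ships the closure to the
#' worker.
#'
#' Names colliding with a lifecycle operation or with an existing manifest
#' member are rejected with a collision error (never silently shadowed);
#' re-registering an existing service-function name replaces it, with a
#' message.
#'
#' @param x The service to extend: a `SimService` (worker-side or local) or a
#'   `SimServiceProxy`.
#' @param fn The callable. Any R function works: closures, or functions
#'   extracted from other objects.
#' @param exposedName Proxy-method name; defaults to the expression supplied
#'   for `fn` when it is a simple name.
#' @return Invisibly, the `ServiceFunctionRecord` (fields `exposedName`,
#'   `callable`).
#' @examples
#' impl <- serviceImplementation("Echo",
#'   run = function(self) NULL, init = function(self) NULL,
#'   start = function(self) NULL, step = function(self) TRUE,
#'   finish = function(self) NULL)
#' svc <- localService(impl)
#' double <- function(x) 2 * x
#' registerServiceFunction(svc, double)
#' callMember(svc, "double", 21)  # 42
#' @export
registerServiceFunction <- function(x, fn, exposedName = NULL) {
  # UseMethod re-matches the original arguments, so the defaulted name is
  # handed to methods through a retained local instead
  .defaultName <- if (is.null(exposedName)) {
    nm <- deparse(substitute(fn))
    if (!grepl("^[.A-Za-z][.A-Za-z0-9_]*$", nm)) {
      stop("supply exposedName when fn is not a simple function name")
    }
    nm
  } else {
    exposedName
  }
  UseMethod("registerServiceFunction")
}

#' @export
registerServiceFunction.SimService <- function(x, fn, exposedName = NULL) {
  if (is.null(exposedName)) exposedName <- .defaultName
  stopifnot(is.function(fn), is.character(exposedName), nzchar(exposedName))
  if (exposedName %in% lifecycleNames()) {
    stopCollision(exposedName, "a lifecycle operation")
  }
  if (exposedName %in% manifestNames(discoverInterface(x$impl))) {
    stopCollision(exposedName, sprintf("an interface member of %s", x$impl$className))
  }
  if (!is.null(get0(exposedName, envir = x$serviceFunctions, inherits = FALSE))) {
    message(sprintf("replacing service function '%s'", exposedName))
  }
  assign(exposedName, fn, envir = x$serviceFunctions)
  invisible(structure(list(exposedName = exposedName, callable = fn),
                      class = "ServiceFunctionRecord"))
}

#' @export
registerServiceFunction.SimServiceProxy <- function(x, fn, exposedName = NULL) {
  if (is.null(exposedName)) exposedName <- .defaultName
  stopifnot(is.function(fn), is.character(exposedName), nzchar(exposedName))
  checkSerializable(list(fn), "service function")
  callRemote(ensureEndpoint(x), "REGISTER_FUNCTION", exposedName,
             list(fn = fn))
  invisible(structure(list(exposedName = exposedName, callable = fn),
                      class = "ServiceFunctionRecord"))
}
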