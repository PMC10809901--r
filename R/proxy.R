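# Client-side proxy objects. A proxy exposes the uniform lifecycle operations
# plus every member of the service's discovered interface under its own name
# and signature, each call dispatched to the worker and its result returned by
# value. Proxies serialize to compact handles from which an equivalent proxy
# (reaching the SAME worker instance) is rebuilt, possibly in another process.

newProxy <- function(endpoint = NULL, handle) {
  px <- new.env(parent = emptyenv())
  px$endpoint <- endpoint
  px$handle <- handle
  px$manifest <- handle$manifest
  class(px) <- "SimServiceProxy"
  px
}

# connection is lazy: a proxy rebuilt from a handle only attaches to the
# worker on its first call, so building is cheap and a dead worker surfaces
# as a transport error at call time.
ensureEndpoint <- function(px) {
  ep <- px[["endpoint"]]
  if (!is.null(ep) && isTRUE(ep$open)) return(ep)
  if (!is.null(ep) && !isTRUE(ep$open)) {
    stopTransport(sprintf("service '%s' has been closed", px[["handle"]]$serviceName))
  }
  h <- px[["handle"]]
  ep <- connectWorker(h$host, h$port, h$key, h$serviceName, pid = h$pid,
                      timeout = h$timeout)
  assign("endpoint", ep, envir = px)
  ep
}

#' Build a proxy from a service handle
#'
#' Constructs the interactive proxy object for a live service. The proxy can
#' be treated as if it were the interface-implementation instance itself: it
#' carries the five lifecycle operations plus `status`, and every
#' manifest member under its own name and signature. Calls to names in neither
#' the manifest nor the worker's service-function table fail worker-side with
#' an unknown-member error, which means service functions registered after the
#' proxy was built are callable immediately, without refreshing.
#'
#' Construction is lazy and cheap; if the handle points at a dead worker the
#' transport error surfaces on the first call.
#'
#' @param handle A `ProxyHandle` (see [proxyHandle()]), or the handle embedded
#'   in a serialized proxy.
#' @return A `SimServiceProxy`.
#' @seealso [createService()], [serializeProxy()]
#' @export
buildProxy <- function(handle) {
  stopifnot(inherits(handle, "ProxyHandle"))
  if (!identical(handle$version, WIRE_VERSION)) {
    stopTransport(sprintf(
      "proxy handle format v%s does not match this build (v%d)",
      format(handle$version), WIRE_VERSION))
  }
  newProxy(endpoint = NULL, handle = handle)
}

#' Extract the serializable handle of a proxy
#'
#' The handle is a self-describing envelope (format version, service name,
#' connection descriptor, manifest) sufficient to reattach to the same worker
#' instance; it is what [serializeProxy()] writes.
#'
#' @param proxy A `SimServiceProxy`.
#' @return A `ProxyHandle`.
#' @export
proxyHandle <- function(proxy) {
  stopifnot(inherits(proxy, "SimServiceProxy"))
  h <- proxy[["handle"]]
  h$manifest <- proxy[["manifest"]]  # carry the freshest manifest we have
  h
}

#' Serialize a proxy; rebuild one from bytes
#'
#' `serializeProxy()` renders a proxy as a raw byte sequence;
#' `deserializeProxy()` rebuilds a functionally equivalent proxy from it. The
#' rebuilt proxy attaches to the *same* worker instance, so state set through
#' one proxy is visible through the other; this is how a live simulation is
#' shipped to parallel client contexts (e.g. batch execution). Ordinary
#' `serialize()`/`unserialize()` on a proxy works too, but drops the live
#' connection, which is re-established lazily.
#'
#' @param proxy A `SimServiceProxy`.
#' @param bytes A raw vector from `serializeProxy()`.
#' @return `serializeProxy()`: a raw vector. `deserializeProxy()`: a
#'   `SimServiceProxy`.
#' @export
serializeProxy <- function(proxy) {
  serialize(proxyHandle(proxy), NULL, xdr = TRUE)
}

#' @rdname serializeProxy
#' @export
deserializeProxy <- function(bytes) {
  stopifnot(is.raw(bytes))
  h <- unserialize(bytes)
  buildProxy(h)
}

#' Re-query a service's live interface
#'
#' Fetches the current union of the implementation's discovered members and
#' all service functions registered so far, and updates the proxy's dispatch
#' table. Because unknown names are resolved worker-side at call time anyway,
#' refreshing is needed only for introspection (e.g. `names(proxy)`), never
#' for calling a freshly registered function.
#'
#' @param proxy A `SimServiceProxy`.
#' @return The current `InterfaceManifest`.
#' @export
refreshManifest <- function(proxy) {
  stopifnot(inherits(proxy, "SimServiceProxy"))
  m <- callRemote(ensureEndpoint(proxy), "MANIFEST")
  assign("manifest", m, envir = proxy)
  m
}

# remote method invocation used by synthesized proxy members
proxyInvoke <- function(px, name, args) {
  checkSerializable(args, sprintf("argument to '%s'", name))
  callRemote(ensureEndpoint(px), "METHOD", name, args)
}

# synthesize a client-side function with the member's own formals, so that
# arity errors (unused arguments) fail client-side exactly as they would on
# the real member; supplied arguments are evaluated in the caller's frame and
# shipped by value.
makeProxyMethod <- function(px, record) {
  fmls <- list()
  for (p in record$parameterNames) {
    fmls[[p]] <- if (p %in% names(record$defaults)) record$defaults[[p]] else quote(expr = )
  }
  f <- function() NULL
  formals(f) <- as.pairlist(fmls)
  body(f) <- quote({
    .caller <- parent.frame()
    .supplied <- as.list(match.call(expand.dots = TRUE))[-1L]
    .args <- lapply(.supplied, eval, envir = .caller)
    proxyInvoke(.px, .name, .args)
  })
  env <- new.env(parent = asNamespace("proxysim"))
  env$.px <- px
  env$.name <- record$name
  environment(f) <- env
  f
}

# forwarding member for names not (yet) in the cached manifest: the worker
# resolves the name against its live tables at call time.
makeForwardingMethod <- function(px, name) {
  f <- function(...) proxyInvoke(.px, .name, list(...))
  env <- new.env(parent = asNamespace("proxysim"))
  env$.px <- px
  env$.name <- name
  environment(f) <- env
  f
}

makeLifecycleMethod <- function(px, op) {
  f <- function() callRemote(ensureEndpoint(.px), "LIFECYCLE", .op)
  env <- new.env(parent = asNamespace("proxysim"))
  env$.px <- px
  env$.op <- op
  environment(f) <- env
  f
}

#' @export
`$.SimServiceProxy` <- function(x, name) {
  if (startsWith(name, ".") || name %in% c("endpoint", "handle", "manifest")) {
    return(get0(sub("^\\.", "", name), envir = x, inherits = FALSE))
  }
  if (name %in% lifecycleNames()) return(makeLifecycleMethod(x, name))
  m <- x[["manifest"]]
  if (!is.null(manifestRecord(m, name, "PROPERTY_READ"))) {
    # property read: one remote round trip per access, value semantics
    return(callRemote(ensureEndpoint(x), "PROPERTY_GET", name))
  }
  rec <- manifestRecord(m, name, "METHOD")
  if (!is.null(rec)) return(makeProxyMethod(x, rec))
  makeForwardingMethod(x, name)
}

#' @export
`$<-.SimServiceProxy` <- function(x, name, value) {
  m <- x[["manifest"]]
  if (!is.null(manifestRecord(m, name, "PROPERTY_WRITE"))) {
    checkSerializable(list(value), sprintf("value for property '%s'", name))
    callRemote(ensureEndpoint(x), "PROPERTY_SET", name, value)
    return(x)
  }
  stopUnknownMember(name)
}

#' @export
names.SimServiceProxy <- function(x) {
  c(lifecycleNames(), manifestNames(x[["manifest"]]))
}

#' @export
print.SimServiceProxy <- function(x, ...) {
  h <- x[["handle"]]
  ep <- x[["endpoint"]]
  state <- if (is.null(ep)) "detached" else if (isTRUE(ep$open)) "attached" else "closed"
  cat(sprintf("<SimServiceProxy %s> worker %s:%d (%s)\n",
              h$serviceName, h$host, h$port, state))
  print(x[["manifest"]])
  invisible(x)
}

# lifecycle generics dispatch remotely for proxies
#' @export
serviceRun.SimServiceProxy <- function(service, ...) {
  callRemote(ensureEndpoint(service), "LIFECYCLE", "run")
}

#' @export
serviceInit.SimServiceProxy <- function(service, ...) {
  callRemote(ensureEndpoint(service), "LIFECYCLE", "init")
}

#' @export
serviceStart.SimServiceProxy <- function(service, ...) {
  callRemote(ensureEndpoint(service), "LIFECYCLE", "start")
}

#' @export
serviceStep.SimServiceProxy <- function(service, ...) {
  callRemote(ensureEndpoint(service), "LIFECYCLE", "step")
}

#' @export
serviceFinish.SimServiceProxy <- function(service, ...) {
  callRemote(ensureEndpoint(service), "LIFECYCLE", "finish")
}

#' @export
serviceStatus.SimServiceProxy <- function(service, ...) {
  callRemote(ensureEndpoint(service), "LIFECYCLE", "status")
}

#' @export
serviceMetrics.SimServiceProxy <- function(service, ...) {
  callRemote(ensureEndpoint(service), "LIFECYCLE", "metrics")
}
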