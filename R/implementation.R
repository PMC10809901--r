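#' Define a simulation-service interface implementation
#'
#' An interface implementation wraps an existing simulator behind the uniform
#' service lifecycle. It supplies the five lifecycle hooks — `run` (startup,
#' e.g. allocating resources), `init` (initializing data), `start` (applying
#' initial conditions), `step` (integrating one step in time; returns a
#' continue/stop indicator), and `finish` (storing final data) — plus any
#' number of simulator-specific public methods and properties. The hooks are
#' only ever invoked through the public lifecycle operations
#' ([serviceRun()] and friends), never directly by clients.
#'
#' Every hook and method receives the instance state environment `self` as its
#' first argument; `constructor(self, ...)` populates it from the forwarded
#' construction arguments. Hooks take no further arguments. A hook may be a
#' no-op (`function(self) NULL`), but all five must be present for the
#' implementation to conform to the contract (checked at registration and
#' discovery).
#'
#' Members whose names begin with a dot are private: they are excluded from
#' the discovered interface and cannot be called through a proxy (they remain
#' reachable from inside the implementation, and can be exposed later under a
#' public name as service functions). Method and property names must not
#' shadow the reserved lifecycle names ([lifecycleNames()]), which every proxy
#' provides uniformly.
#'
#' Implementations are ordinary R values built from closures, so they can be
#' serialized and shipped to a worker process. Closures are serialized
#' together with their enclosing environments *except* the global environment
#' and package namespaces, which are stored by reference; an implementation
#' must therefore not rely on ad-hoc objects left in the caller's global
#' environment.
#'
#' @param className Name of the implementation (used in manifests and
#'   display).
#' @param constructor `function(self, ...)` that initializes the instance
#'   state environment. Construction arguments from [createService()] /
#'   [localService()] are forwarded after `self`.
#' @param run,init,start,step,finish The five lifecycle hooks,
#'   `function(self)`. `step` must return `TRUE` while the simulation may
#'   continue and `FALSE` to signal natural termination (a simulation with no
#'   natural end returns `TRUE` forever).
#' @param methods Named list of public methods `function(self, ...)`.
#' @param properties Named list of properties; each entry is a list with
#'   components `get = function(self)` and/or `set = function(self, value)`.
#' @param metrics Optional `function(self)` returning a named numeric vector
#'   of performance metrics. The naming schema is left to the implementation.
#' @return An object of class `ServiceImplementation`.
#' @seealso [discoverInterface()], [registerService()], [localService()]
#' @export
serviceImplementation <- function(className,
                                  constructor = function(self, ...) NULL,
                                  run = NULL, init = NULL, start = NULL,
                                  step = NULL, finish = NULL,
                                  methods = list(), properties = list(),
                                  metrics = NULL) {
  stopifnot(is.character(className), length(className) == 1L, nzchar(className),
            is.function(constructor), is.list(methods), is.list(properties))
  hooks <- list(run = run, init = init, start = start, step = step, finish = finish)
  badNames <- intersect(c(names(methods), names(properties)), lifecycleNames())
  if (length(badNames)) {
    stop(pxCondition("proxysimNameError", sprintf(
      "member name(s) %s shadow reserved lifecycle names",
      paste(sQuote(badNames), collapse = ", "))))
  }
  if (length(methods) && (is.null(names(methods)) || any(!nzchar(names(methods))))) {
    stop("all methods must be named")
  }
  for (p in properties) {
    stopifnot(is.list(p), all(names(p) %in% c("get", "set")))
  }
  structure(
    list(className = className, constructor = constructor, hooks = hooks,
         methods = methods, properties = properties, metrics = metrics),
    class = "ServiceImplementation"
  )
}

#' @export
print.ServiceImplementation <- function(x, ...) {
  cat(sprintf("<ServiceImplementation %s>\n", x$className))
  print(discoverInterface(x))
  invisible(x)
}

# contract check: all five hooks present and callable
validateImplementation <- function(impl, what = NULL) {
  if (!inherits(impl, "ServiceImplementation")) {
    stopContract(c("run", "init", "start", "step", "finish"),
                 what %||% "object (not a ServiceImplementation)")
  }
  missingHooks <- names(impl$hooks)[!vapply(impl$hooks, is.function, logical(1))]
  if (length(missingHooks)) {
    stopContract(missingHooks, what %||% impl$className)
  }
  invisible(impl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

isPrivateName <- function(name) startsWith(name, ".")

# ---- interface discovery -----------------------------------------------------

signatureRecord <- function(name, kind, fn = NULL) {
  parameterNames <- character(0)
  defaults <- list()
  if (kind == "METHOD" && !is.null(fn)) {
    fm <- formals(fn)
    fm <- fm[setdiff(names(fm), "self")]
    parameterNames <- names(fm)
    hasDefault <- !vapply(fm, function(d) is.symbol(d) && !nzchar(as.character(d)),
                          logical(1))
    defaults <- lapply(fm[hasDefault], function(d) d)
  }
  structure(list(name = name, kind = kind, parameterNames = parameterNames,
                 defaults = defaults),
            class = "MethodSignatureRecord")
}

#' Discover the implementation-specific public interface
#'
#' Inspects an implementation and returns the manifest of members it defines
#' beyond the uniform lifecycle interface: public methods with their
#' signatures (parameter names and defaults, excluding the implicit `self`
#' receiver) and readable/writable properties. Lifecycle hooks and
#' dot-prefixed private members never appear in a manifest. The manifest is
#' what gets replicated onto generated proxy objects.
#'
#' @param impl A [serviceImplementation()].
#' @return An `InterfaceManifest`: a list of `MethodSignatureRecord`s with the
#'   implementation name attached.
#' @examples
#' # a walker exposes get_pos/set_pos beyond the lifecycle interface
#' m <- discoverInterface(randomWalkerImplementation())
#' manifestNames(m)
#' @export
discoverInterface <- function(impl) {
  validateImplementation(impl)
  records <- list()
  for (nm in names(impl$methods)) {
    if (isPrivateName(nm)) next
    records[[length(records) + 1L]] <- signatureRecord(nm, "METHOD", impl$methods[[nm]])
  }
  for (nm in names(impl$properties)) {
    if (isPrivateName(nm)) next
    p <- impl$properties[[nm]]
    if (!is.null(p$get)) {
      records[[length(records) + 1L]] <- signatureRecord(nm, "PROPERTY_READ")
    }
    if (!is.null(p$set)) {
      records[[length(records) + 1L]] <- signatureRecord(nm, "PROPERTY_WRITE")
    }
  }
  newManifest(records, impl$className)
}

newManifest <- function(records, implementationName) {
  nm <- vapply(records, function(r) paste(r$name, r$kind), character(1))
  if (anyDuplicated(nm)) stop("duplicate manifest records")
  structure(list(records = records, implementationName = implementationName),
            class = "InterfaceManifest")
}

#' Manifest accessors
#'
#' `manifestNames()` returns the unique member names in a manifest;
#' `manifestRecord()` retrieves the record(s) for one member, optionally
#' restricted to a member kind (`"METHOD"`, `"PROPERTY_READ"`,
#' `"PROPERTY_WRITE"`).
#'
#' @param manifest An `InterfaceManifest`.
#' @param name Member name.
#' @param kind Optional member kind filter.
#' @return `manifestNames()`: character vector. `manifestRecord()`: a
#'   `MethodSignatureRecord` or `NULL`.
#' @export
manifestNames <- function(manifest) {
  unique(vapply(manifest$records, `[[`, character(1), "name"))
}

#' @rdname manifestNames
#' @export
manifestRecord <- function(manifest, name, kind = NULL) {
  for (r in manifest$records) {
    if (r$name == name && (is.null(kind) || r$kind == kind)) return(r)
  }
  NULL
}

# manifest of the live service = static interface plus registered service
# functions (each a METHOD record); computed worker-side on MANIFEST requests.
liveManifest <- function(service) {
  m <- discoverInterface(service$impl)
  for (nm in ls(service$serviceFunctions)) {
    m$records[[length(m$records) + 1L]] <-
      signatureRecord(nm, "METHOD", get(nm, envir = service$serviceFunctions))
  }
  m
}

#' @export
print.InterfaceManifest <- function(x, ...) {
  cat(sprintf("<InterfaceManifest %s> %d record(s)\n",
              x$implementationName, length(x$records)))
  for (r in x$records) {
    sig <- if (r$kind == "METHOD") sprintf("(%s)", paste(r$parameterNames, collapse = ", ")) else ""
    cat(sprintf("  %-14s %s%s\n", r$kind, r$name, sig))
  }
  invisible(x)
}

#' @export
format.MethodSignatureRecord <- function(x, ...) {
  sprintf("%s [%s]", x$name, x$kind)
}
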