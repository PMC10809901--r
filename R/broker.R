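# Client side of the broker: spawning memory-isolated workers and the
# synchronous request/response channel that drives them.
#
# A worker is a separate R process started with Rscript. Spawn bootstraps over
# a one-shot listening socket on the client: the worker connects back,
# authenticates with a spawn key, receives the serialized implementation and
# constructor arguments, constructs the instance in its isolated memory space,
# opens its own listening socket for reattachment (serialized proxies), and
# reports its pid and port. The bootstrap connection then becomes the client's
# endpoint.

# ---- helpers ----------------------------------------------------------------

# run expr under a private RNG state so broker internals (ports, keys) never
# perturb the caller's random number stream.
withPrivateRNG <- function(expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed((as.integer(Sys.time()) %% 1000000L) * 1000L +
             Sys.getpid() %% 1000L + sample.int(1000L, 1L))
  expr
}

randomKey <- function() {
  paste(sample(c(letters, LETTERS, 0:9), 24L, replace = TRUE), collapse = "")
}

# bind a listening socket on a random high port, retrying on collisions
openListenSocket <- function(attempts = 64L) {
  for (i in seq_len(attempts)) {
    port <- sample(20000:59999, 1L)
    sock <- tryCatch(serverSocket(port), error = function(e) NULL)
    if (!is.null(sock)) return(list(socket = sock, port = port))
  }
  stopTransport("could not bind a listening socket after repeated attempts")
}

#' Is a worker process still alive?
#'
#' @param pid Process id.
#' @return `TRUE` if a process with that id exists.
#' @keywords internal
#' @export
processAlive <- function(pid) {
  isTRUE(suppressWarnings(tools::pskill(pid, 0L)))
}

# poll until a process is gone or the deadline passes
waitProcessExit <- function(pid, timeout) {
  deadline <- Sys.time() + timeout
  while (Sys.time() < deadline) {
    if (!processAlive(pid)) return(TRUE)
    Sys.sleep(0.05)
  }
  !processAlive(pid)
}

# ---- endpoints --------------------------------------------------------------

newEndpoint <- function(con, host, port, key, pid, serviceName, timeout = NULL) {
  ep <- new.env(parent = emptyenv())
  ep$con <- con
  ep$host <- host
  ep$port <- port          # worker's own listening port (reattachment)
  ep$key <- key
  ep$pid <- pid
  ep$serviceName <- serviceName
  ep$nextId <- 1L
  ep$open <- TRUE
  ep$poisoned <- FALSE     # a timed-out request desynchronizes the stream
  ep$timeout <- timeout    # default per-call timeout in seconds; NULL = none
  class(ep) <- "ServiceEndpoint"
  trackEndpoint(ep)
  ep
}

closeEndpointConnection <- function(ep) {
  if (!is.null(ep$con)) {
    tryCatch(close(ep$con), error = function(e) NULL)
    ep$con <- NULL
  }
  ep$open <- FALSE
  untrackEndpoint(ep)
  invisible(NULL)
}

# ---- spawn ------------------------------------------------------------------

#' Launch an implementation in a memory-isolated worker process
#'
#' Starts a fresh R worker process, constructs one instance of `impl` inside
#' it with the forwarded constructor arguments, and returns the client-side
#' endpoint once the worker has entered its dispatch loop. Each worker holds
#' exactly one instance in its own address space, so simulators that keep
#' module-level state can run many instances concurrently without collision.
#'
#' Constructor arguments are checked for serializability before any process is
#' created; an offending value raises a serialization error naming its
#' position. A constructor that fails inside the worker raises a spawn error
#' carrying the remote error text, and the worker is reaped.
#'
#' Most code should use [createService()], which layers naming and bookkeeping
#' on top of this primitive.
#'
#' @param impl A [serviceImplementation()].
#' @param args List of constructor arguments.
#' @param serviceName Label carried by the endpoint (defaults to the
#'   implementation's class name).
#' @param linger Seconds a worker stays alive waiting for a new connection
#'   after its last client connection drops; past that it exits on its own, so
#'   no worker outlives its clients by more than this grace period.
#' @param timeout Default per-call timeout in seconds for this endpoint
#'   (`NULL`, the default, waits indefinitely: simulation steps may be long).
#' @param spawnTimeout Seconds to wait for the worker to boot.
#' @return A `ServiceEndpoint`.
#' @keywords internal
#' @export
spawnWorker <- function(impl, args = list(), serviceName = impl$className,
                        linger = 5, timeout = NULL, spawnTimeout = 60) {
  validateImplementation(impl)
  checkSerializable(args, "constructor argument")
  implFrame <- encodeFrame(impl, "implementation")

  boot <- withPrivateRNG({
    key <- randomKey()
    ls <- openListenSocket()
    list(key = key, socket = ls$socket, port = ls$port)
  })
  on.exit(tryCatch(close(boot$socket), error = function(e) NULL), add = TRUE)

  expr <- sprintf("proxysim:::workerMain('127.0.0.1',%dL,'%s')", boot$port, boot$key)
  logFile <- file.path(tempdir(), sprintf("proxysim-worker-%s.log", boot$key))
  system2(file.path(R.home("bin"), "Rscript"),
          c("--vanilla", "-e", shQuote(expr)),
          env = paste0("R_LIBS=", shQuote(paste(.libPaths(), collapse = .Platform$path.sep))),
          stdout = logFile, stderr = logFile, wait = FALSE)

  if (!socketSelect(list(boot$socket), timeout = spawnTimeout)) {
    stopSpawn(sprintf("worker did not connect within %gs (log: %s)",
                      spawnTimeout, logFile))
  }
  con <- socketAccept(boot$socket, blocking = TRUE, open = "a+b",
                      timeout = max(spawnTimeout, 30))
  hello <- readFrame(con)
  if (is.null(hello) || !identical(hello$key, boot$key)) {
    close(con)
    stopSpawn("worker handshake failed")
  }
  checkWireVersion(hello)

  setup <- list(version = WIRE_VERSION, impl = implFrame, args = args,
                linger = linger, serviceName = serviceName)
  writeFrame(con, encodeFrame(setup, "worker setup"))
  ready <- readFrame(con)
  if (is.null(ready)) {
    close(con)
    stopSpawn("worker died during construction")
  }
  if (!isTRUE(ready$ok)) {
    close(con)
    waitProcessExit(hello$pid, 5)
    if (processAlive(hello$pid)) tools::pskill(hello$pid)
    stopSpawn(sprintf("constructor failed in worker: %s", ready$error$message),
              remoteError = ready$error)
  }
  newEndpoint(con, "127.0.0.1", ready$port, boot$key, hello$pid, serviceName,
              timeout = timeout)
}

# open an additional client connection to a live worker (deserialized proxies)
connectWorker <- function(host, port, key, serviceName, pid = NA_integer_,
                          timeout = NULL, connectTimeout = 10) {
  con <- tryCatch(
    suppressWarnings(socketConnection(host, port = port, blocking = TRUE,
                                      open = "a+b", timeout = connectTimeout)),
    error = function(e) stopTransport(sprintf(
      "cannot reach worker at %s:%d (worker gone?): %s", host, port,
      conditionMessage(e)))
  )
  writeFrame(con, encodeFrame(list(version = WIRE_VERSION, key = key), "attach"))
  ack <- readFrame(con)
  if (is.null(ack) || !isTRUE(ack$ok)) {
    tryCatch(close(con), error = function(e) NULL)
    stopTransport("worker refused the connection (key or version mismatch)")
  }
  newEndpoint(con, host, port, key, as.integer(ack$pid %||% pid), serviceName,
              timeout = timeout)
}

# ---- request/response -------------------------------------------------------

#' Send one request to a worker and wait for its response
#'
#' The synchronous client half of the message contract: writes one
#' `RequestMessage` with a per-endpoint strictly increasing id and blocks
#' until the matching response arrives. A remote `ERROR` outcome is re-raised
#' as a wrapper condition carrying the remote category, message and stack
#' text; a dead worker or closed endpoint raises a transport error instead,
#' so the two failure modes are always distinguishable. With a timeout set,
#' an unanswered call raises a timeout error and poisons the endpoint (the
#' stream can no longer be trusted to pair requests with responses).
#'
#' @param endpoint A `ServiceEndpoint`.
#' @param kind Request kind: `LIFECYCLE`, `METHOD`, `PROPERTY_GET`,
#'   `PROPERTY_SET`, `REGISTER_FUNCTION`, `MANIFEST` or `SHUTDOWN`.
#' @param target Operation or member name.
#' @param payload Argument bundle.
#' @param timeout Seconds to wait for the response; default the endpoint's
#'   configured timeout; `NULL` waits indefinitely.
#' @return The deserialized response payload.
#' @keywords internal
#' @export
callRemote <- function(endpoint, kind, target = "", payload = NULL,
                       timeout = endpoint$timeout) {
  if (!isTRUE(endpoint$open) || is.null(endpoint$con)) {
    stopTransport(sprintf("endpoint to service '%s' is closed", endpoint$serviceName))
  }
  if (isTRUE(endpoint$poisoned)) {
    stopTransport("endpoint poisoned by an earlier timed-out request")
  }
  id <- endpoint$nextId
  endpoint$nextId <- id + 1L
  req <- requestMessage(id, kind, target, payload)
  frame <- encodeFrame(req, sprintf("request '%s'", target))
  tryCatch(writeFrame(endpoint$con, frame), error = function(e) {
    closeEndpointConnection(endpoint)
    stopTransport(sprintf("worker gone: could not send request (%s)",
                          conditionMessage(e)))
  })
  if (!is.null(timeout)) {
    if (!socketSelect(list(endpoint$con), timeout = timeout)) {
      endpoint$poisoned <- TRUE
      stopTimeout(sprintf("no response from service '%s' within %gs",
                          endpoint$serviceName, timeout))
    }
  }
  resp <- tryCatch(readFrame(endpoint$con), error = function(e) NULL)
  if (is.null(resp)) {
    closeEndpointConnection(endpoint)
    stopTransport("worker gone: connection closed before a response arrived")
  }
  checkWireVersion(resp)
  if (!identical(resp$id, id)) {
    closeEndpointConnection(endpoint)
    stopTransport(sprintf("protocol violation: response id %s for request id %d",
                          format(resp$id), id))
  }
  if (identical(resp$outcome, "ERROR")) {
    stopRemote(resp$error$category, resp$error$message, resp$error$trace)
  }
  resp$payload
}

# ---- shutdown ---------------------------------------------------------------

#' Shut down a worker process
#'
#' Best-effort, idempotent teardown: sends `SHUTDOWN`, waits up to
#' `grace` seconds for the worker to acknowledge and exit cleanly, and
#' forcibly reaps the process if it does not. Returns `TRUE` iff the exit was
#' clean (or the worker was already gone).
#'
#' @param endpoint A `ServiceEndpoint`.
#' @param grace Seconds to wait for a clean exit.
#' @return Logical.
#' @keywords internal
#' @export
shutdownWorker <- function(endpoint, grace = 5) {
  if (!isTRUE(endpoint$open) || is.null(endpoint$con)) {
    # already closed here; make sure the process really is gone
    if (!is.na(endpoint$pid) && processAlive(endpoint$pid)) {
      if (!waitProcessExit(endpoint$pid, grace)) {
        tools::pskill(endpoint$pid)
        waitProcessExit(endpoint$pid, 2)
        return(FALSE)
      }
    }
    return(TRUE)
  }
  clean <- FALSE
  if (!isTRUE(endpoint$poisoned)) {
    sent <- tryCatch({
      writeFrame(endpoint$con,
                 encodeFrame(requestMessage(endpoint$nextId, "SHUTDOWN")))
      endpoint$nextId <- endpoint$nextId + 1L
      TRUE
    }, error = function(e) FALSE)
    if (sent && socketSelect(list(endpoint$con), timeout = grace)) {
      resp <- tryCatch(readFrame(endpoint$con), error = function(e) NULL)
      clean <- !is.null(resp) && identical(resp$outcome, "OK")
    }
  }
  closeEndpointConnection(endpoint)
  if (!is.na(endpoint$pid)) {
    if (!waitProcessExit(endpoint$pid, if (clean) grace else grace)) {
      tools::pskill(endpoint$pid)
      waitProcessExit(endpoint$pid, 2)
      clean <- FALSE
    }
  }
  clean
}

# ---- client-exit hygiene ----------------------------------------------------
# Live endpoints are tracked in a session-level table whose finalizer runs at
# garbage collection of the tracker or R shutdown, sending SHUTDOWN to any
# endpoint still open. Workers additionally exit on their own once their last
# connection drops (the linger rule), which covers abnormal client death.

.endpointTracker <- new.env(parent = emptyenv())
.endpointTracker$live <- list()
.endpointTracker$n <- 0L

trackEndpoint <- function(ep) {
  .endpointTracker$n <- .endpointTracker$n + 1L
  ep$token <- sprintf("%s#%d", ep$key, .endpointTracker$n)
  .endpointTracker$live[[ep$token]] <- ep
  invisible(NULL)
}

untrackEndpoint <- function(ep) {
  if (!is.null(ep$token)) .endpointTracker$live[[ep$token]] <- NULL
  invisible(NULL)
}

shutdownAllEndpoints <- function(grace = 2) {
  for (ep in .endpointTracker$live) {
    tryCatch(shutdownWorker(ep, grace = grace), error = function(e) NULL)
  }
  .endpointTracker$live <- list()
  invisible(NULL)
}

#' @export
print.ServiceEndpoint <- function(x, ...) {
  cat(sprintf("<ServiceEndpoint %s> worker pid %s port %d (%s)\n",
              x$serviceName, format(x$pid), x$port,
              if (isTRUE(x$open)) "open" else "closed"))
  invisible(x)
}
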